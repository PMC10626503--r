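#' Sample-based Akaike Information Criterion of a fitted accumulator
#'
#' `AIC = 2k - 2 E[log p(y | x, z, theta)]`, where the expectation over the
#' latent paths is estimated by drawing `n_samples` continuous paths from
#' the Laplace posterior of each trial and averaging the Poisson emission
#' log-likelihood. `k` counts the trainable scalars of the architecture
#' (see [count_free_parameters()]). The Monte-Carlo standard error of the
#' expectation estimate is reported.
#'
#' @param fit a `fit_result`.
#' @param n_samples posterior draws (default 100).
#' @param seed seed for the posterior sampling.
#' @return list of class `model_score`: `aic`, `k`, `expected_ll`, `se`,
#'   `n_samples`, `model`.
#' @export
aic <- function(fit, n_samples = 100, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  spec <- fit$spec
  Tmax <- max(vapply(fit$y, nrow, integer(1)))
  pk <- spec_pack(spec, Tmax)
  totals <- numeric(n_samples)
  for (j in seq_along(fit$y)) {
    nbj <- nrow(fit$y[[j]])
    D <- spec$D
    Vu <- matrix(vapply(seq_len(spec$K),
                        function(k) as.numeric(spec$V[[k]] %*% fit$uvs[[j]]),
                        numeric(D)), nrow = D)
    eps <- matrix(stats::rnorm(nbj * D * n_samples), nbj * D, n_samples)
    ll <- cpp_trial_sample_ll(fit$y[[j]], Vu, pk$A, pk$Qi, pk$ldQ, pk$G,
                              pk$g0[seq_len(nbj), , drop = FALSE], spec$C,
                              spec$d, spec$dt, fit$post[[j]]$x,
                              fit$post[[j]]$q, fit$post[[j]]$xi, eps)
    totals <- totals + ll
  }
  ell <- mean(totals)
  se <- stats::sd(totals) / sqrt(n_samples)
  structure(list(aic = 2 * fit$k - 2 * ell, k = fit$k, expected_ll = ell,
                 se = se, n_samples = n_samples, model = fit$model_kind),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat("<model_score> ", x$model, ": AIC ", format(x$aic, digits = 8),
      " (k = ", x$k, ", E[ll] = ", format(x$expected_ll, digits = 8),
      " +/- ", format(x$se, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Evidence-conditioned explained variance of a fitted model
#'
#' Simulates spike counts from the fitted model `n_sims` times for every
#' trial, computes firing rates of data and simulation with a causal boxcar
#' of `boxcar` seconds, averages them across trials within each signed
#' evidence level (right minus left contrast), restricts time to the window
#' from the fit's latency until the median reaction time, and reports
#'
#' `R^2 = 1 - sum_e sum_t (f_data - f_model)^2 / sum_e sum_t (f_data - fbar)^2`
#'
#' with `fbar` the grand mean of the data traces over evidence levels and
#' times. 1 means the model firing rate matches the data exactly; 0 is the
#' grand-mean predictor; negative values are worse than the grand mean.
#'
#' @param fit a `fit_result`.
#' @param n_sims simulations per trial (default 100).
#' @param boxcar boxcar width (s).
#' @param seed simulation seed.
#' @return list of class `ev_r2`: `r2`, `data_traces`, `model_traces`
#'   (evidence x time matrices of population mean rates), `evidence_levels`,
#'   `time`.
#' @export
explained_variance <- function(fit, n_sims = 100, boxcar = 0.05, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  spec <- fit$spec
  dt <- spec$dt
  t_max_bins <- max(1L, floor(stats::median(fit$rt) / dt))

  data_rate <- lapply(fit$y, function(y) boxcar_rate(y, dt, boxcar))
  model_rate <- vector("list", length(fit$y))
  for (j in seq_along(fit$y)) {
    nbj <- nrow(fit$y[[j]])
    mc <- simulate_trial_ensemble(spec, fit$uvs[[j]], nbj, n_sims)
    model_rate[[j]] <- boxcar_rate(mc, dt, boxcar)
  }
  levs <- sort(unique(fit$evidence))
  nb_keep <- t_max_bins
  dtr <- mtr <- matrix(NA_real_, length(levs), nb_keep)
  for (li in seq_along(levs)) {
    i <- which(fit$evidence == levs[li])
    for (t in seq_len(nb_keep)) {
      avail <- i[vapply(fit$y[i], nrow, integer(1)) >= t]
      if (!length(avail)) next
      dtr[li, t] <- mean(vapply(avail, function(j)
        mean(data_rate[[j]][t, ]), numeric(1)))
      mtr[li, t] <- mean(vapply(avail, function(j)
        mean(model_rate[[j]][t, ]), numeric(1)))
    }
  }
  structure(list(r2 = explained_variance_r2(dtr, mtr),
                 data_traces = dtr, model_traces = mtr,
                 evidence_levels = levs,
                 time = fit$latency + (seq_len(nb_keep) - 0.5) * dt),
            class = "ev_r2")
}

#' Explained-variance core on evidence-by-time rate traces
#'
#' @param data_traces,model_traces numeric matrices (evidence levels x time
#'   points); NA cells are ignored pairwise.
#' @return scalar R-squared (1 = perfect, 0 = grand-mean predictor,
#'   negative = worse than the grand mean); NA with a warning when the data
#'   traces have zero variance.
#' @export
explained_variance_r2 <- function(data_traces, model_traces) {
  ok <- is.finite(data_traces) & is.finite(model_traces)
  d <- data_traces[ok]; m <- model_traces[ok]
  fbar <- mean(d)
  denom <- sum((d - fbar)^2)
  if (denom == 0) {
    warning("zero data variance; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((d - m)^2) / denom
}

# causal boxcar rate (Hz) of a counts matrix (bins x neurons)
boxcar_rate <- function(counts, dt, boxcar) {
  L <- max(1L, round(boxcar / dt))
  nb <- nrow(counts)
  out <- matrix(0, nb, ncol(counts))
  cs <- rbind(0, apply(counts, 2, cumsum))
  for (t in seq_len(nb)) {
    lo <- max(0L, t - L)
    out[t, ] <- (cs[t + 1L, ] - cs[lo + 1L, ]) / ((t - lo) * dt)
  }
  out
}

# mean spike counts over n_sims generative runs of one trial (vectorized
# across simulations; Gumbel-max sampling of the discrete transitions)
simulate_trial_ensemble <- function(spec, uv, nb, n_sims) {
  D <- spec$D; K <- spec$K
  G <- spec$gamma * spec$R
  bf <- boundary_factor(spec, 0:(nb - 1))
  X <- matrix(0, n_sims, D)
  z <- rep(1L, n_sims)
  moved <- rep(FALSE, n_sims)
  mean_counts <- matrix(0, nb, nrow(spec$C))
  Ls <- lapply(spec$Q, function(Q) t(chol(Q)))
  Vus <- lapply(spec$V, function(V) as.numeric(V %*% uv))
  for (t in seq_len(nb)) {
    g0 <- spec$gamma * c(0, rep(-spec$B * bf[t], K - 1))
    logits <- X %*% t(G) + matrix(g0, n_sims, K, byrow = TRUE)
    gum <- -log(-log(matrix(stats::runif(n_sims * K), n_sims, K)))
    znew <- max.col(logits + gum)
    z[!moved] <- znew[!moved]
    moved <- moved | z > 1L
    for (k in unique(z)) {
      i <- which(z == k)
      eps <- matrix(stats::rnorm(length(i) * D), length(i), D)
      X[i, ] <- X[i, , drop = FALSE] %*% t(spec$A[[k]]) +
        matrix(Vus[[k]], length(i), D, byrow = TRUE) +
        eps %*% t(Ls[[k]])
    }
    lam <- emission_rate(spec, X)                     # n_sims x N
    cnt <- matrix(stats::rpois(length(lam), lam), n_sims, ncol(lam))
    mean_counts[t, ] <- colMeans(cnt)
  }
  mean_counts
}

#' AIC-difference model comparison
#'
#' Rescales per-model AIC values as `Delta_i = AIC_i - AIC_min`. The best
#' model has `Delta = 0`; a subpopulation is assigned a preferred model only
#' when every other model has `Delta >= threshold` (default 10), otherwise
#' it is excluded from further analysis. Pairwise AIC differences
#' (single - independent race, single - dependent race, independent -
#' dependent race) are reported when the corresponding models are present.
#'
#' @param scores list of `model_score` objects (or a named numeric vector of
#'   AIC values; names are model identifiers).
#' @param threshold AIC-difference support threshold.
#' @return list of class `comparison_verdict`: `delta` (named), `preferred`
#'   (model name or `"excluded"`), `pairwise` (named numeric), `aic`.
#' @export
compare_models <- function(scores, threshold = 10) {
  if (is.list(scores) && all(vapply(scores, inherits, logical(1),
                                    "model_score"))) {
    aics <- vapply(scores, `[[`, numeric(1), "aic")
    names(aics) <- vapply(scores, `[[`, character(1), "model")
  } else {
    aics <- unlist(scores)
  }
  if (!length(aics)) stop("no model scores")
  delta <- aics - min(aics)
  n_supported <- sum(delta < threshold)
  preferred <- if (length(aics) == 1L) names(aics)[1]
  else if (n_supported > 1L) "excluded"
  else names(aics)[which.min(aics)]

  pw <- c()
  pair <- function(m1, m2, lab) {
    if (all(c(m1, m2) %in% names(aics)))
      pw[lab] <<- unname(aics[m1] - aics[m2])
  }
  pair("single", "independent_race", "delta_si")
  pair("single", "dependent_race", "delta_sd")
  pair("independent_race", "dependent_race", "delta_id")
  structure(list(delta = delta, preferred = preferred, pairwise = pw,
                 aic = aics, threshold = threshold),
            class = "comparison_verdict")
}

#' @export
print.comparison_verdict <- function(x, ...) {
  cat("<comparison_verdict> preferred:", x$preferred, "\n")
  print(round(x$delta, 2))
  invisible(x)
}
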