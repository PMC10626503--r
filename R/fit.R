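#' Fit an accumulator model to a subpopulation by variational Laplace-EM
#'
#' Alternates (a) a discrete E-step: forward-backward message passing over
#' the discrete states conditioned on the current continuous-latent mode,
#' (b) a continuous E-step: a Laplace approximation of the continuous-latent
#' posterior around its mode (damped Newton on the concave per-trial
#' objective), and (c) an M-step that updates only the trainable parameters
#' — the accumulation-state recurrent matrix and noise, the movement-state
#' noise, and the emission parameters C and d — holding the input weights V,
#' the transition parameters and the boundary fixed. The M-step uses the
#' full Laplace second moments, so the recurrent coefficient is not biased
#' by posterior smoothing. A greedy search over the initial-value grid keeps
#' the fit with the highest final objective (a Laplace estimate of the
#' marginal log-likelihood with the discrete chain marginalized exactly at
#' the continuous mode).
#'
#' Trials are filtered as in the modeling contract: equal-contrast trials
#' excluded, go trials only, reaction times within `rt_range`; each trial's
#' window runs from `latency` after stimulus onset until `post_move` after
#' wheel movement.
#'
#' @param dataset a `spike_dataset` for one subpopulation.
#' @param model_kind `"single"`, `"independent_race"` or
#'   `"dependent_race"`.
#' @param boundary_mode boundary mode (see [build_accumulator()]).
#' @param init_grid data.frame of initial values (default
#'   [accumulator_init_grid()]).
#' @param latency accumulation latency (s): neural activity before
#'   `stim_onset + latency` is excluded.
#' @param rt_range reaction-time filter (s).
#' @param post_move window extension past wheel movement (s).
#' @param dt fitting bin width (s).
#' @param gamma transition gain of the fitted spec (fixed, not trained).
#' @param max_em maximum EM iterations.
#' @param tol relative objective-change tolerance.
#' @param q_floor variance floor applied to noise updates.
#' @param seed seed for the Monte-Carlo draws of the emission update.
#' @param emission_mask optional N x D logical matrix of allowed emission
#'   weights. For the race architectures the default constrains each neuron
#'   to the latent of its preference side (contralateral neurons to the
#'   right-choice accumulator, ipsilateral to the left), matching the
#'   neuron-pool semantics of the race reformulation; an unconstrained 2-D
#'   emission map can rotate into a shared-gain axis that soaks up Poisson
#'   variability and defeats the AIC comparison.
#' @return object of class `fit_result`: learned `spec`, `elbo_trace`,
#'   `loglik`, per-trial posterior summaries (`x`, `q`, `xi`), the data used
#'   (`y`, `u`), `k` (free-parameter count), `init` (chosen combination),
#'   `converged`, `trial_idx`, `latency`, `dt`.
#' @export
fit_laplace_em <- function(dataset, model_kind, boundary_mode = "constant",
                           init_grid = NULL, latency = 0,
                           rt_range = c(0.15, 0.5), post_move = 0.05,
                           dt = 0.01, gamma = 25, max_em = 50, tol = 1e-6,
                           q_floor = 1e-6, seed = 1L, emission_mask = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  prep <- prepare_fit_trials(dataset, dt, latency, rt_range, post_move)
  if (length(prep$y) < 2) stop("fewer than 2 trials pass the filters")
  if (is.null(init_grid))
    init_grid <- accumulator_init_grid(model_kind, boundary_mode)
  if (is.null(emission_mask) && model_kind != "single") {
    pref <- dataset$neurons$pref_side
    emission_mask <- cbind(is.na(pref) | pref == "contra",
                           !is.na(pref) & pref == "ipsi")
  }

  best <- NULL
  for (i in seq_len(nrow(init_grid))) {
    g <- as.list(init_grid[i, , drop = FALSE])
    spec <- build_accumulator(model_kind, boundary_mode, init = g,
                              gamma = gamma, dt = dt)
    fit <- em_run(spec, prep, max_em, tol, q_floor, emission_mask)
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$init <- g
    }
  }
  best$trial_idx <- prep$trial_idx
  best$rt <- prep$rt
  best$evidence <- prep$evidence
  best$latency <- latency
  best$model_kind <- model_kind
  class(best) <- "fit_result"
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$model_kind, ", ", length(x$y), " trials, loglik ",
      format(x$loglik, digits = 8),
      if (x$converged) " (converged)" else " (max iterations)", "\n",
      sep = "")
  cat("  A_acc:", format(diag_or_all(x$spec$A[["acc"]]), digits = 4), "\n")
  invisible(x)
}

diag_or_all <- function(m) if (nrow(m) == 1) m[1, 1] else as.numeric(m)

# filter trials and bin counts per the modeling contract
prepare_fit_trials <- function(dataset, dt, latency, rt_range, post_move) {
  tr <- dataset$trials
  keep <- tr$contrast_left != tr$contrast_right &
    tr$choice %in% c("left", "right") & is.finite(tr$reaction_time) &
    tr$reaction_time > rt_range[1] & tr$reaction_time < rt_range[2]
  idx <- which(keep)
  y <- list(); u <- list()
  nn <- length(dataset$spikes)
  for (j in seq_along(idx)) {
    i <- idx[j]
    t0 <- tr$stim_onset[i] + latency
    t1 <- tr$wheel_move[i] + post_move
    nb <- max(2L, floor((t1 - t0) / dt + 1e-9))
    cnt <- matrix(0, nb, nn)
    for (n in seq_len(nn))
      cnt[, n] <- bin_sorted_spikes(dataset$spikes[[n]], t0, dt, nb)
    y[[j]] <- cnt
    u[[j]] <- c(right = tr$contrast_right[i], left = tr$contrast_left[i])
  }
  list(y = y, u = u, trial_idx = idx, rt = tr$reaction_time[idx],
       evidence = tr$contrast_right[idx] - tr$contrast_left[idx])
}

# input vector in model coordinates
input_vec <- function(spec, u) {
  if (spec$M == 1L) u[["right"]] - u[["left"]] else
    c(u[["right"]], u[["left"]])
}

# per-spec constant pieces for the C++ E-step
spec_pack <- function(spec, Tmax) {
  K <- spec$K; D <- spec$D
  A <- array(0, c(D, D, K)); Qi <- array(0, c(D, D, K)); ldQ <- numeric(K)
  for (k in seq_len(K)) {
    A[, , k] <- spec$A[[k]]
    Qi[, , k] <- solve(spec$Q[[k]])
    ldQ[k] <- determinant(spec$Q[[k]], logarithm = TRUE)$modulus
  }
  G <- spec$gamma * spec$R
  # g0[t, ]: gamma * effective r for the transition into step t (0-based t-1)
  bf <- boundary_factor(spec, 0:(Tmax - 1))
  g0 <- cbind(0, matrix(rep(-spec$B * bf, K - 1), ncol = K - 1)) * spec$gamma
  list(A = A, Qi = Qi, ldQ = ldQ, G = G, g0 = g0)
}

# deterministic noiseless latent path used to initialize EM
latent_proxy <- function(spec, uv, nb) {
  D <- spec$D
  X <- matrix(0, nb, D)
  x <- numeric(D)
  A <- spec$A[["acc"]]; Vu <- as.numeric(spec$V[["acc"]] %*% uv)
  for (t in seq_len(nb)) {
    x <- as.numeric(A %*% x + Vu)
    X[t, ] <- x
  }
  X
}

inverse_softplus <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-8))))

# one EM run from a fully initialized spec
em_run <- function(spec, prep, max_em, tol, q_floor, emission_mask = NULL) {
  nt <- length(prep$y)
  nn <- ncol(prep$y[[1]])
  D <- spec$D
  uvs <- lapply(prep$u, function(u) input_vec(spec, u))
  Tmax <- max(vapply(prep$y, nrow, integer(1)))

  # emission init: Poisson GLM of the counts on the deterministic proxy path
  Xp <- do.call(rbind, lapply(seq_len(nt), function(j)
    latent_proxy(spec, uvs[[j]], nrow(prep$y[[j]]))))
  Yall <- do.call(rbind, prep$y)
  d0 <- inverse_softplus(mean(Yall) / spec$dt)
  em0 <- emission_mstep(Xp, Yall, matrix(0, nn, D), d0, spec$dt,
                        mask = emission_mask)
  spec <- set_emissions(spec, em0$C, em0$d)
  spec$C_mask <- emission_mask

  xs <- lapply(seq_len(nt), function(j)
    latent_proxy(spec, uvs[[j]], nrow(prep$y[[j]])))
  elbo_trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_em)) {
    pk <- spec_pack(spec, Tmax)
    elbo <- 0
    post <- vector("list", nt)
    for (j in seq_len(nt)) {
      nbj <- nrow(prep$y[[j]])
      Vu <- vapply(seq_len(spec$K),
                   function(k) as.numeric(spec$V[[k]] %*% uvs[[j]]),
                   numeric(D))
      Vu <- matrix(Vu, nrow = D)
      es <- cpp_trial_estep(prep$y[[j]], Vu, pk$A, pk$Qi, pk$ldQ, pk$G,
                            pk$g0[seq_len(nbj), , drop = FALSE], spec$C,
                            spec$d, spec$dt, xs[[j]])
      post[[j]] <- es
      xs[[j]] <- es$x
      elbo <- elbo + es$logZ + es$emis_ll + 0.5 * es$logdetSigma +
        0.5 * nbj * D * log(2 * pi)
    }
    elbo_trace <- c(elbo_trace, elbo)
    if (it > 1 &&
        abs(elbo - elbo_trace[it - 1]) < tol * max(1, abs(elbo))) {
      converged <- TRUE
      break
    }
    spec <- mstep(spec, prep, post, uvs, q_floor, emission_mask)
  }
  list(spec = spec, elbo_trace = elbo_trace, loglik = elbo_trace[length(elbo_trace)],
       converged = converged, y = prep$y, u = prep$u, uvs = uvs,
       post = post, k = count_free_parameters(spec), dt = spec$dt)
}

# weighted second-moment sums for state k over all trials
state_moments <- function(prep, post, uvs, D, k) {
  S11 <- S01 <- S00 <- matrix(0, D, D)
  Su1 <- Su0 <- matrix(0, length(uvs[[1]]), D)
  wsum <- 0
  for (j in seq_along(post)) {
    es <- post[[j]]
    w <- es$q[, k]
    nb <- length(w)
    X <- es$x
    Xprev <- rbind(rep(0, D), X[-nb, , drop = FALSE])
    Stt <- matrix(es$Stt, D * D, nb)
    Sprev <- cbind(matrix(0, D * D, 1), Stt[, -nb, drop = FALSE])
    Soff <- matrix(es$Soff, D * D, nb)
    S00 <- S00 + matrix(Stt %*% w, D, D) + crossprod(X * w, X)
    S11 <- S11 + matrix(Sprev %*% w, D, D) + crossprod(Xprev * w, Xprev)
    S01 <- S01 + matrix(Soff %*% w, D, D) + crossprod(X * w, Xprev)
    Su1 <- Su1 + uvs[[j]] %o% colSums(Xprev * w)
    Su0 <- Su0 + uvs[[j]] %o% colSums(X * w)
    wsum <- wsum + sum(w)
  }
  list(S11 = S11, S01 = S01, S00 = S00, Su1 = Su1, Su0 = Su0, wsum = wsum)
}

apply_structure <- function(M, kind, type = c("A", "Q")) {
  type <- match.arg(type)
  if (kind %in% c("single", "independent_race")) M[row(M) != col(M)] <- 0
  if (type == "Q") M <- (M + t(M)) / 2
  M
}

floor_cov <- function(Q, q_floor) {
  e <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  e$values <- pmax(e$values, q_floor)
  e$vectors %*% diag(e$values, length(e$values)) %*% t(e$vectors)
}

mstep <- function(spec, prep, post, uvs, q_floor, emission_mask = NULL) {
  D <- spec$D
  V <- spec$V[["acc"]]

  # accumulation state: A by weighted least squares on the expected moments
  # (E[x x'] terms include the Laplace covariances), then Q from the
  # expected residual covariance
  sm <- state_moments(prep, post, uvs, D, 1L)
  if (sm$wsum > 1e-6) {
    VS1 <- V %*% sm$Su1                       # D x D
    S11r <- sm$S11 + diag(1e-10, D)
    if (spec$kind == "dependent_race") {
      A_new <- t(solve(S11r, t(sm$S01 - VS1)))
    } else if (D == 1) {
      A_new <- matrix((sm$S01[1, 1] - VS1[1, 1]) / S11r[1, 1], 1, 1)
    } else {
      A_new <- diag(diag(sm$S01 - VS1) / diag(S11r), D)
    }
    spec$A[["acc"]] <- A_new
  }
  spec$Q[["acc"]] <- floor_cov(apply_structure(
    residual_cov(spec, prep, post, uvs, 1L, spec$A[["acc"]], V),
    spec$kind, "Q"), q_floor)

  # movement states: noise only (A = I, V = 0)
  for (k in 2:spec$K) {
    wtot <- sum(vapply(post, function(es) sum(es$q[, k]), numeric(1)))
    if (wtot < 1e-3) next
    spec$Q[[k]] <- floor_cov(apply_structure(
      residual_cov(spec, prep, post, uvs, k, diag(1, D),
                   matrix(0, D, spec$M)),
      spec$kind, "Q"), q_floor)
  }

  # emissions: the emission term factorizes over bins, so the expected
  # log-likelihood is approximated with Monte-Carlo draws from the per-bin
  # marginal Laplace posteriors (a mode-only update drifts the latent scale)
  L <- 5L
  Xall <- do.call(rbind, lapply(post, function(es) sample_latent_bins(es, L)))
  Yall <- do.call(rbind, prep$y)
  Yrep <- Yall[rep(seq_len(nrow(Yall)), each = L), , drop = FALSE]
  em <- emission_mstep(Xall, Yrep, spec$C, spec$d, spec$dt,
                       mask = emission_mask)
  spec$C <- em$C
  spec$d <- em$d
  spec
}

# L draws per bin from N(mode_t, Sigma_tt), stacked bin-major
sample_latent_bins <- function(es, L) {
  X <- es$x
  nb <- nrow(X); D <- ncol(X)
  S <- matrix(es$Stt, D * D, nb)
  Xrep <- X[rep(seq_len(nb), each = L), , drop = FALSE]
  if (D == 1L) {
    Xrep + sqrt(rep(S[1, ], each = L)) * stats::rnorm(nb * L)
  } else {
    # per-bin 2x2 Cholesky, vectorized
    l11 <- sqrt(pmax(S[1, ], 0))
    l21 <- ifelse(l11 > 0, S[2, ] / l11, 0)
    l22 <- sqrt(pmax(S[4, ] - l21^2, 0))
    e1 <- stats::rnorm(nb * L); e2 <- stats::rnorm(nb * L)
    cbind(Xrep[, 1] + rep(l11, each = L) * e1,
          Xrep[, 2] + rep(l21, each = L) * e1 + rep(l22, each = L) * e2)
  }
}

# expected residual covariance E[(x_t - A x_{t-1} - V u)(...)'] under state k
residual_cov <- function(spec, prep, post, uvs, k, A, V) {
  D <- spec$D
  acc <- matrix(0, D, D)
  wsum <- 0
  for (j in seq_along(post)) {
    es <- post[[j]]
    w <- es$q[, k]
    nb <- length(w)
    X <- es$x
    Xprev <- rbind(rep(0, D), X[-nb, , drop = FALSE])
    c_t <- as.numeric(V %*% uvs[[j]])
    R <- X - Xprev %*% t(A) - matrix(c_t, nb, D, byrow = TRUE)
    Stt <- matrix(es$Stt, D * D, nb)
    Sprev <- cbind(matrix(0, D * D, 1),
                   matrix(es$Stt, D * D, nb)[, -nb, drop = FALSE])
    Soff <- matrix(es$Soff, D * D, nb)
    cov_part <- matrix(Stt %*% w, D, D) +
      A %*% matrix(Sprev %*% w, D, D) %*% t(A) -
      matrix(Soff %*% w, D, D) %*% t(A) -
      A %*% t(matrix(Soff %*% w, D, D))
    acc <- acc + crossprod(R * w, R) + cov_part
    wsum <- wsum + sum(w)
  }
  acc / max(wsum, 1e-12)
}

# Newton ascent of the pooled Poisson softplus emission likelihood in (C, d);
# `mask` (N x D logical) fixes structural zeros of the emission map
emission_mstep <- function(X, Y, C, d, dt, max_iter = 50, tol = 1e-9,
                           mask = NULL) {
  nn <- ncol(Y); D <- ncol(X)
  np <- nn * D + 1L
  if (!is.null(mask)) C[!mask] <- 0
  free <- if (is.null(mask)) rep(TRUE, np) else c(as.vector(t(mask)), TRUE)
  for (it in seq_len(max_iter)) {
    eta <- X %*% t(C) + d
    f <- softplus(eta)
    s <- sigmoid(eta)
    fpp <- s * (1 - s)
    ratio <- ifelse(eta < -30, 1, s / f)
    ratio2 <- ifelse(eta < -30, 0, (fpp * f - s^2) / f^2)
    G <- Y * ratio - s * dt
    Hd <- Y * ratio2 - fpp * dt          # <= 0
    # parameter order: C[1, 1:D], C[2, 1:D], ..., d
    H <- matrix(0, np, np)
    for (n in seq_len(nn)) {
      iset <- ((n - 1) * D + 1):(n * D)
      XH <- X * Hd[, n]
      H[iset, iset] <- crossprod(XH, X)
      H[iset, np] <- H[np, iset] <- colSums(XH)
    }
    H[np, np] <- sum(Hd)
    # grad ordering: C rows vectorized as (neuron, dim); fix to match
    gC <- t(crossprod(X, G))             # nn x D
    grad <- c(as.numeric(t(gC)), sum(G))
    step <- rep(0, np)
    step[free] <- tryCatch(
      solve(H[free, free, drop = FALSE] - diag(1e-10, sum(free)),
            grad[free]),
      error = function(e) rep(0, sum(free)))
    if (!all(is.finite(step))) break
    # Newton for a concave problem: move against H (negative definite)
    Cnew <- C - matrix(step[seq_len(nn * D)], nn, D, byrow = TRUE)
    dnew <- d - step[np]
    # backtracking on the objective
    obj <- function(Cm, dv) {
      e <- X %*% t(Cm) + dv
      sum(Y * (log_softplus(e) + log(dt)) - softplus(e) * dt)
    }
    o0 <- obj(C, d)
    alpha <- 1
    repeat {
      Ct <- C + alpha * (Cnew - C); dtt <- d + alpha * (dnew - d)
      o1 <- obj(Ct, dtt)
      if (is.finite(o1) && o1 >= o0 - 1e-10) break
      alpha <- alpha / 2
      if (alpha < 1e-6) { Ct <- C; dtt <- d; o1 <- o0; break }
    }
    moved <- max(abs(Ct - C), abs(dtt - d))
    C <- Ct; d <- dtt
    if (moved < 1e-8 || o1 - o0 < tol * max(1, abs(o0))) break
  }
  list(C = C, d = d)
}

log_softplus <- function(x) {
  out <- x                                   # x < -30: log softplus ~ x
  mid <- x >= -30 & x <= 30
  out[mid] <- log(log1p(exp(x[mid])))
  hi <- x > 30
  out[hi] <- log(x[hi])
  out
}
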