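#' Spike-count autocorrelation over fixed-length trials
#'
#' Pearson correlation of binned spike counts between every pair of time
#' bins `(i, j), j > i`, computed across trials separately per neuron and
#' pooled by lag `k = j - i` across bin pairs and neurons. With 200 ms
#' trials and 25 ms bins this gives 8 bins and 7 distinct lags. Zero
#' variance bins are dropped from the pooling.
#'
#' @param x either a trials x bins x neurons counts array (e.g. from
#'   [simulate_fixed_length()]), or a `spike_dataset` whose trials are
#'   fixed-length (binned from stimulus onset over `duration`).
#' @param delta bin width (s, default 0.025).
#' @param duration trial duration (s) when `x` is a `spike_dataset`.
#' @return object of class `autocorr_curve`: `lag` (1..L, in bins), `delta`,
#'   `value` (pooled correlation per lag), `n_pairs`, `pairs` (data.frame of
#'   all neuron/bin-pair correlations), `n_trials`.
#' @export
spike_count_autocorrelation <- function(x, delta = 0.025, duration = NULL) {
  if (inherits(x, "spike_dataset")) {
    if (is.null(duration))
      duration <- x$ground_truth$duration
    if (is.null(duration)) stop("duration required for a spike_dataset")
    bc <- bin_spike_counts(x, "stim_onset", c(0, duration), delta)
    counts <- bc$counts
  } else counts <- x
  nt <- dim(counts)[1]; nb <- dim(counts)[2]; nn <- dim(counts)[3]
  if (nt < 20) stop("need >= 20 fixed-length trials")

  lag_l <- list()
  for (n in seq_len(nn)) {
    M <- counts[, , n]
    sds <- apply(M, 2, stats::sd)
    cm <- suppressWarnings(stats::cor(M))
    for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
      if (sds[i] == 0 || sds[j] == 0) next
      lag_l[[length(lag_l) + 1L]] <- c(j - i, cm[i, j])
    }
  }
  if (!length(lag_l)) stop("all bins have zero variance")
  pairs <- as.data.frame(do.call(rbind, lag_l))
  names(pairs) <- c("lag", "r")
  lags <- seq_len(nb - 1)
  val <- vapply(lags, function(k) {
    v <- pairs$r[pairs$lag == k]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  np <- vapply(lags, function(k) sum(pairs$lag == k), numeric(1))
  structure(list(lag = lags, delta = delta, value = val, n_pairs = np,
                 pairs = pairs, n_trials = nt),
            class = "autocorr_curve")
}

# pool several curves (weighted by pair counts per lag)
pool_autocorr <- function(curves) {
  stopifnot(length(curves) >= 1)
  pairs <- do.call(rbind, lapply(curves, `[[`, "pairs"))
  lags <- sort(unique(pairs$lag))
  val <- vapply(lags, function(k) mean(pairs$r[pairs$lag == k]), numeric(1))
  np <- vapply(lags, function(k) sum(pairs$lag == k), numeric(1))
  structure(list(lag = lags, delta = curves[[1]]$delta, value = val,
                 n_pairs = np, pairs = pairs,
                 n_trials = sum(vapply(curves, `[[`, numeric(1),
                                       "n_trials"))),
            class = "autocorr_curve")
}

#' Exponential-decay fit of an autocorrelation curve
#'
#' Least-squares fit of `R(k Delta) = A (exp(-k Delta / tau) + B)` by the
#' Levenberg-Marquardt method, restricted to lags from the start lag on.
#' The start lag is the lag immediately after the largest single-step drop
#' of the pooled autocorrelation (to skip past negative adaptation at short
#' lags). Five initial parameter sets are tried and the fit with the lowest
#' mean squared error kept.
#'
#' @param curve an `autocorr_curve`.
#' @param inits data.frame of starting values (columns `A`, `B`, `tau`);
#'   default five fixed combinations spanning amplitudes 0.5-1, offsets
#'   0-0.1 and timescales 0.05-0.5 s.
#' @param min_lags minimum usable lags after start-lag truncation.
#' @param start_search fraction of the early lags searched for the
#'   adaptation drop (the start-lag rule targets negative adaptation at
#'   short lags; searching all lags would let sampling noise truncate the
#'   curve arbitrarily).
#' @return list of class `timescale_fit`: `A`, `B`, `tau` (s), `mse`,
#'   `start_lag`, `init`; or NULL (with a warning) when every fit fails.
#' @export
fit_timescale <- function(curve, inits = NULL, min_lags = 3,
                          start_search = 0.25) {
  if (is.null(inits))
    inits <- data.frame(A = c(1, 1, 0.5, 0.5, 0.75),
                        B = c(0, 0.1, 0, 0.1, 0.05),
                        tau = c(0.05, 0.2, 0.5, 0.05, 0.2))
  ok <- is.finite(curve$value)
  lags <- curve$lag[ok]; vals <- curve$value[ok]
  all_drops <- vals[-length(vals)] - vals[-1]
  n_search <- max(1L, ceiling(length(all_drops) * start_search))
  drops <- all_drops[seq_len(n_search)]
  # advance past an early drop only when it is anomalously large relative
  # to the typical decay step (the signature of negative adaptation);
  # smooth curves keep every lag
  start_lag <- lags[1]
  if (length(drops) && max(drops) > 1.5 * stats::median(all_drops))
    start_lag <- lags[which.max(drops) + 1L]
  use <- lags >= start_lag
  if (sum(use) < min_lags) {
    start_lag <- lags[1]
    use <- rep(TRUE, length(lags))
  }
  if (sum(use) < min_lags) stop("fewer than min_lags usable lags")
  df <- data.frame(lag_s = lags[use] * curve$delta, r = vals[use])

  best <- NULL
  for (i in seq_len(nrow(inits))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(r ~ A * (exp(-lag_s / tau) + B), data = df,
                        start = as.list(inits[i, ]),
                        lower = c(A = 1e-8, B = 0, tau = 1e-4),
                        upper = c(A = 2, B = 2, tau = 5),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    co0 <- stats::coef(fit)
    # a solution pinned at the tau bounds is degenerate, not a timescale
    if (co0["tau"] >= 5 - 1e-6 || co0["tau"] <= 2e-4) next
    mse <- mean(stats::residuals(fit)^2)
    if (is.null(best) || mse < best$mse) {
      co <- stats::coef(fit)
      best <- list(A = unname(co["A"]), B = unname(co["B"]),
                   tau = unname(co["tau"]), mse = mse,
                   start_lag = start_lag, init = i)
    }
  }
  if (is.null(best)) {
    warning("all exponential fits diverged")
    return(NULL)
  }
  class(best) <- "timescale_fit"
  best
}

#' Integration timescale of one subpopulation
#'
#' Simulates `n_samples` independent sets of fixed-length trials from the
#' subpopulation's (preferred) accumulator spec with the boundary disabled
#' (the latent stays in the accumulation state for the whole trial, input
#' zero), fits the exponential autocorrelation model to each set, and
#' returns the average timescale across sets.
#'
#' @param x an `accumulator_spec` (emissions set) or a `fit_result`.
#' @param n_samples number of simulated trial sets (default 50).
#' @param n_trials trials per set.
#' @param duration trial duration (s).
#' @param delta autocorrelation bin (s).
#' @param seed integer seed.
#' @return list of class `subpop_timescale`: `tau` (mean across sets), `sd`,
#'   `taus` (per set), `n_failed`, `curve` (pooled across sets).
#' @export
subpopulation_timescale <- function(x, n_samples = 50, n_trials = 1000,
                                    duration = 0.2, delta = 0.025,
                                    seed = 1L) {
  spec <- if (inherits(x, "fit_result")) x$spec else x
  stopifnot(inherits(spec, "accumulator_spec"))
  taus <- rep(NA_real_, n_samples)
  curves <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    sim <- simulate_fixed_length(spec, n_trials, duration,
                                 seed = seed + 7919L * (s - 1L),
                                 bin_out = delta)
    cv <- tryCatch(spike_count_autocorrelation(sim$counts, delta),
                   error = function(e) NULL)
    curves[[s]] <- cv
    if (is.null(cv)) next
    ft <- tryCatch(suppressWarnings(fit_timescale(cv)),
                   error = function(e) NULL)
    if (!is.null(ft)) taus[s] <- ft$tau
  }
  n_failed <- sum(is.na(taus))
  if (n_failed > n_samples / 2) {
    warning("more than half of the timescale fits failed")
    return(structure(list(tau = NA_real_, sd = NA_real_, taus = taus,
                          n_failed = n_failed, curve = NULL),
                     class = "subpop_timescale"))
  }
  structure(list(tau = mean(taus, na.rm = TRUE),
                 sd = stats::sd(taus, na.rm = TRUE), taus = taus,
                 n_failed = n_failed,
                 curve = pool_autocorr(Filter(Negate(is.null), curves))),
            class = "subpop_timescale")
}

#' Population-level timescales per region with bootstrap comparisons
#'
#' The population timescale of a region is fitted on the pooled
#' autocorrelation structure of all its subpopulations. Subpopulations are
#' resampled with replacement `n_boot` times to obtain a percentile
#' confidence interval; pairwise region differences are tested with a
#' Wilcoxon rank-sum test on the bootstrap samples, Bonferroni-corrected
#' over region pairs.
#'
#' @param region_curves named list: region name -> list of
#'   `autocorr_curve` objects (one per subpopulation).
#' @param n_boot bootstrap resamples (default 100).
#' @param level confidence level of the percentile interval.
#' @param seed integer seed.
#' @return list of class `region_timescales`: `table` (data.frame region,
#'   tau, ci_low, ci_high, n_subpops), `boot` (region x n_boot matrix of
#'   bootstrap taus), `pairwise` (data.frame region_a, region_b, p,
#'   p_corrected).
#' @export
population_timescale <- function(region_curves, n_boot = 100, level = 0.95,
                                 seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  regions <- names(region_curves)
  stopifnot(!is.null(regions))
  tab <- data.frame(region = regions, tau = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_,
                    n_subpops = vapply(region_curves, length, integer(1)),
                    stringsAsFactors = FALSE)
  boot <- matrix(NA_real_, length(regions), n_boot,
                 dimnames = list(regions, NULL))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  for (ri in seq_along(regions)) {
    curves <- region_curves[[ri]]
    ft <- tryCatch(suppressWarnings(fit_timescale(pool_autocorr(curves))),
                   error = function(e) NULL)
    tab$tau[ri] <- if (is.null(ft)) NA_real_ else ft$tau
    if (length(curves) < 2) next
    for (b in seq_len(n_boot)) {
      pick <- sample.int(length(curves), replace = TRUE)
      fb <- tryCatch(suppressWarnings(
        fit_timescale(pool_autocorr(curves[pick]))), error = function(e) NULL)
      boot[ri, b] <- if (is.null(fb)) NA_real_ else fb$tau
    }
    ci <- stats::quantile(boot[ri, ], qs, na.rm = TRUE, names = FALSE)
    tab$ci_low[ri] <- ci[1]; tab$ci_high[ri] <- ci[2]
  }
  pw <- NULL
  if (length(regions) >= 2) {
    cmb <- utils::combn(regions, 2)
    n_cmp <- ncol(cmb)
    pw <- data.frame(region_a = cmb[1, ], region_b = cmb[2, ],
                     p = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(n_cmp)) {
      xa <- boot[cmb[1, i], ]; xb <- boot[cmb[2, i], ]
      if (sum(is.finite(xa)) >= 2 && sum(is.finite(xb)) >= 2)
        pw$p[i] <- suppressWarnings(
          stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
    }
    pw$p_corrected <- pmin(1, pw$p * n_cmp)
  }
  structure(list(table = tab, boot = boot, pairwise = pw),
            class = "region_timescales")
}

#' Correlation between recurrent strength and integration timescale
#'
#' Per region, Pearson's correlation between the subpopulations' recurrent
#' connection strength (the single accumulator's recurrent coefficient, or
#' the mean of the two diagonal recurrent entries for race models) and their
#' integration timescale, with Bonferroni correction across regions.
#'
#' @param df data.frame with columns `region`, `strength`, `tau`.
#' @param min_n minimum subpopulations per region (use 10 for race-model
#'   analyses).
#' @return data.frame with `region`, `n`, `r`, `p`, `p_corrected`; regions
#'   with too few subpopulations or zero strength variance get NA (flagged
#'   in the `note` column).
#' @export
strength_timescale_correlation <- function(df, min_n = 3) {
  stopifnot(all(c("region", "strength", "tau") %in% names(df)))
  regions <- unique(df$region)
  out <- data.frame(region = regions, n = NA_integer_, r = NA_real_,
                    p = NA_real_, note = "", stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    sub <- df[df$region == regions[i] & is.finite(df$tau), ]
    out$n[i] <- nrow(sub)
    if (nrow(sub) < min_n) { out$note[i] <- "too few subpopulations"; next }
    if (stats::var(sub$strength) == 0) {
      out$note[i] <- "zero strength variance"; next
    }
    ct <- stats::cor.test(sub$strength, sub$tau, method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  n_tested <- sum(is.finite(out$p))
  out$p_corrected <- pmin(1, out$p * max(1, n_tested))
  out
}

#' Recurrent strength of a fitted or specified accumulator
#'
#' The single accumulator's scalar recurrent coefficient, or the average of
#' the two diagonal recurrent entries for race accumulators.
#'
#' @param x an `accumulator_spec` or `fit_result`.
#' @export
recurrent_strength <- function(x) {
  spec <- if (inherits(x, "fit_result")) x$spec else x
  mean(diag(spec$A[["acc"]]))
}
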