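#' Simulate a cohort of tuned inhomogeneous-Poisson neurons
#'
#' Fixture generator for the selectivity statistics: each neuron fires as an
#' inhomogeneous Poisson process whose rate, from `delay` seconds after
#' stimulus onset, is the baseline plus gain-weighted linear functions of the
#' contralateral (right-screen) contrast, the signed choice side (+1 right,
#' -1 left, 0 nogo) and the signed evidence. Negative instantaneous rates are
#' clipped at 0 (and counted in the ground truth). The true onset delay is
#' stored as ground-truth latency.
#'
#' @param n_neurons number of neurons.
#' @param tuning data.frame with columns `stim`, `choice`, `evidence` and
#'   optionally `outcome` (Hz per unit of each variable; `outcome` applies
#'   on hit trials), recycled to `n_neurons` rows; or a single list with
#'   those fields applied to all neurons.
#' @param baseline_rate baseline firing rate (Hz, >= 0).
#' @param trials a `trial_table`.
#' @param seed integer seed.
#' @param delay onset delay of the tuned modulation after stimulus onset (s).
#' @param duration length of the modulated epoch (s).
#' @param baseline_window pre-stimulus baseline epoch length (s).
#' @return a `spike_dataset`; `ground_truth$latency` holds `delay`,
#'   `ground_truth$tuning` the per-neuron gains, `ground_truth$n_clipped` the
#'   number of clipped trial-rates.
#' @export
make_selectivity_cohort <- function(n_neurons, tuning, baseline_rate = 10,
                                    trials, seed = 1L, delay = 0.05,
                                    duration = 0.8, baseline_window = 1.2) {
  stopifnot(n_neurons >= 1, baseline_rate >= 0)
  if (!is.data.frame(tuning)) tuning <- as.data.frame(tuning)
  for (col in c("stim", "choice", "evidence", "outcome"))
    if (is.null(tuning[[col]])) tuning[[col]] <- 0
  if (!all(is.finite(as.matrix(tuning[c("stim", "choice", "evidence",
                                        "outcome")]))))
    stop("tuning gains must be finite")
  tuning <- tuning[rep_len(seq_len(nrow(tuning)), n_neurons), , drop = FALSE]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  s_choice <- ifelse(trials$choice == "right", 1,
                     ifelse(trials$choice == "left", -1, 0))
  nt <- nrow(trials)
  n_clipped <- 0L
  spikes <- vector("list", n_neurons)
  for (n in seq_len(n_neurons)) {
    mod <- baseline_rate +
      tuning$stim[n] * trials$contrast_right +
      tuning$choice[n] * s_choice +
      tuning$evidence[n] * trials$evidence +
      tuning$outcome[n] * (trials$outcome == "hit")
    clipped <- mod < 0
    n_clipped <- n_clipped + sum(clipped)
    mod[clipped] <- 0
    acc <- vector("list", nt)
    for (i in seq_len(nt)) {
      on <- trials$stim_onset[i]
      # piecewise-constant rate: baseline up to onset+delay, modulated after
      nb <- stats::rpois(1, baseline_rate * (baseline_window + delay))
      ns <- stats::rpois(1, mod[i] * (duration - delay))
      acc[[i]] <- c(
        if (nb > 0) on - baseline_window + stats::runif(nb) *
          (baseline_window + delay) else numeric(0),
        if (ns > 0) on + delay + stats::runif(ns) * (duration - delay)
        else numeric(0))
    }
    spikes[[n]] <- sort(unlist(acc, use.names = FALSE))
  }
  pref <- ifelse(tuning$choice >= 0, "contra", "ipsi")
  neurons <- data.frame(neuron_id = seq_len(n_neurons), region = "synthetic",
                        pref_side = pref, stringsAsFactors = FALSE)
  spike_dataset(spikes, trials, neurons,
                ground_truth = list(latency = delay, tuning = tuning,
                                    baseline_rate = baseline_rate,
                                    n_clipped = n_clipped))
}

#' Simulate a Poisson population driven by a shared AR(1) latent
#'
#' Closed-form oracle for the timescale analysis: per trial, a latent AR(1)
#' process `x_t = a x_{t-1} + e_t` (stationary, unit variance) drives all
#' neurons through a linear rate map `rate = offset + gain * x` (Hz, clipped
#' at 0). The latent autocorrelation at lag k is exactly `a^k`, so the true
#' intrinsic timescale is `-step / log(a)` seconds, stored as ground truth.
#'
#' @param a AR(1) coefficient per step, in (0, 1).
#' @param step latent/count bin width (s).
#' @param n_trials number of fixed-length trials.
#' @param duration trial duration (s), a multiple of `step`.
#' @param rate_map list with `gain` and `offset` (Hz).
#' @param n_neurons neurons sharing the latent.
#' @param seed integer seed.
#' @return a `spike_dataset`; `ground_truth$tau` holds the true timescale (s)
#'   and `ground_truth$latents` the trials x bins latent matrix.
#' @export
make_ar1_population <- function(a, step = 0.025, n_trials = 1000,
                                duration = 0.2,
                                rate_map = list(gain = 20, offset = 20),
                                n_neurons = 10, seed = 1L) {
  if (!(a > 0 && a < 1)) stop("a must lie in (0, 1) for a stationary decay")
  nb <- round(duration / step)
  if (abs(nb * step - duration) > 1e-9)
    stop("duration must be a multiple of step")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  X <- matrix(0, n_trials, nb)
  x <- stats::rnorm(n_trials)                     # stationary unit variance
  sd_innov <- sqrt(1 - a^2)
  for (t in seq_len(nb)) {
    x <- a * x + sd_innov * stats::rnorm(n_trials)
    X[, t] <- x
  }
  lam <- pmax(0, rate_map$offset + rate_map$gain * X) * step
  spikes <- vector("list", n_neurons)
  onset <- (duration + 0.1) * (seq_len(n_trials) - 1) + 0.1
  for (n in seq_len(n_neurons)) {
    cnt <- matrix(stats::rpois(length(lam), lam), n_trials, nb)
    tot <- rowSums(cnt)
    acc <- vector("list", n_trials)
    for (i in which(tot > 0)) {
      acc[[i]] <- onset[i] + (rep(seq_len(nb), cnt[i, ]) - 1L) * step +
        stats::runif(tot[i]) * step
    }
    spikes[[n]] <- sort(unlist(acc, use.names = FALSE))
  }
  trials <- data.frame(trial = seq_len(n_trials),
                       contrast_left = 0, contrast_right = 0, evidence = 0,
                       choice = "nogo", outcome = "hit",
                       stim_onset = onset, wheel_move = NA_real_,
                       reaction_time = NA_real_, stringsAsFactors = FALSE)
  class(trials) <- c("trial_table", "data.frame")
  neurons <- data.frame(neuron_id = seq_len(n_neurons), region = "synthetic",
                        pref_side = "contra", stringsAsFactors = FALSE)
  spike_dataset(spikes, trials, neurons,
                ground_truth = list(tau = -step / log(a), a = a, step = step,
                                    duration = duration, latents = X))
}
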