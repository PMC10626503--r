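#' Simulate latents, discrete states and spike counts from a spec
#'
#' Runs the generative recursion of the switching model for each trial:
#' the latent starts at 0, the discrete state is sampled from
#' [transition_probs()] given the previous latent, the latent then evolves
#' under the sampled state's linear-Gaussian dynamics driven by a constant
#' input derived from the trial's contrasts, and spike counts are Poisson
#' draws from the softplus emission rate. A trial commits when the discrete
#' state first enters a movement state (which is absorbing); simulation
#' continues for `post_move` seconds afterwards. Trials that never cross
#' within `max_duration` are labeled nogo.
#'
#' @param spec an `accumulator_spec` with emissions set.
#' @param trials a `trial_table`.
#' @param seed integer seed.
#' @param max_duration maximum simulated accumulation time (s).
#' @param post_move simulated time after movement-state entry (s).
#' @return list with per-trial elements `latents` (T x D), `z` (integer state
#'   paths), `counts` (T x N), and vectors `choice`, `rt` (s, NA for nogo).
#' @export
simulate_accumulator <- function(spec, trials, seed = 1L, max_duration = 1.0,
                                 post_move = 0.05) {
  if (is.null(spec$C)) stop("emissions not set; see set_emissions()")
  stopifnot(nrow(trials) >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  dt <- spec$dt
  n_post <- round(post_move / dt)
  max_steps <- round(max_duration / dt)
  D <- spec$D
  nt <- nrow(trials)
  u_all <- trial_inputs(spec, trials)

  latents <- vector("list", nt); zpaths <- vector("list", nt)
  counts <- vector("list", nt)
  choice <- rep(NA_character_, nt); rt <- rep(NA_real_, nt)

  for (i in seq_len(nt)) {
    u <- u_all[i, ]
    x <- numeric(D)
    xs <- matrix(NA_real_, max_steps + n_post, D)
    zs <- integer(max_steps + n_post)
    move_step <- NA_integer_
    t <- 0L
    while (TRUE) {
      t <- t + 1L
      if (is.na(move_step)) {
        p <- transition_probs(spec, x, t - 1L)
        z <- sample.int(spec$K, 1L, prob = p)
        if (z > 1L) move_step <- t
      } else z <- zs[t - 1L]            # absorbing movement state
      mu <- spec$A[[z]] %*% x + spec$V[[z]] %*% u
      x <- as.numeric(mu + chol_mult(spec$Q[[z]], stats::rnorm(D)))
      xs[t, ] <- x; zs[t] <- z
      if (!is.na(move_step) && t >= move_step + n_post - 1L) break
      if (is.na(move_step) && t >= max_steps) break
    }
    xs <- xs[seq_len(t), , drop = FALSE]; zs <- zs[seq_len(t)]
    lam <- emission_rate(spec, xs)
    counts[[i]] <- matrix(stats::rpois(length(lam), lam), nrow = t)
    latents[[i]] <- xs; zpaths[[i]] <- zs
    if (!is.na(move_step)) {
      choice[i] <- unname(spec$choice_map[spec$states[zs[move_step]]])
      rt[i] <- move_step * dt
    } else choice[i] <- "nogo"
  }
  list(latents = latents, z = zpaths, counts = counts,
       choice = choice, rt = rt, dt = dt)
}

# per-trial constant input: evidence difference for the single accumulator,
# (right contrast, left contrast) for the races
trial_inputs <- function(spec, trials) {
  if (spec$M == 1L) {
    matrix(trials$contrast_right - trials$contrast_left, ncol = 1)
  } else {
    cbind(trials$contrast_right, trials$contrast_left)
  }
}

chol_mult <- function(Q, z) {
  if (length(z) == 1L) return(sqrt(Q[1, 1]) * z)
  t(chol(Q)) %*% z
}

#' Simulate a spike dataset from an accumulator spec
#'
#' Wraps [simulate_accumulator()] into a [spike_dataset()]: spike counts are
#' converted to spike times (uniform within their bin, offset by the trial's
#' stimulus onset), the trial table's choice, outcome, wheel-movement time and
#' reaction time are replaced by the model's boundary crossings, and baseline
#' inter-trial spiking at the emission rate of the resting latent
#' (`softplus(d)` Hz) is added so that baseline z-scoring is well defined.
#' The generating spec, latent paths and discrete paths are stored as ground
#' truth.
#'
#' @inheritParams simulate_accumulator
#' @param baseline_window window (s) before stimulus onset filled with
#'   baseline spiking.
#' @param region region label stored in the neuron metadata.
#' @return a `spike_dataset`.
#' @export
simulate_accumulator_dataset <- function(spec, trials, seed = 1L,
                                         max_duration = 1.0, post_move = 0.05,
                                         baseline_window = 1.2,
                                         region = "synthetic") {
  sim <- simulate_accumulator(spec, trials, seed, max_duration, post_move)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1003L)

  nn <- nrow(spec$C); nt <- nrow(trials)
  dt <- spec$dt
  base_rate <- softplus(spec$d)
  spikes <- vector("list", nn)
  for (n in seq_len(nn)) spikes[[n]] <- vector("list", nt)
  for (i in seq_len(nt)) {
    on <- trials$stim_onset[i]
    tb <- nrow(sim$counts[[i]])
    for (n in seq_len(nn)) {
      cnt <- sim$counts[[i]][, n]
      tot <- sum(cnt)
      ts <- if (tot > 0)
        on + (rep(seq_len(tb), cnt) - 1L) * dt + stats::runif(tot) * dt
      else numeric(0)
      nb <- stats::rpois(1, base_rate * baseline_window)
      bs <- if (nb > 0) on - stats::runif(nb) * baseline_window else numeric(0)
      spikes[[n]][[i]] <- c(bs, ts)
    }
  }
  spikes <- lapply(spikes, function(l) sort(unlist(l, use.names = FALSE)))

  trials$choice <- sim$choice
  trials$reaction_time <- sim$rt
  trials$wheel_move <- trials$stim_onset + sim$rt
  higher <- ifelse(trials$contrast_right > trials$contrast_left, "right",
              ifelse(trials$contrast_left > trials$contrast_right, "left",
                ifelse(trials$contrast_left == 0, "nogo", "either")))
  trials$outcome <- ifelse(
    (higher == sim$choice) | (higher == "either" & sim$choice != "nogo"),
    "hit", "miss")

  pref <- neuron_preferences(spec)
  neurons <- data.frame(neuron_id = seq_len(nn), region = region,
                        pref_side = pref, stringsAsFactors = FALSE)
  spike_dataset(spikes, trials, neurons,
                ground_truth = list(spec = spec, latents = sim$latents,
                                    z = sim$z, rt = sim$rt,
                                    choice = sim$choice, latency = 0))
}

# one-hemisphere convention: contra(lateral)-preferring neurons load
# positively on the right-choice latent (or the single latent); ipsi the
# reverse
neuron_preferences <- function(spec) {
  C <- spec$C
  if (spec$D == 1L) {
    ifelse(C[, 1] >= 0, "contra", "ipsi")
  } else {
    ifelse(C[, 1] >= C[, 2], "contra", "ipsi")
  }
}

#' Default emission weights for a simulated subpopulation
#'
#' Builds an N x D emission matrix following the one-hemisphere convention:
#' contra-preferring neurons load `+gain` on the single latent or the
#' right-choice accumulator; ipsi-preferring neurons load `-gain` on the
#' single latent or `+gain` on the left-choice accumulator.
#'
#' @param kind architecture name.
#' @param n_contra,n_ipsi neuron counts per preference side.
#' @param gain emission weight magnitude (approximate Hz of rate modulation
#'   per unit latent).
#' @return N x D matrix.
#' @export
default_emission_weights <- function(kind, n_contra = 2, n_ipsi = 2,
                                     gain = 15) {
  n <- n_contra + n_ipsi
  if (kind == "single") {
    matrix(c(rep(gain, n_contra), rep(-gain, n_ipsi)), ncol = 1)
  } else {
    rbind(
      if (n_contra > 0) cbind(rep(gain, n_contra), rep(0, n_contra)),
      if (n_ipsi > 0) cbind(rep(0, n_ipsi), rep(gain, n_ipsi)))
  }
}

#' Simulate fixed-length trials with the boundary disabled
#'
#' For timescale estimation: the latent stays in the accumulation state for
#' the full duration (no absorbing crossings, zero input) and spike counts
#' are emitted per model bin. Returns the counts re-binned at `bin_out` for
#' the autocorrelation analysis.
#'
#' @param spec an `accumulator_spec` with emissions set.
#' @param n_trials number of trials.
#' @param duration trial duration (s).
#' @param seed integer seed.
#' @param bin_out output count bin (s); must be a multiple of an integer
#'   number of model bins times `spec$dt` within rounding.
#' @return list `counts`: array trials x bins x neurons, `bin`: `bin_out`.
#' @export
simulate_fixed_length <- function(spec, n_trials, duration = 0.2, seed = 1L,
                                  bin_out = 0.025) {
  if (is.null(spec$C)) stop("emissions not set")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dt <- spec$dt
  steps <- round(duration / dt)
  D <- spec$D; nn <- nrow(spec$C)
  A <- spec$A[["acc"]]; Q <- spec$Q[["acc"]]
  L <- t(chol(Q))
  # stationary start so the autocorrelation is stationary over the window
  # (zero start if the dynamics are not stable)
  if (max(abs(eigen(A, only.values = TRUE)$values)) < 1) {
    Sig <- stationary_cov(A, Q)
    X <- matrix(stats::rnorm(n_trials * D), n_trials, D) %*% chol(Sig)
  } else {
    X <- matrix(0, n_trials, D)
  }
  counts <- array(0L, dim = c(n_trials, steps, nn))
  for (t in seq_len(steps)) {
    X <- X %*% t(A) + matrix(stats::rnorm(n_trials * D), n_trials, D) %*% t(L)
    lam <- emission_rate(spec, X)
    counts[, t, ] <- stats::rpois(length(lam), lam)
  }
  ratio <- bin_out / dt
  nb <- floor(steps * dt / bin_out + 1e-9)
  out <- array(0L, dim = c(n_trials, nb, nn))
  if (abs(ratio - round(ratio)) < 1e-8) {
    ratio <- round(ratio)
    for (b in seq_len(nb)) {
      idx <- ((b - 1L) * ratio + 1L):(b * ratio)
      out[, b, ] <- apply(counts[, idx, , drop = FALSE], c(1, 3), sum)
    }
  } else {
    # non-commensurate bins: spread counts uniformly within their model bin
    # as spike times, then re-bin at bin_out
    for (n in seq_len(nn)) for (i in seq_len(n_trials)) {
      cnt <- counts[i, , n]
      tot <- sum(cnt)
      if (tot == 0) next
      ts <- (rep(seq_len(steps), cnt) - 1L) * dt + stats::runif(tot) * dt
      idx <- floor(ts / bin_out) + 1L
      keep <- idx <= nb
      out[i, , n] <- tabulate(idx[keep], nbins = nb)
    }
  }
  list(counts = out, bin = bin_out)
}

# stationary covariance of x_t = A x_{t-1} + e, e ~ N(0, Q), by iteration
stationary_cov <- function(A, Q) {
  S <- Q
  for (i in 1:500) {
    S2 <- A %*% S %*% t(A) + Q
    if (max(abs(S2 - S)) < 1e-12) { S <- S2; break }
    S <- S2
  }
  S
}
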