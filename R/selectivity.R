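#' Area under the ROC curve from two spike-count samples
#'
#' Normalized Mann-Whitney U statistic: the probability that a random draw
#' from `b` exceeds a random draw from `a`, counting tied pairs as 0.5.
#' Computed from midranks of the pooled sample, which is algebraically
#' identical to pair counting with the half-tie rule.
#'
#' @param a,b nonempty numeric samples.
#' @return value in \[0, 1\]; `auroc(a, b) + auroc(b, a) == 1`.
#' @export
auroc <- function(a, b) {
  if (!length(a) || !length(b)) stop("auroc: empty sample")
  r <- rank(c(a, b))
  nb <- length(b)
  (sum(r[(length(a) + 1L):(length(a) + nb)]) - nb * (nb + 1) / 2) /
    (length(a) * nb)
}

# within-column midranks of a matrix, one frank() call via column offsets
colranks <- function(M) {
  n <- nrow(M); nc <- ncol(M)
  if (nc == 1L) return(matrix(data.table::frank(M[, 1]), n, 1))
  rng <- range(M)
  span <- (rng[2] - rng[1]) + 1
  v <- as.vector(M) + rep.int((seq_len(nc) - 1) * span, rep.int(n, nc))
  r <- data.table::frank(v)
  matrix(r - rep.int((seq_len(nc) - 1) * n, rep.int(n, nc)), n, nc)
}

# auROC per column of M (trials x times): P(b-row value > a-row value)
auroc_columns <- function(M, is_b) {
  nb <- sum(is_b); na <- nrow(M) - nb
  r <- colranks(M)
  (colSums(r[is_b, , drop = FALSE]) - nb * (nb + 1) / 2) / (na * nb)
}

#' Binned, smoothed and z-scored firing rates
#'
#' Spike counts in 0.005 s bins, smoothed with a causal half-Gaussian kernel
#' (SD 0.02 s, past bins only), and z-scored per neuron against the
#' across-trial mean and SD of the smoothed rate during the pre-stimulus
#' baseline (-0.9 to -0.1 s, stimulus aligned). Neurons with zero baseline SD
#' are flagged and their traces set to NA.
#'
#' @param dataset a `spike_dataset`.
#' @param align `"stim_onset"` or `"wheel_move"`.
#' @param window analysis window (s) relative to the alignment event.
#' @param bin bin width (s).
#' @param kernel_sd half-Gaussian SD (s).
#' @param baseline baseline window (s), stimulus aligned.
#' @return list with `rates` (trials x bins x neurons, z-scored), `time`
#'   (bin left edges), `trials` (retained trial rows), `excluded` (logical
#'   per neuron: zero baseline SD), `baseline_mean`, `baseline_sd`.
#' @export
preprocess_rates <- function(dataset, align = "stim_onset",
                             window = c(-0.1, 0.3), bin = 0.005,
                             kernel_sd = 0.02, baseline = c(-0.9, -0.1)) {
  kern <- half_gaussian_kernel(kernel_sd, bin)
  L <- length(kern) - 1L
  sm_win <- smoothed_counts(dataset, align, window, bin, kern)
  sm_base <- smoothed_counts(dataset, "stim_onset", baseline, bin, kern)

  nn <- length(dataset$spikes)
  mu <- sd <- numeric(nn)
  for (n in seq_len(nn)) {
    bvals <- sm_base$sm[, , n]
    mu[n] <- mean(bvals)
    sd[n] <- stats::sd(as.vector(bvals))
  }
  excluded <- !is.finite(sd) | sd == 0
  rates <- sm_win$sm
  for (n in seq_len(nn)) {
    rates[, , n] <- if (excluded[n]) NA_real_ else (rates[, , n] - mu[n]) / sd[n]
  }
  list(rates = rates, time = sm_win$time, trials = sm_win$trials,
       excluded = excluded, baseline_mean = mu, baseline_sd = sd, bin = bin)
}

half_gaussian_kernel <- function(sd, bin) {
  L <- ceiling(4 * sd / bin)
  w <- exp(-((0:L) * bin)^2 / (2 * sd^2))
  w / sum(w)
}

# counts binned over `window` extended left by the kernel length, smoothed
# causally; returns trials x bins x neurons array of smoothed rates (Hz)
smoothed_counts <- function(dataset, align, window, bin, kern) {
  L <- length(kern) - 1L
  ext <- c(window[1] - L * bin, window[2])
  bc <- bin_spike_counts(dataset, align, ext, bin)
  nb_ext <- dim(bc$counts)[2]
  nb <- nb_ext - L
  # W[j, t]: weight of extended bin j in output bin t
  W <- matrix(0, nb_ext, nb)
  for (t in seq_len(nb)) W[(t + L) - (0:L), t] <- kern
  nt <- dim(bc$counts)[1]; nn <- dim(bc$counts)[3]
  sm <- array(NA_real_, dim = c(nt, nb, nn))
  for (n in seq_len(nn)) sm[, , n] <- (bc$counts[, , n] %*% W) / bin
  list(sm = sm, time = bc$time[(L + 1):nb_ext], trials = bc$trials)
}

# ---- combined-condition groupings ------------------------------------------

# returns a list of comparisons; each has idx_a, idx_b (row indices into the
# trial table) and a weight (total trial count)
metric_comparisons <- function(trials, metric, min_trials = 3) {
  cmp <- list()
  add <- function(ia, ib) {
    if (length(ia) >= min_trials && length(ib) >= min_trials)
      cmp[[length(cmp) + 1L]] <<- list(a = ia, b = ib,
                                       w = length(ia) + length(ib))
  }
  if (metric == "stimulus") {
    grp <- interaction(trials$choice, trials$contrast_left, drop = FALSE)
    for (g in levels(grp)) {
      i <- which(grp == g)
      add(i[trials$contrast_right[i] == 0], i[trials$contrast_right[i] > 0])
    }
  } else if (metric %in% c("CP", "DP")) {
    uneq <- trials$contrast_left != trials$contrast_right
    grp <- interaction(trials$contrast_left, trials$contrast_right,
                       drop = FALSE)
    for (g in levels(grp)) {
      i <- which(grp == g & uneq)
      if (!length(i)) next
      if (metric == "CP") {
        add(i[trials$choice[i] == "left"], i[trials$choice[i] == "right"])
      } else {
        add(i[trials$outcome[i] == "miss"], i[trials$outcome[i] == "hit"])
      }
    }
  } else if (metric == "ES") {
    levs <- sort(unique(round(trials$evidence / 0.25) * 0.25))
    full <- seq(-1, 1, by = 0.25)
    levs <- full[full %in% levs]
    # level k versus all lower levels pooled, for k = 2..(#levels)
    for (k in 2:length(levs)) {
      add(which(trials$evidence < levs[k] - 1e-9),
          which(abs(trials$evidence - levs[k]) < 1e-9))
    }
  } else stop("unknown metric: ", metric)
  cmp
}

metric_defaults <- function(metric) {
  switch(metric,
         stimulus = list(align = "stim_onset", window = c(-0.1, 0.3)),
         CP = list(align = "wheel_move", window = c(-0.3, 0.1)),
         DP = list(align = "stim_onset", window = c(-0.1, 0.3)),
         ES = list(align = "stim_onset", window = c(-0.1, 0.4)))
}

# deviation transform per metric
metric_transform <- function(metric, v) {
  switch(metric,
         stimulus = abs(v - 0.5),
         CP = abs(v - 0.5),
         DP = v - 0.5,
         ES = abs(v - 0.5))
}

# weighted-average auROC time series for one neuron's rate matrix; `cache`
# (per-column sort order + tie groups, see cpp_order_groups) makes repeated
# relabelings O(n) per column
ccs_neuron <- function(rates, cmp, cache = NULL) {
  if (!length(cmp)) return(rep(NA_real_, ncol(rates)))
  if (is.null(cache)) cache <- cpp_order_groups(rates)
  n <- nrow(rates)
  acc <- 0; wsum <- 0
  for (cc in cmp) {
    labels <- integer(n)
    labels[cc$a] <- 1L
    labels[cc$b] <- 2L
    v <- as.numeric(cpp_auroc_subsets(cache$ord, cache$grp, labels))
    acc <- acc + cc$w * v
    wsum <- wsum + cc$w
  }
  acc / wsum
}

#' Combined-condition auROC selectivity
#'
#' Computes one of four combined-condition selectivity statistics per neuron
#' and time point, as a trial-count-weighted average of condition-wise auROC
#' values:
#'
#' * `"stimulus"`: trials split into 12 groups (choice x left contrast);
#'   within each, contralateral (right) contrast > 0 versus = 0. Reported as
#'   the absolute deviation |auROC - 0.5|.
#' * `"CP"` (choice probability): 12 unequal contrast-pair groups; right
#'   versus left choice, wheel-movement aligned (-0.3 to 0.1 s default);
#'   reported as |auROC - 0.5|.
#' * `"DP"` (detect probability): 12 unequal contrast-pair groups; hit versus
#'   miss, stimulus aligned (-0.1 to 0.3 s); reported signed, auROC - 0.5.
#' * `"ES"` (evidence selectivity): 9 signed-evidence groups (-1 to 1, step
#'   0.25); each level versus all lower levels pooled (8 comparisons);
#'   reported as |auROC - 0.5|.
#'
#' Conditions with fewer than `min_trials` trials on either side are dropped
#' from the average; a neuron whose conditions all drop gets NA.
#'
#' @param dataset a `spike_dataset`.
#' @param metric `"stimulus"`, `"CP"`, `"DP"` or `"ES"`.
#' @param window,align override the metric's default analysis window.
#' @param bin bin width (s).
#' @param min_trials minimum trials per side per condition.
#' @param prep optional precomputed [preprocess_rates()] output.
#' @return object of class `selectivity_result`: `value` (neurons x time,
#'   transformed), `raw` (weighted auROC), `time`, `metric`, `align`,
#'   `window`, `excluded`.
#' @export
combined_condition_selectivity <- function(dataset,
                                           metric = c("stimulus", "CP", "DP",
                                                      "ES"),
                                           window = NULL, align = NULL,
                                           bin = 0.005, min_trials = 3,
                                           prep = NULL) {
  metric <- match.arg(metric)
  de <- metric_defaults(metric)
  if (is.null(window)) window <- de$window
  if (is.null(align)) align <- de$align
  if (is.null(prep))
    prep <- preprocess_rates(dataset, align = align, window = window,
                             bin = bin)
  cmp <- metric_comparisons(prep$trials, metric, min_trials)
  nn <- dim(prep$rates)[3]
  nb <- dim(prep$rates)[2]
  raw <- matrix(NA_real_, nn, nb)
  for (n in seq_len(nn)) {
    if (prep$excluded[n]) next
    raw[n, ] <- ccs_neuron(prep$rates[, , n, drop = TRUE], cmp)
  }
  structure(list(metric = metric, value = metric_transform(metric, raw),
                 raw = raw, time = prep$time, align = align, window = window,
                 excluded = prep$excluded, trials = prep$trials),
            class = "selectivity_result")
}

#' Shuffle-null significance of a selectivity statistic
#'
#' Repeats the combined-condition auROC computation on trial labels permuted
#' within the metric's grouping structure (choice within contrast-pair groups
#' for CP, hit/miss within groups for DP, contralateral contrast within
#' choice x left-contrast groups for the stimulus metric, evidence labels
#' across trials for ES). The shuffle band is the 2.5th-97.5th percentile of
#' `n_shuffles` shuffled values per time point; an observed value is
#' significant when it falls outside the band *and* lies in a run of at least
#' three consecutive significant time points (the two-significant-neighbors
#' rule).
#'
#' @inheritParams combined_condition_selectivity
#' @param n_shuffles number of label permutations (>= 2).
#' @param level band coverage (default 0.95).
#' @param seed seed for the permutations.
#' @return a `selectivity_result` with additional elements `sig` (logical
#'   neurons x time mask), `band_lo`, `band_hi`.
#' @export
shuffle_significance <- function(dataset, metric = c("stimulus", "CP", "DP",
                                                     "ES"),
                                 n_shuffles = 100, window = NULL,
                                 align = NULL, bin = 0.005, min_trials = 3,
                                 level = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(n_shuffles >= 2)
  de <- metric_defaults(metric)
  if (is.null(window)) window <- de$window
  if (is.null(align)) align <- de$align
  prep <- preprocess_rates(dataset, align = align, window = window, bin = bin)
  obs <- combined_condition_selectivity(dataset, metric, window, align, bin,
                                        min_trials, prep = prep)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  trials <- prep$trials
  nn <- dim(prep$rates)[3]; nb <- dim(prep$rates)[2]
  lo <- hi <- matrix(NA_real_, nn, nb)
  sig <- matrix(FALSE, nn, nb)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  # permutations shared across neurons (one null ensemble per dataset)
  perms <- lapply(seq_len(n_shuffles), function(s)
    permute_labels(trials, metric))
  cmp_perm <- lapply(perms, function(tr)
    metric_comparisons(tr, metric, min_trials))
  for (n in seq_len(nn)) {
    if (prep$excluded[n]) next
    rates_n <- prep$rates[, , n, drop = TRUE]
    cache <- cpp_order_groups(rates_n)
    null_vals <- matrix(NA_real_, n_shuffles, nb)
    for (s in seq_len(n_shuffles)) {
      null_vals[s, ] <- metric_transform(
        metric, ccs_neuron(rates_n, cmp_perm[[s]], cache))
    }
    qs <- apply(null_vals, 2, stats::quantile, probs = probs, na.rm = TRUE,
                names = FALSE)
    lo[n, ] <- qs[1, ]; hi[n, ] <- qs[2, ]
    outside <- !is.na(obs$value[n, ]) &
      (obs$value[n, ] < lo[n, ] | obs$value[n, ] > hi[n, ])
    sig[n, ] <- neighbor_rule(outside)
  }
  obs$sig <- sig; obs$band_lo <- lo; obs$band_hi <- hi
  obs$n_shuffles <- n_shuffles
  obs
}

# permute the labels the metric compares, within its grouping structure
permute_labels <- function(trials, metric) {
  tr <- trials
  if (metric == "CP") {
    grp <- interaction(tr$contrast_left, tr$contrast_right, drop = FALSE)
    tr$choice <- permute_within(tr$choice, grp)
  } else if (metric == "DP") {
    grp <- interaction(tr$contrast_left, tr$contrast_right, drop = FALSE)
    tr$outcome <- permute_within(tr$outcome, grp)
  } else if (metric == "stimulus") {
    grp <- interaction(tr$choice, tr$contrast_left, drop = FALSE)
    tr$contrast_right <- permute_within(tr$contrast_right, grp)
  } else {                                   # ES: evidence labels shuffled
    tr$evidence <- sample(tr$evidence)
  }
  tr
}

permute_within <- function(x, grp) {
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (length(i) > 1) x[i] <- x[sample(i)]
  }
  x
}

# keep only points lying in runs of >= 3 consecutive significant points
neighbor_rule <- function(sig) {
  sig[is.na(sig)] <- FALSE
  r <- rle(sig)
  r$values <- r$values & r$lengths >= 3
  inverse.rle(r)
}

#' Accumulation latency of a population
#'
#' First time after stimulus onset at which population activity departs from
#' baseline: go trials with reaction times in `rt_range` are kept, spike
#' counts (0.005 s bins, -0.5 to 0.5 s around stimulus onset) are smoothed
#' with a causal boxcar of `boxcar` seconds and averaged across neurons
#' within each trial; each time point in (0, 0.5\] s is compared against the
#' baseline point at -0.1 s with a Mann-Whitney rank-sum test across trials.
#' The latency is the first time with p < `alpha` that lies in a run of at
#' least three significant points; absent (NA) when no point qualifies.
#'
#' @param dataset a `spike_dataset`.
#' @param rt_range reaction-time filter (s) for qualifying go trials.
#' @param boxcar causal boxcar width (s).
#' @param bin bin width (s).
#' @param alpha significance level.
#' @return list with `latency` (s or NA), `p_values`, `time`, `n_trials`.
#' @export
estimate_latency <- function(dataset, rt_range = c(0.15, 0.5), boxcar = 0.1,
                             bin = 0.005, alpha = 0.05) {
  tr <- dataset$trials
  go <- tr$choice %in% c("left", "right") & is.finite(tr$reaction_time) &
    tr$reaction_time >= rt_range[1] & tr$reaction_time <= rt_range[2]
  if (sum(go) < 2) stop("need at least 2 qualifying go trials")
  sub <- dataset
  sub$trials <- tr[go, , drop = FALSE]

  L <- round(boxcar / bin)
  ext <- c(-0.5 - L * bin, 0.5)
  bc <- bin_spike_counts(sub, "stim_onset", ext, bin)
  # population mean rate per trial, causal boxcar of L bins
  pop <- apply(bc$counts, c(1, 2), mean) / bin
  nb_ext <- ncol(pop)
  W <- matrix(0, nb_ext, nb_ext - L)
  for (t in seq_len(nb_ext - L)) W[(t + L) - (0:(L - 1)), t] <- 1 / L
  sm <- pop %*% W
  time <- bc$time[(L + 1):nb_ext]

  ib <- which.min(abs(time - (-0.1)))
  base_vals <- sm[, ib]
  idx <- which(time > 0 & time <= 0.5)
  pv <- vapply(idx, function(j)
    stats::wilcox.test(sm[, j], base_vals, exact = FALSE)$p.value,
    numeric(1))
  sig <- neighbor_rule(pv < alpha)
  lat <- if (any(sig)) time[idx[which(sig)[1]]] else NA_real_
  list(latency = lat, p_values = pv, time = time[idx], n_trials = sum(go))
}

#' Write per-neuron selectivity tables
#'
#' @param result a `selectivity_result` (with or without significance).
#' @param path CSV output path.
#' @export
write_selectivity <- function(result, path) {
  nn <- nrow(result$value)
  df <- data.frame(
    neuron_id = rep(seq_len(nn), each = length(result$time)),
    time = rep(result$time, nn),
    value = as.vector(t(result$value)),
    significant = if (!is.null(result$sig)) as.vector(t(result$sig)) else NA)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
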