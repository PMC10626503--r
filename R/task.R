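#' Generate trials for the two-alternative contrast discrimination task
#'
#' Simulates the trial structure of a 2AFC visual contrast task: on each trial
#' a grating of contrast 0, 0.25, 0.5 or 1 appears on the left and/or right
#' screen and the subject turns a wheel toward the higher-contrast side (or
#' withholds a response when both screens are blank). Contrast pairs are drawn
#' uniformly over the 4 x 4 grid; the four equal-contrast cells can be
#' excluded, leaving the 12 unequal condition cells used by the
#' combined-condition selectivity statistics.
#'
#' Choices follow a simple lapse rule: the higher-contrast side is chosen with
#' probability `accuracy`, otherwise the other side; blank trials are answered
#' nogo with probability `accuracy`. Reaction times of go trials are drawn
#' uniformly from `rt_range`. Downstream accumulator simulation
#' ([simulate_accumulator_dataset()]) replaces choice and reaction time with
#' the model's own boundary crossings; the behavioral columns generated here
#' matter only when the trial table is used on its own.
#'
#' @param n_trials number of trials (>= 1).
#' @param include_equal_contrast keep the four equal-contrast cells?
#' @param rt_range length-2 numeric, uniform range (s) for go-trial reaction
#'   times, `rt_range[1] < rt_range[2]`.
#' @param seed integer seed; identical seeds give identical tables.
#' @param accuracy probability that the reward-maximizing response is made.
#' @param stim_onset_spacing spacing (s) between consecutive stimulus onsets;
#'   the first onset is at `stim_onset_spacing`.
#' @return a `data.frame` of class `trial_table` with columns `trial`,
#'   `contrast_left`, `contrast_right`, `evidence` (right minus left),
#'   `choice` (`"left"|"right"|"nogo"`), `outcome` (`"hit"|"miss"`),
#'   `stim_onset`, `wheel_move` (NA for nogo) and `reaction_time` (s, NA for
#'   nogo).
#' @export
make_task_trials <- function(n_trials, include_equal_contrast = FALSE,
                             rt_range = c(0.15, 0.5), seed = 1L,
                             accuracy = 0.8, stim_onset_spacing = 3) {
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 1)
    stop("n_trials must be a positive count")
  if (length(rt_range) != 2L || rt_range[1] >= rt_range[2] || any(rt_range < 0))
    stop("rt_range must be an increasing nonnegative pair (s)")
  n_trials <- as.integer(n_trials)

  levels4 <- c(0, 0.25, 0.5, 1)
  grid <- expand.grid(contrast_left = levels4, contrast_right = levels4)
  if (!include_equal_contrast)
    grid <- grid[grid$contrast_left != grid$contrast_right, , drop = FALSE]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  cell <- sample.int(nrow(grid), n_trials, replace = TRUE)
  cl <- grid$contrast_left[cell]
  cr <- grid$contrast_right[cell]
  ev <- cr - cl

  correct_side <- ifelse(cl == 0 & cr == 0, "nogo",
                    ifelse(cr > cl, "right", ifelse(cl > cr, "left", "either")))
  lapse <- stats::runif(n_trials) > accuracy
  choice <- character(n_trials)
  for (i in seq_len(n_trials)) {
    cs <- correct_side[i]
    if (cs == "either") {            # equal nonzero contrasts: either turn rewarded
      choice[i] <- sample(c("left", "right"), 1L)
    } else if (!lapse[i]) {
      choice[i] <- cs
    } else {
      alts <- setdiff(c("left", "right", "nogo"), cs)
      choice[i] <- sample(alts, 1L)
    }
  }
  # reward rule: higher-contrast side chosen; nogo correct iff both contrasts 0;
  # equal nonzero contrasts reward any turn
  hit <- (correct_side == "nogo" & choice == "nogo") |
         (correct_side == "either" & choice != "nogo") |
         (correct_side == choice & correct_side %in% c("left", "right"))
  stim_onset <- stim_onset_spacing * seq_len(n_trials)
  rt <- ifelse(choice == "nogo", NA_real_,
               stats::runif(n_trials, rt_range[1], rt_range[2]))
  out <- data.frame(
    trial = seq_len(n_trials),
    contrast_left = cl, contrast_right = cr, evidence = ev,
    choice = choice,
    outcome = ifelse(hit, "hit", "miss"),
    stim_onset = stim_onset,
    wheel_move = stim_onset + rt,
    reaction_time = rt,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trial_table", "data.frame")
  out
}

# save/restore the global RNG state so generators are pure functions of `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Assemble a spike dataset
#'
#' The central data container: spike times per neuron (absolute session time,
#' seconds), a trial table, per-neuron metadata, and optional ground truth
#' carried along from a generator.
#'
#' @param spikes list of numeric vectors, one sorted vector of spike times per
#'   neuron.
#' @param trials a `trial_table` (see [make_task_trials()]).
#' @param neurons `data.frame` with one row per neuron; columns `neuron_id`,
#'   `region`, `pref_side` (`"contra"|"ipsi"`).
#' @param ground_truth optional list (generating spec, latent paths, latency...).
#' @return object of class `spike_dataset`.
#' @export
spike_dataset <- function(spikes, trials, neurons = NULL, ground_truth = NULL) {
  stopifnot(is.list(spikes), inherits(trials, "data.frame"))
  spikes <- lapply(spikes, function(s) sort(as.numeric(s)))
  if (any(vapply(spikes, function(s) length(s) > 0 && s[1] < 0, logical(1))))
    stop("spike times must be nonnegative")
  if (is.null(neurons)) {
    neurons <- data.frame(neuron_id = seq_along(spikes),
                          region = "synthetic", pref_side = "contra",
                          stringsAsFactors = FALSE)
  }
  stopifnot(nrow(neurons) == length(spikes))
  structure(list(spikes = spikes, trials = trials, neurons = neurons,
                 ground_truth = ground_truth),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("<spike_dataset> ", length(x$spikes), " neurons, ",
      nrow(x$trials), " trials, ",
      sum(lengths(x$spikes)), " spikes\n", sep = "")
  invisible(x)
}

#' Number of neurons in a spike dataset
#' @param dataset a `spike_dataset`.
#' @export
n_neurons <- function(dataset) length(dataset$spikes)

#' Bin spike counts around an alignment event
#'
#' Counts spikes of every neuron in half-open bins `[t, t + bin)` relative to
#' a per-trial alignment event.
#'
#' @param dataset a `spike_dataset`.
#' @param align `"stim_onset"` or `"wheel_move"`; trials lacking the event are
#'   dropped.
#' @param window numeric length-2, window (s) relative to the event.
#' @param bin bin width (s).
#' @return list with `counts` (array trials x bins x neurons), `time` (bin
#'   left edges), `trials` (the retained trial rows).
#' @export
bin_spike_counts <- function(dataset, align = "stim_onset",
                             window = c(-0.1, 0.3), bin = 0.005) {
  tr <- dataset$trials
  ev <- tr[[align]]
  keep <- is.finite(ev)
  tr <- tr[keep, , drop = FALSE]
  ev <- ev[keep]
  edges_rel <- seq(window[1], window[2], by = bin)
  nb <- length(edges_rel) - 1L
  nt <- nrow(tr); nn <- length(dataset$spikes)
  counts <- array(0L, dim = c(nt, nb, nn))
  for (n in seq_len(nn)) {
    st <- dataset$spikes[[n]]
    if (!length(st)) next
    for (i in seq_len(nt)) {
      counts[i, , n] <- bin_sorted_spikes(st, ev[i] + window[1], bin, nb)
    }
  }
  list(counts = counts, time = edges_rel[-length(edges_rel)], trials = tr,
       bin = bin)
}

# counts of a sorted spike vector in nb half-open bins starting at `lo`;
# O(log n) window location via findInterval
bin_sorted_spikes <- function(st, lo, bin, nb) {
  hi <- lo + nb * bin
  i0 <- findInterval(lo, st, left.open = TRUE) + 1L
  i1 <- findInterval(hi - 1e-12, st)
  if (i0 > i1) return(integer(nb))
  s <- st[i0:i1]
  idx <- floor((s - lo) / bin) + 1L
  idx[idx > nb] <- nb
  tabulate(idx, nbins = nb)
}

#' Write / read a spike dataset as plain-text tables
#'
#' Writers emit a two-column spike table (`neuron_id`, `time_s`), a trial CSV
#' with the trial-table fields, a neuron metadata CSV, and (optionally) a YAML
#' ground-truth sidecar. `read_spike_dataset()` accepts the same layout.
#'
#' @param dataset a `spike_dataset`.
#' @param dir output directory (created if missing).
#' @param sep field separator for the spike table (`"\t"` or `","`).
#' @return `dir`, invisibly.
#' @export
write_spike_dataset <- function(dataset, dir, sep = "\t") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- data.frame(
    neuron_id = rep(dataset$neurons$neuron_id, lengths(dataset$spikes)),
    time_s = unlist(dataset$spikes, use.names = FALSE))
  utils::write.table(sp, file.path(dir, "spikes.tsv"), sep = sep,
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$ground_truth)) {
    gt <- dataset$ground_truth
    gt_simple <- gt[vapply(gt, function(e)
      is.numeric(e) || is.character(e) || is.logical(e), logical(1))]
    yaml::write_yaml(gt_simple, file.path(dir, "ground_truth.yml"))
  }
  invisible(dir)
}

#' @rdname write_spike_dataset
#' @export
read_spike_dataset <- function(dir) {
  sp <- utils::read.table(file.path(dir, "spikes.tsv"), header = TRUE,
                          sep = "", stringsAsFactors = FALSE)
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  class(trials) <- c("trial_table", "data.frame")
  neurons <- utils::read.csv(file.path(dir, "neurons.csv"),
                             stringsAsFactors = FALSE)
  spikes <- lapply(neurons$neuron_id, function(id)
    sort(sp$time_s[sp$neuron_id == id]))
  gt_path <- file.path(dir, "ground_truth.yml")
  gt <- if (file.exists(gt_path)) yaml::read_yaml(gt_path) else NULL
  spike_dataset(spikes, trials, neurons, gt)
}
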