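#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()] with defaults matching
#' the analysis constants used throughout the package: 100 shuffles for the
#' selectivity nulls, AIC support threshold 10, reaction-time window
#' 0.15-0.5 s, subpopulations of 4 neurons, 50 timescale sample sets, 100
#' bootstrap resamples, 0.025 s autocorrelation bins, 0.005 s selectivity
#' bins, 0.1 s latency boxcar and 0.05 s explained-variance boxcar. Unknown
#' keys are rejected by name; overrides are recorded in the manifest.
#'
#' @param ... overrides of the defaults listed above. `regions` is a named
#'   list: region name -> list with `A` (recurrent strength of the
#'   generating accumulator), optional `kind`, `V`, `Q`, `n_neurons`
#'   (accumulator-driven), `n_stim` (stimulus-only) and `n_untuned`
#'   (constant-rate) neuron counts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    stages = c("simulate", "selectivity", "dpca", "fit", "compare",
               "timescales"),
    regions = list(
      regionA = list(A = 0.95, kind = "single", V = 0.05, Q = 0.02,
                     n_neurons = 12, n_stim = 6, n_untuned = 4),
      regionB = list(A = 0.98, kind = "single", V = 0.05, Q = 0.02,
                     n_neurons = 12, n_stim = 6, n_untuned = 4)),
    n_trials = 400,
    n_shuffles = 100,
    aic_threshold = 10,
    rt_range = c(0.15, 0.5),
    subpop_size = 4,
    n_subpops_per_region = 20,
    timescale_samples = 50,
    timescale_trials = 200,
    n_boot = 100,
    autocorr_delta = 0.025,
    selectivity_bin = 0.005,
    latency_boxcar = 0.1,
    ev_boxcar = 0.05,
    fit_dt = 0.01,
    gamma = 25,
    max_em = 50,
    emission_gain = 15,
    emission_offset = 15,
    reduced_init_grid = FALSE,
    aic_samples = 100)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (!is.null(over$regions)) cfg$regions <- over$regions
  cfg$overrides <- names(over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Subset a spike dataset to selected neurons
#'
#' @param dataset a `spike_dataset`.
#' @param ids neuron ids to keep.
#' @export
subset_neurons <- function(dataset, ids) {
  sel <- match(ids, dataset$neurons$neuron_id)
  if (anyNA(sel)) stop("unknown neuron id(s)")
  spike_dataset(dataset$spikes[sel], dataset$trials,
                dataset$neurons[sel, , drop = FALSE],
                dataset$ground_truth)
}

#' Screen for DDM-like neurons
#'
#' Combines the screening chain: membership in the decision cluster of the
#' fuzzy C-means grouping on the dPCA marginalization R-squared values,
#' significant choice probability and evidence selectivity under the shuffle
#' null, and an automated ramping criterion (significant nonzero linear
#' slope of the trial-averaged rate over the accumulation window on trials
#' of the preferred choice, with sign consistent with the preference).
#'
#' @param dataset a `spike_dataset` (one region).
#' @param n_shuffles shuffle count for the significance nulls.
#' @param ramp_window window (s, wheel-movement aligned) for the
#'   ramping regression.
#' @param alpha significance level of the ramping slope.
#' @param seed seed for the shuffle nulls.
#' @return data.frame with `neuron_id`, `cluster`, `cp_sig`, `es_sig`,
#'   `ramping`, `pref_side`, `ddm_like`.
#' @export
find_ddm_neurons <- function(dataset, n_shuffles = 100,
                             ramp_window = c(-0.25, 0), alpha = 0.05,
                             seed = 1L) {
  nn <- length(dataset$spikes)
  tensor <- build_marginalized_tensor(dataset)
  cluster_lab <- rep(NA_character_, nn)
  r2 <- tryCatch({
    dp <- fit_dpca(tensor)
    marginalization_r2(dp, tensor)
  }, error = function(e) NULL)
  if (!is.null(r2) && sum(stats::complete.cases(r2)) >= 3) {
    cl <- tryCatch(cluster_neurons(r2, seed = seed), error = function(e) NULL)
    if (!is.null(cl)) cluster_lab[cl$neuron_id] <- cl$label
  }

  cp <- shuffle_significance(dataset, "CP", n_shuffles, seed = seed)
  es <- shuffle_significance(dataset, "ES", n_shuffles, seed = seed + 1L)
  cp_sig <- rowSums(cp$sig) > 0
  es_sig <- rowSums(es$sig) > 0
  # preferred side from the signed choice auROC (P(right > left) > 0.5)
  mean_raw <- rowMeans(cp$raw, na.rm = TRUE)
  pref <- ifelse(is.nan(mean_raw), NA_character_,
                 ifelse(mean_raw >= 0.5, "contra", "ipsi"))

  ramping <- ramping_screen(dataset, pref, ramp_window, alpha)
  data.frame(neuron_id = dataset$neurons$neuron_id,
             cluster = cluster_lab, cp_sig = cp_sig, es_sig = es_sig,
             ramping = ramping, pref_side = pref,
             ddm_like = !is.na(cluster_lab) & cluster_lab == "decision" &
               cp_sig & es_sig & ramping,
             stringsAsFactors = FALSE)
}

# significant monotone trend of the trial-averaged rate on preferred-choice
# trials, sign matching the preference. The regression is movement-aligned
# (the ramp-to-threshold signature): each bin averages the trials whose
# accumulation epoch (post stimulus onset) covers that bin.
ramping_screen <- function(dataset, pref, window = c(-0.25, 0),
                           alpha = 0.05, bin = 0.01, min_trials = 5) {
  bc <- bin_spike_counts(dataset, "wheel_move", window, bin)
  tr <- bc$trials
  nn <- dim(bc$counts)[3]
  nb <- length(bc$time)
  # accumulation-epoch mask: bin must lie after the trial's stimulus onset
  rt <- tr$wheel_move - tr$stim_onset
  rt[!is.finite(rt)] <- Inf
  pre <- outer(-rt, bc$time, `<=`)
  out <- logical(nn)
  for (n in seq_len(nn)) {
    if (is.na(pref[n])) next
    side <- if (pref[n] == "contra") "right" else "left"
    i <- which(tr$choice == side)
    if (length(i) < min_trials) next
    cnt <- bc$counts[i, , n, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = length(i))
    msk <- pre[i, , drop = FALSE]
    n_per_bin <- colSums(msk)
    use <- n_per_bin >= min_trials
    if (sum(use) < 5) next
    avg <- colSums(cnt * msk)[use] / n_per_bin[use] / bin
    fitlm <- stats::lm(avg ~ bc$time[use])
    co <- summary(fitlm)$coefficients
    if (nrow(co) < 2) next
    out[n] <- co[2, 4] < alpha && co[2, 1] > 0
  }
  out
}

#' Form subpopulations of DDM-like neurons
#'
#' Repeatedly samples `size` DDM-like neurons without replacement within
#' each region. A subpopulation is bilateral when it contains both
#' contralateral and ipsilateral choice preferences, unilateral otherwise;
#' unilateral subpopulations are fitted with the single accumulator only.
#'
#' @param neurons data.frame with `neuron_id`, `region`, `pref_side`
#'   (DDM-like neurons only).
#' @param size neurons per subpopulation (default 4).
#' @param n_subpops draws per region.
#' @param seed integer seed.
#' @return data.frame with `subpop_id`, `region`, `bilateral` and a
#'   list-column `neuron_ids`; regions with fewer than `size` neurons are
#'   skipped.
#' @export
form_subpopulations <- function(neurons, size = 4, n_subpops = 20,
                                seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- list()
  for (reg in unique(neurons$region)) {
    sub <- neurons[neurons$region == reg, ]
    if (nrow(sub) < size) next
    for (s in seq_len(n_subpops)) {
      pick <- sub[sample.int(nrow(sub), size), ]
      out[[length(out) + 1L]] <- data.frame(
        subpop_id = paste0(reg, "_", s), region = reg,
        bilateral = length(unique(pick$pref_side)) == 2,
        stringsAsFactors = FALSE)
      out[[length(out)]]$neuron_ids <- list(pick$neuron_id)
    }
  }
  if (!length(out)) return(data.frame(subpop_id = character(0),
                                      region = character(0),
                                      bilateral = logical(0)))
  do.call(rbind, out)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in order on synthetic data generated from the
#' config: per region, an accumulator-driven population (plus untuned
#' neurons) is simulated on a shared trial table; DDM-like neurons are
#' screened (dPCA cluster + selectivity significance + ramping);
#' subpopulations are formed and fitted with the applicable accumulator
#' models; models are compared by AIC difference; timescales are estimated
#' per subpopulation and per region. All tables are written as CSV to
#' `out_dir` along with a `manifest.yml` recording the seed, package
#' version and overridden defaults.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @return invisible list with the main tables (`ddm_table`,
#'   `subpop_table`, `comparison_table`, `timescale_table`,
#'   `region_table`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("evaccum_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  st <- config$stages

  # --- simulate -------------------------------------------------------------
  datasets <- list()
  for (ri in seq_along(config$regions)) {
    reg <- names(config$regions)[ri]
    rc <- config$regions[[ri]]
    kind <- if (is.null(rc$kind)) "single" else rc$kind
    trials <- make_task_trials(config$n_trials, seed = seed + 11L * ri)
    spec <- build_accumulator(kind, init = list(A = rc$A, V = rc$V, Q = rc$Q),
                              gamma = config$gamma, dt = config$fit_dt)
    nc <- ceiling(rc$n_neurons / 2); ni <- rc$n_neurons - nc
    C <- default_emission_weights(kind, nc, ni, gain = config$emission_gain)
    spec <- set_emissions(spec, C, config$emission_offset)
    ds <- simulate_accumulator_dataset(spec, trials, seed = seed + 101L * ri,
                                       region = reg)
    add_cohort <- function(ds, n, tuning, seed_off) {
      if (is.null(n) || n == 0) return(ds)
      extra <- make_selectivity_cohort(
        n, tuning, baseline_rate = softplus(config$emission_offset),
        trials = ds$trials, seed = seed + seed_off * ri)
      extra$neurons$neuron_id <- max(ds$neurons$neuron_id) + seq_len(n)
      extra$neurons$region <- reg
      spike_dataset(c(ds$spikes, extra$spikes), ds$trials,
                    rbind(ds$neurons, extra$neurons), ds$ground_truth)
    }
    ds <- add_cohort(ds, rc$n_stim,
                     list(stim = config$emission_gain, choice = 0,
                          evidence = 0), 307L)
    ds <- add_cohort(ds, rc$n_untuned,
                     list(stim = 0, choice = 0, evidence = 0), 211L)
    datasets[[reg]] <- ds
  }

  # --- screen (selectivity + dpca) -----------------------------------------
  ddm_tables <- list()
  for (reg in names(datasets)) {
    tab <- find_ddm_neurons(datasets[[reg]], n_shuffles = config$n_shuffles,
                            seed = seed + 31L)
    tab$region <- reg
    ddm_tables[[reg]] <- tab
  }
  ddm_table <- do.call(rbind, ddm_tables)
  utils::write.csv(ddm_table, file.path(out_dir, "ddm_neurons.csv"),
                   row.names = FALSE)

  # --- subpopulations -------------------------------------------------------
  ddm <- ddm_table[ddm_table$ddm_like, ]
  subpops <- form_subpopulations(ddm, size = config$subpop_size,
                                 n_subpops = config$n_subpops_per_region,
                                 seed = seed + 41L)
  utils::write.csv(subpops[, c("subpop_id", "region", "bilateral")],
                   file.path(out_dir, "subpopulations.csv"),
                   row.names = FALSE)

  # --- fit + compare --------------------------------------------------------
  # reduced grid keeps the full V search (V is fixed during training, so
  # its value can only come from the grid) and drops extra A/Q starts
  grid_for <- function(kind, reduced) {
    g <- accumulator_init_grid(kind)
    if (reduced) g[g$A == g$A[1] & g$Q == g$Q[1], , drop = FALSE] else g
  }
  comp_rows <- list()
  ts_rows <- list()
  region_curves <- list()
  if (all(c("fit", "compare") %in% st) && nrow(subpops) > 0) {
    for (i in seq_len(nrow(subpops))) {
      sp <- subpops[i, ]
      ds <- subset_neurons(datasets[[sp$region]], sp$neuron_ids[[1]])
      kinds <- if (sp$bilateral)
        c("single", "independent_race", "dependent_race") else "single"
      fits <- list(); scores <- list()
      for (kind in kinds) {
        f <- tryCatch(fit_laplace_em(
          ds, kind, init_grid = grid_for(kind, config$reduced_init_grid),
          rt_range = config$rt_range, dt = config$fit_dt,
          gamma = config$gamma, max_em = config$max_em),
          error = function(e) NULL)
        if (is.null(f)) next
        fits[[kind]] <- f
        scores[[kind]] <- aic(f, n_samples = config$aic_samples,
                              seed = seed + 53L + i)
      }
      if (!length(fits)) next
      verdict <- compare_models(scores, threshold = config$aic_threshold)
      pref_kind <- if (verdict$preferred %in% names(fits)) verdict$preferred
        else names(which.min(vapply(scores, `[[`, numeric(1), "aic")))
      best_fit <- fits[[pref_kind]]
      r2 <- tryCatch(explained_variance(best_fit, n_sims = 50,
                                        boxcar = config$ev_boxcar,
                                        seed = seed + 61L + i)$r2,
                     error = function(e) NA_real_)
      getaic <- function(k) if (k %in% names(scores)) scores[[k]]$aic else NA
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        subpop_id = sp$subpop_id, region = sp$region,
        bilateral = sp$bilateral,
        AIC_single = getaic("single"),
        AIC_irace = getaic("independent_race"),
        AIC_drace = getaic("dependent_race"),
        verdict = verdict$preferred, R2_best = r2,
        stringsAsFactors = FALSE)

      if ("timescales" %in% st) {
        ts <- subpopulation_timescale(best_fit,
                                      n_samples = config$timescale_samples,
                                      n_trials = config$timescale_trials,
                                      delta = config$autocorr_delta,
                                      seed = seed + 71L + i)
        ts_rows[[length(ts_rows) + 1L]] <- data.frame(
          subpop_id = sp$subpop_id, region = sp$region,
          tau = ts$tau, tau_sd = ts$sd,
          strength = recurrent_strength(best_fit),
          stringsAsFactors = FALSE)
        if (!is.null(ts$curve))
          region_curves[[sp$region]] <-
            c(region_curves[[sp$region]], list(ts$curve))
      }
    }
  }
  comparison_table <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame()
  utils::write.csv(comparison_table,
                   file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  timescale_table <- if (length(ts_rows)) do.call(rbind, ts_rows) else
    data.frame()
  utils::write.csv(timescale_table,
                   file.path(out_dir, "subpop_timescales.csv"),
                   row.names = FALSE)

  region_table <- data.frame()
  if (length(region_curves)) {
    pt <- population_timescale(region_curves, n_boot = config$n_boot,
                               seed = seed + 83L)
    region_table <- pt$table
    utils::write.csv(region_table,
                     file.path(out_dir, "region_timescales.csv"),
                     row.names = FALSE)
    if (!is.null(pt$pairwise))
      utils::write.csv(pt$pairwise,
                       file.path(out_dir, "region_pairwise.csv"),
                       row.names = FALSE)
    if (nrow(timescale_table) > 0) {
      corr <- strength_timescale_correlation(timescale_table)
      utils::write.csv(corr,
                       file.path(out_dir, "strength_timescale.csv"),
                       row.names = FALSE)
    }
  }

  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("evaccum")),
    overridden_defaults = config$overrides,
    stages = st,
    n_regions = length(config$regions),
    n_subpops = nrow(subpops))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))

  invisible(list(ddm_table = ddm_table, subpop_table = subpops,
                 comparison_table = comparison_table,
                 timescale_table = timescale_table,
                 region_table = region_table, out_dir = out_dir))
}
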