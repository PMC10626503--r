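test_that("auroc matches hand-checkable cases", {
  expect_equal(auroc(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(auroc(c(2, 2, 2), c(2, 2, 2)), 0.5)
  expect_equal(auroc(c(0, 1, 1), c(1, 2, 0)), 5.5 / 9, tolerance = 1e-15)
  expect_error(auroc(numeric(0), 1:3), "empty")
})

test_that("auroc agrees with the rank-sum implementation and is antisymmetric", {
  set.seed(1)
  for (i in 1:200) {
    a <- stats::rpois(sample(3:10, 1), 3)
    b <- stats::rpois(sample(3:10, 1), 3)
    # independent oracle: normalized Mann-Whitney statistic
    w <- suppressWarnings(stats::wilcox.test(b, a))$statistic
    expect_equal(auroc(a, b), unname(w) / (length(a) * length(b)),
                 tolerance = 1e-12)
    expect_equal(auroc(a, b) + auroc(b, a), 1, tolerance = 1e-12)
  }
})

test_that("the order-cache auROC path equals the scalar implementation", {
  set.seed(2)
  M <- matrix(stats::rpois(60 * 8, 2) + stats::runif(60 * 8, 0, 1e-3), 60, 8)
  M[sample(length(M), 100)] <- 0                       # heavy ties
  cache <- evaccum:::cpp_order_groups(M)
  for (i in 1:30) {
    lab <- sample(0:2, 60, replace = TRUE)
    if (sum(lab == 1) == 0 || sum(lab == 2) == 0) next
    fast <- as.numeric(evaccum:::cpp_auroc_subsets(cache$ord, cache$grp,
                                                   as.integer(lab)))
    slow <- apply(M, 2, function(col)
      auroc(col[lab == 1], col[lab == 2]))
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("preprocessing z-scores against the baseline epoch", {
  tr <- make_task_trials(120, seed = 3)
  ds <- make_selectivity_cohort(5, list(stim = 0, choice = 0, evidence = 0),
                                baseline_rate = 15, trials = tr, seed = 4)
  prep <- preprocess_rates(ds, window = c(-0.9, -0.1))
  expect_false(any(prep$excluded))
  for (n in 1:5) expect_lt(abs(mean(prep$rates[, , n])), 0.1)
  # a silent neuron is flagged and excluded
  ds$spikes[[3]] <- numeric(0)
  prep2 <- preprocess_rates(ds, window = c(-0.1, 0.3))
  expect_true(prep2$excluded[3])
  expect_true(all(is.na(prep2$rates[, , 3])))
})

test_that("auROC metrics are invariant to doubling all spike counts", {
  tr <- make_task_trials(150, seed = 5)
  ds <- make_selectivity_cohort(2, list(stim = 0, choice = 8, evidence = 0),
                                baseline_rate = 10, trials = tr, seed = 6)
  res1 <- combined_condition_selectivity(ds, "CP")
  ds2 <- ds
  # duplicate every spike: counts double, ranks are preserved
  ds2$spikes <- lapply(ds$spikes, function(s) sort(c(s, s)))
  res2 <- combined_condition_selectivity(ds2, "CP")
  expect_equal(res1$raw, res2$raw, tolerance = 1e-12)
})

test_that("evidence selectivity uses eight ordered comparisons", {
  tr <- make_task_trials(4000, include_equal_contrast = TRUE, seed = 7)
  cmp <- evaccum:::metric_comparisons(tr, "ES", min_trials = 3)
  expect_length(cmp, 8)
  # comparison k pools all lower evidence levels
  levs <- sort(unique(tr$evidence))
  for (k in seq_along(cmp)) {
    b_ev <- unique(tr$evidence[cmp[[k]]$b])
    expect_length(b_ev, 1)
    expect_true(all(tr$evidence[cmp[[k]]$a] < b_ev))
  }
})

test_that("metric groupings give 12 combined conditions where applicable", {
  tr <- make_task_trials(6000, include_equal_contrast = TRUE, seed = 8)
  expect_lte(length(evaccum:::metric_comparisons(tr, "DP", 1)), 12)
  stim_cmp <- evaccum:::metric_comparisons(tr, "stimulus", 1)
  expect_lte(length(stim_cmp), 12)
  expect_gt(length(stim_cmp), 6)
})

test_that("untuned neurons stay inside the shuffle band, tuned ones escape it", {
  tr <- make_task_trials(400, seed = 9)
  ds <- make_selectivity_cohort(
    4, data.frame(stim = 0, choice = 0, evidence = c(0, 0, 10, 10)),
    baseline_rate = 10, trials = tr, seed = 10)
  res <- shuffle_significance(ds, "ES", n_shuffles = 60, seed = 11)
  post <- res$time > 0.05
  expect_lte(mean(res$sig[1:2, ]), 0.06)
  expect_true(all(rowSums(res$sig[3:4, post, drop = FALSE]) > 0))
})

test_that("the neighbor rule removes isolated significant points", {
  sig <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(evaccum:::neighbor_rule(sig),
               c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                 FALSE))
  expect_true(all(evaccum:::neighbor_rule(rep(TRUE, 5))))
  expect_false(any(evaccum:::neighbor_rule(c(TRUE, TRUE, FALSE, TRUE))))
})

test_that("permuted labels center the metric at zero deviation, shrinking with n", {
  mean_dev <- vapply(c(400, 1600), function(n) {
    tr <- make_task_trials(n, seed = 12)
    ds <- make_selectivity_cohort(3, list(stim = 0, choice = 6, evidence = 0),
                                  baseline_rate = 10, trials = tr, seed = 13)
    prep <- preprocess_rates(ds, align = "wheel_move", window = c(-0.3, 0.1))
    vals <- numeric(0)
    set.seed(14)
    for (s in 1:8) {
      trp <- evaccum:::permute_labels(prep$trials, "CP")
      cmp <- evaccum:::metric_comparisons(trp, "CP", 3)
      if (!length(cmp)) next
      v <- evaccum:::ccs_neuron(prep$rates[, , 1], cmp)
      vals <- c(vals, abs(v - 0.5))
    }
    mean(vals)
  }, numeric(1))
  expect_lt(mean_dev[2], mean_dev[1])
})

test_that("latency estimation brackets a constructed onset delay", {
  tr <- make_task_trials(200, seed = 15)
  ds <- make_selectivity_cohort(20, list(stim = 0, choice = 0, evidence = 0,
                                         outcome = 10),
                                baseline_rate = 10, trials = tr, seed = 16,
                                delay = 0.08)
  lat <- estimate_latency(ds)
  expect_true(is.finite(lat$latency))
  expect_gte(lat$latency, 0.08)
  expect_lte(lat$latency, 0.18)
  # invariant to uniform rate scaling (rank-based test)
  ds2 <- ds
  ds2$spikes <- lapply(ds$spikes, function(s) sort(c(s, s)))
  expect_equal(estimate_latency(ds2)$latency, lat$latency)
})

test_that("stationary populations mostly yield no latency", {
  tr <- make_task_trials(150, seed = 17)
  res <- vapply(1:8, function(s) {
    ds <- make_selectivity_cohort(15, list(stim = 0, choice = 0,
                                           evidence = 0),
                                  baseline_rate = 10, trials = tr, seed = s)
    estimate_latency(ds)$latency
  }, numeric(1))
  # the pointwise test is exact but the run-length correction leaves some
  # family-wise error under 100 ms smoothing; require a clear majority absent
  expect_gte(mean(is.na(res)), 0.5)
})
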