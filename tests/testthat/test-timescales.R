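test_that("the AR(1) ground-truth timescale follows the closed form", {
  ds <- make_ar1_population(0.95, step = 0.025, n_trials = 50, seed = 1)
  expect_equal(ds$ground_truth$tau, 0.4874, tolerance = 1e-4)
  ds2 <- make_ar1_population(0.99, step = 0.025, n_trials = 50, seed = 1)
  expect_equal(ds2$ground_truth$tau, 2.4875, tolerance = 1e-4)
  expect_error(make_ar1_population(1.0, n_trials = 50), "stationary")
  # empirical lag-1 autocorrelation of the latent matches a
  ds3 <- make_ar1_population(0.9, n_trials = 2000, seed = 2)
  X <- ds3$ground_truth$latents
  r1 <- mean(vapply(1:7, function(i) stats::cor(X[, i], X[, i + 1]),
                    numeric(1)))
  expect_equal(r1, 0.9, tolerance = 0.03)
})

test_that("autocorrelation pooling has the right lag structure", {
  set.seed(3)
  counts <- array(stats::rpois(500 * 8 * 3, 2), c(500, 8, 3))
  cv <- spike_count_autocorrelation(counts, 0.025)
  expect_equal(cv$lag, 1:7)
  # independent bins: all pooled correlations near zero
  expect_true(all(abs(cv$value) < 3 / sqrt(500)))
  # invariant to neuron relabeling and trial order
  cv2 <- spike_count_autocorrelation(counts[sample(500), , c(3, 1, 2)], 0.025)
  expect_equal(sort(cv$pairs$r), sort(cv2$pairs$r), tolerance = 1e-12)
  expect_error(spike_count_autocorrelation(counts[1:10, , ]), ">= 20")
})

test_that("AR(1)-driven counts decay monotonically in pooled autocorrelation", {
  ds <- make_ar1_population(0.95, n_trials = 4000, n_neurons = 8, seed = 4)
  cv <- spike_count_autocorrelation(ds, 0.025, duration = 0.2)
  # allow small noise: fit a line to log-ish decay instead of strict sort
  expect_gt(cv$value[1], cv$value[4])
  expect_gt(cv$value[4], cv$value[7] - 0.01)
  expect_true(all(cv$value > 0))
})

test_that("noiseless exponential curves are recovered exactly", {
  lag_s <- (1:7) * 0.025
  truth <- list(A = 0.8, B = 0.05, tau = 0.3)
  vals <- truth$A * (exp(-lag_s / truth$tau) + truth$B)
  curve <- structure(list(lag = 1:7, delta = 0.025, value = vals,
                          n_pairs = rep(10, 7),
                          pairs = data.frame(lag = 1:7, r = vals),
                          n_trials = 100), class = "autocorr_curve")
  ft <- fit_timescale(curve)
  expect_equal(ft$A, truth$A, tolerance = 1e-4)
  expect_equal(ft$B, truth$B, tolerance = 1e-4)
  expect_equal(ft$tau, truth$tau, tolerance = 1e-4)
})

test_that("a sharp early drop moves the start lag past the adaptation", {
  vals <- c(0.5, 0.2, 0.18, 0.16, 0.145, 0.13, 0.12)
  curve <- structure(list(lag = 1:7, delta = 0.025, value = vals,
                          n_pairs = rep(10, 7),
                          pairs = data.frame(lag = 1:7, r = vals),
                          n_trials = 100), class = "autocorr_curve")
  expect_equal(fit_timescale(curve)$start_lag, 2)
})

test_that("subpopulation timescales are deterministic and degenerate correctly", {
  spec <- build_accumulator("single", init = list(A = 0.9, Q = 0.02))
  spec <- set_emissions(spec, default_emission_weights("single", 2, 2), 15,
                        dt = 0.01)
  st1 <- subpopulation_timescale(spec, n_samples = 3, n_trials = 400,
                                 seed = 5)
  st2 <- subpopulation_timescale(spec, n_samples = 3, n_trials = 400,
                                 seed = 5)
  expect_identical(st1$taus, st2$taus)
  # n_samples = 1 equals a single simulate + fit round
  st3 <- subpopulation_timescale(spec, n_samples = 1, n_trials = 400,
                                 seed = 5)
  expect_equal(st3$tau, st1$taus[1])
})

test_that("larger recurrent strength gives longer subpopulation timescales", {
  taus <- vapply(c(0.85, 0.95), function(A) {
    spec <- build_accumulator("single", init = list(A = A, Q = 0.02))
    spec <- set_emissions(spec, default_emission_weights("single", 2, 2), 15,
                          dt = 0.01)
    subpopulation_timescale(spec, n_samples = 8, n_trials = 800,
                            seed = 6)$tau
  }, numeric(1))
  expect_lt(taus[1], taus[2])
})

test_that("strength-timescale correlation handles edge cases and scaling", {
  df <- data.frame(region = "x", strength = seq(0.9, 0.99, length.out = 12),
                   tau = NA)
  df$tau <- 0.1 + 2 * (df$strength - 0.9) + c(0.01, -0.01)[1 + (1:12) %% 2]
  out <- strength_timescale_correlation(df)
  expect_gt(out$r[1], 0.9)
  # affine rescaling of tau leaves r unchanged
  df2 <- df; df2$tau <- 1000 * df$tau + 7
  expect_equal(strength_timescale_correlation(df2)$r, out$r,
               tolerance = 1e-12)
  # constant strength flagged
  df3 <- df; df3$strength <- 0.95
  out3 <- strength_timescale_correlation(df3)
  expect_true(is.na(out3$r[1]))
  expect_match(out3$note[1], "variance")
  # too few subpopulations flagged
  out4 <- strength_timescale_correlation(df[1:2, ])
  expect_match(out4$note[1], "few")
})

test_that("region bootstrap separates distinct timescales and not identical ones", {
  mk_curves <- function(A, n, seed0) lapply(seq_len(n), function(s) {
    spec <- build_accumulator("single", init = list(A = A, Q = 0.02))
    spec <- set_emissions(spec, default_emission_weights("single", 2, 2), 15,
                          dt = 0.01)
    sim <- simulate_fixed_length(spec, 3000, 0.2, seed = seed0 + s,
                                 bin_out = 0.025)
    spike_count_autocorrelation(sim$counts, 0.025)
  })
  rc <- list(fast = mk_curves(0.8, 8, 100), slow = mk_curves(0.94, 8, 200),
             slow2 = mk_curves(0.94, 8, 300))
  pt <- population_timescale(rc, n_boot = 40, seed = 7)
  expect_lt(pt$table$tau[1], pt$table$tau[2])
  p_diff <- pt$pairwise$p_corrected[pt$pairwise$region_a == "fast" &
                                      pt$pairwise$region_b == "slow"]
  expect_lt(p_diff, 0.001)
  # identically generated regions: the rank-sum on bootstrap replicates is
  # anticonservative by construction, so compare effect sizes instead
  d_same <- abs(pt$table$tau[2] - pt$table$tau[3])
  d_diff <- abs(pt$table$tau[1] - pt$table$tau[2])
  expect_lt(d_same, 0.5 * d_diff)
})
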