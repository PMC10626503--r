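test_that("noise-free simulation drifts deterministically to the boundary", {
  spec <- build_accumulator("single", init = list(A = 0.98, V = 0.05,
                                                  Q = 1e-12,
                                                  Q_move = 1e-12))
  spec <- set_emissions(spec, matrix(c(10, -10), 2, 1), 12, dt = 0.01)
  tr <- make_task_trials(40, seed = 1)
  tr$contrast_left <- 0; tr$contrast_right <- 1; tr$evidence <- 1
  sim <- simulate_accumulator(spec, tr, seed = 2)
  expect_true(all(sim$choice == "right"))
  # deterministic first passage of x_t = A x_{t-1} + V
  x <- 0; t_star <- 0
  repeat {
    t_star <- t_star + 1
    x <- 0.98 * x + 0.05
    if (x >= spec$B) break
  }
  # the softmax boundary lets commitment begin a few steps before the
  # deterministic crossing; all RTs cluster just below it
  expect_true(all(abs(sim$rt - t_star * spec$dt) <= 0.06))
  expect_lt(abs(mean(sim$rt) - t_star * spec$dt), 0.04)
  expect_lt(stats::sd(sim$rt), 0.03)
})

test_that("zero emission rate produces zero spikes", {
  spec <- build_accumulator("single")
  spec <- set_emissions(spec, matrix(0, 3, 1), -40, dt = 0.01)
  tr <- make_task_trials(10, seed = 1)
  sim <- simulate_accumulator(spec, tr, seed = 2)
  expect_equal(sum(vapply(sim$counts, sum, numeric(1))), 0)
})

test_that("choices are psychometric and reaction times chronometric", {
  spec <- fx_single_spec()
  tr <- make_task_trials(1200, seed = 11)
  # force two evidence levels with >= 500 trials each
  tr$contrast_left <- 0
  tr$contrast_right <- rep(c(0.25, 1), length.out = nrow(tr))
  tr$evidence <- tr$contrast_right
  sim <- simulate_accumulator(spec, tr, seed = 12)
  p_right <- tapply(sim$choice == "right", tr$evidence, mean)
  expect_gt(p_right[["1"]], p_right[["0.25"]])
  rt_by_ev <- tapply(sim$rt, tr$evidence, mean, na.rm = TRUE)
  expect_lt(rt_by_ev[["1"]], rt_by_ev[["0.25"]])
})

test_that("simulated datasets are deterministic and spikes stay in-window", {
  spec <- fx_single_spec()
  tr <- make_task_trials(30, seed = 4)
  d1 <- simulate_accumulator_dataset(spec, tr, seed = 5)
  d2 <- simulate_accumulator_dataset(spec, tr, seed = 5)
  expect_identical(d1$spikes, d2$spikes)
  expect_identical(d1$trials, d2$trials)
  # conservation: every spike inside its trial's simulated window
  ends <- ifelse(is.na(d1$trials$wheel_move),
                 d1$trials$stim_onset + 1.0, d1$trials$wheel_move + 0.05)
  starts <- d1$trials$stim_onset - 1.2
  for (st in d1$spikes) {
    in_some <- vapply(st, function(x)
      any(x >= starts & x <= ends + 0.011), logical(1))
    expect_true(all(in_some))
  }
})

test_that("no-crossing trials are labeled nogo and the boundary-free limit never commits", {
  spec <- build_accumulator("single", init = list(A = 0.9, V = 0.001,
                                                  Q = 1e-6), B = 1e6)
  spec <- set_emissions(spec, matrix(5, 1, 1), 10, dt = 0.01)
  tr <- make_task_trials(15, seed = 2)
  sim <- simulate_accumulator(spec, tr, seed = 3, max_duration = 0.5)
  expect_true(all(sim$choice == "nogo"))
  expect_true(all(is.na(sim$rt)))
  expect_true(all(vapply(sim$z, function(z) all(z == 1L), logical(1))))
})

test_that("deeper boundary collapse shortens reaction times", {
  tr <- make_task_trials(1000, seed = 6)
  mean_rt <- vapply(c(0.25, 0.75), function(beta) {
    spec <- build_accumulator("single", "exponential_collapse",
                              init = list(A = 0.98, V = 0.02, Q = 0.005,
                                          beta = beta, tau_c = 30))
    spec <- set_emissions(spec, matrix(c(10, -10), 2, 1), 12, dt = 0.01)
    sim <- simulate_accumulator(spec, tr, seed = 7)
    mean(sim$rt, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean_rt[1], mean_rt[2])
})

test_that("mutual inhibition decorrelates the race accumulators", {
  tr <- make_task_trials(400, seed = 8)
  tr$contrast_left <- 0.5; tr$contrast_right <- 0.5; tr$evidence <- 0
  end_corr <- function(kind, offd) {
    spec <- build_accumulator(kind, init = list(A = 0.95, V = 0.03, Q = 0.01,
                                                A_offdiag = offd,
                                                V_offdiag = 0), B = 1e6)
    spec <- set_emissions(spec, default_emission_weights(kind, 1, 1), 10,
                          dt = 0.01)
    sim <- simulate_accumulator(spec, tr, seed = 9, max_duration = 0.3)
    ends <- t(vapply(sim$latents, function(x) x[nrow(x), ], numeric(2)))
    stats::cor(ends[, 1], ends[, 2])
  }
  expect_lt(end_corr("dependent_race", -0.2),
            end_corr("independent_race", 0))
})

test_that("fixed-length simulation stores the AR(1) structure of the latent", {
  spec <- fx_single_spec()
  sim <- simulate_fixed_length(spec, 100, 0.2, seed = 3, bin_out = 0.025)
  expect_equal(dim(sim$counts), c(100, 8, 4))
  sim2 <- simulate_fixed_length(spec, 100, 0.2, seed = 3, bin_out = 0.025)
  expect_identical(sim$counts, sim2$counts)
})
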