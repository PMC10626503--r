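test_that("architectures have the prescribed shapes and structure", {
  s <- build_accumulator("single")
  expect_equal(c(s$K, s$D, s$M), c(3, 1, 1))
  ir <- build_accumulator("independent_race")
  expect_equal(c(ir$K, ir$D, ir$M), c(3, 2, 2))
  offd <- row(ir$A[["acc"]]) != col(ir$A[["acc"]])
  expect_true(all(ir$A[["acc"]][offd] == 0))
  expect_true(all(ir$V[["acc"]][offd] == 0))
  expect_true(all(ir$Q[["acc"]][offd] == 0))
  dr <- build_accumulator("dependent_race")
  expect_equal(c(dr$K, dr$D, dr$M), c(5, 2, 2))
  expect_equal(dr$A[["acc"]][1, 2], -0.05)
  for (spec in list(s, ir, dr)) for (st in spec$states[-1]) {
    expect_equal(spec$A[[st]], diag(1, spec$D))
    expect_true(all(spec$V[[st]] == 0))
  }
})

test_that("transition probabilities match the softmax boundary rule", {
  s <- build_accumulator("single", gamma = 1)
  # x = 0: logits (0, -1, -1) -> softmax = (0.5761, 0.2119, 0.2119)
  e1 <- exp(-1)
  expect_equal(transition_probs(s, 0),
               c(1, e1, e1) / (1 + 2 * e1), tolerance = 1e-12)
  expect_equal(round(transition_probs(s, 0), 4), c(0.5761, 0.2119, 0.2119))
  # x = B = 1: logits (0, 0, -2) -> softmax = (0.4683, 0.4683, 0.0634)
  e2 <- exp(-2)
  expect_equal(transition_probs(s, 1),
               c(1, 1, e2) / (2 + e2), tolerance = 1e-12)
  expect_equal(round(transition_probs(s, 1), 4), c(0.4683, 0.4683, 0.0634))
})

test_that("transition rows sum to one for all architectures and boundaries", {
  set.seed(1)
  for (kind in c("single", "independent_race", "dependent_race")) {
    for (bm in c("constant", "linear_collapse", "exponential_collapse")) {
      spec <- build_accumulator(kind, bm, gamma = sample(c(1, 25, 100), 1))
      for (i in 1:20) {
        x <- stats::rnorm(spec$D, sd = 2)
        t <- sample(0:200, 1)
        p <- transition_probs(spec, x, t)
        expect_equal(sum(p), 1, tolerance = 1e-12)
        expect_true(all(p >= 0))
      }
    }
  }
})

test_that("collapsing boundary profiles match direct evaluation", {
  for (beta in c(0.3, 0.4, 0.5)) for (tc in c(50, 100)) {
    spec <- build_accumulator("single", "exponential_collapse",
                              init = list(beta = beta, tau_c = tc))
    t <- 0:300
    expect_equal(boundary_factor(spec, t),
                 beta + (1 - beta) * exp(-t / tc), tolerance = 1e-12)
    expect_equal(boundary_factor(spec, 0), 1)
    expect_lt(abs(boundary_factor(spec, 1e7) - beta), 1e-9)
  }
  lin <- build_accumulator("single", "linear_collapse",
                           init = list(beta = 0.01))
  expect_equal(boundary_factor(lin, c(0, 50, 100)), c(1, 0.5, 0))
})

test_that("emission rates follow the softplus model", {
  spec <- build_accumulator("single")
  spec <- set_emissions(spec, matrix(0, 3, 1), 5, dt = 0.01)
  expect_equal(emission_rate(spec, 2.5),
               rep(log1p(exp(5)) * 0.01, 3), tolerance = 1e-12)
  spec2 <- set_emissions(spec, matrix(c(1, 2, 0.5), 3, 1), 0)
  expect_equal(emission_rate(spec2, 0), rep(log(2) * 0.01, 3),
               tolerance = 1e-12)
  # monotone in the latent for nonnegative weights
  r1 <- emission_rate(spec2, 0.2)
  r2 <- emission_rate(spec2, 0.7)
  expect_true(all(r2 >= r1))
})

test_that("free-parameter counts respect structural constraints", {
  # single: A(1) + Q_acc(1) + 2 movement Q(1 each) + C(4) + d(1) = 9
  s <- set_emissions(build_accumulator("single"),
                     default_emission_weights("single", 2, 2), 15)
  expect_equal(count_free_parameters(s), 9L)
  # independent race (all diagonal): 2 + 2 + 2*2 + 8 + 1 = 17
  ir <- set_emissions(build_accumulator("independent_race"),
                      default_emission_weights("independent_race", 2, 2), 15)
  expect_equal(count_free_parameters(ir), 17L)
  # dependent race (full): 4 + 3 + 4*3 + 8 + 1 = 28
  dr <- set_emissions(build_accumulator("dependent_race"),
                      default_emission_weights("dependent_race", 2, 2), 15)
  expect_equal(count_free_parameters(dr), 28L)
})

test_that("initial-value grids carry the published search values", {
  g <- accumulator_init_grid("single")
  expect_setequal(unique(g$A), c(0.95, 1))
  expect_setequal(unique(g$V), c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_setequal(unique(g$Q), c(0.005, 0.01))
  gd <- accumulator_init_grid("dependent_race")
  expect_setequal(unique(gd$A_offdiag), -0.05)
  expect_setequal(unique(gd$V_offdiag), c(-0.01, -0.02, -0.03))
  expect_setequal(unique(gd$Q), 0.01)
  gc <- accumulator_init_grid("single", "exponential_collapse")
  expect_setequal(unique(gc$beta), c(0.3, 0.4, 0.5))
  expect_setequal(unique(gc$tau_c), c(50, 100))
})

test_that("specs serialize to YAML and back", {
  spec <- set_emissions(build_accumulator("dependent_race",
                                          "exponential_collapse"),
                        default_emission_weights("dependent_race", 3, 1), 12)
  path <- withr::local_tempfile(fileext = ".yml")
  write_accumulator_spec(spec, path)
  back <- read_accumulator_spec(path)
  expect_equal(back$A, spec$A, tolerance = 1e-12)
  expect_equal(back$Q, spec$Q, tolerance = 1e-12)
  expect_equal(back$C, spec$C, tolerance = 1e-12)
  expect_equal(back$boundary, spec$boundary)
})
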