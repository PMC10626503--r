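test_that("Laplace-EM recovers dynamics and emissions on simulated data", {
  fit <- fx_single_fit()
  a_hat <- fit$spec$A[["acc"]][1, 1]
  expect_gt(a_hat, 0.94)
  expect_lt(a_hat, 1.01)
  # emission weights recover sign structure and rough scale (true +/-15)
  expect_true(all(sign(fit$spec$C[, 1]) == c(1, 1, -1, -1)))
  expect_true(all(abs(abs(fit$spec$C[, 1]) - 15) < 8))
  expect_lt(abs(fit$spec$d - 15), 3)
})

test_that("the objective trace settles to a converged value", {
  fit <- fx_single_fit()
  d <- diff(fit$elbo_trace)
  n <- length(d)
  # the Laplace marginal estimate may drift while parameters converge;
  # require the per-iteration change to shrink by an order of magnitude
  expect_lt(mean(abs(d[max(1, n - 2):n])), 0.1 * mean(abs(d[1:3])))
  expect_true(all(abs(d) < 0.01 * abs(fit$loglik)))
})

test_that("posterior discrete marginals are proper and crossings localized", {
  fit <- fx_single_fit()
  for (j in sample(seq_along(fit$post), 10)) {
    q <- fit$post[[j]]$q
    expect_equal(rowSums(q), rep(1, nrow(q)), tolerance = 1e-8)
    # trials start in the accumulation state with near certainty
    expect_gt(q[1, 1], 0.9)
    # movement-state mass can only appear, never vanish (absorbing states)
    move <- rowSums(q[, 2:3, drop = FALSE])
    expect_true(all(diff(move) > -1e-6))
  }
})

test_that("true generating parameters beat mismatched parameters in objective", {
  ds <- fx_single_ds()
  near_truth <- fit_laplace_em(ds, "single",
                               init_grid = data.frame(A = 0.98, V = 0.05,
                                                      Q = 0.005),
                               max_em = 1, seed = 1)
  mismatched <- fit_laplace_em(ds, "single",
                               init_grid = data.frame(A = 0.5, V = 0.01,
                                                      Q = 0.005),
                               max_em = 1, seed = 1)
  expect_gt(near_truth$loglik, mismatched$loglik)
})

test_that("the greedy initialization search keeps the best of the grid", {
  ds <- fx_single_ds()
  grid <- data.frame(A = c(0.5, 0.95), V = c(0.01, 0.05), Q = 0.005)
  fit <- fit_laplace_em(ds, "single", init_grid = grid, max_em = 6, seed = 2)
  expect_equal(fit$init$A, 0.95)
  expect_equal(fit$init$V, 0.05)
})

test_that("trial filters follow the modeling contract", {
  ds <- fx_single_ds()
  prep <- evaccum:::prepare_fit_trials(ds, 0.01, 0, c(0.15, 0.5), 0.05)
  tr <- ds$trials[prep$trial_idx, ]
  expect_true(all(tr$contrast_left != tr$contrast_right))
  expect_true(all(tr$choice %in% c("left", "right")))
  expect_true(all(tr$reaction_time > 0.15 & tr$reaction_time < 0.5))
  # window length: latency to wheel move + 50 ms at 10 ms bins
  expect_equal(vapply(prep$y, nrow, integer(1)),
               pmax(2L, floor((tr$reaction_time + 0.05) / 0.01 + 1e-9)))
})
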