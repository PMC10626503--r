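fx_dpca_cohort <- function() fx_memo("dpca_cohort", function() {
  tr <- make_task_trials(1200, seed = 21)
  make_selectivity_cohort(
    30, data.frame(stim = rep(c(12, 0), each = 15),
                   outcome = rep(c(0, 12), each = 15),
                   choice = 0, evidence = 0),
    baseline_rate = 12, trials = tr, seed = 22)
})

test_that("marginalizations sum to the full (centered) tensor", {
  tens <- build_marginalized_tensor(fx_dpca_cohort())
  total <- tens$marg$t + tens$marg$st + tens$marg$dt + tens$marg$sdt
  expect_lt(max(abs(total - tens$X)), 1e-10)
  expect_equal(tens$contrasts, c(1, 0.5, 0.25, 0))
})

test_that("stimulus-only neurons have negligible decision marginalization", {
  tens <- build_marginalized_tensor(fx_dpca_cohort())
  stim_ids <- 1:15
  pow <- function(m, ids) mean(m[ids, , , ]^2)
  expect_gt(pow(tens$marg$st, stim_ids), 5 * pow(tens$marg$dt, stim_ids))
  # finite-trial noise lands mostly in the interaction residual, so the
  # bound there is looser
  expect_gt(pow(tens$marg$st, stim_ids), 3 * pow(tens$marg$sdt, stim_ids))
})

test_that("silent neurons are excluded by the spike-count mask", {
  ds <- fx_dpca_cohort()
  ds$spikes[[5]] <- numeric(0)
  tens <- build_marginalized_tensor(ds)
  expect_false(tens$included[5])
  expect_true(all(tens$included[-5]))
})

test_that("dPCA recovers a planted low-rank stimulus subspace", {
  # synthetic tensor: rank-2 stimulus structure + small noise
  set.seed(23)
  nn <- 30; nb <- 40
  F2 <- matrix(stats::rnorm(nn * 2), nn, 2)
  s_profiles <- rbind(seq(-1.5, 1.5, length.out = 4),
                      c(1, -1, -1, 1))
  t_prof <- rbind(sin(seq(0, pi, length.out = nb)),
                  cos(seq(0, pi, length.out = nb)))
  X <- array(0, c(nn, 4, 2, nb))
  for (s in 1:4) for (d in 1:2) for (t in 1:nb)
    X[, s, d, t] <- F2 %*% (s_profiles[, s] * t_prof[, t]) +
      stats::rnorm(nn, sd = 0.05)
  tens <- structure(list(X = X - mean(X), included = rep(TRUE, nn)),
                    class = "marginalized_tensor")
  grand <- apply(tens$X, 1, mean)
  Xc <- sweep(tens$X, 1, grand)
  m_t <- apply(Xc, c(1, 4), mean)
  m_st <- apply(Xc, c(1, 2, 4), mean)
  m_dt <- apply(Xc, c(1, 3, 4), mean)
  full_t <- aperm(array(m_t, c(nn, nb, 4, 2)), c(1, 3, 4, 2))
  full_st <- aperm(array(m_st, c(nn, 4, nb, 2)), c(1, 2, 4, 3)) - full_t
  full_dt <- aperm(array(m_dt, c(nn, 2, nb, 4)), c(1, 4, 2, 3)) - full_t
  tens$X <- Xc
  tens$marg <- list(t = full_t, st = full_st, dt = full_dt,
                    sdt = Xc - full_t - full_st - full_dt)
  fit <- fit_dpca(tens, n_components = 10)
  Xst <- evaccum:::unroll(full_st)
  recon <- fit$F$st %*% fit$D$st %*% evaccum:::unroll(Xc)
  frac <- 1 - sum((recon - Xst)^2) / sum(Xst^2)
  expect_gte(frac, 0.9)
})

test_that("component count never increases the loss and zero tensors cost nothing", {
  tens <- build_marginalized_tensor(fx_dpca_cohort())
  l5 <- fit_dpca(tens, n_components = 5)$loss
  l20 <- fit_dpca(tens, n_components = 20)$loss
  expect_lte(l20, l5 + 1e-8)
  zt <- tens
  zt$X <- zt$X * 0
  for (a in names(zt$marg)) zt$marg[[a]] <- zt$marg[[a]] * 0
  zfit <- fit_dpca(zt)
  expect_equal(zfit$loss, 0)
})

test_that("marginalization R2 separates stimulus from decision neurons", {
  tens <- build_marginalized_tensor(fx_dpca_cohort())
  fit <- fit_dpca(tens)
  r2 <- marginalization_r2(fit, tens)
  expect_true(all(r2$R2_st <= 1 + 1e-9, na.rm = TRUE))
  stim <- r2$neuron_id <= 15
  expect_gt(mean(r2$R2_st[stim] > r2$R2_dt[stim]), 0.9)
  expect_gt(mean(r2$R2_dt[!stim] > r2$R2_st[!stim]), 0.9)
})

test_that("fuzzy C-means recovers separated blobs and matches e1071", {
  set.seed(24)
  pts <- rbind(cbind(stats::rnorm(50, 0.8, 0.05), stats::rnorm(50, 0.1, 0.05)),
               cbind(stats::rnorm(50, 0.1, 0.05), stats::rnorm(50, 0.8, 0.05)),
               cbind(stats::rnorm(50, 0.15, 0.05), stats::rnorm(50, 0.2, 0.05)))
  df <- data.frame(R2_st = pts[, 1], R2_dt = pts[, 2])
  cl <- cluster_neurons(df, seed = 25)
  truth <- rep(c("stimulus", "decision", "interaction"), each = 50)
  expect_gte(mean(cl$label == truth), 0.95)
  expect_equal(rowSums(cl$membership), rep(1, 150), tolerance = 1e-9)
  expect_true(all(diff(cl$objective) <= 1e-8))
  # permutation invariance of the centroids (up to relabeling)
  perm <- sample(150)
  cl2 <- cluster_neurons(df[perm, ], seed = 25)
  c1 <- cl$centers[order(cl$centers[, 1]), ]
  c2 <- cl2$centers[order(cl2$centers[, 1]), ]
  expect_equal(c1, c2, tolerance = 0.05)
  # independent implementation agreement
  skip_if_not_installed("e1071")
  cm <- e1071::cmeans(pts, 3, m = 2)
  e_lab <- apply(cm$membership, 1, which.max)
  tab <- table(e_lab, cl$label)
  expect_gte(sum(apply(tab, 1, max)) / 150, 0.95)
})

test_that("degenerate identical points give equal memberships", {
  df <- data.frame(R2_st = c(0, 0, 0, 1, 1, 0.5),
                   R2_dt = c(0, 0, 0, 1, 1, 0.2))
  fcm <- evaccum:::fuzzy_cmeans(as.matrix(df), 3, seed = 1)
  expect_equal(rowSums(fcm$membership), rep(1, 6), tolerance = 1e-9)
})
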