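test_that("contrast sampling respects the condition grid", {
  tr <- make_task_trials(2000, include_equal_contrast = FALSE, seed = 1)
  expect_true(all(tr$contrast_left != tr$contrast_right))
  cells <- unique(paste(tr$contrast_left, tr$contrast_right))
  expect_length(cells, 12)

  tr2 <- make_task_trials(2000, include_equal_contrast = TRUE, seed = 1)
  expect_length(unique(paste(tr2$contrast_left, tr2$contrast_right)), 16)
  expect_true(all(tr2$contrast_left %in% c(0, 0.25, 0.5, 1)))
})

test_that("trial tables are deterministic per seed and validate inputs", {
  expect_identical(make_task_trials(50, seed = 9),
                   make_task_trials(50, seed = 9))
  expect_false(identical(make_task_trials(50, seed = 9),
                         make_task_trials(50, seed = 10)))
  expect_error(make_task_trials(0), "positive")
  expect_error(make_task_trials(10, rt_range = c(0.5, 0.2)), "increasing")
})

test_that("trial-table invariants hold: evidence, timing, reward rule", {
  tr <- make_task_trials(500, include_equal_contrast = TRUE, seed = 3)
  expect_true(all(tr$evidence == tr$contrast_right - tr$contrast_left))
  expect_lte(length(unique(tr$evidence)), 9)
  go <- tr$choice != "nogo"
  expect_equal(tr$reaction_time[go], tr$wheel_move[go] - tr$stim_onset[go])
  expect_true(all(is.na(tr$reaction_time[!go])))
  # reward rule: hit iff higher-contrast side chosen (nogo iff both blank)
  higher <- ifelse(tr$contrast_right > tr$contrast_left, "right",
             ifelse(tr$contrast_left > tr$contrast_right, "left",
               ifelse(tr$contrast_left == 0, "nogo", "either")))
  expected_hit <- (higher == tr$choice) |
    (higher == "either" & tr$choice != "nogo")
  expect_equal(tr$outcome == "hit", expected_hit)
})

test_that("spike datasets round-trip through the plain-text writers", {
  ds <- make_ar1_population(0.9, n_trials = 30, n_neurons = 3, seed = 2)
  dir <- withr::local_tempdir()
  write_spike_dataset(ds, dir)
  back <- read_spike_dataset(dir)
  expect_equal(back$spikes, ds$spikes, tolerance = 1e-9)
  expect_equal(back$trials$evidence, ds$trials$evidence)
  expect_equal(back$neurons$pref_side, ds$neurons$pref_side)
  expect_equal(back$ground_truth$tau, ds$ground_truth$tau, tolerance = 1e-6)
})

test_that("spike binning counts every spike in half-open bins", {
  ds <- spike_dataset(
    list(c(0.9, 1.0025, 1.0074, 1.0051, 1.299)),
    data.frame(trial = 1, contrast_left = 0, contrast_right = 1,
               evidence = 1, choice = "right", outcome = "hit",
               stim_onset = 1, wheel_move = 1.3, reaction_time = 0.3))
  bc <- bin_spike_counts(ds, "stim_onset", c(0, 0.3), 0.005)
  expect_equal(sum(bc$counts), 4)              # 0.9 falls before the window
  expect_equal(bc$counts[1, 1, 1], 1)          # [0, 0.005): spike at 1.0025
  expect_equal(bc$counts[1, 2, 1], 2)          # [0.005, 0.01)
  expect_equal(bc$counts[1, 60, 1], 1)         # last bin: 1.299
})
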