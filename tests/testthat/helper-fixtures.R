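# shared small fixtures, built once per test run

fx_env <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(fx_env[[key]])) fx_env[[key]] <- builder()
  fx_env[[key]]
}

# 300-trial task table
fx_trials <- function() fx_memo("trials", function()
  make_task_trials(300, seed = 42))

# small single-accumulator dataset (4 neurons)
fx_single_ds <- function() fx_memo("single_ds", function() {
  spec <- fx_single_spec()
  simulate_accumulator_dataset(spec, fx_trials(), seed = 7)
})

fx_single_spec <- function() fx_memo("single_spec", function() {
  spec <- build_accumulator("single",
                            init = list(A = 0.98, V = 0.05, Q = 0.005))
  set_emissions(spec, default_emission_weights("single", 2, 2), 15,
                dt = 0.01)
})

# a modest single-accumulator fit reused by fit/selection tests
fx_single_fit <- function() fx_memo("single_fit", function()
  fit_laplace_em(fx_single_ds(), "single",
                 init_grid = data.frame(A = 0.95, V = 0.05, Q = 0.005),
                 max_em = 25, tol = 1e-5, seed = 3))

# brute-force auROC: count pairs with b > a, half credit for ties
oracle_auroc <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (y > x) + 0.5 * (y == x)
  s / (length(a) * length(b))
}
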