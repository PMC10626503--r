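#' Construct an accumulator microcircuit specification
#'
#' Builds one of three accumulator architectures formulated as a recurrent
#' switching linear dynamical system (rSLDS) with Poisson spike emissions:
#'
#' * `"single"`: one decision variable accumulating the difference of the two
#'   input streams between boundaries at +/-B (the drift-diffusion model).
#'   K = 3 discrete states (accumulation, right wheel movement, left wheel
#'   movement), D = 1 latent, M = 1 input.
#' * `"independent_race"`: two uncoupled integrators, one per choice, racing
#'   to a boundary at +B. Dynamics, input weights and noise are diagonal.
#'   K = 3, D = 2, M = 2.
#' * `"dependent_race"`: two fully-connected integrators (mutual /
#'   feedforward coupling through off-diagonal dynamics); because coupled
#'   accumulators can be driven to either boundary, K = 5 discrete states
#'   (accumulation plus positive/negative crossing states per accumulator),
#'   D = 2, M = 2.
#'
#' Discrete-state transitions depend on the continuous latent through fixed
#' (untrained) parameters: the accumulation-state logit is 0 and each movement
#' state's logit is the signed accumulator value minus the boundary, scaled by
#' the transition gain `gamma` (see [transition_probs()]). Movement states
#' have identity dynamics, zero input weight and are absorbing. The dynamics
#' offset b is excluded throughout (fixed 0).
#'
#' @param kind `"single"`, `"independent_race"` or `"dependent_race"`.
#' @param boundary_mode `"constant"`, `"linear_collapse"` or
#'   `"exponential_collapse"`.
#' @param init list of initial parameter values; recognized fields `A`
#'   (diagonal recurrent strength), `V` (diagonal input weight), `Q`
#'   (diagonal noise variance), `A_offdiag`, `V_offdiag` (dependent race
#'   only), `Q_move` (movement-state noise variance), `beta`, `tau_c`
#'   (collapsing-boundary offset and decay constant, `tau_c` in time steps).
#'   Missing fields take mid-grid defaults.
#' @param gamma transition gain (sharpness of the boundary). The default 25
#'   makes boundary crossing nearly deterministic at 0.01 s steps; see the
#'   methods vignette for why the soft gain of 1 is unusable for generation.
#' @param B boundary height (default 1).
#' @param dt emission bin width (s).
#' @return object of class `accumulator_spec`.
#' @export
build_accumulator <- function(kind = c("single", "independent_race",
                                       "dependent_race"),
                              boundary_mode = c("constant", "linear_collapse",
                                                "exponential_collapse"),
                              init = list(), gamma = 25, B = 1, dt = 0.01) {
  kind <- match.arg(kind)
  boundary_mode <- match.arg(boundary_mode)
  defaults <- list(A = 0.98, V = 0.05, Q = 0.005, A_offdiag = -0.05,
                   V_offdiag = -0.02, Q_move = 0.005, beta = 0.4, tau_c = 100)
  if (kind[1] == "dependent_race" && is.null(init$Q)) init$Q <- 0.01
  for (nm in names(defaults)) if (is.null(init[[nm]])) init[[nm]] <- defaults[[nm]]

  if (kind == "single") {
    K <- 3L; D <- 1L; M <- 1L
    states <- c("acc", "rwm", "lwm")
    choice_map <- c(rwm = "right", lwm = "left")
    Rmat <- matrix(c(0, 1, -1), nrow = 3)
    A_acc <- matrix(init$A[1], 1, 1)
    V_acc <- matrix(init$V[1], 1, 1)
    Q_acc <- matrix(init$Q[1], 1, 1)
  } else if (kind == "independent_race") {
    K <- 3L; D <- 2L; M <- 2L
    states <- c("acc", "rwm", "lwm")
    choice_map <- c(rwm = "right", lwm = "left")
    Rmat <- rbind(c(0, 0), c(1, 0), c(0, 1))
    A_acc <- diag(rep_len(init$A, 2))
    V_acc <- diag(rep_len(init$V, 2))
    Q_acc <- diag(rep_len(init$Q, 2))
  } else {
    K <- 5L; D <- 2L; M <- 2L
    states <- c("acc", "prwm", "nrwm", "plwm", "nlwm")
    # positive crossing of an accumulator commits to its own side; a
    # collapse of an accumulator to -B is evidence for the other side
    choice_map <- c(prwm = "right", nrwm = "left", plwm = "left",
                    nlwm = "right")
    Rmat <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    A_acc <- diag(rep_len(init$A, 2))
    A_acc[A_acc == 0] <- rep_len(init$A_offdiag, 2)
    V_acc <- diag(rep_len(init$V, 2))
    V_acc[V_acc == 0] <- rep_len(init$V_offdiag, 2)
    Q_acc <- diag(rep_len(init$Q, 2))
  }
  rvec <- c(0, rep(-B, K - 1L))

  A <- c(list(A_acc), rep(list(diag(1, D)), K - 1L))
  V <- c(list(V_acc), rep(list(matrix(0, D, M)), K - 1L))
  Q <- c(list(Q_acc), rep(list(diag(init$Q_move[1], D)), K - 1L))
  names(A) <- names(V) <- names(Q) <- states

  spec <- structure(list(
    kind = kind, K = K, D = D, M = M,
    A = A, V = V, Q = Q,
    R = Rmat, r = rvec, gamma = gamma, B = B,
    boundary = list(mode = boundary_mode, beta = init$beta,
                    tau_c = init$tau_c),
    C = NULL, d = NULL, dt = dt,
    states = states, choice_map = choice_map,
    trainable = list(A_acc = TRUE, Q_acc = TRUE, Q_move = TRUE,
                     V_acc = FALSE, emissions = TRUE)
  ), class = "accumulator_spec")
  validate_accumulator(spec)
  spec
}

validate_accumulator <- function(spec) {
  with(spec, {
    stopifnot(K == length(states), nrow(R) == K, length(r) == K,
              all(dim(A[[1]]) == c(D, D)), all(dim(V[[1]]) == c(D, M)))
    if (kind == "independent_race") {
      offd <- row(A[["acc"]]) != col(A[["acc"]])
      if (any(A[["acc"]][offd] != 0) || any(V[["acc"]][offd] != 0) ||
          any(Q[["acc"]][offd] != 0))
        stop("independent race requires diagonal A, V, Q")
    }
    for (s in states[-1]) {
      if (any(A[[s]] != diag(1, D)) || any(V[[s]] != 0))
        stop("movement states must have A = I, V = 0")
    }
  })
  invisible(spec)
}

#' Attach Poisson emission parameters to a spec
#'
#' Emission model: counts per bin are Poisson with mean
#' `softplus(C x + d) * dt`. `C` maps the D latent dimensions to N neurons;
#' the scalar offset `d` is shared across neurons.
#'
#' @param spec an `accumulator_spec`.
#' @param C numeric N x D matrix of emission weights.
#' @param d scalar shared offset (units of the softplus argument; for large
#'   values `softplus(d)` is approximately the baseline rate in Hz).
#' @param dt optional new bin width (s).
#' @return the updated spec.
#' @export
set_emissions <- function(spec, C, d, dt = NULL) {
  C <- as.matrix(C)
  stopifnot(ncol(C) == spec$D, length(d) == 1L)
  spec$C <- C
  spec$d <- as.numeric(d)
  if (!is.null(dt)) spec$dt <- dt
  spec
}

#' Time profile of the decision boundary
#'
#' Returns the effective boundary at step `t` (0-based), divided by B:
#' 1 for a constant boundary; `max(0, 1 - beta t / B)` for the linear
#' collapse; `f(t) = beta + (1 - beta) exp(-t / tau_c)` for the exponential
#' collapse, so `f(0) = 1` and `f(t) -> beta`.
#'
#' @param spec an `accumulator_spec`.
#' @param t step index (vectorized, in units of `dt`).
#' @export
boundary_factor <- function(spec, t) {
  bm <- spec$boundary
  switch(bm$mode,
         constant = rep(1, length(t)),
         linear_collapse = pmax(0, 1 - bm$beta * t / spec$B),
         exponential_collapse = bm$beta + (1 - bm$beta) * exp(-t / bm$tau_c))
}

#' Discrete-state transition probabilities
#'
#' Probability of the next discrete state given the current continuous latent:
#' `softmax(gamma * (R x + r(t)))`, where the movement-state entries of `r(t)`
#' equal minus the (possibly collapsing) effective boundary. Transitions out
#' of a movement state are absorbing and do not depend on `x`; this function
#' returns the accumulation-source row.
#'
#' @param spec an `accumulator_spec`.
#' @param x numeric latent vector (length D).
#' @param t step index (0-based), used by collapsing boundaries.
#' @return probability vector over the K discrete states (sums to 1).
#' @export
transition_probs <- function(spec, x, t = 0) {
  stopifnot(length(x) == spec$D, all(is.finite(x)))
  logits <- transition_logits(spec, x, t)
  p <- exp(logits - max(logits))
  p / sum(p)
}

transition_logits <- function(spec, x, t) {
  reff <- c(0, rep(-spec$B * boundary_factor(spec, t), spec$K - 1L))
  as.numeric(spec$gamma * (spec$R %*% x + reff))
}

#' Expected spike counts per bin
#'
#' `softplus(C x + d) * dt`, elementwise over neurons; strictly positive.
#'
#' @param spec an `accumulator_spec` with emissions set.
#' @param x latent vector (length D) or T x D matrix of latents.
#' @return per-neuron expected counts (vector, or T x N matrix for matrix
#'   input).
#' @export
emission_rate <- function(spec, x) {
  if (is.null(spec$C)) stop("emissions not set; see set_emissions()")
  if (is.matrix(x)) {
    eta <- x %*% t(spec$C) + spec$d
    softplus(eta) * spec$dt
  } else {
    as.numeric(softplus(spec$C %*% x + spec$d) * spec$dt)
  }
}

# numerically stable softplus and its derivatives
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Free (trainable) parameter count of a spec
#'
#' Counts trainable scalars under the architecture's structural constraints:
#' the accumulation-state recurrent matrix (diagonal for the independent
#' race, full for the dependent race), the accumulation and movement-state
#' noise (co)variances (diagonal where the architecture is diagonal,
#' symmetric otherwise), the emission weights C and the shared offset d.
#' Input weights V, transition parameters and the boundary are fixed.
#'
#' @param spec an `accumulator_spec` with emissions set.
#' @export
count_free_parameters <- function(spec) {
  D <- spec$D
  diag_struct <- spec$kind %in% c("single", "independent_race")
  nA <- if (diag_struct) D else D * D
  nQ <- if (diag_struct) D else D * (D + 1) / 2
  n_move <- (spec$K - 1L) * nQ
  nE <- if (is.null(spec$C)) 0L
  else if (!is.null(spec$C_mask)) sum(spec$C_mask) + 1L
  else length(spec$C) + 1L
  as.integer(nA + nQ + n_move + nE)
}

#' Initial-value grids for the greedy initialization search
#'
#' The grids over which model fitting tries initial dynamics values, per
#' architecture: single accumulator `A in {0.95, 1}`,
#' `V in {0.01, ..., 0.05}`, `Q in {0.005, 0.01}`; independent race
#' `A in {0.95, 1}`, `V in {0.01, 0.02, 0.03}`, `Q in {0.005, 0.01}`;
#' dependent race diagonal `A in {0.95, 1}`, `V in {0.01, 0.02, 0.03}`,
#' `Q in {0.01}`, off-diagonal `A in {-0.05}`, `V in {-0.01, -0.02, -0.03}`.
#' Collapsing boundaries add `beta in {0.3, 0.4, 0.5}`,
#' `tau_c in {50, 100}` steps.
#'
#' @param kind architecture name.
#' @param boundary_mode boundary mode.
#' @return data.frame with one row per initial-value combination.
#' @export
accumulator_init_grid <- function(kind, boundary_mode = "constant") {
  g <- switch(kind,
    single = expand.grid(A = c(0.95, 1), V = c(0.01, 0.02, 0.03, 0.04, 0.05),
                         Q = c(0.005, 0.01)),
    independent_race = expand.grid(A = c(0.95, 1), V = c(0.01, 0.02, 0.03),
                                   Q = c(0.005, 0.01)),
    dependent_race = expand.grid(A = c(0.95, 1), V = c(0.01, 0.02, 0.03),
                                 Q = 0.01, A_offdiag = -0.05,
                                 V_offdiag = c(-0.01, -0.02, -0.03)),
    stop("unknown kind: ", kind))
  if (boundary_mode != "constant")
    g <- merge(g, expand.grid(beta = c(0.3, 0.4, 0.5), tau_c = c(50, 100)))
  g
}

#' Serialize / deserialize a spec as YAML
#'
#' @param spec an `accumulator_spec`.
#' @param path file path.
#' @export
write_accumulator_spec <- function(spec, path) {
  ser <- list(kind = spec$kind, gamma = spec$gamma, B = spec$B, dt = spec$dt,
              boundary = spec$boundary,
              A = lapply(spec$A, function(m) as.numeric(m)),
              V = lapply(spec$V, function(m) as.numeric(m)),
              Q = lapply(spec$Q, function(m) as.numeric(m)),
              C = if (!is.null(spec$C)) list(values = as.numeric(spec$C),
                                             nrow = nrow(spec$C)),
              d = spec$d)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_accumulator_spec
#' @export
read_accumulator_spec <- function(path) {
  ser <- yaml::read_yaml(path)
  spec <- build_accumulator(ser$kind, ser$boundary$mode,
                            init = list(beta = ser$boundary$beta,
                                        tau_c = ser$boundary$tau_c),
                            gamma = ser$gamma, B = ser$B, dt = ser$dt)
  D <- spec$D
  for (s in spec$states) {
    spec$A[[s]] <- matrix(ser$A[[s]], D, D)
    spec$V[[s]] <- matrix(ser$V[[s]], D, spec$M)
    spec$Q[[s]] <- matrix(ser$Q[[s]], D, D)
  }
  if (!is.null(ser$C))
    spec <- set_emissions(spec, matrix(ser$C$values, nrow = ser$C$nrow), ser$d)
  spec
}

#' @export
print.accumulator_spec <- function(x, ...) {
  cat("<accumulator_spec> ", x$kind, " (K=", x$K, ", D=", x$D, ", M=", x$M,
      "), boundary ", x$boundary$mode,
      if (!is.null(x$C)) paste0(", ", nrow(x$C), " neurons") else
        ", emissions unset",
      "\n", sep = "")
  invisible(x)
}
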