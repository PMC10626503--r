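#' Build the marginalized population-activity tensor
#'
#' Trial-averaged activity of every neuron over contralateral (right-screen)
#' contrast level (ordered 1, 0.5, 0.25, 0), decision (hit, miss) and time
#' (-0.1 to 0.3 s, stimulus aligned), with the standard marginalization
#' decomposition into condition-independent (`t`), stimulus (`st`), decision
#' (`dt`) and interaction (`sdt`) parts. The stored tensor is centered per
#' neuron (the per-neuron grand mean is kept separately) so the four
#' marginalizations sum exactly to it. Neurons whose average total spike
#' count from stimulus onset to wheel movement is below one are flagged in
#' the inclusion mask. Empty condition cells are imputed with the
#' condition-independent mean and flagged.
#'
#' @param dataset a `spike_dataset`.
#' @param window time window (s), stimulus aligned.
#' @param bin bin width (s).
#' @return list of class `marginalized_tensor`: `X` (centered N x 4 x 2 x T
#'   array), `marg` (list `t`, `st`, `dt`, `sdt` of same-shaped arrays),
#'   `grand_mean` (per neuron), `contrasts`, `time`, `included` (logical),
#'   `imputed` (logical 4 x 2).
#' @export
build_marginalized_tensor <- function(dataset, window = c(-0.1, 0.3),
                                      bin = 0.01) {
  tr <- dataset$trials
  bc <- bin_spike_counts(dataset, "stim_onset", window, bin)
  tr <- bc$trials
  contrasts <- c(1, 0.5, 0.25, 0)
  nn <- dim(bc$counts)[3]; nb <- dim(bc$counts)[2]

  X <- array(NA_real_, dim = c(nn, 4, 2, nb))
  counts_cell <- matrix(0L, 4, 2)
  for (si in 1:4) for (di in 1:2) {
    dec <- if (di == 1) "hit" else "miss"
    i <- which(tr$contrast_right == contrasts[si] & tr$outcome == dec)
    counts_cell[si, di] <- length(i)
    if (length(i))
      X[, si, di, ] <- t(apply(bc$counts[i, , , drop = FALSE], c(2, 3),
                               mean)) / bin
  }
  imputed <- counts_cell == 0

  # inclusion: average total spike count >= 1 between onset and wheel move
  go <- is.finite(tr$wheel_move)
  avg_cnt <- rep(0, nn)
  if (any(go)) {
    tot <- matrix(0, sum(go), nn)
    gidx <- which(go)
    for (n in seq_len(nn)) {
      st <- dataset$spikes[[n]]
      for (j in seq_along(gidx)) {
        i <- gidx[j]
        tot[j, n] <- sum(st >= tr$stim_onset[i] & st < tr$wheel_move[i])
      }
    }
    avg_cnt <- colMeans(tot)
  }
  included <- avg_cnt >= 1

  # impute empty cells with the condition-independent mean
  Xt_raw <- apply(X, c(1, 4), mean, na.rm = TRUE)
  for (si in 1:4) for (di in 1:2) if (imputed[si, di])
    X[, si, di, ] <- Xt_raw

  grand <- apply(X, 1, mean)
  Xc <- sweep(X, 1, grand)
  m_t <- apply(Xc, c(1, 4), mean)                       # N x T
  m_st <- apply(Xc, c(1, 2, 4), mean)                   # N x 4 x T
  m_dt <- apply(Xc, c(1, 3, 4), mean)                   # N x 2 x T
  full_t <- aperm(array(m_t, c(nn, nb, 4, 2)), c(1, 3, 4, 2))
  full_st <- aperm(array(m_st, c(nn, 4, nb, 2)), c(1, 2, 4, 3)) - full_t
  full_dt <- aperm(array(m_dt, c(nn, 2, nb, 4)), c(1, 4, 2, 3)) - full_t
  full_sdt <- Xc - full_t - full_st - full_dt

  structure(list(X = Xc, marg = list(t = full_t, st = full_st, dt = full_dt,
                                     sdt = full_sdt),
                 grand_mean = grand, contrasts = contrasts, time = bc$time,
                 included = included, imputed = imputed,
                 avg_count = avg_cnt),
            class = "marginalized_tensor")
}

unroll <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1])
}

#' Fit demixed principal component analysis
#'
#' Minimizes `sum_alpha || X_alpha - F_alpha D_alpha X ||^2` over per
#' marginalization encoder (`F_alpha`) and decoder (`D_alpha`) matrices by
#' reduced-rank ridge regression of each marginalization on the full centered
#' data: the ridge solution is truncated to its leading singular components,
#' and the `n_components` components with the largest explained variance
#' across all marginalizations are retained. The ridge penalty is chosen by
#' generalized cross-validation over a log-spaced grid unless given.
#'
#' @param tensor a `marginalized_tensor`.
#' @param n_components total task-related components across marginalizations.
#' @param ridge nonnegative ridge penalty, or NULL for the GCV choice.
#' @return list of class `dpca_result`: per-marginalization `F` and `D`
#'   matrices, `n_comp` (allocation), `var_explained`, `loss`, `ridge`.
#' @export
fit_dpca <- function(tensor, n_components = 20, ridge = NULL) {
  keep <- tensor$included
  if (!any(keep)) stop("no neurons pass the inclusion mask")
  X <- unroll(tensor$X)[keep, , drop = FALSE]
  margs <- lapply(tensor$marg, function(m) unroll(m)[keep, , drop = FALSE])
  nn <- nrow(X)

  sv <- svd(X)
  if (is.null(ridge)) ridge <- gcv_ridge(sv, margs)
  shrink <- ifelse(sv$d > 1e-12, sv$d / (sv$d^2 + ridge), 0)

  alphas <- names(margs)
  comps <- list()
  Ws <- stats::setNames(vector("list", length(alphas)), alphas)
  for (a in alphas) {
    # ridge fit M = X_a V diag(d^2/(d^2+ridge)) V', then SVD for rank cut
    W <- margs[[a]] %*% sv$v %*% diag(shrink, length(sv$d)) %*% t(sv$u)
    Ws[[a]] <- W
    M <- W %*% X
    r <- min(dim(M), n_components)
    sm <- svd(M, nu = r, nv = 0)
    for (i in seq_len(r)) {
      if (sm$d[i] <= 1e-12) break
      comps[[length(comps) + 1L]] <- list(alpha = a, f = sm$u[, i],
                                          var = sm$d[i]^2)
    }
  }
  if (!length(comps)) {                      # zero tensor
    Fs <- Ds <- stats::setNames(vector("list", length(alphas)), alphas)
    for (a in alphas) {
      Fs[[a]] <- matrix(0, nn, 0); Ds[[a]] <- matrix(0, 0, nn)
    }
    return(structure(list(F = Fs, D = Ds,
                          n_comp = stats::setNames(rep(0L, length(alphas)),
                                                   alphas),
                          var_explained = numeric(0), loss = 0,
                          ridge = ridge, included = keep),
                     class = "dpca_result"))
  }
  ord <- order(vapply(comps, `[[`, numeric(1), "var"), decreasing = TRUE)
  kept <- comps[ord[seq_len(min(n_components, length(comps)))]]

  Fs <- Ds <- stats::setNames(vector("list", length(alphas)), alphas)
  n_comp <- stats::setNames(integer(length(alphas)), alphas)
  loss <- 0
  for (a in alphas) {
    fa <- vapply(Filter(function(cc) cc$alpha == a, kept), `[[`,
                 numeric(nn), "f")
    if (is.null(dim(fa))) fa <- matrix(fa, nrow = nn, ncol = length(fa) / nn)
    W <- Ws[[a]]
    Fa <- fa
    Da <- t(Fa) %*% W
    Fs[[a]] <- Fa; Ds[[a]] <- Da
    n_comp[a] <- ncol(Fa)
    loss <- loss + sum((margs[[a]] - Fa %*% Da %*% X)^2)
  }
  structure(list(F = Fs, D = Ds, n_comp = n_comp,
                 var_explained = vapply(kept, `[[`, numeric(1), "var"),
                 loss = loss, ridge = ridge, included = keep),
            class = "dpca_result")
}

# GCV over a log grid: regression of each marginalization on X through the
# shared predictor SVD; df = sum d^2/(d^2+lambda)
gcv_ridge <- function(sv, margs) {
  nobs <- ncol(margs[[1]])
  d2 <- sv$d^2
  if (all(d2 < 1e-12)) return(0)
  cand <- c(0, 10^seq(-6, 2, by = 1) * mean(d2))
  best <- cand[1]; best_gcv <- Inf
  for (lam in cand) {
    df <- sum(ifelse(d2 > 1e-300, d2 / (d2 + lam), 0))
    if (!is.finite(df) || df >= nobs) next
    rss <- 0
    for (m in margs) {
      P <- m %*% sv$v                        # N x r
      fit <- P %*% diag(d2 / (d2 + lam), length(d2)) %*% t(sv$v)
      rss <- rss + sum((m - fit)^2)
    }
    g <- rss / (1 - df / nobs)^2
    if (is.finite(g) && g < best_gcv) { best_gcv <- g; best <- lam }
  }
  best
}

#' Per-neuron explained variance of the stimulus and decision components
#'
#' Reconstructs the (centered) data through each marginalization's encoder
#' and decoder and reports, per neuron, `R^2 = 1 - ||recon - X||^2 /
#' ||X - grand mean||^2` for the stimulus (`st`) and decision (`dt`)
#' marginalization components. Zero-variance neurons get NA.
#'
#' @param result a `dpca_result`.
#' @param tensor the `marginalized_tensor` it was fitted to.
#' @return data.frame with `neuron_id`, `R2_st`, `R2_dt` for included
#'   neurons.
#' @export
marginalization_r2 <- function(result, tensor) {
  keep <- result$included
  X <- unroll(tensor$X)[keep, , drop = FALSE]
  denom <- rowSums(X^2)
  out <- data.frame(neuron_id = which(keep), R2_st = NA_real_,
                    R2_dt = NA_real_)
  for (a in c("st", "dt")) {
    recon <- result$F[[a]] %*% result$D[[a]] %*% X
    r2 <- 1 - rowSums((recon - X)^2) / denom
    r2[denom == 0] <- NA_real_
    out[[paste0("R2_", a)]] <- r2
  }
  out
}

#' Fuzzy C-means clustering of neurons by marginalization R-squared
#'
#' Standard fuzzy C-means on the (R2_st, R2_dt) plane. Cluster identities are
#' assigned from the centroids: the cluster whose centroid maximizes
#' `R2_st - R2_dt` is `"stimulus"`, the one maximizing `R2_dt - R2_st` is
#' `"decision"`, the remainder `"interaction"`. Memberships sum to one per
#' neuron; degenerate identical points yield equal memberships.
#'
#' @param r2_pairs data.frame with columns `R2_st`, `R2_dt` (and optionally
#'   `neuron_id`); rows with NA are dropped.
#' @param n_clusters number of clusters (default 3).
#' @param fuzzifier fuzziness exponent m > 1 (default 2).
#' @param tol convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @param seed seed for the membership initialization.
#' @return list of class `neuron_clusters`: `label` (per neuron),
#'   `membership` (matrix), `centers`, `objective` (per-iteration trace),
#'   `neuron_id`.
#' @export
cluster_neurons <- function(r2_pairs, n_clusters = 3, fuzzifier = 2,
                            tol = 1e-6, max_iter = 300, seed = 1L) {
  x <- as.matrix(r2_pairs[, c("R2_st", "R2_dt")])
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  if (nrow(unique(x)) < n_clusters)
    stop("need at least n_clusters distinct points")
  fcm <- fuzzy_cmeans(x, n_clusters, fuzzifier, tol, max_iter, seed)

  score_st <- fcm$centers[, 1] - fcm$centers[, 2]
  lab <- rep("interaction", n_clusters)
  lab[which.max(score_st)] <- "stimulus"
  remaining <- setdiff(seq_len(n_clusters), which.max(score_st))
  lab[remaining[which.max(-score_st[remaining])]] <- "decision"
  hard <- apply(fcm$membership, 1, which.max)
  ids <- if (!is.null(r2_pairs$neuron_id)) r2_pairs$neuron_id[ok] else
    which(ok)
  structure(list(label = lab[hard], membership = fcm$membership,
                 centers = fcm$centers, center_label = lab,
                 objective = fcm$objective, neuron_id = ids),
            class = "neuron_clusters")
}

# plain fuzzy C-means with a recorded objective trace
fuzzy_cmeans <- function(x, k, m = 2, tol = 1e-6, max_iter = 300, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(x)
  u <- matrix(stats::runif(n * k), n, k)
  u <- u / rowSums(u)
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    um <- u^m
    centers <- t(um) %*% x / colSums(um)
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    obj <- c(obj, sum(um * d2))
    zero <- d2 < 1e-15
    inv <- (1 / pmax(d2, 1e-15))^(1 / (m - 1))
    u_new <- inv / rowSums(inv)
    # points coinciding with a center: full membership there
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u_new[hit, ] <- 0
      u_new[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    if (it > 1 && abs(obj[it] - obj[it - 1]) < tol * max(1, abs(obj[it - 1])))
      { u <- u_new; break }
    u <- u_new
  }
  um <- u^m
  centers <- t(um) %*% x / colSums(um)
  list(membership = u, centers = centers, objective = obj)
}

#' Write the neuron-cluster table
#'
#' @param clusters a `neuron_clusters`.
#' @param r2_pairs the R-squared table the clustering used.
#' @param path CSV output path.
#' @export
write_neuron_clusters <- function(clusters, r2_pairs, path) {
  df <- data.frame(neuron_id = clusters$neuron_id,
                   R2_st = r2_pairs$R2_st[match(clusters$neuron_id,
                                                r2_pairs$neuron_id)],
                   R2_dt = r2_pairs$R2_dt[match(clusters$neuron_id,
                                                r2_pairs$neuron_id)],
                   label = clusters$label)
  mem <- as.data.frame(clusters$membership)
  names(mem) <- paste0("membership_", clusters$center_label)
  utils::write.csv(cbind(df, mem), path, row.names = FALSE)
  invisible(path)
}
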