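#' Eigenspectrum of a snapshot stack
#'
#' Three conventions are implemented and labelled, because a single-frame
#' image, a channel covariance, and a snapshot Gram matrix all yield ranked
#' non-negative eigenvalues but measure different things:
#'
#' * `"spatial-svd-pooled"` (default): squared singular values of each
#'   frame's rows x cols matrix, pooled over frames and ranked.  Defined for
#'   any frame count and bounded by `min(rows, cols) * k`.
#' * `"channel-covariance"`: eigenvalues of the channels x channels
#'   covariance across frames (computed via the Gram trick, so arbitrary
#'   channel subsets are cheap).  The only mode defined on channel subsets.
#' * `"snapshot-gram"`: eigenvalues of the uncentred frames x frames Gram
#'   matrix.
#'
#' @param stack a [snapshot_stack()], or a channels x frames matrix (for
#'   `"channel-covariance"` / `"snapshot-gram"` on channel subsets).
#' @param mode decomposition convention.
#' @return An `eigen_spectrum`: list with sorted non-negative `values`,
#'   `mode`, `n_channels`, `n_snapshots`.
#' @export
eigenspectrum <- function(stack,
                          mode = c("spatial-svd-pooled", "channel-covariance",
                                   "snapshot-gram")) {
  mode <- match.arg(mode)
  if (inherits(stack, "snapshot_stack")) {
    if (n_frames(stack) < 1) stop("empty stack")
    X <- as_channel_matrix(stack)
    dims <- dim(stack$frames)
  } else if (is.matrix(stack)) {
    if (mode == "spatial-svd-pooled")
      stop("spatial-svd-pooled requires a snapshot_stack (grid frames)")
    X <- stack
    dims <- c(nrow(stack), 1L, ncol(stack))
  } else stop("stack must be a snapshot_stack or a matrix")
  k <- ncol(X)
  vals <- switch(mode,
    "spatial-svd-pooled" = {
      v <- unlist(lapply(seq_len(dims[3]), function(f)
        svd(matrix(X[, f], dims[1], dims[2]), nu = 0, nv = 0)$d^2))
      v
    },
    "channel-covariance" = {
      if (k < 2) stop("channel covariance needs >= 2 frames")
      Xc <- X - rowMeans(X)
      eigen(crossprod(Xc) / (k - 1), symmetric = TRUE, only.values = TRUE)$values
    },
    "snapshot-gram" = {
      eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
    })
  vals <- sort(pmax(vals, 0), decreasing = TRUE)
  structure(list(values = vals, mode = mode, n_channels = nrow(X),
                 n_snapshots = k),
            class = "eigen_spectrum")
}

#' Participation ratio of an eigenspectrum
#'
#' `PR = (sum(lambda))^2 / sum(lambda^2)`: the squared first moment of the
#' spectrum over its second moment.  PR is 1 when a single eigenvalue
#' carries all variance, equals the number of eigenvalues when they are all
#' equal, and is invariant to scaling the spectrum by any positive constant.
#'
#' @param spec an `eigen_spectrum` from [eigenspectrum()], or a numeric
#'   vector of eigenvalues.
#' @return A `complexity_result`: list with `pr`, `pr_per_sqrt_n`
#'   (PR / sqrt(channel count)), `pr_per_sqrt_k` (PR / sqrt(snapshot
#'   count)), `mode`, `n_channels`, `n_snapshots`.
#' @examples
#' participation_ratio(c(1, 1, 1, 1))$pr   # 4
#' participation_ratio(c(2, 1, 1))$pr      # 16/6
#' @export
participation_ratio <- function(spec) {
  if (inherits(spec, "eigen_spectrum")) {
    vals <- spec$values; mode <- spec$mode
    n <- spec$n_channels; k <- spec$n_snapshots
  } else {
    vals <- as.numeric(spec); mode <- "values"
    n <- NA_integer_; k <- NA_integer_
  }
  if (any(vals < 0)) stop("eigenvalues must be non-negative")
  s2 <- sum(vals^2)
  if (s2 == 0) stop("all-zero eigenspectrum: PR undefined")
  pr <- sum(vals)^2 / s2
  structure(list(pr = pr,
                 pr_per_sqrt_n = if (is.na(n)) NA_real_ else pr / sqrt(n),
                 pr_per_sqrt_k = if (is.na(k)) NA_real_ else pr / sqrt(k),
                 mode = mode, n_channels = n, n_snapshots = k),
            class = "complexity_result")
}

#' Normalised participation ratio
#'
#' PR scales with the number of channels and with the number of snapshots;
#' dividing by the square root of either yields estimates that are more
#' comparable across acquisition scales.
#'
#' @param result a `complexity_result` from [participation_ratio()].
#' @param by `"channels"` (PR / sqrt(N)) or `"snapshots"` (PR / sqrt(k)).
#' @param n override for the channel / snapshot count if not recorded.
#' @return the normalised PR (scalar).
#' @export
normalized_pr <- function(result, by = c("channels", "snapshots"), n = NULL) {
  by <- match.arg(by)
  cnt <- if (!is.null(n)) n
  else if (by == "channels") result$n_channels else result$n_snapshots
  if (is.null(cnt) || is.na(cnt)) stop("count unknown; supply n")
  result$pr / sqrt(cnt)
}

#' Convenience: participation ratio of a stack
#' @param stack a [snapshot_stack()].
#' @param mode passed to [eigenspectrum()].
#' @return scalar PR.
#' @export
stack_pr <- function(stack, mode = "spatial-svd-pooled") {
  participation_ratio(eigenspectrum(stack, mode))$pr
}

#' PR as a function of the number of analysed channels
#'
#' For each requested channel count, draws seeded random channel subsets of
#' the event's time series and computes the PR of the subset's channel
#' covariance (the only decomposition defined on arbitrary subsets).
#'
#' @param stack a [snapshot_stack()].
#' @param counts channel counts (each >= 2 and <= total channels).
#' @param reps random subsets per count.
#' @param seed integer seed.
#' @return data.frame: n_channels, mean_pr, sd_pr, mean_pr_per_sqrt_n.
#' @export
pr_vs_channel_count <- function(stack, counts, reps = 10L, seed = 1L) {
  stopifnot(inherits(stack, "snapshot_stack"))
  X <- as_channel_matrix(stack)
  N <- nrow(X)
  if (any(counts < 2)) stop("channel counts must be >= 2")
  if (any(counts > N)) stop("channel counts exceed available channels")
  rows <- lapply(seq_along(counts), function(ci) {
    n <- counts[ci]
    prs <- vapply(seq_len(reps), function(r) {
      sub <- with_seed(derive_seed(seed, paste0("subset", ci, "_", r)),
                       sample.int(N, n))
      participation_ratio(eigenspectrum(X[sub, , drop = FALSE],
                                        mode = "channel-covariance"))$pr
    }, numeric(1))
    data.frame(n_channels = n, mean_pr = mean(prs), sd_pr = stats::sd(prs),
               mean_pr_per_sqrt_n = mean(prs) / sqrt(n))
  })
  do.call(rbind, rows)
}

#' PR as a function of the number of snapshots
#'
#' For each `k`, selects `k` evenly spaced frames from the event and
#' computes the PR, together with the sqrt(k)-normalised value.
#'
#' @param stack a [snapshot_stack()].
#' @param ks snapshot counts (each >= 1, <= frame count).
#' @param mode passed to [eigenspectrum()].
#' @return data.frame: k, pr, pr_per_sqrt_k.
#' @export
pr_vs_snapshot_count <- function(stack, ks, mode = "spatial-svd-pooled") {
  stopifnot(inherits(stack, "snapshot_stack"))
  nf <- n_frames(stack)
  if (any(ks < 1)) stop("k must be >= 1")
  if (any(ks > nf)) stop("k exceeds the frame count")
  rows <- lapply(ks, function(k) {
    sub <- if (k == 1) subset_frames(stack, round((nf + 1) / 2))
    else select_evenly_spaced(stack, k)
    pr <- stack_pr(sub, mode)
    data.frame(k = k, pr = pr, pr_per_sqrt_k = pr / sqrt(k))
  })
  do.call(rbind, rows)
}

#' PR under additive Gaussian noise
#'
#' Adds seeded Gaussian noise of every (mean, sd) combination to the event's
#' snapshots and reports the resulting PR, averaged over repetitions —
#' the direct-noise counterpart of driving a generative model with varied
#' input statistics.
#'
#' @param stack a [snapshot_stack()].
#' @param means,sds noise means and SDs in uV.
#' @param reps repetitions per setting.
#' @param seed integer seed.
#' @param mode passed to [eigenspectrum()].
#' @return data.frame: mean, sd, mean_pr, sd_pr.
#' @export
pr_noise_sweep <- function(stack, means = 0, sds = c(0, 50, 100), reps = 5L,
                           seed = 1L, mode = "spatial-svd-pooled") {
  stopifnot(inherits(stack, "snapshot_stack"))
  grid <- expand.grid(mean = means, sd = sds)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    m <- grid$mean[g]; s <- grid$sd[g]
    prs <- vapply(seq_len(reps), function(r) {
      noisy <- add_gaussian_noise(stack, m, s,
                                  seed = derive_seed(seed, paste0(g, "_", r)))
      stack_pr(noisy, mode)
    }, numeric(1))
    data.frame(mean = m, sd = s, mean_pr = mean(prs), sd_pr = stats::sd(prs))
  })
  do.call(rbind, rows)
}

#' Levina-Bickel maximum-likelihood intrinsic dimension
#'
#' The k-nearest-neighbour MLE of intrinsic dimension: for each point `x`,
#' `m_k(x) = [ 1/(k-2) * sum_{j<k} log( T_k(x) / T_j(x) ) ]^{-1}` with
#' `T_j(x)` the distance to the j-th neighbour.  The `k-2` normalisation is
#' the standard debiased form (the summed log-ratios follow a
#' Gamma(k-1) law, so the raw `k-1` estimator overestimates by
#' `(k-1)/(k-2)`).  Estimates are averaged over points and over `k` in
#' `[k_min, k_max]` (the estimator's usual usage when no single k is
#' prescribed).  Duplicate points (zero distances) are handled by a
#' tie-perturbation of the distances.
#'
#' @param points numeric matrix, one point per row.
#' @param k_min,k_max neighbour range (needs `>= k_max + 1` points).
#' @return scalar dimension estimate.
#' @examples
#' x <- matrix(rnorm(200 * 2), 200)                 # 2-D cloud
#' lbmle_dimension(cbind(x, matrix(0, 200, 8)))     # ~2 in 10-D
#' @export
lbmle_dimension <- function(points, k_min = 5L, k_max = 15L) {
  stopifnot(is.matrix(points), k_min >= 3, k_max >= k_min)
  n <- nrow(points)
  if (n < k_max + 1) stop("need at least k_max + 1 points")
  D <- as.matrix(stats::dist(points))
  diag(D) <- Inf
  ## tie-perturbation: lift exact duplicates to a negligible distance
  eps <- 1e-12 * max(D[is.finite(D)])
  D[D == 0] <- eps
  Ds <- apply(D, 1, function(d) sort(d)[seq_len(k_max)])   # k_max x n
  logD <- log(Ds)
  est_k <- vapply(k_min:k_max, function(k) {
    ## debiased inverse mean log-ratio per point, averaged over points
    mk <- (k - 2) / (colSums(logD[rep(k, k - 1), , drop = FALSE]) -
                       colSums(logD[seq_len(k - 1), , drop = FALSE]))
    mean(mk[is.finite(mk)])
  }, numeric(1))
  mean(est_k)
}

#' Intrinsic dimension of a wave segment
#'
#' Applies [lbmle_dimension()] to the segment's 1-ms frames, each flattened
#' to a channel vector.  Frame-to-frame stochasticity therefore contributes
#' to the estimate, as it does in recorded segments.
#'
#' @param stack a [snapshot_stack()].
#' @param k_min,k_max passed to [lbmle_dimension()].
#' @param max_points subsample cap on the number of frames (evenly spaced).
#' @return scalar dimension estimate.
#' @export
segment_lbmle <- function(stack, k_min = 5L, k_max = 15L, max_points = 400L) {
  stopifnot(inherits(stack, "snapshot_stack"))
  X <- t(as_channel_matrix(stack))
  if (nrow(X) > max_points)
    X <- X[round(seq(1, nrow(X), length.out = max_points)), , drop = FALSE]
  lbmle_dimension(X, k_min, k_max)
}

#' Two-sample Student's t comparison of PR values
#'
#' Pooled-variance two-sample t-test (classical Student form, as used to
#' contrast complexity between conditions).
#'
#' @param prs_a,prs_b numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p_value`, group means, and a flag for
#'   degenerate (zero pooled variance) input.
#' @export
compare_conditions <- function(prs_a, prs_b) {
  stopifnot(length(prs_a) >= 2, length(prs_b) >= 2)
  n1 <- length(prs_a); n2 <- length(prs_b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(prs_a) + (n2 - 1) * stats::var(prs_b)) / df
  degenerate <- sp2 <= 0
  if (degenerate) {
    tval <- if (mean(prs_a) == mean(prs_b)) 0 else Inf * sign(mean(prs_a) - mean(prs_b))
  } else {
    tval <- (mean(prs_a) - mean(prs_b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- if (is.finite(tval)) 2 * stats::pt(-abs(tval), df) else 0
  list(t = tval, df = df, p_value = p,
       mean_a = mean(prs_a), mean_b = mean(prs_b), degenerate = degenerate)
}
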