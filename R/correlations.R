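#' Pairwise electrode correlations within a wave
#'
#' Pearson correlation between the per-channel time series over the event
#' window.  Zero-variance channels have undefined correlations; they are
#' recorded as `NA` and excluded from downstream distance bins.
#'
#' @param stack a [snapshot_stack()] with >= 3 frames, or a channels x
#'   frames matrix.
#' @return A `correlation_result`: list with symmetric `matrix`
#'   (unit diagonal), and `valid` (logical per-channel flag).
#' @export
pairwise_correlations <- function(stack) {
  X <- if (inherits(stack, "snapshot_stack")) as_channel_matrix(stack)
  else stack
  stopifnot(is.matrix(X))
  if (ncol(X) < 3) stop("need >= 3 frames for correlations")
  sds <- apply(X, 1, stats::sd)
  valid <- is.finite(sds) & sds > 0
  C <- matrix(NA_real_, nrow(X), nrow(X))
  if (any(valid)) C[valid, valid] <- stats::cor(t(X[valid, , drop = FALSE]))
  diag(C) <- 1
  structure(list(matrix = C, valid = valid), class = "correlation_result")
}

#' Mean correlation matrix over several waves
#'
#' Element-wise average of per-event correlation matrices (entries missing
#' in an event are excluded from its average).
#'
#' @param stacks list of [snapshot_stack()]s (or `correlation_result`s).
#' @return A `correlation_result` with the averaged matrix.
#' @export
mean_correlation_matrix <- function(stacks) {
  stopifnot(length(stacks) >= 1)
  mats <- lapply(stacks, function(s) {
    if (inherits(s, "correlation_result")) s$matrix
    else pairwise_correlations(s)$matrix
  })
  acc <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  cnt <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  for (m in mats) {
    ok <- is.finite(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt <- cnt + ok
  }
  M <- acc / cnt
  M[cnt == 0] <- NA_real_
  structure(list(matrix = M, valid = rowSums(cnt) > 0),
            class = "correlation_result")
}

#' Correlation as a function of electrode distance
#'
#' Bins electrode-pair distances into `n_bins` equal-width bins, reports the
#' per-bin mean correlation with its SEM, and fits a line to (bin centre,
#' bin mean), as the binned-presentation regression of correlation against
#' distance.  With `from_center`, only pairs between the electrode nearest
#' to `center` and every other electrode are used (correlation relative to
#' the centre of mass).
#'
#' @param corr a `correlation_result` from [pairwise_correlations()].
#' @param layout an [electrode_layout()] providing pair distances.
#' @param n_bins number of distance bins.
#' @param from_center optional `(row, col)` centre for the centre-referenced
#'   variant.
#' @param weighted weight the bin regression by pair count (default); the
#'   sparsest long-distance bins carry few effective pairs and, over short
#'   band-limited windows, large sampling variance.
#' @return list with `bins` (data.frame: distance, mean_corr, sem, n),
#'   `slope` (per um), `intercept`, `r_squared`, `p_value`.
#' @export
correlation_vs_distance <- function(corr, layout, n_bins = 20,
                                    from_center = NULL, weighted = TRUE) {
  stopifnot(inherits(corr, "correlation_result"),
            inherits(layout, "electrode_layout"))
  C <- corr$matrix
  if (is.null(from_center)) {
    D <- layout_distances(layout)
    iu <- upper.tri(C)
    d <- D[iu]; r <- C[iu]
  } else {
    ch <- nearest_channel(layout, from_center[1], from_center[2])
    d <- sqrt((layout$x_um - layout$x_um[ch])^2 +
                (layout$y_um - layout$y_um[ch])^2)
    r <- C[ch, ]
    keep <- seq_along(r) != ch
    d <- d[keep]; r <- r[keep]
  }
  ok <- is.finite(r)
  d <- d[ok]; r <- r[ok]
  if (!length(d)) stop("no valid correlation pairs")
  br <- seq(0, max(d) * (1 + 1e-9), length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE, labels = FALSE)
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    rb <- r[bin == b]
    data.frame(distance = (br[b] + br[b + 1]) / 2, mean_corr = mean(rb),
               sem = stats::sd(rb) / sqrt(length(rb)), n = length(rb))
  }))
  if (nrow(bins) >= 3) {
    fit <- if (weighted)
      stats::lm(mean_corr ~ distance, data = bins, weights = bins$n)
    else stats::lm(mean_corr ~ distance, data = bins)
    sm <- summary(fit)
    slope <- stats::coef(fit)[["distance"]]
    r2 <- sm$r.squared
    p <- sm$coefficients["distance", "Pr(>|t|)"]
  } else {
    slope <- NA_real_; r2 <- NA_real_; p <- NA_real_
  }
  list(bins = bins, slope = slope,
       intercept = if (nrow(bins) >= 3) stats::coef(fit)[[1]] else NA_real_,
       r_squared = r2, p_value = p)
}
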