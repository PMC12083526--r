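#' Pairwise Pearson correlation between per-time feature vectors
#'
#' @param traces A numeric matrix whose columns are time points (rows are
#'   features, e.g. masked DED voxels), or a list of equal-length vectors.
#' @return Symmetric matrix of Pearson correlation coefficients with unit
#'   diagonal. Zero-variance vectors yield `NA` rows/columns (with a
#'   warning), never a silent 0.
#' @export
feature_correlation_map <- function(traces) {
  if (is.list(traces) && !is.matrix(traces)) {
    n <- lengths(traces)
    if (length(unique(n)) != 1) stop("feature vectors must share a length")
    traces <- do.call(cbind, traces)
  }
  if (ncol(traces) < 2) stop("need at least 2 time points")
  sds <- apply(traces, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(traces))
  if (any(sds == 0)) {
    warning("zero-variance feature vector(s): correlation undefined (NA)")
    cc[sds == 0, ] <- NA_real_
    cc[, sds == 0] <- NA_real_
  }
  diag(cc)[sds > 0] <- 1
  cc
}

#' SVD of a masked DED map series
#'
#' Stacks the masked voxels of each map as the rows (one column per time
#' point) and decomposes the matrix as `U diag(SV) t(V)`. The left
#' singular vectors (`lsv`) are time-invariant component maps over the
#' masked voxel set, the right singular vectors (`rsv`) their magnitude
#' traces over time, and `sv` the non-negative weights in decreasing
#' order. Sign convention: each component is flipped so that its masked
#' voxel of largest absolute loading is positive.
#'
#' @param series List of `density_map`s on identical grids.
#' @param mask A [region_mask()] on that grid.
#' @param times Optional numeric time stamps (seconds) for the series.
#' @return Object of class `svd_result`: `lsv` (voxels x k), `rsv`
#'   (time x k), `sv`, `mask`, `times`, `grid`.
#' @export
svd_decompose <- function(series, mask, times = NULL) {
  if (length(series) < 2) stop("need at least 2 maps")
  dims <- lapply(series, function(m) dim(m$values))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("maps are on inconsistent grids")
  if (!identical(as.integer(dims[[1]]), as.integer(mask$grid)))
    stop("mask grid does not match map grid")
  if (!any(mask$voxels)) stop("empty mask")
  X <- vapply(series, function(m) m$values[mask$voxels],
              numeric(sum(mask$voxels)))
  sv <- svd(X)
  for (i in seq_along(sv$d)) {
    j <- which.max(abs(sv$u[, i]))
    if (sv$u[j, i] < 0) {
      sv$u[, i] <- -sv$u[, i]
      sv$v[, i] <- -sv$v[, i]
    }
  }
  structure(list(lsv = sv$u, rsv = sv$v, sv = sv$d, mask = mask,
                 times = times, grid = as.integer(dims[[1]])),
            class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf("<svd_result> %d components over %d voxels x %d time points\n",
              length(x$sv), nrow(x$lsv), nrow(x$rsv)))
  cat("  singular values:", paste(signif(x$sv, 4), collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct a map series from leading SVD components
#'
#' Per-time maps rebuilt as
#' \eqn{\sum_{i \le n} SV_i \, lSV_i \, rSV_i(t)}; voxels outside the
#' mask are zero.
#'
#' @param result An [svd_decompose()] result.
#' @param n_components How many leading components to keep (1..k).
#' @return List of `density_map`s, one per time point.
#' @export
svd_reconvolute <- function(result, n_components) {
  k <- length(result$sv)
  if (!is.numeric(n_components) || n_components < 1 || n_components > k)
    stop("n_components must lie in [1, ", k, "]")
  n_components <- as.integer(n_components)
  U <- result$lsv[, seq_len(n_components), drop = FALSE]
  V <- result$rsv[, seq_len(n_components), drop = FALSE]
  D <- result$sv[seq_len(n_components)]
  X <- U %*% (D * t(V))            # voxels x time
  lapply(seq_len(ncol(X)), function(t) {
    v <- array(0, dim = result$grid)
    v[result$mask$voxels] <- X[, t]
    density_map(v, result$mask$cell, provenance = "plain")
  })
}

#' Integrated DED time trace from a map series
#'
#' Convenience wrapper: applies [integrate_region()] to every map in a
#' series and assembles a [time_trace()].
#'
#' @param series List of `density_map`s.
#' @param mask A `region_mask`.
#' @param times Time points in seconds.
#' @param sign,level_sigma,threshold Passed to [integrate_region()].
#' @param label Trace label.
#' @return A `time_trace`.
#' @export
ded_trace <- function(series, mask, times, sign = "negative",
                      level_sigma = 3, threshold = TRUE, label = "DED") {
  stopifnot(length(series) == length(times))
  vals <- vapply(series, integrate_region, numeric(1), mask = mask,
                 sign = sign, level_sigma = level_sigma, threshold = threshold)
  time_trace(times, vals, label = label)
}
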