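#' Intensity-weighted centroid of a feature
#'
#' @param f An [feature()] object.
#' @return Named numeric vector `c(rt =, mz =)` -- the intensity-weighted
#'   mean peak position. The weighted mean is used (rather than, say, the
#'   apex) because it is robust to asymmetric elution envelopes.
#' @export
compute_centroid <- function(f) {
  stopifnot(inherits(f, "ms_feature"))
  tot <- sum(f$peaks$intensity)
  if (tot <= 0) stop(sprintf("feature '%s' has zero total intensity", f$id))
  c(rt = sum(f$peaks$rt * f$peaks$intensity) / tot,
    mz = sum(f$peaks$mz * f$peaks$intensity) / tot)
}

#' Centroids of every feature in a chromatogram
#'
#' @param fs An [feature_set()] object.
#' @return Data frame with columns `source_id`, `feature_id`, `rt`, `mz`.
#' @export
feature_centroids <- function(fs) {
  stopifnot(inherits(fs, "ms_feature_set"))
  if (!length(fs$features))
    return(data.frame(source_id = character(0), feature_id = character(0),
                      rt = numeric(0), mz = numeric(0)))
  cent <- t(vapply(fs$features, compute_centroid, numeric(2)))
  data.frame(source_id = fs$source_id,
             feature_id = vapply(fs$features, `[[`, character(1), "id"),
             rt = cent[, "rt"], mz = cent[, "mz"], row.names = NULL)
}

#' Estimate the RT scaling factor
#'
#' RT varies over a much larger numeric range than m/z, so before any
#' distance computation the RT axis is divided by a factor proportional to
#' the ratio of the average feature length along RT (max - min over peaks,
#' seconds) to the average feature width along m/z (Da). After division, the
#' two dimensions vary on a comparable scale and the l1 ground distance
#' treats them even-handedly.
#'
#' @param sets List of [feature_set()] objects (or a single one).
#' @param k Proportionality constant (default 1); exposed as config
#'   `rt_scale_k`.
#' @return An object of class `rt_scaling` with elements `factor`
#'   (seconds per m/z-equivalent unit) and `k`. Features with zero m/z span
#'   (single m/z value) are excluded from the width average -- they would
#'   otherwise drive the denominator to zero -- but are still scaled.
#' @export
estimate_rt_scaling <- function(sets, k = 1) {
  if (inherits(sets, "ms_feature_set")) sets <- list(sets)
  stopifnot(k > 0)
  spans <- lapply(sets, function(fs) {
    t(vapply(fs$features, function(f)
      c(rt = diff(range(f$peaks$rt)), mz = diff(range(f$peaks$mz))),
      numeric(2)))
  })
  spans <- do.call(rbind, spans)
  if (is.null(spans) || !nrow(spans)) stop("no features to estimate scaling from")
  mz_spans <- spans[, "mz"][spans[, "mz"] > 0]
  if (!length(mz_spans))
    stop("all features have zero m/z span; supply an explicit scaling factor")
  rt_spans <- spans[, "rt"][spans[, "rt"] > 0]
  if (!length(rt_spans)) rt_spans <- 0
  factor <- k * mean(rt_spans) / mean(mz_spans)
  if (!is.finite(factor) || factor <= 0)
    stop("estimated scaling factor is not positive; supply one explicitly")
  structure(list(factor = factor, k = k), class = "rt_scaling")
}

#' @export
print.rt_scaling <- function(x, ...) {
  cat(sprintf("<rt_scaling> factor = %.4f s per m/z-equivalent unit (k = %g)\n",
              x$factor, x$k))
  invisible(x)
}

#' Apply (or invert) RT scaling
#'
#' Divides every peak's RT by `info$factor`; m/z is untouched. The map is a
#' bijection: `apply_scaling(apply_scaling(x, s), s, invert = TRUE)`
#' restores the original coordinates.
#'
#' @param fs An [feature_set()] object.
#' @param info An `rt_scaling` object (or a positive number used directly as
#'   the factor).
#' @param invert If `TRUE`, multiply instead of divide.
#' @return The feature set in scaled (or unscaled) coordinates.
#' @export
apply_scaling <- function(fs, info, invert = FALSE) {
  stopifnot(inherits(fs, "ms_feature_set"))
  factor <- if (inherits(info, "rt_scaling")) info$factor else as.numeric(info)
  stopifnot(is.finite(factor), factor > 0)
  if (invert) factor <- 1 / factor
  feats <- lapply(fs$features, function(f) {
    f$peaks$rt <- f$peaks$rt / factor
    f
  })
  out <- feature_set(fs$source_id, feats)
  out$rt_unit <- if (invert || factor == 1) fs$rt_unit else "scaled"
  out
}

#' Construct a unit-mass discrete measure
#'
#' @param points Numeric matrix with columns `rt` (scaled) and `mz`.
#' @param weights Positive weights summing to 1 (within 1e-9).
#' @return An object of class `gw_measure`.
#' @export
measure <- function(points, weights) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) == length(weights),
            nrow(points) >= 1, all(weights > 0))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("measure weights must sum to 1")
  colnames(points) <- c("rt", "mz")
  structure(list(points = unname(points), weights = as.numeric(weights)),
            class = "gw_measure")
}

#' Normalize a feature into a unit-mass measure
#'
#' Weights are the peak intensities divided by their total, making measures
#' of differently abundant analytes directly comparable and giving the
#' untransported-mass penalty a common meaning across features.
#' Zero-intensity peaks are dropped (they carry no mass).
#'
#' @param f An [feature()] object in scaled coordinates.
#' @return A [measure()] object.
#' @export
to_measure <- function(f) {
  stopifnot(inherits(f, "ms_feature"))
  keep <- f$peaks$intensity > 0
  tot <- sum(f$peaks$intensity[keep])
  if (tot <= 0) stop(sprintf("feature '%s' has zero total intensity", f$id))
  measure(cbind(rt = f$peaks$rt[keep], mz = f$peaks$mz[keep]),
          f$peaks$intensity[keep] / tot)
}

#' @export
print.gw_measure <- function(x, ...) {
  cat(sprintf("<gw_measure> %d support points, mass %.6f\n",
              nrow(x$points), sum(x$weights)))
  invisible(x)
}

# Reduce an over-large support by intensity-weighted binning on a
# (rt, mz) grid; transport is quadratic in support size.
reduce_measure <- function(m, max_support = 500L) {
  n <- nrow(m$points)
  if (n <= max_support) return(m)
  nb <- ceiling(sqrt(max_support))
  cuts <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    findInterval(v, seq(r[1], r[2], length.out = nb + 1L),
                 rightmost.closed = TRUE)
  }
  bin <- paste(cuts(m$points[, 1]), cuts(m$points[, 2]))
  w <- vapply(split(m$weights, bin), sum, numeric(1))
  rt <- vapply(split(seq_len(n), bin), function(i)
    sum(m$points[i, 1] * m$weights[i]) / sum(m$weights[i]), numeric(1))
  mz <- vapply(split(seq_len(n), bin), function(i)
    sum(m$points[i, 2] * m$weights[i]) / sum(m$weights[i]), numeric(1))
  measure(cbind(rt, mz), w / sum(w))
}
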