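#' LC-MS feature: a set of weighted peaks in the (RT, m/z) plane
#'
#' A feature is the atomic object of the alignment: the connected region of
#' signal attributed to one analyte by an upstream feature detector,
#' represented here as a finite set of peaks, each with a retention time
#' (seconds), a mass-to-charge ratio (Da) and a nonnegative intensity.
#'
#' @param id Feature identifier, unique within its chromatogram.
#' @param rt,mz,intensity Equal-length numeric vectors of peak coordinates
#'   (RT in seconds, m/z in Da) and nonnegative intensities.
#' @param charge Optional integer charge state.
#' @param annotations Optional character vector of identification labels.
#' @return An object of class `ms_feature` with elements `id`, `peaks`
#'   (a data frame with columns `rt`, `mz`, `intensity`), `charge` and
#'   `annotations`.
#' @examples
#' f <- feature("f1", rt = c(100, 102), mz = c(500, 500.5), intensity = c(3, 1))
#' compute_centroid(f)
#' @export
feature <- function(id, rt, mz, intensity, charge = NA_integer_,
                    annotations = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("feature id must be a nonempty string")
  n <- length(rt)
  if (n < 1L) stop("a feature needs at least one peak")
  if (length(mz) != n || length(intensity) != n)
    stop("rt, mz and intensity must have equal length")
  if (!all(is.finite(rt)) || !all(is.finite(mz)))
    stop("peak rt and mz must be finite")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("peak intensities must be finite and nonnegative")
  if (!any(intensity > 0))
    stop(sprintf("feature '%s' has no peak with positive intensity", id))
  structure(
    list(id = id,
         peaks = data.frame(rt = as.numeric(rt), mz = as.numeric(mz),
                            intensity = as.numeric(intensity)),
         charge = as.integer(charge),
         annotations = annotations),
    class = "ms_feature")
}

#' @export
print.ms_feature <- function(x, ...) {
  cat(sprintf("<ms_feature '%s'> %d peaks, RT %.1f-%.1f s, m/z %.4f-%.4f\n",
              x$id, nrow(x$peaks), min(x$peaks$rt), max(x$peaks$rt),
              min(x$peaks$mz), max(x$peaks$mz)))
  invisible(x)
}

#' One chromatogram's detected features
#'
#' @param source_id Nonempty chromatogram label.
#' @param features List of [feature()] objects with unique ids.
#' @return An object of class `ms_feature_set`. RT is always carried in
#'   seconds; readers never convert units silently.
#' @export
feature_set <- function(source_id, features = list()) {
  if (!is.character(source_id) || length(source_id) != 1L || !nzchar(source_id))
    stop("source_id must be a nonempty string")
  if (!all(vapply(features, inherits, logical(1), "ms_feature")))
    stop("features must be a list of ms_feature objects")
  ids <- vapply(features, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicated feature ids in '%s': %s", source_id,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(features) <- ids
  structure(list(source_id = source_id, features = features,
                 rt_unit = "seconds"),
            class = "ms_feature_set")
}

#' @export
print.ms_feature_set <- function(x, ...) {
  cat(sprintf("<ms_feature_set '%s'> %d features\n", x$source_id,
              length(x$features)))
  invisible(x)
}

#' @export
length.ms_feature_set <- function(x) length(x$features)

#' Ground-truth consensus features for evaluation
#'
#' @param consensus_sets List of data frames, each with columns `source_id`
#'   and `feature_id`, one per ground-truth consensus feature. Every set must
#'   reference at least two distinct chromatograms, and no (source, feature)
#'   pair may appear in two sets.
#' @return An object of class `gw_ground_truth`.
#' @export
ground_truth <- function(consensus_sets) {
  if (!length(consensus_sets)) stop("ground truth must contain at least one consensus set")
  keys <- character(0)
  for (i in seq_along(consensus_sets)) {
    s <- consensus_sets[[i]]
    if (!all(c("source_id", "feature_id") %in% names(s)))
      stop("each consensus set needs source_id and feature_id columns")
    if (length(unique(s$source_id)) < 2L)
      stop(sprintf("consensus set %d references fewer than 2 chromatograms", i))
    k <- paste(s$source_id, s$feature_id, sep = "\r")
    if (anyDuplicated(k))
      stop(sprintf("duplicated membership inside consensus set %d", i))
    keys <- c(keys, k)
  }
  if (anyDuplicated(keys))
    stop("a (source_id, feature_id) pair appears in more than one consensus set")
  structure(list(consensus_sets = consensus_sets), class = "gw_ground_truth")
}

#' A consensus feature: mutually corresponding features across chromatograms
#'
#' @param consensus_id Identifier of the consensus feature.
#' @param members Data frame with columns `source_id`, `feature_id` and
#'   optionally `centroid_rt`, `centroid_mz` (original units); no
#'   (source, feature) pair may repeat. The aligner's own output contains at
#'   most one member per chromatogram (guaranteed by construction in
#'   [assemble_consensus()]); the container deliberately does not force
#'   this, so that evaluation can also represent an over-merged consensus
#'   produced by other tools.
#' @param cluster Integer index of the centroid cluster this consensus
#'   originated from (`NA` for the two-chromatogram special case).
#' @return An object of class `gw_consensus_feature`.
#' @export
consensus_feature <- function(consensus_id, members, cluster = NA_integer_) {
  if (!nrow(members)) stop("a consensus feature needs at least one member")
  if (anyDuplicated(paste(members$source_id, members$feature_id, sep = "\r")))
    stop("duplicated (source_id, feature_id) member in a consensus feature")
  if (is.null(members$centroid_rt)) members$centroid_rt <- NA_real_
  if (is.null(members$centroid_mz)) members$centroid_mz <- NA_real_
  structure(list(consensus_id = as.character(consensus_id),
                 members = members, cluster = as.integer(cluster)),
            class = "gw_consensus_feature")
}

#' @export
print.gw_consensus_feature <- function(x, ...) {
  cat(sprintf("<consensus '%s'> %d members: %s\n", x$consensus_id,
              nrow(x$members),
              paste(x$members$source_id, x$members$feature_id, sep = ":",
                    collapse = ", ")))
  invisible(x)
}

# internal key helpers -------------------------------------------------------

member_keys <- function(cf) paste(cf$members$source_id, cf$members$feature_id,
                                  sep = "\r")

gt_keys <- function(gt) lapply(gt$consensus_sets, function(s)
  paste(s$source_id, s$feature_id, sep = "\r"))
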