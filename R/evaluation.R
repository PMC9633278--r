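#' Alignment precision and recall against a ground truth
#'
#' Per-ground-truth-consensus generalization of precision and recall: for
#' each ground-truth set `G`, the best-matching tool consensus `t*` is the
#' one with the largest intersection with `G` (ties broken toward the
#' smaller tool consensus, then the lexicographically first id);
#' `recall(G) = |t* n G| / |G|` measures how completely the group was
#' recovered, `precision(G) = |t* n G| / |t*|` measures how little foreign
#' signal was admixed (0 if nothing intersects `G`). Both are averaged
#' arithmetically over all ground-truth sets.
#'
#' @param gt A [ground_truth()] object.
#' @param tool List of [consensus_feature()] objects.
#' @return List with `precision`, `recall`, and `per_consensus` (data frame
#'   with one row per ground-truth set: `gt_index`, `best_tool`,
#'   `intersection`, `gt_size`, `tool_size`, `precision`, `recall`).
#' @export
alignment_precision_recall <- function(gt, tool) {
  stopifnot(inherits(gt, "gw_ground_truth"))
  gsets <- gt_keys(gt)
  if (!length(gsets)) stop("empty ground truth")
  tsets <- lapply(tool, member_keys)
  tids <- vapply(tool, `[[`, character(1), "consensus_id")
  rows <- lapply(seq_along(gsets), function(i) {
    g <- gsets[[i]]
    inter <- vapply(tsets, function(t) length(intersect(t, g)), integer(1))
    if (!length(inter) || max(inter) == 0L) {
      return(data.frame(gt_index = i, best_tool = NA_character_,
                        intersection = 0L, gt_size = length(g),
                        tool_size = NA_integer_, precision = 0,
                        recall = 0))
    }
    sizes <- lengths(tsets)
    ord <- order(-inter, sizes, tids)
    b <- ord[1]
    data.frame(gt_index = i, best_tool = tids[b], intersection = inter[b],
               gt_size = length(g), tool_size = sizes[b],
               precision = inter[b] / sizes[b],
               recall = inter[b] / length(g))
  })
  per <- do.call(rbind, rows)
  list(precision = mean(per$precision), recall = mean(per$recall),
       per_consensus = per)
}

#' F-score: harmonic mean of alignment precision and recall
#'
#' @param p,r Alignment precision and recall, both in `[0, 1]`.
#' @return `2 * p * r / (p + r)`, or 0 when both are 0.
#' @examples
#' f_score(0.74, 0.83)
#' @export
f_score <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Identification recall over a chromatogram subset
#'
#' An identification label "repeats" over the subset when it annotates
#' features in at least two of its chromatograms; a repeating
#' identification is "properly aligned" when all its annotated features
#' within the subset fall inside one tool consensus. IR is the fraction of
#' repeating identifications that are properly aligned.
#'
#' @param annotated Named list mapping identification label to a data frame
#'   with columns `source_id`, `feature_id` (see [read_annotations()]).
#' @param tool List of [consensus_feature()] objects.
#' @param subset Character vector of `source_id`s (at least two) over which
#'   IR is computed; defaults to every chromatogram seen in `annotated`.
#' @return IR in `[0, 1]`, with attributes `n_repeating` and `n_aligned`.
#'   When no identification repeats, returns `NA` (flagged by
#'   `n_repeating = 0`) with a warning.
#' @export
identification_recall <- function(annotated, tool, subset = NULL) {
  if (is.null(subset))
    subset <- unique(unlist(lapply(annotated, `[[`, "source_id")))
  if (length(subset) < 2L) stop("subset must contain at least 2 chromatograms")
  tsets <- lapply(tool, member_keys)
  repeating <- 0L
  aligned <- 0L
  for (ann in annotated) {
    ann <- ann[ann$source_id %in% subset, , drop = FALSE]
    if (length(unique(ann$source_id)) < 2L) next
    repeating <- repeating + 1L
    keys <- paste(ann$source_id, ann$feature_id, sep = "\r")
    if (any(vapply(tsets, function(t) all(keys %in% t), logical(1))))
      aligned <- aligned + 1L
  }
  if (repeating == 0L) {
    warning("no repeating identifications over the subset; IR undefined")
    return(structure(NA_real_, n_repeating = 0L, n_aligned = 0L))
  }
  structure(aligned / repeating, n_repeating = repeating,
            n_aligned = aligned)
}

#' Fraction of swapped feature pairs in a true correspondence
#'
#' Over all unordered pairs of correspondences, a pair is a swap when the
#' two features' RT order differs between the two runs (strict sign flip;
#' exact ties count as non-swaps).
#'
#' @param pairing Data frame with columns `rt_a` and `rt_b`: the centroid
#'   RTs of each corresponding feature in run A and run B (as produced by
#'   [simulate_drift()]). At least two rows.
#' @return Fraction of swapped pairs, with attributes `n_swapped`,
#'   `n_pairs`, and `swapped_index` (2-column matrix of swapped row pairs).
#' @export
swap_fraction <- function(pairing) {
  n <- nrow(pairing)
  if (is.null(n) || n < 2L) stop("need at least 2 correspondences")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  da <- pairing$rt_a[idx[, 1]] - pairing$rt_a[idx[, 2]]
  db <- pairing$rt_b[idx[, 1]] - pairing$rt_b[idx[, 2]]
  swapped <- sign(da) != sign(db) & da != 0 & db != 0
  structure(sum(swapped) / nrow(idx),
            n_swapped = sum(swapped), n_pairs = nrow(idx),
            swapped_index = idx[swapped, , drop = FALSE])
}

# Which correspondences of a true pairing were recovered by the tool:
# recovered means some consensus contains both (source_a, id_a) and
# (source_b, id_b).
pairs_recovered <- function(pairing, tool, source_a, source_b) {
  tsets <- lapply(tool, member_keys)
  ka <- paste(source_a, pairing$id_a, sep = "\r")
  kb <- paste(source_b, pairing$id_b, sep = "\r")
  vapply(seq_len(nrow(pairing)), function(i)
    any(vapply(tsets, function(t) (ka[i] %in% t) && (kb[i] %in% t),
               logical(1))),
    logical(1))
}

#' Fraction of swapped pairs resolved by the tool
#'
#' A swapped pair (as identified by [swap_fraction()]) is resolved when both
#' of its correspondences are correctly recovered in the tool consensus.
#'
#' @param pairing True-correspondence data frame with columns `id_a`,
#'   `id_b`, `rt_a`, `rt_b`.
#' @param tool List of [consensus_feature()] objects.
#' @param source_a,source_b `source_id`s of the two runs.
#' @return Resolved fraction in `[0, 1]` with attributes `n_swapped` and
#'   `n_resolved`; `NA` (flagged, with a warning) when no pair is swapped.
#' @export
swap_resolution_rate <- function(pairing, tool, source_a, source_b) {
  sf <- swap_fraction(pairing)
  sw <- attr(sf, "swapped_index")
  if (!nrow(sw)) {
    warning("no swapped pairs; resolution rate undefined")
    return(structure(NA_real_, n_swapped = 0L, n_resolved = 0L))
  }
  rec <- pairs_recovered(pairing, tool, source_a, source_b)
  resolved <- rec[sw[, 1]] & rec[sw[, 2]]
  structure(mean(resolved), n_swapped = nrow(sw),
            n_resolved = sum(resolved))
}
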