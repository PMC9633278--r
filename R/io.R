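#' Read detected features from an OpenMS featureXML file
#'
#' One `ms_feature` is built per `<feature>` element. The peak set is
#' reconstructed from the feature's convex-hull points (all `<convexhull>`
#' elements, typically one per mass trace), with the feature's total
#' intensity apportioned uniformly over its hull points: hull points carry no
#' per-point intensity, and a uniform split preserves the total mass, which
#' is all the unit-mass normalization downstream retains. RT is read as
#' stored; featureXML from OpenMS stores seconds. Files storing minutes are
#' not auto-detected -- convert explicitly (`rt_minutes = TRUE`), because
#' silent unit guessing corrupts the scaled distances.
#'
#' @param path Path to a featureXML file.
#' @param source_id Chromatogram label; defaults to the file stem.
#' @param rt_minutes If `TRUE`, RT values are converted from minutes to
#'   seconds on read.
#' @return An [feature_set()] object.
#' @export
read_featurexml <- function(path, source_id = NULL, rt_minutes = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("malformed featureXML in '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (is.null(source_id))
    source_id <- tools::file_path_sans_ext(basename(path))
  # strip namespaces so xpath works across featureXML dialect versions
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//featureList/feature")
  if (!length(nodes)) nodes <- xml2::xml_find_all(doc, ".//feature")
  if (!length(nodes)) {
    warning(sprintf("no features found in '%s'", path))
    return(feature_set(source_id, list()))
  }
  feats <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    fid <- xml2::xml_attr(nd, "id")
    if (is.na(fid) || !nzchar(fid)) fid <- sprintf("feature_%d", i)
    pos <- xml2::xml_find_all(nd, "./position")
    if (length(pos) < 2L)
      stop(sprintf("feature '%s' in '%s': missing <position> elements", fid, path))
    dims <- xml2::xml_attr(pos, "dim")
    vals <- as.numeric(xml2::xml_text(pos))
    rt0 <- vals[match("0", dims)]
    mz0 <- vals[match("1", dims)]
    if (is.na(rt0) || is.na(mz0))
      stop(sprintf("feature '%s' in '%s': non-numeric <position>", fid, path))
    inten_txt <- xml2::xml_text(xml2::xml_find_first(nd, "./intensity"))
    intensity <- suppressWarnings(as.numeric(inten_txt))
    if (is.na(intensity))
      stop(sprintf("feature '%s' in '%s': missing or non-numeric <intensity>",
                   fid, path))
    charge_txt <- xml2::xml_text(xml2::xml_find_first(nd, "./charge"))
    charge <- suppressWarnings(as.integer(charge_txt))
    pts <- xml2::xml_find_all(nd, "./convexhull/pt")
    if (length(pts)) {
      rt <- as.numeric(xml2::xml_attr(pts, "x"))
      mz <- as.numeric(xml2::xml_attr(pts, "y"))
      if (any(is.na(rt)) || any(is.na(mz)))
        stop(sprintf("feature '%s' in '%s': non-numeric convexhull <pt>",
                     fid, path))
    } else {
      rt <- rt0
      mz <- mz0
    }
    if (rt_minutes) rt <- rt * 60
    feats[[i]] <- feature(fid, rt = rt, mz = mz,
                          intensity = rep(intensity / length(rt), length(rt)),
                          charge = charge)
  }
  feature_set(source_id, feats)
}

#' Read features from the plain TSV dialect
#'
#' Tab-separated, UTF-8, `.` decimal separator; header row with columns
#' `feature_id`, `rt`, `mz`, `intensity` (an optional `charge` column is
#' honored); one row per peak. Rows are grouped into features by
#' `feature_id`, preserving file order.
#'
#' @param path Path to the TSV file.
#' @param source_id Chromatogram label; defaults to the file stem.
#' @return An [feature_set()] object.
#' @export
read_feature_tsv <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(source_id))
    source_id <- tools::file_path_sans_ext(basename(path))
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  required <- c("feature_id", "rt", "mz", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("missing column(s) in '%s': %s", path,
                 paste(missing_cols, collapse = ", ")))
  if (!nrow(df)) return(feature_set(source_id, list()))
  for (col in c("rt", "mz", "intensity")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) || anyNA(v))
      stop(sprintf("non-numeric '%s' value at row %d of '%s'", col,
                   if (length(bad)) bad[1] else which(is.na(v))[1], path))
    df[[col]] <- v
  }
  if (any(df$intensity < 0)) {
    stop(sprintf("negative intensity at row %d of '%s'",
                 which(df$intensity < 0)[1], path))
  }
  charge <- if ("charge" %in% names(df))
    suppressWarnings(as.integer(df$charge)) else rep(NA_integer_, nrow(df))
  ids <- unique(df$feature_id)
  feats <- lapply(ids, function(fid) {
    rows <- df$feature_id == fid
    feature(fid, rt = df$rt[rows], mz = df$mz[rows],
            intensity = df$intensity[rows],
            charge = charge[which(rows)[1]])
  })
  feature_set(source_id, feats)
}

#' Write a feature set to the plain TSV dialect
#'
#' @param fs An [feature_set()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fs, path) {
  stopifnot(inherits(fs, "ms_feature_set"))
  rows <- lapply(fs$features, function(f)
    data.frame(feature_id = f$id, rt = f$peaks$rt, mz = f$peaks$mz,
               intensity = f$peaks$intensity,
               charge = f$charge))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(0), rt = numeric(0), mz = numeric(0),
               intensity = numeric(0), charge = integer(0))
  write_tsv_lf(df, path)
  invisible(path)
}

#' Write consensus features to TSV
#'
#' Columns `consensus_id`, `source_id`, `feature_id`, `centroid_rt`,
#' `centroid_mz`; one row per member, ordered by consensus id then source id,
#' so identical alignments always produce byte-identical files.
#'
#' @param consensus List of [consensus_feature()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  rows <- lapply(consensus, function(cf) {
    data.frame(consensus_id = cf$consensus_id,
               source_id = cf$members$source_id,
               feature_id = cf$members$feature_id,
               centroid_rt = cf$members$centroid_rt,
               centroid_mz = cf$members$centroid_mz)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(consensus_id = character(0), source_id = character(0),
               feature_id = character(0), centroid_rt = numeric(0),
               centroid_mz = numeric(0))
  df <- df[order(df$consensus_id, df$source_id, df$feature_id), , drop = FALSE]
  write_tsv_lf(df, path)
  invisible(path)
}

#' Read a consensus TSV back into consensus features
#'
#' Inverse of [write_consensus()] on membership.
#'
#' @param path Path to a consensus TSV.
#' @return List of [consensus_feature()] objects.
#' @export
read_consensus <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c(consensus_id = "character",
                                  source_id = "character",
                                  feature_id = "character"))
  if (!all(c("consensus_id", "source_id", "feature_id") %in% names(df)))
    stop(sprintf("missing consensus columns in '%s'", path))
  lapply(split(df, df$consensus_id), function(s)
    consensus_feature(s$consensus_id[1],
                      data.frame(source_id = s$source_id,
                                 feature_id = s$feature_id,
                                 centroid_rt = s$centroid_rt,
                                 centroid_mz = s$centroid_mz)))
}

#' Read a ground-truth consensus table
#'
#' TSV with columns `consensus_id`, `source_id`, `feature_id`; rows are
#' grouped by `consensus_id`.
#'
#' @param path Path to the TSV file.
#' @return A [ground_truth()] object.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  required <- c("consensus_id", "source_id", "feature_id")
  if (!all(required %in% names(df)))
    stop(sprintf("missing column(s) in '%s': %s", path,
                 paste(setdiff(required, names(df)), collapse = ", ")))
  sets <- lapply(split(df, df$consensus_id), function(s)
    data.frame(source_id = s$source_id, feature_id = s$feature_id))
  ground_truth(unname(sets))
}

#' Read a feature-annotation table
#'
#' TSV with columns `identification`, `source_id`, `feature_id`: one row per
#' feature annotated with an identification label (e.g., a peptide sequence).
#'
#' @param path Path to the TSV file.
#' @return Named list mapping identification label to a data frame with
#'   columns `source_id`, `feature_id` -- the input of
#'   [identification_recall()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  required <- c("identification", "source_id", "feature_id")
  if (!all(required %in% names(df)))
    stop(sprintf("missing column(s) in '%s': %s", path,
                 paste(setdiff(required, names(df)), collapse = ", ")))
  lapply(split(df, df$identification), function(s)
    data.frame(source_id = s$source_id, feature_id = s$feature_id))
}

# TSV writer shared by all outputs: UTF-8, LF, '.' decimal separator.
write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
}
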