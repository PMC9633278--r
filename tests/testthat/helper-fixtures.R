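# Shared fixture builders and independent oracles.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A tiny hand-built feature: single analyte with a few peaks.
toy_feature <- function(id = "f1", rt0 = 100, mz0 = 500, n = 3,
                        intensity = rep(1, n)) {
  feature(id, rt = rt0 + seq_len(n) - 1, mz = rep(mz0, n),
          intensity = intensity)
}

# A feature set of k well-separated single-peak features.
toy_set <- function(source_id = "A", k = 3, rt_step = 100, mz_step = 50) {
  feature_set(source_id, lapply(seq_len(k), function(i)
    feature(sprintf("%s%d", tolower(source_id), i),
            rt = rt_step * i, mz = 300 + mz_step * i, intensity = 1)))
}

# Random unit-mass measure with <= max_pts support points in [0, 1]^2.
random_measure <- function(max_pts = 10) {
  n <- sample.int(max_pts, 1)
  w <- runif(n)
  measure(cbind(runif(n), runif(n)), w / sum(w))
}

# Independent oracle: brute-force optimal partial matching with per-feature
# trash cost, by exhaustive recursion over all injective partial assignments.
brute_force_matching <- function(C, trash) {
  n <- nrow(C); m <- ncol(C)
  best <- Inf
  recurse <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n) { best <<- cost; return() }
    recurse(i + 1L, used, cost + trash)
    if (m) for (j in seq_len(m)[!seq_len(m) %in% used])
      recurse(i + 1L, c(used, j), cost + C[i, j])
  }
  recurse(1L, integer(0), 0)
  best
}

# featureXML fixture writer (OpenMS dialect, trimmed to what the reader uses)
write_featurexml_fixture <- function(path, features) {
  feat_xml <- vapply(features, function(f) {
    pts <- paste(sprintf('\t\t\t\t<pt x="%g" y="%g" />', f$rt, f$mz),
                 collapse = "\n")
    sprintf(paste0(
      '\t\t<feature id="%s">\n',
      '\t\t\t<position dim="0">%g</position>\n',
      '\t\t\t<position dim="1">%g</position>\n',
      '\t\t\t<intensity>%g</intensity>\n',
      '\t\t\t<quality dim="0">0</quality>\n',
      '\t\t\t<charge>%d</charge>\n',
      '\t\t\t<convexhull nr="0">\n%s\n\t\t\t</convexhull>\n',
      '\t\t</feature>'),
      f$id, mean(f$rt), mean(f$mz), f$intensity, f$charge, pts)
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<featureMap version="1.9" xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance">',
    sprintf('\t<featureList count="%d">', length(features)),
    feat_xml,
    '\t</featureList>',
    '</featureMap>'), path)
  path
}

fxml_feature <- function(id, rt, mz, intensity = 1000, charge = 2L) {
  list(id = id, rt = rt, mz = mz, intensity = intensity, charge = charge)
}
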