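#' Cluster feature centroids into consensus candidates
#'
#' Two-stage clustering of the scaled centroids of all chromatograms: a
#' seeded k-means stage with `k = ceil(total features / chromatograms) *
#' overcluster` (deliberately overclustered so that no cluster spans two
#' analytes), followed by an agglomerative merge (average linkage, Manhattan
#' distance) of the k-means centers with merge threshold `cluster_cut`,
#' which fuses centers that the overclustering split. Each final cluster is
#' a candidate consensus feature.
#'
#' @param centroids Data frame with columns `source_id`, `feature_id`, `rt`,
#'   `mz` in scaled coordinates (see [feature_centroids()]).
#' @param cfg A [run_config()] object.
#' @param n_chromatograms Number of chromatograms the centroids came from
#'   (defaults to the number of distinct `source_id`s).
#' @return An object of class `gw_clusters`: list with `labels` (integer
#'   vector parallel to `centroids` rows, values `1..s`), `s`, and the
#'   input key columns.
#' @export
cluster_centroids <- function(centroids, cfg = run_config(),
                              n_chromatograms = length(unique(centroids$source_id))) {
  stopifnot(nrow(centroids) >= 1)
  pts <- as.matrix(centroids[, c("rt", "mz")])
  uniq <- unique(pts)
  n_distinct <- nrow(uniq)
  k <- ceiling(ceiling(nrow(pts) / max(1L, n_chromatograms)) *
                 cfg$overcluster)
  if (k > n_distinct) {
    warning(sprintf("k clamped from %d to %d distinct centroid positions",
                    k, n_distinct))
    k <- n_distinct
  }
  if (n_distinct == 1L) {
    labels <- rep(1L, nrow(pts))
    s <- 1L
  } else {
    if (k >= n_distinct) {
      # overclustering saturates: every distinct position is its own
      # stage-1 cluster (k-means with k = n is this, exactly)
      stage1 <- match(paste(pts[, 1], pts[, 2]), paste(uniq[, 1], uniq[, 2]))
      centers <- uniq
    } else {
      km <- with_seed(cfg$seed,
        suppressWarnings(kmeans(pts, centers = k, iter.max = 50L,
                                nstart = 1L)))
      stage1 <- km$cluster
      centers <- km$centers
    }
    hc <- hclust(dist(centers, method = "manhattan"), method = "average")
    merged <- cutree(hc, h = cfg$cluster_cut)
    labels <- merged[stage1]
    # contiguous 1..s in order of first appearance
    labels <- match(labels, unique(labels))
    s <- max(labels)
  }
  structure(list(labels = as.integer(labels), s = as.integer(s),
                 source_id = centroids$source_id,
                 feature_id = centroids$feature_id),
            class = "gw_clusters")
}

#' @export
print.gw_clusters <- function(x, ...) {
  cat(sprintf("<gw_clusters> %d features in %d clusters\n",
              length(x$labels), x$s))
  invisible(x)
}

# label lookup: (source_id, feature_id) -> cluster index
cluster_label_map <- function(clusters) {
  setNames(clusters$labels,
           paste(clusters$source_id, clusters$feature_id, sep = "\r"))
}

#' Build the per-chromatogram matching network
#'
#' Constructs the flow network whose minimum-cost maximum flow is the
#' optimal matching of one chromatogram's features (`L` nodes) against the
#' pooled features of all other chromatograms (`R` nodes), grouped into
#' consensus-candidate clusters (`C` nodes):
#' source -> each `L_i` (capacity 1, cost 0); `L_i -> R_j` for every cached
#' candidate pair (capacity 1, cost = integer-scaled GWD); each `R_j` -> its
#' own cluster `C_k` (capacity 1, cost 0); each `C_k` -> sink (capacity 1),
#' so a cluster absorbs at most one feature of the `L` chromatogram; and a
#' trash path `L_i -> Tr` (capacity 1, cost = integer-scaled `c`) with
#' `Tr -> sink` of capacity `n`, so any feature may remain unmatched at cost
#' `c` regardless of how many clusters exist. Costs are made integral by
#' multiplying by `int_scale` and rounding, as required by exact min-cost
#' flow arithmetic; remaining ties are broken by node index, a documented
#' source of run-to-run stability.
#'
#' @param L An [feature_set()] (scaled) whose features form the `L` side.
#' @param pool Pooled features from [pool_features()] (scaled).
#' @param clusters A `gw_clusters` assignment covering every pool feature.
#' @param cache A `gw_distance_cache` between `L` and `pool`.
#' @param trash_cost Cost `c` of leaving a feature unmatched (GWD units).
#' @param int_scale Integer cost scale.
#' @return An object of class `gw_flow_network`.
#' @export
build_flow_network <- function(L, pool, clusters, cache,
                               trash_cost = 19, int_scale = 1e4) {
  stopifnot(inherits(L, "ms_feature_set"))
  n <- length(L$features)
  m <- length(pool$features)
  lab_map <- cluster_label_map(clusters)
  pool_lab <- unname(lab_map[paste(pool$source_id, pool$feature_id,
                                   sep = "\r")])
  if (anyNA(pool_lab)) stop("every pool feature must carry a cluster label")
  s <- if (m) max(clusters$s) else 0L
  l_ids <- names(L$features)
  # node numbering: S=1, L = 2..n+1, R = n+2..n+m+1, C = ..., Tr, T
  S <- 1L
  Lo <- 1L
  Ro <- n + 1L
  Co <- n + m + 1L
  Tr <- n + m + s + 2L
  Tk <- n + m + s + 3L
  edges <- list(
    data.frame(from = S, to = Lo + seq_len(n), cap = 1,
               cost = 0, kind = "S-L", li = seq_len(n), rj = NA_integer_))
  if (nrow(cache)) {
    li <- match(cache$target_id, l_ids)
    if (anyNA(li)) stop("cache references features absent from L")
    ord <- order(li, cache$pool_index)
    edges$LR <- data.frame(from = Lo + li[ord], to = Ro + cache$pool_index[ord],
                           cap = 1, cost = round(cache$cost[ord] * int_scale),
                           kind = "L-R", li = li[ord],
                           rj = cache$pool_index[ord])
  }
  edges$LTr <- data.frame(from = Lo + seq_len(n), to = Tr, cap = 1,
                          cost = round(trash_cost * int_scale), kind = "L-Tr",
                          li = seq_len(n), rj = NA_integer_)
  if (m)
    edges$RC <- data.frame(from = Ro + seq_len(m), to = Co + pool_lab,
                           cap = 1, cost = 0, kind = "R-C",
                           li = NA_integer_, rj = seq_len(m))
  if (s)
    edges$CT <- data.frame(from = Co + seq_len(s), to = Tk, cap = 1,
                           cost = 0, kind = "C-T", li = NA_integer_,
                           rj = NA_integer_)
  edges$TrT <- data.frame(from = Tr, to = Tk, cap = n, cost = 0,
                          kind = "Tr-T", li = NA_integer_, rj = NA_integer_)
  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL
  structure(list(edges = edges, n = n, m = m, s = s, n_nodes = Tk,
                 source = S, sink = Tk, l_ids = l_ids,
                 pool_source = pool$source_id, pool_id = pool$feature_id,
                 pool_cluster = pool_lab, int_scale = int_scale,
                 L_source = L$source_id),
            class = "gw_flow_network")
}

#' @export
print.gw_flow_network <- function(x, ...) {
  cat(sprintf("<gw_flow_network> n=%d L, m=%d R, s=%d clusters, %d edges\n",
              x$n, x$m, x$s, nrow(x$edges)))
  invisible(x)
}

#' Solve a matching network by minimum-cost maximum flow
#'
#' Computes the minimum-cost flow of value `n` (always feasible: every `L`
#' feature is either matched or trashed) with a successive-shortest-path
#' solver, and decodes the unit flows `L_i -> R_j -> C_k` into (feature,
#' cluster) pairs. Deterministic for a fixed network.
#'
#' @param net A `gw_flow_network` from [build_flow_network()].
#' @return An object of class `gw_matching`: list with `pairs` (data frame
#'   `feature_id`, `pool_source`, `pool_id`, `cluster`, `cost` -- the
#'   realized integer-scaled cost divided back by `int_scale`), `unmatched`
#'   (character vector of trashed `L` feature ids), `flow_cost` (total
#'   objective, GWD units), and the solved per-edge flows.
#' @export
solve_matching <- function(net) {
  stopifnot(inherits(net, "gw_flow_network"))
  if (net$n == 0L)
    return(structure(list(pairs = data.frame(feature_id = character(0),
                                             pool_source = character(0),
                                             pool_id = character(0),
                                             cluster = integer(0),
                                             cost = numeric(0)),
                          unmatched = character(0), flow_cost = 0,
                          flows = numeric(0), L_source = net$L_source),
                     class = "gw_matching"))
  e <- net$edges
  res <- .mcf_solve(e$from, e$to, e$cap, e$cost, net$n_nodes, net$source,
                    net$sink, net$n)
  fl <- res$flow
  lr <- which(e$kind == "L-R" & fl > 0.5)
  pairs <- data.frame(
    feature_id = net$l_ids[e$li[lr]],
    pool_source = net$pool_source[e$rj[lr]],
    pool_id = net$pool_id[e$rj[lr]],
    cluster = net$pool_cluster[e$rj[lr]],
    cost = e$cost[lr] / net$int_scale)
  trashed <- which(e$kind == "L-Tr" & fl > 0.5)
  structure(list(pairs = pairs, unmatched = net$l_ids[e$li[trashed]],
                 flow_cost = res$total_cost / net$int_scale, flows = fl,
                 L_source = net$L_source),
            class = "gw_matching")
}

#' @export
print.gw_matching <- function(x, ...) {
  cat(sprintf("<gw_matching> %d matched, %d trashed, cost %.4f\n",
              nrow(x$pairs), length(x$unmatched), x$flow_cost))
  invisible(x)
}

#' Optimal matching between two chromatograms
#'
#' The two-chromatogram special case: the clustering stage is omitted and
#' the network loses its cluster layer (`L_i -> R_j -> sink` directly, each
#' `R_j` of capacity 1), so the result is the optimal partial matching of
#' the two feature sets with per-feature opt-out at cost `trash_cost`.
#'
#' @param a,b [feature_set()] objects in scaled coordinates.
#' @param params A [gwd_params()] object.
#' @param trash_cost Cost of leaving a feature unmatched.
#' @param window Centroid cutoff for candidate pairs; default `2 * lam`.
#' @param int_scale Integer cost scale.
#' @param cache Optional precomputed `gw_distance_cache` between `a` and
#'   `b`.
#' @return Data frame with columns `id_a`, `id_b`, `cost`; attribute
#'   `unmatched_a`, `unmatched_b` list the features left unmatched.
#' @export
match_two <- function(a, b, params = gwd_params(),
                      trash_cost = 1.9 * params$lam,
                      window = 2 * params$lam, int_scale = 1e4,
                      cache = NULL) {
  stopifnot(inherits(a, "ms_feature_set"), inherits(b, "ms_feature_set"))
  pool <- pool_features(list(b))
  if (is.null(cache)) cache <- pairwise_costs(a, pool, params, window)
  # degenerate clustering: each pool feature is its own cluster
  clusters <- structure(list(labels = seq_along(pool$features),
                             s = length(pool$features),
                             source_id = pool$source_id,
                             feature_id = pool$feature_id),
                        class = "gw_clusters")
  net <- build_flow_network(a, pool, clusters, cache, trash_cost, int_scale)
  mt <- solve_matching(net)
  out <- data.frame(id_a = mt$pairs$feature_id, id_b = mt$pairs$pool_id,
                    cost = mt$pairs$cost)
  attr(out, "unmatched_a") <- mt$unmatched
  attr(out, "unmatched_b") <- setdiff(pool$feature_id, out$id_b)
  attr(out, "flow_cost") <- mt$flow_cost
  out
}

#' Assemble consensus features from per-chromatogram matchings
#'
#' The consensus feature of cluster `k` collects every (chromatogram,
#' feature) pair matched to `k` across the matching iterations. Each
#' chromatogram serves as the `L` side exactly once and each cluster has
#' unit capacity per iteration, so a consensus can contain at most one
#' feature per chromatogram by construction (asserted). Consensus features
#' with fewer than two members are dropped unless `keep_singletons`.
#'
#' @param matchings List of `gw_matching` objects, one per chromatogram.
#' @param clusters The `gw_clusters` assignment used to build the networks.
#' @param centroids Optional data frame of original-unit centroids
#'   (`source_id`, `feature_id`, `rt`, `mz`) used to annotate members.
#' @param keep_singletons Keep single-member consensus features.
#' @return List of [consensus_feature()] objects.
#' @export
assemble_consensus <- function(matchings, clusters, centroids = NULL,
                               keep_singletons = FALSE) {
  rows <- do.call(rbind, lapply(matchings, function(mt) {
    if (!nrow(mt$pairs)) return(NULL)
    data.frame(source_id = mt$L_source, feature_id = mt$pairs$feature_id,
               cluster = mt$pairs$cluster)
  }))
  if (is.null(rows) || !nrow(rows)) return(list())
  if (!is.null(centroids)) {
    idx <- match(paste(rows$source_id, rows$feature_id, sep = "\r"),
                 paste(centroids$source_id, centroids$feature_id, sep = "\r"))
    rows$centroid_rt <- centroids$rt[idx]
    rows$centroid_mz <- centroids$mz[idx]
  }
  out <- list()
  for (k in sort(unique(rows$cluster))) {
    members <- rows[rows$cluster == k, , drop = FALSE]
    stopifnot(!anyDuplicated(members$source_id))
    if (nrow(members) < 2L && !keep_singletons) next
    out[[length(out) + 1L]] <-
      consensus_feature(sprintf("c%04d", k),
                        members[, setdiff(names(members), "cluster"),
                                drop = FALSE],
                        cluster = k)
  }
  out
}

#' Align chromatograms
#'
#' The full pipeline: estimate and apply RT scaling; compute centroids;
#' cluster them into consensus candidates (skipped for exactly two
#' chromatograms, which are matched directly); for each chromatogram in
#' input order, compute the sparse pairwise GWD cache against the pooled
#' others, build the matching network and solve it; finally assemble the
#' per-cluster consensus features.
#'
#' @param sets List of at least two [feature_set()] objects (seconds).
#' @param cfg A [run_config()] object.
#' @return An object of class `gw_alignment`: list with `consensus` (list of
#'   [consensus_feature()]), and `report` (scaling factor, cluster count
#'   `s`, per-iteration matched/trashed counts and flow costs, resolved
#'   configuration).
#' @export
align <- function(sets, cfg = run_config()) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("alignment needs at least 2 feature sets")
  stopifnot(all(vapply(sets, inherits, logical(1), "ms_feature_set")))
  empty <- vapply(sets, function(s) length(s$features) == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("dropping empty chromatogram(s): %s",
                    paste(vapply(sets[empty], `[[`, character(1), "source_id"),
                          collapse = ", ")))
    sets <- sets[!empty]
  }
  if (length(sets) < 2L)
    stop("fewer than 2 non-empty feature sets; nothing to align")
  src <- vapply(sets, `[[`, character(1), "source_id")
  if (anyDuplicated(src)) stop("source_ids must be unique across inputs")

  params <- config_gwd_params(cfg)
  scaling <- estimate_rt_scaling(sets, k = cfg$rt_scale_k)
  orig_centroids <- do.call(rbind, lapply(sets, feature_centroids))
  scaled <- lapply(sets, apply_scaling, info = scaling)
  names(scaled) <- src

  if (length(scaled) == 2L) {
    pairs <- match_two(scaled[[1]], scaled[[2]], params,
                       trash_cost = cfg$trash_cost, window = cfg$window,
                       int_scale = cfg$int_scale)
    consensus <- list()
    if (nrow(pairs)) {
      for (i in seq_len(nrow(pairs))) {
        members <- data.frame(
          source_id = c(src[1], src[2]),
          feature_id = c(pairs$id_a[i], pairs$id_b[i]))
        idx <- match(paste(members$source_id, members$feature_id, sep = "\r"),
                     paste(orig_centroids$source_id,
                           orig_centroids$feature_id, sep = "\r"))
        members$centroid_rt <- orig_centroids$rt[idx]
        members$centroid_mz <- orig_centroids$mz[idx]
        consensus[[i]] <- consensus_feature(sprintf("c%04d", i), members)
      }
    }
    report <- list(factor = scaling$factor, s = NA_integer_,
                   n_chromatograms = 2L,
                   iterations = data.frame(
                     source_id = src[1], matched = nrow(pairs),
                     trashed = length(attr(pairs, "unmatched_a")),
                     flow_cost = attr(pairs, "flow_cost")),
                   config = unclass(cfg))
    return(structure(list(consensus = consensus, report = report),
                     class = "gw_alignment"))
  }

  scaled_centroids <- do.call(rbind, lapply(scaled, feature_centroids))
  clusters <- cluster_centroids(scaled_centroids, cfg,
                                n_chromatograms = length(scaled))
  matchings <- vector("list", length(scaled))
  iter_rows <- vector("list", length(scaled))
  for (i in seq_along(scaled)) {
    L <- scaled[[i]]
    pool <- pool_features(scaled, exclude = src[i])
    cache <- pairwise_costs(L, pool, params, window = cfg$window)
    net <- build_flow_network(L, pool, clusters, cache,
                              trash_cost = cfg$trash_cost,
                              int_scale = cfg$int_scale)
    matchings[[i]] <- solve_matching(net)
    iter_rows[[i]] <- data.frame(source_id = src[i],
                                 matched = nrow(matchings[[i]]$pairs),
                                 trashed = length(matchings[[i]]$unmatched),
                                 flow_cost = matchings[[i]]$flow_cost)
  }
  consensus <- assemble_consensus(matchings, clusters, orig_centroids,
                                  keep_singletons = cfg$keep_singletons)
  report <- list(factor = scaling$factor, s = clusters$s,
                 n_chromatograms = length(scaled),
                 iterations = do.call(rbind, iter_rows),
                 config = unclass(cfg))
  structure(list(consensus = consensus, report = report),
            class = "gw_alignment")
}

#' @export
print.gw_alignment <- function(x, ...) {
  cat(sprintf("<gw_alignment> %d consensus features from %d chromatograms (RT factor %.3f)\n",
              length(x$consensus), x$report$n_chromatograms,
              x$report$factor))
  invisible(x)
}
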