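test_that("centroid clustering separates well-spaced groups", {
  # two blobs of identical points, far apart
  cents <- data.frame(
    source_id = rep(c("A", "B"), each = 5),
    feature_id = paste0("f", 1:10),
    rt = rep(c(0, 100), each = 5), mz = rep(c(300, 800), each = 5))
  cl <- suppressWarnings(cluster_centroids(cents, run_config()))
  expect_equal(cl$s, 2)
  expect_length(unique(cl$labels[1:5]), 1)
  expect_length(unique(cl$labels[6:10]), 1)
  expect_false(cl$labels[1] == cl$labels[6])

  # all points identical -> one cluster
  same <- data.frame(source_id = "A", feature_id = paste0("f", 1:4),
                     rt = 1, mz = 2)
  expect_equal(suppressWarnings(cluster_centroids(same, run_config()))$s, 1)
})

test_that("clustering recovers well-separated groups, stable across seeds,
           matching a single-linkage oracle", {
  set.seed(33)
  centers <- cbind(rt = c(0, 50, 100, 150), mz = c(300, 600, 900, 1200))
  pts <- do.call(rbind, lapply(1:4, function(g)
    cbind(centers[g, 1] + runif(5, -1, 1), centers[g, 2] + runif(5, -1, 1))))
  cents <- data.frame(source_id = rep(c("A", "B", "C", "D", "E"), times = 4),
                      feature_id = paste0("f", 1:20),
                      rt = pts[, 1], mz = pts[, 2])
  truth <- rep(1:4, each = 5)
  # oracle: single-linkage on the same points with the same cut
  sl <- cutree(hclust(dist(pts, method = "manhattan"), "single"), k = 4)
  for (seed in 1:5) {
    cl <- cluster_centroids(cents, run_config(seed = seed))
    expect_equal(cl$s, 4)
    # group-pure: label is a bijective relabeling of the truth & oracle
    expect_equal(length(unique(paste(cl$labels, truth))), 4)
    expect_equal(length(unique(paste(cl$labels, sl))), 4)
  }
})

test_that("flow network construction follows the wiring rules", {
  a <- feature_set("A", list(toy_feature("a1", rt0 = 1, mz0 = 5)))
  pool <- pool_features(list(feature_set("B",
    list(toy_feature("b1", rt0 = 1, mz0 = 5)))))
  clusters <- suppressWarnings(cluster_centroids(
    data.frame(source_id = "B", feature_id = "b1", rt = 1, mz = 5),
    run_config()))
  cache <- data.frame(target_id = "a1", pool_source = "B", pool_id = "b1",
                      pool_index = 1L, cost = 0.31342)
  net <- build_flow_network(a, pool, clusters, cache, trash_cost = 19)
  e <- net$edges
  # n=1, m=1, s=1: exactly the six canonical edges
  expect_equal(nrow(e), 6)
  expect_setequal(e$kind, c("S-L", "L-R", "L-Tr", "R-C", "C-T", "Tr-T"))
  # integer cost scaling: GWD 0.31342 at 1e4 -> 3134
  expect_equal(e$cost[e$kind == "L-R"], 3134)
  expect_equal(e$cap[e$kind == "Tr-T"], net$n)
  expect_true(all(e$cap[e$kind != "Tr-T"] == 1))

  # pruned pair: no L-R edge; the feature is trashable only
  net2 <- build_flow_network(a, pool, clusters, cache[0, ], trash_cost = 19)
  expect_false("L-R" %in% net2$edges$kind)
  mt <- solve_matching(net2)
  expect_equal(mt$unmatched, "a1")
})

test_that("matching solves small instances optimally, including trash", {
  # 2x2 block-diagonal costs, expensive trash: match the cheap diagonal
  mk_net <- function(C, trash) {
    n <- nrow(C); m <- ncol(C)
    a <- feature_set("A", lapply(seq_len(n), function(i)
      toy_feature(paste0("a", i), rt0 = i, mz0 = 0)))
    pool <- pool_features(list(feature_set("B", lapply(seq_len(m), function(j)
      toy_feature(paste0("b", j), rt0 = j, mz0 = 0)))))
    clusters <- structure(list(labels = seq_len(m), s = m,
                               source_id = pool$source_id,
                               feature_id = pool$feature_id),
                          class = "gw_clusters")
    cache <- expand.grid(li = seq_len(n), rj = seq_len(m))
    cache <- data.frame(target_id = paste0("a", cache$li),
                        pool_source = "B", pool_id = paste0("b", cache$rj),
                        pool_index = cache$rj,
                        cost = C[cbind(cache$li, cache$rj)])
    build_flow_network(a, pool, clusters, cache, trash_cost = trash)
  }
  C <- matrix(c(1, 10, 10, 1), 2, byrow = TRUE)
  mt <- solve_matching(mk_net(C, 100))
  expect_equal(sort(paste(mt$pairs$feature_id, mt$pairs$pool_id)),
               c("a1 b1", "a2 b2"))
  expect_equal(mt$flow_cost, 2)

  # cheap trash: both features are better off unmatched (0.8 < any match)
  mt2 <- solve_matching(mk_net(C, 0.4))
  expect_equal(nrow(mt2$pairs), 0)
  expect_setequal(mt2$unmatched, c("a1", "a2"))
  expect_equal(mt2$flow_cost, 0.8)

  # a canonical swapped-features cost pattern: corresponding pairs cost
  # (0.3, 80.3), crossed pairs (46.3, 46.3); the matcher must prefer the
  # corresponding assignment (80.6 over 92.6)
  C3 <- matrix(c(0.3, 46.3, 46.3, 80.3), 2, byrow = TRUE)
  mt3 <- solve_matching(mk_net(C3, 1000))
  expect_equal(sort(paste(mt3$pairs$feature_id, mt3$pairs$pool_id)),
               c("a1 b1", "a2 b2"))
  expect_equal(mt3$flow_cost, 80.6)
})

test_that("solved flows respect conservation and capacities", {
  set.seed(12)
  a <- feature_set("A", lapply(1:4, function(i)
    toy_feature(paste0("a", i), rt0 = runif(1, 0, 50), mz0 = runif(1, 0, 50))))
  b <- feature_set("B", lapply(1:5, function(j)
    toy_feature(paste0("b", j), rt0 = runif(1, 0, 50), mz0 = runif(1, 0, 50))))
  pool <- pool_features(list(b))
  clusters <- suppressWarnings(cluster_centroids(pool$centroids, run_config()))
  cache <- pairwise_costs(a, pool, gwd_params(lam = 30), window = 1e6)
  net <- build_flow_network(a, pool, clusters, cache, trash_cost = 40)
  mt <- solve_matching(net)
  fl <- mt$flows
  e <- net$edges
  expect_true(all(fl >= -1e-9 & fl <= e$cap + 1e-9))
  # conservation at every interior node
  for (v in setdiff(seq_len(net$n_nodes), c(net$source, net$sink)))
    expect_equal(sum(fl[e$to == v]), sum(fl[e$from == v]), tolerance = 1e-9)
  # max flow: every L feature matched or trashed
  expect_equal(nrow(mt$pairs) + length(mt$unmatched), 4)
})

test_that("two-set matching equals exhaustive enumeration on random
           instances", {
  set.seed(4)
  p <- gwd_params(lam = 30)
  for (t in 1:25) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    A <- feature_set("A", lapply(seq_len(n), function(i)
      feature(paste0("a", i), runif(1, 0, 10), runif(1, 0, 10), 1)))
    B <- feature_set("B", lapply(seq_len(m), function(j)
      feature(paste0("b", j), runif(1, 0, 10), runif(1, 0, 10), 1)))
    trash <- runif(1, 1, 25)
    mt <- match_two(A, B, p, trash_cost = trash, window = 1e9)
    C <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m))
      C[i, j] <- exact_gwd(to_measure(A$features[[i]]),
                           to_measure(B$features[[j]]), p)$cost
    # same integer rounding as the network applies
    opt <- brute_force_matching(round(C * 1e4) / 1e4, round(trash * 1e4) / 1e4)
    got <- sum(mt$cost) + (n - nrow(mt)) * round(trash * 1e4) / 1e4
    expect_equal(got, opt, tolerance = 1e-9)
  }
})

test_that("match_two endpoints: identity and all-trash", {
  fs <- toy_set("A", k = 4)
  fs_b <- toy_set("B", k = 4)
  p <- gwd_params(lam = 10)
  mt <- match_two(fs, fs_b, p, trash_cost = 19)
  expect_equal(nrow(mt), 4)
  expect_equal(substr(mt$id_a, 2, 2), substr(mt$id_b, 2, 2))
  expect_true(all(mt$cost < 1e-6))

  far <- feature_set("B", lapply(1:4, function(i)
    feature(paste0("b", i), rt = 1e5 + 100 * i, mz = 2000 + 50 * i,
            intensity = 1)))
  mt2 <- match_two(fs, far, p, trash_cost = 0.5)
  expect_equal(nrow(mt2), 0)
  expect_setequal(attr(mt2, "unmatched_a"), c("a1", "a2", "a3", "a4"))
})

test_that("consensus assembly groups by cluster and drops singletons", {
  mk_matching <- function(src, ids, clusters_of)
    structure(list(pairs = data.frame(feature_id = ids,
                                      pool_source = "x", pool_id = "y",
                                      cluster = clusters_of,
                                      cost = 0),
                   unmatched = character(0), flow_cost = 0,
                   L_source = src),
              class = "gw_matching")
  clusters <- structure(list(labels = 1:3, s = 3L,
                             source_id = c("A", "B", "C"),
                             feature_id = c("f1", "f2", "f3")),
                        class = "gw_clusters")
  m <- list(mk_matching("A", c("a1", "a2"), c(7L, 8L)),
            mk_matching("B", c("b1"), 7L),
            mk_matching("C", c("c1"), 7L))
  cons <- assemble_consensus(m, clusters)
  expect_length(cons, 1)  # cluster 8 is a singleton, dropped by default
  expect_equal(nrow(cons[[1]]$members), 3)
  expect_equal(cons[[1]]$cluster, 7L)
  both <- assemble_consensus(m, clusters, keep_singletons = TRUE)
  expect_length(both, 2)
})

test_that("aligning identical chromatograms recovers every feature pair", {
  gen <- generate_chromatogram(generator_params(n_features = 10, seed = 5), "A")
  twin <- gen$features; twin$source_id <- "B"
  aln <- align(list(gen$features, twin), run_config())
  expect_length(aln$consensus, 10)
  for (cf in aln$consensus) {
    expect_equal(nrow(cf$members), 2)
    expect_length(unique(cf$members$feature_id), 1)
  }
})

test_that("alignment tolerates an empty chromatogram with a warning", {
  gen <- generate_chromatogram(generator_params(n_features = 6, seed = 6), "A")
  b <- simulate_drift(gen$features, drift_params(3, 0.005, seed = 7), "B")$drifted
  c3 <- simulate_drift(gen$features, drift_params(3, 0.005, seed = 8), "C")$drifted
  empty <- feature_set("D", list())
  expect_warning(aln <- align(list(gen$features, b, c3, empty), run_config()),
                 "empty chromatogram")
  expect_equal(aln$report$n_chromatograms, 3)
  expect_gt(length(aln$consensus), 0)
  expect_error(align(list(gen$features)), "at least 2")
})

test_that("small-drift alignment recovers nearly all true pairs", {
  gen <- generate_chromatogram(generator_params(n_features = 100, seed = 31), "A")
  dr <- simulate_drift(gen$features, drift_params(5, 0.01, seed = 32), "B")
  aln <- suppressWarnings(align(list(gen$features, dr$drifted), run_config()))
  rec <- gwalign:::pairs_recovered(dr$pairing, aln$consensus, "A", "B")
  expect_gte(sum(rec), 95)
})

test_that("permuting chromatogram order changes few consensus memberships", {
  gen <- generate_chromatogram(generator_params(n_features = 40, seed = 41), "A")
  b <- simulate_drift(gen$features, drift_params(8, 0.02, seed = 42), "B")$drifted
  c3 <- simulate_drift(gen$features, drift_params(8, 0.02, seed = 43), "C")$drifted
  key <- function(aln) vapply(aln$consensus, function(cf)
    paste(sort(paste(cf$members$source_id, cf$members$feature_id)),
          collapse = ";"), character(1))
  k1 <- key(suppressWarnings(align(list(gen$features, b, c3), run_config())))
  k2 <- key(suppressWarnings(align(list(c3, b, gen$features), run_config())))
  overlap <- length(intersect(k1, k2)) / max(length(k1), length(k2))
  expect_gte(overlap, 0.9)
})
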