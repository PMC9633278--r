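cf <- function(id, src, feat)
  consensus_feature(id, data.frame(source_id = src, feature_id = feat))

test_that("alignment precision/recall on hand-worked cases", {
  # perfect reproduction
  gt <- ground_truth(list(
    data.frame(source_id = c("A", "B"), feature_id = c("f1", "f1")),
    data.frame(source_id = c("A", "B"), feature_id = c("f2", "f2"))))
  tool <- list(cf("t1", c("A", "B"), c("f1", "f1")),
               cf("t2", c("A", "B"), c("f2", "f2")))
  pr <- alignment_precision_recall(gt, tool)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  # dropped member: gt {A1,B1,C1}, tool {A1,B1} -> R = 2/3, P = 1
  gt2 <- ground_truth(list(
    data.frame(source_id = c("A", "B", "C"), feature_id = c("f1", "f1", "f1"))))
  pr2 <- alignment_precision_recall(gt2, list(cf("t1", c("A", "B"),
                                                 c("f1", "f1"))))
  expect_equal(pr2$recall, 2 / 3)
  expect_equal(pr2$precision, 1)

  # merged consensus: two gt sets absorbed into one tool set -> P = 0.5, R = 1
  gt3 <- ground_truth(list(
    data.frame(source_id = c("A", "B"), feature_id = c("f1", "f1")),
    data.frame(source_id = c("A", "B"), feature_id = c("f2", "f2"))))
  merged <- list(cf("t1", c("A", "B", "A", "B"), c("f1", "f1", "f2", "f2")))
  pr3 <- alignment_precision_recall(gt3, merged)
  expect_equal(pr3$precision, 0.5)
  expect_equal(pr3$recall, 1)

  # nothing intersecting -> zero for that set
  pr4 <- alignment_precision_recall(gt2, list(cf("t1", c("A", "B"),
                                                 c("zz", "zz"))))
  expect_equal(pr4$precision, 0)
  expect_equal(pr4$recall, 0)

  expect_error(alignment_precision_recall(
    structure(list(consensus_sets = list()), class = "gw_ground_truth"),
    tool), "empty ground truth")
})

test_that("F-score reproduces benchmark two-decimal arithmetic, stays harmonic", {
  expect_equal(round(f_score(0.88, 0.91), 2), 0.89)
  expect_equal(round(f_score(0.73, 0.82), 2), 0.77)
  expect_equal(round(f_score(0.74, 0.83), 2), 0.78)
  expect_equal(f_score(1, 1), 1)
  expect_equal(f_score(0, 0), 0)
  set.seed(2)
  p <- runif(30); r <- runif(30)
  f <- f_score(p, r)
  expect_true(all(f <= pmax(p, r) + 1e-12))
  expect_true(all(f <= (p + r) / 2 + 1e-12))
})

test_that("identification recall counts repeating identifications", {
  tool <- list(cf("t1", c("A", "B"), c("f1", "g1")),
               cf("t2", c("A", "B"), c("f2", "g2")))
  ann <- list(
    PEP1 = data.frame(source_id = c("A", "B"), feature_id = c("f1", "g1")),
    PEP2 = data.frame(source_id = c("A", "B"), feature_id = c("f2", "g2")))
  expect_equal(as.numeric(identification_recall(ann, tool)), 1.0)

  # one identification split across two consensus features -> 0.5
  ann$PEP2 <- data.frame(source_id = c("A", "B"), feature_id = c("f2", "g1"))
  ir <- identification_recall(ann, tool)
  expect_equal(as.numeric(ir), 0.5)
  expect_equal(attr(ir, "n_repeating"), 2L)

  # single-chromatogram identification excluded from the denominator
  ann$PEP3 <- data.frame(source_id = "A", feature_id = "f9")
  expect_equal(attr(identification_recall(ann, tool), "n_repeating"), 2L)

  # no repeats: flagged undefined
  solo <- list(P = data.frame(source_id = "A", feature_id = "f1"))
  expect_warning(ir0 <- identification_recall(solo, tool, subset = c("A", "B")),
                 "undefined")
  expect_true(is.na(ir0))
  expect_error(identification_recall(ann, tool, subset = "A"), "at least 2")
})

test_that("swap fraction counts order inversions between runs", {
  no_drift <- data.frame(rt_a = c(10, 20, 30), rt_b = c(10, 20, 30))
  expect_equal(as.numeric(swap_fraction(no_drift)), 0)
  reversal <- data.frame(rt_a = c(10, 20, 30), rt_b = c(30, 20, 10))
  expect_equal(as.numeric(swap_fraction(reversal)), 1)
  mixed <- data.frame(rt_a = c(10, 20, 30), rt_b = c(15, 5, 35))
  expect_equal(as.numeric(swap_fraction(mixed)), 1 / 3)
  # exact ties are not swaps
  ties <- data.frame(rt_a = c(10, 20), rt_b = c(5, 5))
  expect_equal(as.numeric(swap_fraction(ties)), 0)
  expect_error(swap_fraction(no_drift[1, , drop = FALSE]), "at least 2")
})

test_that("swap resolution rate scores recovered swapped pairs", {
  pairing <- data.frame(id_a = c("f1", "f2", "f3"), id_b = c("f1", "f2", "f3"),
                        rt_a = c(10, 20, 30), rt_b = c(25, 15, 35))
  # swapped pairs: (f1,f2) only
  tool_all <- list(cf("t1", c("A", "B"), c("f1", "f1")),
                   cf("t2", c("A", "B"), c("f2", "f2")),
                   cf("t3", c("A", "B"), c("f3", "f3")))
  expect_equal(as.numeric(swap_resolution_rate(pairing, tool_all, "A", "B")), 1)
  tool_none <- list(cf("t1", c("A", "B"), c("f1", "f2")))
  expect_equal(as.numeric(swap_resolution_rate(pairing, tool_none, "A", "B")), 0)

  # two swapped pairs, exactly one fully recovered -> 0.5
  pairing2 <- data.frame(id_a = c("f1", "f2", "f3"), id_b = c("f1", "f2", "f3"),
                         rt_a = c(10, 20, 30), rt_b = c(25, 15, 5))
  sf <- swap_fraction(pairing2)
  expect_equal(attr(sf, "n_swapped"), 3L)  # all three pairs invert
  tool_partial <- list(cf("t1", c("A", "B"), c("f1", "f1")),
                       cf("t2", c("A", "B"), c("f2", "f2")))
  # resolved: (f1,f2) yes; (f1,f3) no; (f2,f3) no -> 1/3
  expect_equal(as.numeric(swap_resolution_rate(pairing2, tool_partial,
                                               "A", "B")), 1 / 3)

  no_swap <- data.frame(id_a = "f1", id_b = "f1", rt_a = c(1, 2),
                        rt_b = c(1, 2))
  expect_warning(r <- swap_resolution_rate(
    data.frame(id_a = c("a", "b"), id_b = c("a", "b"),
               rt_a = c(1, 2), rt_b = c(1, 2)), tool_all, "A", "B"),
    "no swapped pairs")
  expect_true(is.na(r))
})

test_that("splitting cannot raise recall; merging cannot raise precision", {
  set.seed(14)
  for (trial in 1:10) {
    srcs <- c("A", "B", "C", "D")
    gt <- ground_truth(lapply(1:4, function(i)
      data.frame(source_id = srcs, feature_id = paste0("f", i))))
    # random tool consensus over the same features
    pool <- expand.grid(source_id = srcs, feature_id = paste0("f", 1:4),
                        stringsAsFactors = FALSE)
    assign <- sample(1:5, nrow(pool), replace = TRUE)
    tool <- Filter(Negate(is.null), lapply(1:5, function(k) {
      mem <- pool[assign == k, , drop = FALSE]
      mem <- mem[!duplicated(mem$source_id), , drop = FALSE]
      if (!nrow(mem)) return(NULL)
      consensus_feature(paste0("t", k), mem)
    }))
    base <- alignment_precision_recall(gt, tool)
    # split the largest tool consensus in two
    sizes <- vapply(tool, function(x) nrow(x$members), integer(1))
    big <- which.max(sizes)
    if (sizes[big] >= 2) {
      mem <- tool[[big]]$members
      half <- seq_len(nrow(mem)) <= nrow(mem) / 2
      split_tool <- c(tool[-big],
                      list(consensus_feature("s1", mem[half, , drop = FALSE]),
                           consensus_feature("s2", mem[!half, , drop = FALSE])))
      expect_lte(alignment_precision_recall(gt, split_tool)$recall,
                 base$recall + 1e-12)
    }
    # merge two tool consensus (when sources allow)
    if (length(tool) >= 2) {
      mem2 <- rbind(tool[[1]]$members, tool[[2]]$members)
      if (!anyDuplicated(mem2$source_id)) {
        merged_tool <- c(tool[-(1:2)],
                         list(consensus_feature("m", mem2)))
        expect_lte(alignment_precision_recall(gt, merged_tool)$precision,
                   base$precision + 1e-12)
      }
    }
  }
})
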