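#' Pipeline configuration
#'
#' Collects every tunable of the alignment pipeline with its default.
#'
#' @param lam Trash-distance parameter of the generalized Wasserstein
#'   distance, in scaled-coordinate units. Set it so that `2 * lam` exceeds
#'   the largest drift expected between corresponding features after RT
#'   scaling; the distance saturates at `2 * lam`.
#' @param eps,tol,max_iter Sinkhorn solver controls; see [gwd_params()].
#' @param trash_cost Cost `c` of leaving a feature unmatched; default
#'   `1.9 * lam`, just under the `2 * lam` saturation, so a feature is
#'   trashed rather than matched at a cost no better than "no match".
#' @param rt_scale_k Proportionality constant of the RT scaling factor.
#' @param window Centroid-distance cutoff for the pairwise cost cache;
#'   default `2 * lam`.
#' @param overcluster K-means overclustering factor: stage-1 k is
#'   `ceil(total features / chromatograms) * overcluster`.
#' @param cluster_cut Merge threshold (scaled l1) of the agglomerative
#'   stage: k-means centers closer than this are fused into one consensus
#'   candidate. Default `lam / 4`: wide enough to absorb the centroid
#'   scatter of one analyte across runs, narrow enough not to fuse distinct
#'   analytes (a cut on the order of `lam` or above fuses neighbours and,
#'   since a cluster accepts one feature per chromatogram, silently drops
#'   features).
#' @param int_scale Costs are multiplied by this and rounded to integers for
#'   the flow solver; default `1e4`, i.e., four decimals of GWD survive.
#' @param seed Seed of the k-means stage (the only randomized step).
#' @param keep_singletons Keep consensus features with a single member.
#' @param max_support See [gwd_params()].
#' @return An object of class `gw_config`.
#' @export
run_config <- function(lam = 10, eps = lam / 100, tol = 1e-6,
                       max_iter = 5000L, trash_cost = 1.9 * lam,
                       rt_scale_k = 1, window = 2 * lam, overcluster = 2,
                       cluster_cut = lam / 4, int_scale = 1e4, seed = 42L,
                       keep_singletons = FALSE, max_support = 500L) {
  stopifnot(lam > 0, eps > 0, tol > 0, max_iter >= 1, trash_cost >= 0,
            rt_scale_k > 0, window > 0, overcluster > 0, cluster_cut > 0,
            int_scale > 0)
  structure(list(lam = lam, eps = eps, tol = tol,
                 max_iter = as.integer(max_iter), trash_cost = trash_cost,
                 rt_scale_k = rt_scale_k, window = window,
                 overcluster = overcluster, cluster_cut = cluster_cut,
                 int_scale = int_scale, seed = as.integer(seed),
                 keep_singletons = isTRUE(keep_singletons),
                 max_support = as.integer(max_support)),
            class = "gw_config")
}

# gwd_params view of a config
config_gwd_params <- function(cfg) {
  gwd_params(lam = cfg$lam, eps = cfg$eps, tol = cfg$tol,
             max_iter = cfg$max_iter, max_support = cfg$max_support)
}
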