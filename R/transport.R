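#' Parameters of the generalized Wasserstein distance
#'
#' `lam` is the trash-distance parameter: signal may be left untransported
#' at a penalty of `lam` per unit of mass on each side, so no mass ever
#' travels farther than it would cost to destroy and re-create it, and the
#' distance between fully disjoint unit measures saturates at `2 * lam`.
#' `eps` is the entropic regularization strength of the Sinkhorn solver
#' (same units as the ground distance); `tol` is the convergence tolerance
#' on the marginal change between iterations; `max_iter` caps the number of
#' scaling iterations.
#'
#' Defaults: `eps = lam / 100` keeps the regularized cost within a couple of
#' percent of the exact value on small supports while remaining stable in
#' the log domain; `tol = 1e-6`; `max_iter = 5000`.
#'
#' @param lam Trash distance, in scaled-coordinate units; must be positive.
#' @param eps Entropic regularization strength.
#' @param tol Convergence tolerance on marginal violation.
#' @param max_iter Iteration cap.
#' @param max_support Supports larger than this are reduced by
#'   intensity-weighted binning before transport (quadratic memory).
#' @return An object of class `gwd_params`.
#' @export
gwd_params <- function(lam = 10, eps = lam / 100, tol = 1e-6,
                       max_iter = 5000L, max_support = 500L) {
  stopifnot(lam > 0, eps > 0, tol > 0, max_iter >= 1)
  structure(list(lam = lam, eps = eps, tol = tol,
                 max_iter = as.integer(max_iter),
                 max_support = as.integer(max_support)),
            class = "gwd_params")
}

#' Manhattan ground distance between scaled points
#'
#' @param a,b Numeric vectors `c(rt, mz)` in the same scaled frame.
#' @return `|drt| + |dmz|`.
#' @export
ground_distance <- function(a, b) {
  sum(abs(a - b))
}

# Pairwise l1 cost matrix between the supports of two measures.
cost_matrix <- function(mu, nu) {
  abs(outer(mu$points[, 1], nu$points[, 1], "-")) +
    abs(outer(mu$points[, 2], nu$points[, 2], "-"))
}

#' Exact generalized Wasserstein distance
#'
#' Reference solver: minimizes
#' `sum(T * d) + lam * (|mu| - |T_mu|) + lam * (|nu| - |T_nu|)` over
#' nonnegative plans with `T_mu <= mu`, `T_nu <= nu` (the total-variation
#' divergence: untransported mass costs `lam` per unit on each side).
#' Solved exactly as a minimum-cost flow on the trash-augmented balanced
#' transportation network: a virtual trash point is appended to each side at
#' distance `lam` from everything and distance 0 from the other trash point.
#' Intended for modest supports; use [sinkhorn_gwd()] in bulk.
#'
#' @param mu,nu [measure()] objects.
#' @param params A [gwd_params()] object.
#' @return List with elements `cost`, `plan` (matrix of mass flows between
#'   the supports of `mu` and `nu`), `mu_marginal`, `nu_marginal`.
#' @examples
#' m1 <- measure(cbind(0, 0), 1)
#' m2 <- measure(cbind(3, 2), 1)
#' exact_gwd(m1, m2, gwd_params(lam = 10))$cost  # ground distance 5
#' @export
exact_gwd <- function(mu, nu, params = gwd_params()) {
  stopifnot(inherits(mu, "gw_measure"), inherits(nu, "gw_measure"),
            inherits(params, "gwd_params"))
  mu <- reduce_measure(mu, params$max_support)
  nu <- reduce_measure(nu, params$max_support)
  n <- nrow(mu$points); m <- nrow(nu$points)
  C <- cost_matrix(mu, nu)
  mass_mu <- sum(mu$weights); mass_nu <- sum(nu$weights)
  # nodes: 1 = source, 2..(n+1) = mu, n+2 = mu-trash, then nu, nu-trash, sink
  S <- 1L; Lo <- 1L; TL <- n + 2L; Ro <- n + 2L; TR <- n + m + 3L
  Tk <- n + m + 4L
  from <- c(rep(S, n), S,
            rep(Lo + seq_len(n), each = m), Lo + seq_len(n),
            rep(TL, m), TL,
            Ro + seq_len(m), TR)
  to <- c(Lo + seq_len(n), TL,
          rep(Ro + seq_len(m), times = n), rep(TR, n),
          Ro + seq_len(m), TR,
          rep(Tk, m), Tk)
  cap <- c(mu$weights, mass_nu,
           rep(Inf, n * m), rep(Inf, n),
           rep(Inf, m), Inf,
           nu$weights, mass_mu)
  cost <- c(rep(0, n), 0,
            as.numeric(t(C)), rep(params$lam, n),
            rep(params$lam, m), 0,
            rep(0, m), 0)
  cap[!is.finite(cap)] <- mass_mu + mass_nu  # effective infinity
  res <- .mcf_solve(from, to, cap, cost, Tk, S, Tk, mass_mu + mass_nu)
  # decode the mu x nu block of flows
  block <- res$flow[(n + 2L):(n + 1L + n * m)]
  plan <- matrix(block, nrow = n, ncol = m, byrow = TRUE)
  list(cost = res$total_cost, plan = plan,
       mu_marginal = rowSums(plan), nu_marginal = colSums(plan))
}

#' Entropically regularized generalized Wasserstein distance
#'
#' Fast approximate solver: Sinkhorn-Knopp diagonal scaling in the log
#' domain (stable for small `eps`), with the dual potentials capped at `lam`
#' -- the proximal step of the total-variation marginal penalty, which is
#' what allows mass to stay behind. Iterates until the largest change of
#' either plan marginal between successive iterations falls below
#' `params$tol` or `params$max_iter` is reached. The reported cost is the
#' transport-part objective evaluated on the resulting plan (the entropy
#' term is excluded); no further debiasing is applied.
#'
#' @inheritParams exact_gwd
#' @param return_plan If `TRUE`, include the regularized plan in the result.
#' @return List with elements `cost`, `converged`, `iterations`, and
#'   optionally `plan`. A non-converged run warns and returns the best
#'   value, flagged by `converged = FALSE`.
#' @export
sinkhorn_gwd <- function(mu, nu, params = gwd_params(), return_plan = FALSE) {
  stopifnot(inherits(mu, "gw_measure"), inherits(nu, "gw_measure"),
            inherits(params, "gwd_params"))
  mu <- reduce_measure(mu, params$max_support)
  nu <- reduce_measure(nu, params$max_support)
  C <- cost_matrix(mu, nu)
  res <- .sinkhorn_core(mu$weights, nu$weights, C, params$lam, params$eps,
                        params$tol, params$max_iter)
  if (!res$converged)
    warning(sprintf("Sinkhorn did not reach tol %.1e in %d iterations",
                    params$tol, params$max_iter))
  out <- list(cost = res$cost, converged = res$converged,
              iterations = res$iterations)
  if (return_plan) {
    out$plan <- res$plan
    out$mu_marginal <- res$mu_marginal
    out$nu_marginal <- res$nu_marginal
  }
  out
}

#' Sparse cache of pairwise feature distances
#'
#' Computes the Sinkhorn GWD only for feature pairs whose centroids lie
#' within `window` in scaled l1 distance; the default window `2 * lam` is
#' the saturation level of the distance itself, so a pair farther apart can
#' never beat the trash option and its entry is simply absent.
#'
#' @param target An [feature_set()] in scaled coordinates (the `L` side).
#' @param pool An [feature_set()] or a pooled feature list as produced by
#'   [pool_features()] (the `R` side).
#' @param params A [gwd_params()] object.
#' @param window Centroid-distance cutoff (scaled l1); default `2 * lam`.
#' @return An object of class `gw_distance_cache`: a data frame with columns
#'   `target_id`, `pool_source`, `pool_id`, `pool_index`, `cost`, with the
#'   window stored as an attribute.
#' @export
pairwise_costs <- function(target, pool, params = gwd_params(),
                           window = 2 * params$lam) {
  stopifnot(inherits(target, "ms_feature_set"))
  if (inherits(pool, "ms_feature_set")) pool <- pool_features(list(pool))
  tc <- feature_centroids(target)
  pc <- pool$centroids
  t_measures <- lapply(target$features, to_measure)
  p_measures <- lapply(pool$features, to_measure)
  rows <- vector("list", length(t_measures))
  n_nonconv <- 0L
  n_pairs <- 0L
  for (i in seq_along(t_measures)) {
    d <- abs(pc$rt - tc$rt[i]) + abs(pc$mz - tc$mz[i])
    cand <- which(d <= window)
    if (!length(cand)) next
    costs <- vapply(cand, function(j) {
      res <- suppressWarnings(
        sinkhorn_gwd(t_measures[[i]], p_measures[[j]], params))
      if (!res$converged) n_nonconv <<- n_nonconv + 1L
      res$cost
    }, numeric(1))
    n_pairs <- n_pairs + length(cand)
    rows[[i]] <- data.frame(target_id = tc$feature_id[i],
                            pool_source = pc$source_id[cand],
                            pool_id = pc$feature_id[cand],
                            pool_index = cand, cost = costs)
  }
  if (n_nonconv > 0L)
    warning(sprintf(
      "Sinkhorn reached max_iter before tol on %d of %d candidate pairs",
      n_nonconv, n_pairs))
  entries <- if (any(!vapply(rows, is.null, logical(1))))
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))]) else
      data.frame(target_id = character(0), pool_source = character(0),
                 pool_id = character(0), pool_index = integer(0),
                 cost = numeric(0))
  rownames(entries) <- NULL
  structure(entries, window = window, class = c("gw_distance_cache",
                                                "data.frame"))
}

#' Pool features of several chromatograms
#'
#' Concatenates the features of all sets (optionally excluding one, which
#' serves as the `L` side of a matching iteration), remembering each
#' feature's chromatogram of origin.
#'
#' @param sets List of [feature_set()] objects.
#' @param exclude Optional `source_id` to leave out.
#' @return List with elements `features` (list), `source_id` (character),
#'   `feature_id` (character), `centroids` (data frame).
#' @export
pool_features <- function(sets, exclude = NULL) {
  keep <- if (is.null(exclude)) sets else
    Filter(function(s) s$source_id != exclude, sets)
  feats <- unlist(lapply(keep, `[[`, "features"), recursive = FALSE,
                  use.names = FALSE)
  src <- unlist(lapply(keep, function(s)
    rep(s$source_id, length(s$features))))
  ids <- vapply(feats, `[[`, character(1), "id")
  cents <- do.call(rbind, lapply(keep, feature_centroids))
  if (is.null(cents))
    cents <- data.frame(source_id = character(0), feature_id = character(0),
                        rt = numeric(0), mz = numeric(0))
  list(features = feats, source_id = as.character(src),
       feature_id = as.character(ids), centroids = cents)
}
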