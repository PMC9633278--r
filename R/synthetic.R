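#' Parameters of the synthetic chromatogram generator
#'
#' The generator emulates what an upstream feature detector hands to the
#' aligner: isotopic-envelope-shaped features, i.e., peaks on an m/z grid
#' spaced `1/z` Da apart with a unimodal (geometrically decaying) envelope,
#' smoothed over RT with a Gaussian elution profile sampled at the scan
#' interval. Defaults describe a typical nanoflow proteomics run: a 30-min
#' usable gradient (RT 100-1900 s), precursors between 300 and 1500 Da,
#' charges 1-3, four isotopologues, 8-s elution sigma sampled every 2 s.
#' It does not emulate chemically accurate isotope abundances, peak-shape
#' tailing, co-eluting interference or detector noise.
#'
#' @param n_features Number of features to generate.
#' @param mz_window,rt_window Ranges (Da, seconds) for the monoisotopic m/z
#'   and the elution apex.
#' @param charge_range Integer charge states sampled uniformly.
#' @param n_isotopes Isotopologue count per envelope.
#' @param envelope_decay Geometric decay ratio of the envelope.
#' @param elution_sigma Gaussian elution sigma (seconds); peaks are laid
#'   out over +/- 2 sigma.
#' @param scan_interval RT sampling step (seconds).
#' @param intensity_scale Median feature intensity (arbitrary units);
#'   per-feature abundance is log-normal around it (sdlog 0.5).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return An object of class `gw_generator_params`.
#' @export
generator_params <- function(n_features = 100L, mz_window = c(300, 1500),
                             rt_window = c(100, 1900), charge_range = 1:3,
                             n_isotopes = 4L, envelope_decay = 0.7,
                             elution_sigma = 8, scan_interval = 2,
                             intensity_scale = 1e5, seed = 1L) {
  stopifnot(n_features >= 1, diff(mz_window) > 0, diff(rt_window) > 0,
            all(charge_range >= 1), n_isotopes >= 1, envelope_decay > 0,
            elution_sigma > 0, scan_interval > 0, intensity_scale > 0)
  structure(list(n_features = as.integer(n_features), mz_window = mz_window,
                 rt_window = rt_window,
                 charge_range = as.integer(charge_range),
                 n_isotopes = as.integer(n_isotopes),
                 envelope_decay = envelope_decay,
                 elution_sigma = elution_sigma,
                 scan_interval = scan_interval,
                 intensity_scale = intensity_scale, seed = as.integer(seed)),
            class = "gw_generator_params")
}

# Build one envelope-shaped feature (deterministic given its arguments).
# `envelope` overrides the geometric decay with explicit isotopologue weights.
synth_feature <- function(id, mz0, rt_center, charge, n_isotopes, decay,
                          sigma, interval, scale,
                          envelope = decay^(seq_len(n_isotopes) - 1L)) {
  stopifnot(length(envelope) == n_isotopes, all(envelope > 0))
  half <- floor(2 * sigma / interval) * interval
  rt_grid <- seq(rt_center - half, rt_center + half, by = interval)
  iso <- seq_len(n_isotopes) - 1L
  rt <- rep(rt_grid, times = n_isotopes)
  mz <- rep(mz0 + iso / charge, each = length(rt_grid))
  env <- rep(envelope, each = length(rt_grid))
  elution <- rep(exp(-(rt_grid - rt_center)^2 / (2 * sigma^2)),
                 times = n_isotopes)
  feature(id, rt = rt, mz = mz, intensity = scale * env * elution,
          charge = as.integer(charge))
}

#' Generate a synthetic chromatogram with known feature parameters
#'
#' @param p A [generator_params()] object.
#' @param source_id Chromatogram label.
#' @return List with `features` (an [feature_set()]) and `catalog` (data
#'   frame of the true per-feature parameters: `feature_id`, `rt_center`,
#'   `mz0`, `charge`, `sigma`, `scale`).
#' @export
generate_chromatogram <- function(p = generator_params(),
                                  source_id = "synthetic") {
  stopifnot(inherits(p, "gw_generator_params"))
  with_seed(p$seed, {
    mz0 <- runif(p$n_features, p$mz_window[1], p$mz_window[2])
    rtc <- runif(p$n_features, p$rt_window[1], p$rt_window[2])
    charge <- if (length(p$charge_range) == 1L)
      rep(p$charge_range, p$n_features)
    else sample(p$charge_range, p$n_features, replace = TRUE)
    scale <- p$intensity_scale * exp(rnorm(p$n_features, 0, 0.5))
    catalog <- data.frame(feature_id = sprintf("F%04d", seq_len(p$n_features)),
                          rt_center = rtc, mz0 = mz0, charge = charge,
                          sigma = p$elution_sigma, scale = scale)
    feats <- lapply(seq_len(p$n_features), function(i)
      synth_feature(catalog$feature_id[i], mz0[i], rtc[i], charge[i],
                    p$n_isotopes, p$envelope_decay, p$elution_sigma,
                    p$scan_interval, scale[i]))
    list(features = feature_set(source_id, feats), catalog = catalog)
  })
}

#' Drift simulation parameters
#'
#' @param rt_range Half-width of the uniform RT shift (seconds; default 150,
#'   i.e., shifts drawn from (-150 s, 150 s)).
#' @param mz_range Half-width of the uniform m/z shift (Da; default 0.3).
#' @param seed RNG seed.
#' @return An object of class `gw_drift_params`.
#' @export
drift_params <- function(rt_range = 150, mz_range = 0.3, seed = 1L) {
  stopifnot(rt_range >= 0, mz_range >= 0)
  structure(list(rt_range = rt_range, mz_range = mz_range,
                 seed = as.integer(seed)),
            class = "gw_drift_params")
}

#' Simulate retention-time and m/z drift
#'
#' Shifts every feature rigidly by an independent uniform draw within
#' `(-rt_range, rt_range)` seconds and `(-mz_range, mz_range)` Da. Because
#' shifts are independent per feature, nearby features can swap elution
#' order -- the regime monotone warping methods cannot resolve.
#'
#' @param fs An [feature_set()] (original run).
#' @param d A [drift_params()] object.
#' @param source_id Label of the drifted run; default appends `"_drifted"`.
#' @return List with `drifted` (an [feature_set()]) and `pairing`: the true
#'   correspondence data frame with columns `id_a`, `id_b`, `rt_a`, `rt_b`
#'   (centroid RTs before/after), `mz_a`, `mz_b`, `drt`, `dmz`.
#' @export
simulate_drift <- function(fs, d = drift_params(),
                           source_id = paste0(fs$source_id, "_drifted")) {
  stopifnot(inherits(fs, "ms_feature_set"), inherits(d, "gw_drift_params"))
  n <- length(fs$features)
  if (!n) stop("cannot drift an empty feature set")
  with_seed(d$seed, {
    drt <- runif(n, -d$rt_range, d$rt_range)
    dmz <- runif(n, -d$mz_range, d$mz_range)
    feats <- vector("list", n)
    for (i in seq_len(n)) {
      f <- fs$features[[i]]
      f$peaks$rt <- f$peaks$rt + drt[i]
      f$peaks$mz <- f$peaks$mz + dmz[i]
      feats[[i]] <- f
    }
    drifted <- feature_set(source_id, feats)
    cent_a <- feature_centroids(fs)
    cent_b <- feature_centroids(drifted)
    pairing <- data.frame(id_a = cent_a$feature_id, id_b = cent_b$feature_id,
                          rt_a = cent_a$rt, rt_b = cent_b$rt,
                          mz_a = cent_a$mz, mz_b = cent_b$mz,
                          drt = drt, dmz = dmz)
    list(drifted = drifted, pairing = pairing)
  })
}

#' A minimal elution-order-swap scenario
#'
#' Two runs of two same-m/z features whose elution order reverses between
#' runs: RT centers `t0` and `t0 + gap` in run A, `t0` and `t0 - gap` in
#' run B (shift pattern `(0, -2 gap)`). The two features carry distinct but
#' symmetric isotopic-envelope weights, so their m/z centroids coincide: a
#' point-reduction of the features is then provably ambiguous -- the
#' correct (swapped) pairing and the crossed pairing have exactly equal
#' total centroid distance. Note that a difference in elution width alone
#' would not disambiguate either: under an l1 ground distance, reshaping a
#' wider elution profile onto a narrower one is absorbed into any
#' sufficiently large RT shift (the crossed transport cost collapses to the
#' plain centroid shift). The envelope difference lives in the m/z
#' dimension, orthogonal to the drift, so the transport distance penalizes
#' the crossed pairing no matter the shift, and matching by generalized
#' Wasserstein distance recovers the true correspondence.
#'
#' @param gap RT separation in seconds (> 0).
#' @param rt_center Apex of the first feature (seconds).
#' @param mz0 Shared monoisotopic m/z (Da).
#' @param envelopes List of two distinct symmetric weight vectors (equal
#'   length), one isotopic envelope per feature.
#' @param sigma Shared elution sigma (seconds).
#' @param charge,scan_interval,intensity_scale Passed to the feature
#'   builder.
#' @return List with `a`, `b` (two [feature_set()] objects) and `pairing`
#'   (true correspondence; `swap_fraction(pairing)` is 1 by construction).
#' @export
make_swap_scenario <- function(gap = 30, rt_center = 500, mz0 = 600,
                               envelopes = list(c(1, 2, 1) / 4,
                                                c(1, 1, 1) / 3),
                               sigma = 8, charge = 1L,
                               scan_interval = 2, intensity_scale = 1e5) {
  if (gap <= 0) stop("gap must be positive")
  if (length(envelopes) != 2L ||
      length(envelopes[[1]]) != length(envelopes[[2]]) ||
      isTRUE(all.equal(envelopes[[1]] / sum(envelopes[[1]]),
                       envelopes[[2]] / sum(envelopes[[2]]))))
    stop("the two envelopes must have equal length and distinct shapes")
  n_iso <- length(envelopes[[1]])
  mk <- function(id, center, env)
    synth_feature(id, mz0, center, charge, n_iso, decay = 1,
                  sigma, scan_interval, intensity_scale, envelope = env)
  a <- feature_set("run_a", list(mk("f1", rt_center, envelopes[[1]]),
                                 mk("f2", rt_center + gap, envelopes[[2]])))
  b <- feature_set("run_b", list(mk("f1", rt_center, envelopes[[1]]),
                                 mk("f2", rt_center - gap, envelopes[[2]])))
  cent_a <- feature_centroids(a)
  cent_b <- feature_centroids(b)
  pairing <- data.frame(id_a = cent_a$feature_id, id_b = cent_b$feature_id,
                        rt_a = cent_a$rt, rt_b = cent_b$rt,
                        mz_a = cent_a$mz, mz_b = cent_b$mz)
  list(a = a, b = b, pairing = pairing)
}
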