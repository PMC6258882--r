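#' Synthetic phantom specification
#'
#' Defines a 3D multi-compartment phantom for the multi-echo decay
#' simulator. Each labeled region carries a set of relaxation compartments
#' (T2, T1, volume fraction); fractions are normalized to sum to one per
#' region. The refocusing flip angle varies smoothly across the volume
#' (B1 inhomogeneity) as
#' `angle(v) = b1_center + b1_amplitude * cos(pi*sx) * cos(pi*sy)`,
#' with `sx, sy` signed normalized in-plane coordinates in \[-1/2, 1/2\],
#' clamped to (0, 180\].
#'
#' The default is a pure white-matter block: myelin water (T2 ~15 ms, the
#' conventional short-component value) at fraction `wm_mwf`,
#' intra/extracellular water (T2 70 ms) for the rest.
#' `csf_frac > 0` converts a corner block of the volume to CSF (T2 2 s).
#'
#' @param shape Integer vector of 3 voxel dimensions.
#' @param wm_mwf True white-matter myelin water fraction (default 0.10).
#' @param myelin_t2,ie_t2,csf_t2 Compartment T2 times in seconds.
#' @param t1 Shared T1 in seconds.
#' @param csf_frac Fraction of the x extent converted to a CSF slab
#'   (0 = none).
#' @param b1_center Mean refocusing flip angle in degrees.
#' @param b1_amplitude Spatial amplitude of the flip-angle variation in
#'   degrees.
#' @param snr First-echo signal-to-noise ratio (signal / noise SD).
#' @param seed Integer seed for the noise stream.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(10L, 10L, 2L), wm_mwf = 0.10,
                         myelin_t2 = 0.015, ie_t2 = 0.070, csf_t2 = 2.0,
                         t1 = 1.0, csf_frac = 0,
                         b1_center = 165, b1_amplitude = 10,
                         snr = 200, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1),
            wm_mwf >= 0, wm_mwf <= 1, snr > 0,
            csf_frac >= 0, csf_frac <= 1,
            b1_center > 0, b1_center + abs(b1_amplitude) <= 180 + 1e-9)
  structure(list(shape = shape, wm_mwf = wm_mwf, myelin_t2 = myelin_t2,
                 ie_t2 = ie_t2, csf_t2 = csf_t2, t1 = t1,
                 csf_frac = csf_frac, b1_center = b1_center,
                 b1_amplitude = b1_amplitude, snr = snr,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Region label map: 1 = white matter, 2 = CSF slab (leading x planes).
phantom_regions <- function(spec) {
  reg <- array(1L, spec$shape)
  n_csf <- floor(spec$csf_frac * spec$shape[1])
  if (n_csf > 0) reg[seq_len(n_csf), , ] <- 2L
  reg
}

# Compartment table per region label: columns t2, t1, fraction (sum 1).
# CSF gets a physical T1 (~4 s) so its long T2 is not unphysical; the FIT
# still assumes T1 = 1 s everywhere, which is a realistic model mismatch.
phantom_compartments <- function(spec) {
  list(
    `1` = data.frame(t2 = c(spec$myelin_t2, spec$ie_t2),
                     t1 = spec$t1,
                     fraction = c(spec$wm_mwf, 1 - spec$wm_mwf)),
    `2` = data.frame(t2 = spec$csf_t2, t1 = max(spec$t1, 4.0), fraction = 1)
  )
}

# Smooth deterministic flip-angle (B1) map.
phantom_b1_map <- function(spec) {
  d <- spec$shape
  sx <- (seq_len(d[1]) - (d[1] + 1) / 2) / max(d[1], 1)
  sy <- (seq_len(d[2]) - (d[2] + 1) / 2) / max(d[2], 1)
  plane <- spec$b1_center +
    spec$b1_amplitude * outer(cos(pi * sx), cos(pi * sy))
  ang <- array(rep(plane, d[3]), d)
  pmin(pmax(ang, 1e-6), 180)
}

#' Generate a noiseless synthetic multi-echo phantom
#'
#' Renders each voxel's decay curve as the fraction-weighted sum of
#' [epg_echo_amplitudes()] over its region's compartments, at the voxel's
#' true flip angle. Deterministic (noise is added separately by
#' [add_noise()]).
#'
#' @param spec A [phantom_spec()].
#' @param train An [echo_train()].
#' @return List with `volume` (4D noiseless decay data), and `truth`: a
#'   list of `mwf` (true myelin-window fraction per voxel), `angle`
#'   (true flip-angle map), and `regions` (label map).
#' @export
generate_phantom <- function(spec, train = echo_train()) {
  stopifnot(inherits(spec, "phantom_spec"))
  regions <- phantom_regions(spec)
  comp <- phantom_compartments(spec)
  b1 <- phantom_b1_map(spec)
  shape <- spec$shape
  n_vox <- prod(shape)
  vol <- matrix(0, n_vox, train$n_echoes)
  true_mwf <- array(NA_real_, shape)

  # curves are cached on (region, angle rounded to 0.01 deg): the B1 field
  # is smooth so many voxels share an angle
  cache <- new.env(parent = emptyenv())
  window <- c(0.015, 0.040)
  for (v in seq_len(n_vox)) {
    cc <- comp[[as.character(regions[v])]]
    fr <- cc$fraction / sum(cc$fraction)
    ang <- round(b1[v], 2)
    key <- paste0(regions[v], "@", ang)
    curve <- cache[[key]]
    if (is.null(curve)) {
      basis <- epg_train_matrix(cc$t2, cc$t1[1], ang, train)
      curve <- as.numeric(basis %*% fr)
      cache[[key]] <- curve
    }
    vol[v, ] <- curve
    true_mwf[v] <- sum(fr[cc$t2 >= window[1] & cc$t2 <= window[2]])
  }
  list(volume = array(vol, c(shape, train$n_echoes)),
       truth = list(mwf = true_mwf, angle = b1, regions = regions))
}

#' Add measurement noise to a decay volume
#'
#' Adds i.i.d. zero-mean Gaussian noise with SD `ref / snr` to every echo
#' of every voxel, where `ref` defaults to the mean noiseless first-echo
#' signal over voxels with signal. `type = "rician"` instead takes the
#' magnitude of a complex Gaussian perturbation (the magnitude-image noise
#' model); at SNR >= 50 the two are practically indistinguishable.
#'
#' @param volume 4D decay array.
#' @param snr First-echo signal-to-noise ratio (> 0).
#' @param seed Integer seed.
#' @param ref Reference signal level; default mean nonzero first-echo
#'   signal.
#' @param type `"gaussian"` (default) or `"rician"`.
#' @return Noisy 4D array of the same shape.
#' @export
add_noise <- function(volume, snr, seed = 1L, ref = NULL,
                      type = c("gaussian", "rician")) {
  type <- match.arg(type)
  stopifnot(length(dim(volume)) == 4, snr > 0)
  if (is.infinite(snr)) return(volume)
  if (is.null(ref)) {
    e1 <- volume[, , , 1, drop = FALSE]
    ref <- mean(e1[e1 > 0])
    if (!is.finite(ref)) ref <- 1
  }
  sigma <- ref / snr
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n <- length(volume)
  if (type == "gaussian") {
    out <- volume + array(stats::rnorm(n, 0, sigma), dim(volume))
  } else {
    out <- sqrt((volume + array(stats::rnorm(n, 0, sigma), dim(volume)))^2 +
                  array(stats::rnorm(n, 0, sigma), dim(volume))^2)
  }
  out
}

#' Generate a paired two-site synthetic study
#'
#' Emulates the sampling structure of a two-site reproducibility study:
#' each participant draws a true white-matter MWF offset
#' `~ Normal(0, between_participant_sd)` shared across sites, and the same
#' underlying anatomy is rendered under each site's SNR and B1 settings.
#' Per-participant randomness uses seed `seed + participant index`, so
#' individual participants are reproducible in isolation.
#'
#' @param n_participants Number of participants (>= 2).
#' @param site1,site2 Named lists of [phantom_spec()] overrides per site
#'   (e.g. `list(snr = 200, b1_center = 170)`).
#' @param between_participant_sd SD of the participant-level true MWF
#'   offset, in MWF units (default 0.01).
#' @param base_mwf Population mean true MWF (default 0.10).
#' @param shape Phantom dimensions per participant.
#' @param seed Master integer seed.
#' @param train An [echo_train()].
#' @return Object of class `two_site_study`: list with `records` (one
#'   entry per participant x site holding `participant`, `site`, `volume`,
#'   `truth`, `spec`) and the study parameters.
#' @export
generate_two_site_study <- function(n_participants = 10L,
                                    site1 = list(snr = 200),
                                    site2 = list(snr = 150),
                                    between_participant_sd = 0.01,
                                    base_mwf = 0.10,
                                    shape = c(6L, 6L, 2L),
                                    seed = 1L,
                                    train = echo_train()) {
  n_participants <- as.integer(n_participants)
  stopifnot(n_participants >= 2, between_participant_sd >= 0)
  site_specs <- list(site1 = site1, site2 = site2)
  records <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (p in seq_len(n_participants)) {
    set.seed(as.integer(seed) + p)
    offset <- if (between_participant_sd > 0)
      stats::rnorm(1, 0, between_participant_sd) else 0
    mwf_p <- min(max(base_mwf + offset, 0), 1)
    for (s in names(site_specs)) {
      args <- utils::modifyList(
        list(shape = shape, wm_mwf = mwf_p, seed = seed),
        site_specs[[s]])
      spec <- do.call(phantom_spec, args)
      ph <- generate_phantom(spec, train)
      noise_seed <- as.integer(seed) + 1000L * p +
        if (s == "site1") 1L else 2L
      vol <- add_noise(ph$volume, spec$snr, seed = noise_seed)
      records[[length(records) + 1L]] <-
        list(participant = p, site = s, volume = vol, truth = ph$truth,
             spec = spec)
    }
  }
  structure(list(records = records, n_participants = n_participants,
                 between_participant_sd = between_participant_sd,
                 base_mwf = base_mwf, seed = as.integer(seed),
                 train = train),
            class = "two_site_study")
}

#' @export
print.two_site_study <- function(x, ...) {
  cat(sprintf(
    "two_site_study: %d participants x 2 sites, base MWF %.3f (sd %.3f)\n",
    x$n_participants, x$base_mwf, x$between_participant_sd))
  invisible(x)
}
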