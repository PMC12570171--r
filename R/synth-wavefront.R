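## Synthetic activation wavefronts on surface meshes with known LAT and CV
## ground truth, rendered as biphasic unipolar electrograms.
##
## The electrogram waveform is (a scaled) negative time-derivative of a
## Gaussian centred at the local activation time, so the steepest negative
## slope falls exactly at the true LAT.

#' Specification for a synthetic activation wavefront dataset
#'
#' @param mesh an [ep_mesh()]; default a flat 40 x 40 mm patch.
#' @param electrode_density electrodes per cm^2.
#' @param wave_kind `"planar"`, `"radial"`, or `"collision"` (two opposing
#'   planar waves meeting mid-domain).
#' @param speed conduction speed, m/s (= mm/ms).
#' @param direction 3-vector, propagation direction for planar waves.
#' @param focus 3-vector, origin for radial waves (default mesh centroid).
#' @param egm_fs electrogram sampling rate, Hz.
#' @param egm_width full width of the biphasic deflection, ms.
#' @param noise_sd additive white noise SD, mV.
#' @param lat_noise_sd SD of timing jitter added to each electrode's true
#'   activation when rendering its electrogram, ms (truth annotations stay
#'   noise-free).
#' @param cs_reference_time activation time on the coronary-sinus reference
#'   channel, ms (same clock as the LATs).
#' @param seed integer RNG seed.
#' @export
wavefront_synth_spec <- function(mesh = NULL, electrode_density = 10,
                                 wave_kind = c("planar", "radial", "collision"),
                                 speed = 0.5, direction = c(1, 0, 0),
                                 focus = NULL, egm_fs = 953.6, egm_width = 10,
                                 noise_sd = 0, lat_noise_sd = 0,
                                 cs_reference_time = 0, seed = 1L) {
  wave_kind <- match.arg(wave_kind)
  .assert(speed > 0, "speed must be positive")
  if (is.null(mesh)) mesh <- flat_patch_mesh(40, 40, 2)
  structure(list(mesh = mesh, electrode_density = electrode_density,
                 wave_kind = wave_kind, speed = speed,
                 direction = direction / sqrt(sum(direction^2)),
                 focus = focus, egm_fs = egm_fs, egm_width = egm_width,
                 noise_sd = noise_sd, lat_noise_sd = lat_noise_sd,
                 cs_reference_time = cs_reference_time, seed = as.integer(seed)),
            class = "wavefront_synth_spec")
}

#' Electrogram dataset container
#'
#' @param signals mV matrix, electrodes x samples.
#' @param fs sampling rate, Hz.
#' @param electrode_xyz electrode coordinates (n x 3), mm.
#' @param mesh an [ep_mesh()].
#' @param cs_signal reference-channel signal (mV) or NULL.
#' @param chamber_label `"RA"` or `"LA"`.
#' @export
egm_dataset <- function(signals, fs, electrode_xyz, mesh, cs_signal = NULL,
                        chamber_label = "RA") {
  .assert(fs > 0, "fs must be positive")
  .assert(nrow(signals) == nrow(electrode_xyz),
          "signals and electrode_xyz disagree on electrode count")
  structure(list(signals = as.matrix(signals), fs = fs,
                 electrode_xyz = as.matrix(electrode_xyz), mesh = mesh,
                 cs_signal = cs_signal, chamber_label = chamber_label),
            class = "egm_dataset")
}

## biphasic deflection: positive-then-negative, steepest downslope at `lat`
.egm_deflection <- function(t_ms, lat, width, amp = 1) {
  sig <- width / 4
  u <- -(t_ms - lat) / sig * exp(-(t_ms - lat)^2 / (2 * sig^2))
  amp * u / exp(-0.5)        # unit peak amplitude
}

## analytic LAT field (ms) at points P for a spec
.true_lat <- function(P, spec) {
  v <- spec$speed   # mm/ms
  switch(spec$wave_kind,
    planar = as.numeric(P %*% spec$direction) / v,
    radial = {
      f <- spec$focus %||% colMeans(spec$mesh$vertices)
      sqrt(colSums((t(P) - f)^2)) / v
    },
    collision = {
      x <- as.numeric(P %*% spec$direction)
      pmin(x - min(x), max(x) - x) / v
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## analytic CV vectors (m/s) at points P
.true_cv <- function(P, spec) {
  v <- spec$speed
  switch(spec$wave_kind,
    planar = matrix(spec$direction * v, nrow = nrow(P), ncol = 3, byrow = TRUE),
    radial = {
      f <- spec$focus %||% colMeans(spec$mesh$vertices)
      d <- t(t(P) - f)
      r <- sqrt(rowSums(d^2))
      r[r == 0] <- Inf
      d / r * v
    },
    collision = {
      x <- as.numeric(P %*% spec$direction)
      s <- ifelse(x - min(x) <= max(x) - x, 1, -1)
      outer(s, spec$direction) * v
    })
}

#' Generate a synthetic electrogram dataset with ground truth
#'
#' @param spec a [wavefront_synth_spec()].
#' @return list with `dataset` (an [egm_dataset()]) and `truth`: per-electrode
#'   `lat` (ms, on the reference clock), `cv_vectors` (m/s), the mesh-vertex
#'   LAT field `vertex_lat`, `cs_time`, and for collision waves the position
#'   of the collision line along the propagation axis (`collision_coord`).
#' @export
gen_wavefront <- function(spec) {
  .assert(inherits(spec, "wavefront_synth_spec"),
          "spec must be a wavefront_synth_spec")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  el <- sample_electrodes(spec$mesh, spec$electrode_density, seed = spec$seed)
  lat <- .true_lat(el, spec)
  cvv <- .true_cv(el, spec)
  vlat <- .true_lat(spec$mesh$vertices, spec)

  jitter <- if (spec$lat_noise_sd > 0)
    rnorm(length(lat), sd = spec$lat_noise_sd) else 0
  render_lat <- lat + jitter

  t_start <- 50   # ms of quiet baseline before the reference instant
  t_end <- max(render_lat, spec$cs_reference_time) + 60
  ns <- ceiling((t_start + t_end) * spec$egm_fs / 1000)
  t_ms <- (seq_len(ns) - 1) / spec$egm_fs * 1000 - t_start  # 0 = reference clock origin

  S <- t(vapply(seq_len(nrow(el)),
                function(i) .egm_deflection(t_ms, render_lat[i], spec$egm_width),
                numeric(ns)))
  if (spec$noise_sd > 0)
    S <- S + matrix(rnorm(length(S), sd = spec$noise_sd), nrow = nrow(S))
  cs <- .egm_deflection(t_ms, spec$cs_reference_time, spec$egm_width)

  x_along <- as.numeric(el %*% spec$direction)
  list(dataset = egm_dataset(S, spec$egm_fs, el, spec$mesh, cs_signal = cs),
       truth = list(lat = lat, cv_vectors = cvv, vertex_lat = vlat,
                    cs_time = spec$cs_reference_time,
                    t0_index = which.min(abs(t_ms)), time_ms = t_ms,
                    collision_coord = if (spec$wave_kind == "collision")
                      (min(x_along) + max(x_along)) / 2 else NA_real_))
}

#' Specification and generator for two-group cohort feature samples
#'
#' @param n_group_a,n_group_b group sizes.
#' @param mean_a,mean_b group means (ms).
#' @param sd_a,sd_b group SDs (ms).
#' @param seed integer RNG seed.
#' @return `gen_cohort()` returns a list with numeric vectors `a` and `b`.
#' @export
cohort_synth_spec <- function(n_group_a, n_group_b, mean_a, mean_b,
                              sd_a, sd_b, seed = 1L) {
  .assert(n_group_a >= 2 && n_group_b >= 2, "need n >= 2 per group")
  .assert(sd_a > 0 && sd_b > 0, "sd must be positive")
  structure(list(n_group_a = n_group_a, n_group_b = n_group_b,
                 mean_a = mean_a, mean_b = mean_b, sd_a = sd_a, sd_b = sd_b,
                 seed = as.integer(seed)),
            class = "cohort_synth_spec")
}

#' @rdname cohort_synth_spec
#' @param spec a `cohort_synth_spec`.
#' @export
gen_cohort <- function(spec) {
  .assert(inherits(spec, "cohort_synth_spec"),
          "spec must be a cohort_synth_spec")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  list(a = rnorm(spec$n_group_a, spec$mean_a, spec$sd_a),
       b = rnorm(spec$n_group_b, spec$mean_b, spec$sd_b))
}
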