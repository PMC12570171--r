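## Unipolar electrogram conditioning, local-activation-time detection,
## projection onto the surface mesh, outlier exclusion, RBF LAT-map
## reconstruction, and total atrial activation time.

#' Configuration for electrogram processing
#'
#' @param sg_order,sg_span Savitzky-Golay detrending order and span
#'   (samples; must be odd).
#' @param bp_order Butterworth band-pass order.
#' @param bp_low,bp_high band-pass corner frequencies, Hz.
#' @param neighborhood_radius outlier-check radius, mm.
#' @param outlier_tol LAT deviation from the neighborhood median beyond
#'   which a point is excluded, ms.
#' @param distance_gate maximum electrode-to-mesh distance, mm.
#' @param support_radius interpolation support radius, mm (NaN beyond).
#' @export
egm_config <- function(sg_order = 2, sg_span = 201, bp_order = 5,
                       bp_low = 2, bp_high = 100, neighborhood_radius = 2,
                       outlier_tol = 10, distance_gate = 5,
                       support_radius = 10) {
  .assert(sg_span %% 2 == 1, "sg_span must be odd")
  .assert(bp_low < bp_high, "bp_low must be below bp_high")
  structure(as.list(environment()), class = "egm_config")
}

#' Condition electrogram signals
#'
#' Detrending by subtraction of the Savitzky-Golay-smoothed trend (order 2,
#' span 201 samples) followed by a zero-phase fifth-order Butterworth
#' band-pass.
#'
#' @param signals mV matrix (electrodes x samples) or vector.
#' @param fs sampling rate, Hz.
#' @param cfg an [egm_config()].
#' @return conditioned signals, same shape.
#' @export
egm_condition <- function(signals, fs, cfg = egm_config()) {
  one <- is.null(dim(signals))
  X <- if (one) matrix(signals, nrow = 1) else as.matrix(signals)
  .assert(ncol(X) > cfg$sg_span,
          "signal shorter than the Savitzky-Golay span")
  .assert(cfg$bp_high < fs / 2, "bp_high must be below Nyquist")
  bp <- signal::butter(cfg$bp_order, c(cfg$bp_low, cfg$bp_high) / (fs / 2),
                       type = "pass")
  for (i in seq_len(nrow(X))) {
    trend <- signal::sgolayfilt(X[i, ], p = cfg$sg_order, n = cfg$sg_span)
    X[i, ] <- signal::filtfilt(bp, X[i, ] - trend)
  }
  if (one) X[1, ] else X
}

#' Detect the local activation time of one electrogram
#'
#' LAT = time of the maximum negative slope (central-difference derivative,
#' parabolic sub-sample refinement) minus the reference time.
#'
#' @param x conditioned electrogram (mV).
#' @param cs_time reference activation time, ms (same clock as `time_ms`).
#' @param fs sampling rate, Hz.
#' @param time_ms optional time axis, ms (default starts at 0).
#' @return list with `lat` (ms relative to the reference) and `edge_flag`
#'   (TRUE when the derivative minimum sits at the window edge; low
#'   confidence).
#' @export
detect_lat <- function(x, cs_time = 0, fs, time_ms = NULL) {
  .assert(is.finite(cs_time), "cs_time must be finite")
  n <- length(x)
  if (is.null(time_ms)) time_ms <- (seq_len(n) - 1) / fs * 1000
  d <- c(NA, (x[3:n] - x[1:(n - 2)]) / 2, NA) * fs / 1000  # mV/ms
  i <- which.min(d)
  edge <- i <= 2 || i >= n - 1
  t_act <- time_ms[i]
  if (!edge) {
    ## parabolic refinement of the derivative minimum
    y0 <- d[i - 1]; y1 <- d[i]; y2 <- d[i + 1]
    den <- y0 - 2 * y1 + y2
    if (is.finite(den) && abs(den) > 1e-12) {
      delta <- 0.5 * (y0 - y2) / den
      delta <- max(-0.5, min(0.5, delta))
      t_act <- t_act + delta * 1000 / fs
    }
  }
  list(lat = t_act - cs_time, edge_flag = edge)
}

#' Project electrode LATs onto the nearest mesh vertices
#'
#' Electrodes farther than `distance_gate` from their nearest vertex are
#' dropped; multiple LATs landing on a shared vertex are averaged.
#'
#' @param electrode_xyz electrode coordinates (n x 3), mm.
#' @param lats per-electrode LATs, ms.
#' @param mesh an [ep_mesh()].
#' @param cfg an [egm_config()].
#' @return list with `vertex_lat` (per-vertex, NA where unsampled),
#'   `vertex_count` (source electrodes per vertex), `n_dropped`.
#' @export
project_to_mesh <- function(electrode_xyz, lats, mesh, cfg = egm_config()) {
  D <- .cross_dist(as.matrix(electrode_xyz), mesh$vertices)
  nearest <- apply(D, 1, which.min)
  dmin <- D[cbind(seq_len(nrow(D)), nearest)]
  ok <- dmin <= cfg$distance_gate
  if (!any(ok)) stop("no electrode within the distance gate", call. = FALSE)
  nv <- nrow(mesh$vertices)
  sums <- counts <- numeric(nv)
  for (i in which(ok)) {
    v <- nearest[i]
    sums[v] <- sums[v] + lats[i]
    counts[v] <- counts[v] + 1
  }
  vertex_lat <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  list(vertex_lat = vertex_lat, vertex_count = counts,
       n_dropped = sum(!ok))
}

#' Neighborhood-based LAT outlier exclusion
#'
#' A populated vertex is an outlier when its LAT deviates from the median of
#' the other populated vertices within `neighborhood_radius` (Euclidean,
#' default 2 mm) by more than `outlier_tol`, provided the neighborhood has
#' at least 2 other members.  Vertices with fewer neighbors are retained and
#' flagged as isolated.
#'
#' @param vertex_lat per-vertex LATs (NA where unsampled).
#' @param mesh an [ep_mesh()].
#' @param cfg an [egm_config()].
#' @return list with logical `valid` (per vertex; NA-lat vertices FALSE) and
#'   `isolated` flags.
#' @export
exclude_lat_outliers <- function(vertex_lat, mesh, cfg = egm_config()) {
  pop <- which(!is.na(vertex_lat))
  .assert(length(pop) >= 4, "need at least 4 populated vertices")
  P <- mesh$vertices[pop, , drop = FALSE]
  D <- .cross_dist(P, P)
  valid <- rep(FALSE, length(vertex_lat))
  isolated <- rep(FALSE, length(vertex_lat))
  valid[pop] <- TRUE
  for (k in seq_along(pop)) {
    nb <- which(D[k, ] <= cfg$neighborhood_radius & seq_along(pop) != k)
    if (length(nb) >= 2) {
      if (abs(vertex_lat[pop[k]] - median(vertex_lat[pop[nb]])) >
          cfg$outlier_tol)
        valid[pop[k]] <- FALSE
    } else {
      isolated[pop[k]] <- TRUE
    }
  }
  list(valid = valid, isolated = isolated)
}

#' Reconstruct a LAT map by Gaussian RBF interpolation
#'
#' Gaussian-kernel radial basis interpolation over the valid vertices, with
#' kernel width and smoothing selected by leave-one-out cross-validation.
#' Vertices beyond `support_radius` of every datum are NaN.
#'
#' @param mesh an [ep_mesh()].
#' @param vertex_lat per-vertex LATs (NA where unsampled).
#' @param valid logical mask over vertices.
#' @param cfg an [egm_config()].
#' @return object of class `lat_map`: `vertex_lat` (interpolated, per
#'   vertex), `source_idx`, `source_lat`, `valid`, `fit` (the RBF fit).
#' @export
interpolate_lat <- function(mesh, vertex_lat, valid = !is.na(vertex_lat),
                            cfg = egm_config()) {
  src <- which(valid & !is.na(vertex_lat))
  .assert(length(src) >= 4, "need at least 4 valid points to interpolate")
  fit <- rbf_fit(mesh$vertices[src, , drop = FALSE], vertex_lat[src])
  pred <- fit$predict(mesh$vertices, support_radius = cfg$support_radius)
  structure(list(vertex_lat = pred, source_idx = src,
                 source_lat = vertex_lat[src], valid = valid, fit = fit,
                 mesh = mesh),
            class = "lat_map")
}

#' Total atrial activation time
#'
#' Time from the earliest valid right-atrial LAT to the activation detected
#' at the distal coronary-sinus electrode.
#'
#' @param ra_lats valid right-atrial LATs (ms) - a numeric vector or a
#'   `lat_map` (its source LATs are used).
#' @param cs_distal_time distal coronary-sinus activation time, ms.
#' @return TAAT in ms, with attribute `physiology_flag` = TRUE when the
#'   value is not positive.
#' @export
compute_taat <- function(ra_lats, cs_distal_time) {
  if (inherits(ra_lats, "lat_map")) ra_lats <- ra_lats$source_lat
  ra_lats <- ra_lats[is.finite(ra_lats)]
  .assert(length(ra_lats) >= 1, "empty RA LAT map")
  .assert(is.finite(cs_distal_time), "cs_distal_time must be finite")
  taat <- cs_distal_time - min(ra_lats)
  attr(taat, "physiology_flag") <- taat <= 0
  taat
}

#' Full LAT-mapping pipeline for one electrogram dataset
#'
#' Condition, detect per-electrode LATs against the reference channel,
#' project to the mesh, exclude outliers, and interpolate.
#'
#' @param ds an [egm_dataset()].
#' @param cfg an [egm_config()].
#' @param condition logical; apply [egm_condition()] first.
#' @return a `lat_map` with extra fields `electrode_lat`, `edge_flags`,
#'   `n_dropped`, `cs_time`.
#' @export
egm_lat_map <- function(ds, cfg = egm_config(), condition = TRUE) {
  S <- ds$signals
  if (condition && ncol(S) > cfg$sg_span) S <- egm_condition(S, ds$fs, cfg)
  cs_time <- 0
  if (!is.null(ds$cs_signal)) {
    cs <- if (condition && length(ds$cs_signal) > cfg$sg_span)
      egm_condition(ds$cs_signal, ds$fs, cfg) else ds$cs_signal
    cs_time <- detect_lat(cs, 0, ds$fs)$lat
  }
  det <- lapply(seq_len(nrow(S)), function(i) detect_lat(S[i, ], 0, ds$fs))
  lats <- vapply(det, `[[`, numeric(1), "lat") - cs_time
  edges <- vapply(det, `[[`, logical(1), "edge_flag")
  proj <- project_to_mesh(ds$electrode_xyz, lats, ds$mesh, cfg)
  excl <- exclude_lat_outliers(proj$vertex_lat, ds$mesh, cfg)
  lm <- interpolate_lat(ds$mesh, proj$vertex_lat, excl$valid, cfg)
  lm$electrode_lat <- lats
  lm$edge_flags <- edges
  lm$n_dropped <- proj$n_dropped
  lm$cs_time <- cs_time
  lm$isolated <- excl$isolated
  lm
}
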