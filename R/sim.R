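## Tissue model construction, pacing schedules, the AF-induction protocol,
## wave counting, and scenario comparison.

#' Build a 2-D atrial tissue model
#'
#' Rectangular monodomain sheet with fibers along x.  A fraction of nodes
#' can carry a sodium-conductance loss-of-function factor (heterogeneous
#' channelopathy), and a fraction of transverse (cross-fiber) couplings can
#' be removed to emulate fibrotic decoupling.  Both masks are drawn by a
#' seeded shuffle with exact `floor(fraction * n)` counts.
#'
#' @param width,height sheet size, mm.
#' @param spacing node spacing, mm.
#' @param d_long,d_trans longitudinal / transverse diffusivity, mm^2/ms.
#'   The default transverse value is only modestly below the longitudinal
#'   one because structural (fibrotic) decoupling, not continuous
#'   anisotropy, carries most of the transverse resistance in the scenarios
#'   this model is built for.
#' @param brs_fraction fraction of nodes with reduced g_Na.
#' @param gna_factor g_Na multiplier on flagged nodes (0.30 = 70% loss).
#' @param brs_patch_mm correlation length (mm) of the sodium-channel
#'   loss-of-function mask.  The default draws spatially patchy regions
#'   (a thresholded smoothed Gaussian random field) with exactly
#'   `floor(brs_fraction * n)` flagged nodes, emulating the mm-scale
#'   patchy substrate of heterogeneous channel dysfunction; `0` selects
#'   nodes independently at random instead.
#' @param fibrosis_fraction fraction of transverse couplings removed.
#' @param ionic an [ionic_params()] (remodeling multipliers).
#' @param seed integer seed for the masks.
#' @return list of class `tissue_model`.
#' @export
build_tissue <- function(width = 50, height = 50, spacing = 0.5,
                         d_long = 0.15, d_trans = 0.1125,
                         brs_fraction = 0, gna_factor = 0.30,
                         brs_patch_mm = 7, fibrosis_fraction = 0,
                         ionic = ionic_params(), seed = 1L) {
  .assert(brs_fraction >= 0 && brs_fraction <= 1,
          "brs_fraction must be in [0, 1]")
  .assert(fibrosis_fraction >= 0 && fibrosis_fraction <= 1,
          "fibrosis_fraction must be in [0, 1]")
  .assert(d_long > d_trans, "anisotropy ratio must exceed 1")
  nx <- round(width / spacing) + 1L
  ny <- round(height / spacing) + 1L
  n <- nx * ny
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_brs <- floor(brs_fraction * n)
  brs_mask <- rep(FALSE, n)
  if (n_brs > 0) {
    if (brs_patch_mm > 0) {
      z <- .smooth_field(nx, ny, round(brs_patch_mm / spacing / 2))
      brs_mask[order(z, decreasing = TRUE)[seq_len(n_brs)]] <- TRUE
    } else {
      brs_mask[sample.int(n, n_brs)] <- TRUE
    }
  }
  gna <- ifelse(brs_mask, gna_factor, 1.0)
  ## transverse (y-direction) edge couplings; fibrotic edges removed
  n_ye <- nx * (ny - 1L)
  fib_mask <- rep(FALSE, n_ye)
  n_fib <- floor(fibrosis_fraction * n_ye)
  if (n_fib > 0) fib_mask[sample.int(n_ye, n_fib)] <- TRUE
  wx <- rep(d_long / spacing^2, (nx - 1L) * ny)
  wy <- rep(d_trans / spacing^2, n_ye)
  wy[fib_mask] <- 0
  structure(list(nx = nx, ny = ny, spacing = spacing, n = n,
                 d_long = d_long, d_trans = d_trans,
                 wx = wx, wy = wy, gna_factor = gna,
                 brs_mask = brs_mask, fibrosis_mask = fib_mask,
                 ionic = ionic, seed = as.integer(seed)),
            class = "tissue_model")
}

## Gaussian random field on the grid, separable smoothing with half-width
## `hw` nodes; consumes the current RNG stream (call under set.seed)
.smooth_field <- function(nx, ny, hw) {
  z <- matrix(rnorm(nx * ny), nx, ny)
  if (hw >= 1) {
    k <- stats::dnorm(seq(-3, 3, length.out = 2 * hw + 1))
    k <- k / sum(k)
    z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
    z <- t(apply(t(z), 2, function(row) stats::filter(row, k, circular = TRUE)))
  }
  as.vector(z)
}

#' Node index of the grid point nearest (x, y) in mm
#' @param model a `tissue_model`.
#' @param x,y coordinates, mm.
#' @export
tissue_node_at <- function(model, x, y) {
  ix <- pmin(model$nx - 1L, pmax(0L, round(x / model$spacing)))
  iy <- pmin(model$ny - 1L, pmax(0L, round(y / model$spacing)))
  as.integer(iy * model$nx + ix + 1L)
}

## nodes of a square stimulus patch (side mm) centred on a node
.stim_patch <- function(model, center_node, side = 1.5) {
  c0 <- center_node - 1L
  cx <- c0 %% model$nx
  cy <- c0 %/% model$nx
  r <- max(0L, round(side / 2 / model$spacing))
  xs <- max(0L, cx - r):min(model$nx - 1L, cx + r)
  ys <- max(0L, cy - r):min(model$ny - 1L, cy + r)
  as.integer(outer(xs, ys * model$nx, "+") + 1L)
}

#' Initial state matrix for a tissue model (all nodes at rest)
#' @param model a `tissue_model`.
#' @param state optional 21-vector overriding [crn_initial_state()].
#' @export
tissue_initial_states <- function(model, state = crn_initial_state()) {
  matrix(as.numeric(state), nrow = 21, ncol = model$n)
}

.check_cfl <- function(model, dt) {
  dmax <- max(model$d_long, model$d_trans)
  bound <- model$spacing^2 / (4 * dmax)
  if (dt > bound)
    stop(sprintf("dt = %g ms violates the diffusion stability bound %g ms",
                 dt, bound), call. = FALSE)
}

#' Advance tissue states by explicit time stepping
#'
#' Operator splitting: Rush-Larsen gating, forward-Euler concentrations and
#' membrane voltage, explicit anisotropic diffusion with no-flux boundaries.
#'
#' @param model a [build_tissue()] model.
#' @param states 21 x n state matrix (see [tissue_initial_states()]).
#' @param dt time step, ms.
#' @param n_steps number of steps.
#' @param stim_nodes optional node indices receiving current.
#' @param stim_amp stimulus density, pA/pF (positive depolarizes).
#' @return updated 21 x n state matrix.
#' @export
step_tissue <- function(model, states, dt = 0.02, n_steps = 1L,
                        stim_nodes = integer(0), stim_amp = 0) {
  .check_cfl(model, dt)
  out <- tissue_run_cpp(states, model$ionic, model$gna_factor,
                        model$nx, model$ny, model$wx, model$wy,
                        dt, n_steps * dt,
                        as.integer(stim_nodes) - 1L,
                        if (length(stim_nodes)) 0 else numeric(0),
                        n_steps * dt, stim_amp,
                        -60, 0, FALSE)
  out$state
}

#' Run a single-cell CRN simulation
#'
#' @param duration_ms simulated time, ms.
#' @param dt time step, ms.
#' @param ionic an [ionic_params()].
#' @param gna_factor sodium-conductance multiplier.
#' @param stim_times stimulus onset times, ms.
#' @param stim_dur,stim_amp stimulus duration (ms) and density (pA/pF).
#' @param state0 initial state.
#' @param record_every_ms Vm recording cadence, ms.
#' @return list with `t`, `vm`, final `state`.
#' @export
crn_cell_run <- function(duration_ms, dt = 0.02, ionic = ionic_params(),
                         gna_factor = 1, stim_times = numeric(0),
                         stim_dur = 2, stim_amp = 20,
                         state0 = crn_initial_state(),
                         record_every_ms = 1) {
  crn_cell_cpp(as.numeric(state0), ionic, gna_factor, dt, duration_ms,
               stim_times, stim_dur, stim_amp, record_every_ms)
}

#' APD90 of the last action potential in a Vm trace
#'
#' Action-potential duration at 90% repolarization, measured from the last
#' upstroke (max dV/dt) to the crossing of rest + 10% of the AP amplitude.
#'
#' @param t,vm time (ms) and voltage (mV) vectors.
#' @return APD90 in ms (NA if no AP found).
#' @export
apd90 <- function(t, vm) {
  dv <- diff(vm) / diff(t)
  up <- which(dv > 5)           # upstroke samples
  if (!length(up)) return(NA_real_)
  i_up <- up[length(up)]
  rest <- vm[max(1, i_up - 5)]
  seg <- vm[i_up:length(vm)]
  peak <- max(seg)
  v90 <- peak - 0.9 * (peak - rest)
  below <- which(seg < v90 & seq_along(seg) > which.max(seg))
  if (!length(below)) return(NA_real_)
  i0 <- below[1]
  ## linear interpolation of the crossing
  tt <- t[i_up:length(vm)]
  frac <- (seg[i0 - 1] - v90) / (seg[i0 - 1] - seg[i0])
  (tt[i0 - 1] + frac * (tt[i0] - tt[i0 - 1])) - t[i_up]
}

#' Decreasing burst-pacing interval schedule
#'
#' Linearly decreasing coupling intervals from `start_interval` to
#' `end_interval` whose sum is within one interval of `train_duration`.
#'
#' @param train_duration train length, s.
#' @param start_interval,end_interval first and last interval, ms.
#' @return numeric vector of intervals, ms.
#' @export
make_schedule <- function(train_duration = 2.5, start_interval = 200,
                          end_interval = 120) {
  .assert(start_interval >= end_interval && end_interval > 0,
          "need start_interval >= end_interval > 0")
  total <- train_duration * 1000
  .assert(total >= start_interval,
          "train shorter than a single interval")
  if (start_interval == end_interval) {
    warning("constant pacing train (start = end)")
    return(rep(start_interval, floor(total / start_interval)))
  }
  n <- round(2 * total / (start_interval + end_interval))
  seq(start_interval, end_interval, length.out = n)
}

#' Count propagating waves in a voltage snapshot
#'
#' Number of connected components of the suprathreshold node set
#' (Vm > threshold), using 4-neighbor grid connectivity.
#'
#' @param vm voltage snapshot: an nx x ny matrix or a vector with
#'   `nx`/`ny` given.
#' @param threshold mV.
#' @param nx,ny grid dimensions when `vm` is a vector.
#' @return integer wave count.
#' @export
count_waves <- function(vm, threshold = -60, nx = nrow(vm), ny = ncol(vm)) {
  v <- as.numeric(vm)
  .assert(length(v) == nx * ny, "vm length must equal nx * ny")
  as.integer(count_waves_cpp(v, nx, ny, threshold))
}

#' Default pacing-site lattice
#'
#' Evenly spaced interior lattice of pacing locations.
#'
#' @param model a `tissue_model`.
#' @param n_sites number of sites.
#' @return integer node indices.
#' @export
pacing_sites <- function(model, n_sites = 20) {
  k <- ceiling(sqrt(n_sites))
  w <- (model$nx - 1) * model$spacing
  h <- (model$ny - 1) * model$spacing
  gx <- w * (seq_len(k) - 0.5) / k
  gy <- h * (seq_len(k) - 0.5) / k
  pts <- expand.grid(x = gx, y = gy)
  pts <- pts[seq_len(min(n_sites, nrow(pts))), ]
  tissue_node_at(model, pts$x, pts$y)
}

#' Burst-pacing AF-induction protocol over multiple sites
#'
#' Each site receives a 2.5-s train of stimuli with progressively shorter
#' coupling intervals; the simulation continues for `post_pacing_ms` after
#' the train.  Induction is successful (sustained) when suprathreshold
#' activity persists through the final 100 ms.  Wave counts are computed
#' every millisecond and averaged over the post-pacing period.
#'
#' @param model a [build_tissue()] model.
#' @param sites pacing-site node indices (default [pacing_sites()]).
#' @param schedule interval schedule, ms (default [make_schedule()]).
#' @param dt time step, ms.
#' @param post_pacing_ms simulated time after the last stimulus, ms.
#' @param stim_amp,stim_dur stimulus density (pA/pF) and duration (ms).
#' @param patch_mm stimulus patch side, mm.
#' @param early_stop stop a run early once activity has died out.
#' @param sustained_window_ms window at the end of the run that must
#'   contain activity for the run to count as sustained, ms.
#' @return list of class `sim_result`: per-site `sustained`,
#'   `mean_wave_count` (post-pacing), `wave_counts` (list),
#'   `inducibility_rate`, `mean_wave_count_sustained`,
#'   `mean_wave_count_all`.
#' @export
run_af_protocol <- function(model, sites = pacing_sites(model),
                            schedule = make_schedule(), dt = 0.02,
                            post_pacing_ms = 1000, stim_amp = 40,
                            stim_dur = 2, patch_mm = 1.5,
                            early_stop = TRUE, sustained_window_ms = 100) {
  .check_cfl(model, dt)
  stim_times <- 10 + c(0, cumsum(schedule[-length(schedule)]))
  train_end <- max(stim_times) + stim_dur
  duration <- train_end + post_pacing_ms
  .assert(duration > train_end, "simulation must extend beyond the train")
  states0 <- tissue_initial_states(model)
  res <- lapply(sites, function(site) {
    nodes <- .stim_patch(model, site, patch_mm)
    out <- tissue_run_cpp(states0, model$ionic, model$gna_factor,
                          model$nx, model$ny, model$wx, model$wy,
                          dt, duration, nodes - 1L, stim_times,
                          stim_dur, stim_amp, -60, 0, early_stop)
    wc <- out$wave_counts
    post <- wc[seq.int(ceiling(train_end) + 1L, length(wc))]
    tail_w <- tail(wc, sustained_window_ms)
    list(sustained = any(tail_w > 0), mean_wave_count = mean(post),
         wave_counts = wc, stopped_early = out$stopped_early)
  })
  sustained <- vapply(res, `[[`, logical(1), "sustained")
  mwc <- vapply(res, `[[`, numeric(1), "mean_wave_count")
  structure(list(sites = sites, sustained = sustained,
                 mean_wave_count = mwc,
                 wave_counts = lapply(res, `[[`, "wave_counts"),
                 inducibility_rate = mean(sustained),
                 mean_wave_count_sustained =
                   if (any(sustained)) mean(mwc[sustained]) else NA_real_,
                 mean_wave_count_all = mean(mwc)),
            class = "sim_result")
}

#' Compare AF-induction outcomes across scenarios
#'
#' Pairwise Welch t tests on per-site mean wave counts and Fisher exact
#' tests on induced/not-induced counts, Bonferroni-adjusted.
#'
#' @param results named list of `sim_result` objects (>= 2).
#' @return data.frame with one row per scenario pair.
#' @export
compare_scenarios <- function(results) {
  .assert(length(results) >= 2, "need at least 2 scenarios")
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("scenario", seq_along(results))
  pairs <- utils::combn(length(results), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- results[[ij[1]]]; b <- results[[ij[2]]]
    p_t <- if (sd(a$mean_wave_count) > 0 || sd(b$mean_wave_count) > 0)
      welch_t(a$mean_wave_count, b$mean_wave_count)$p else 1
    tab <- rbind(c(sum(a$sustained), sum(!a$sustained)),
                 c(sum(b$sustained), sum(!b$sustained)))
    p_f <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
           else contingency(tab, "fisher")
    data.frame(scenario_a = nm[ij[1]], scenario_b = nm[ij[2]],
               mean_waves_a = mean(a$mean_wave_count),
               mean_waves_b = mean(b$mean_wave_count),
               inducibility_a = a$inducibility_rate,
               inducibility_b = b$inducibility_rate,
               p_waves = p_t, p_inducibility = p_f)
  })
  out <- do.call(rbind, rows)
  out$p_waves_bonferroni <- bonferroni(out$p_waves)
  out$p_inducibility_bonferroni <- bonferroni(out$p_inducibility)
  out
}
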