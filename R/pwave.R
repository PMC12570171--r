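## 12-lead ECG preprocessing, epoching, R-peak detection, P-wave template
## averaging, delineation, and the 5 global + 60 per-lead features.

#' Configuration for the P-wave pipeline
#'
#' @param epoch_len epoch length, s.
#' @param corr_threshold minimum cross-correlation with the template for a
#'   beat to be retained.
#' @param window_pre_r P-window start before the R peak, ms.
#' @param window_len P-window length, ms.
#' @param lp_cutoff Chebyshev low-pass cutoff, Hz.
#' @param lp_order Chebyshev filter order.
#' @param lp_ripple Chebyshev passband ripple, dB.
#' @param notch_hz mains notch frequency (50, 60) or NA to disable.
#' @param delineation_threshold_frac onset/offset threshold as a fraction of
#'   the lead's peak amplitude above baseline.
#' @param baseline_ms initial window used for the baseline estimate, ms.
#' @param entropy_bins histogram bins for Shannon entropy.
#' @param sampen_m,sampen_r_frac sample-entropy embedding dimension and
#'   tolerance (fraction of segment SD).
#' @param peak_prominence_frac minimum peak prominence (fraction of lead
#'   peak) for the peak count.
#' @param max_lag_ms maximum alignment lag for template cross-correlation.
#' @param r_lead lead used for R-peak detection.
#' @export
pwave_config <- function(epoch_len = 15, corr_threshold = 0.9,
                         window_pre_r = 350, window_len = 300,
                         lp_cutoff = 100, lp_order = 5, lp_ripple = 0.5,
                         notch_hz = NA, delineation_threshold_frac = 0.05,
                         baseline_ms = 40, entropy_bins = 10,
                         sampen_m = 2, sampen_r_frac = 0.2,
                         peak_prominence_frac = 0.1, max_lag_ms = 50,
                         r_lead = "II") {
  .assert(corr_threshold > 0 && corr_threshold <= 1,
          "corr_threshold must be in (0, 1]")
  .assert(window_len <= window_pre_r,
          "window_len must not exceed window_pre_r")
  structure(as.list(environment()), class = "pwave_config")
}

#' Preprocess an ECG recording
#'
#' Optional mains notch (2nd-order IIR at the configured frequency) followed
#' by a fifth-order Chebyshev type-I low-pass at 100 Hz.  Both filters are
#' applied forward-backward (zero phase) so fiducial timing is unbiased.
#'
#' @param rec an [ecg_recording()].
#' @param cfg a [pwave_config()].
#' @return the filtered [ecg_recording()].
#' @export
pwave_preprocess <- function(rec, cfg = pwave_config()) {
  .assert(cfg$lp_cutoff < rec$fs / 2, "low-pass cutoff must be below Nyquist")
  X <- rec$samples
  if (!is.na(cfg$notch_hz)) {
    nt <- .design_notch(cfg$notch_hz, rec$fs)
    for (i in seq_len(nrow(X)))
      X[i, ] <- signal::filtfilt(nt, X[i, ])
  }
  ch <- signal::cheby1(cfg$lp_order, cfg$lp_ripple,
                       cfg$lp_cutoff / (rec$fs / 2), type = "low")
  for (i in seq_len(nrow(X)))
    X[i, ] <- signal::filtfilt(ch, X[i, ])
  out <- rec
  out$samples <- X
  out
}

## 2nd-order IIR notch biquad, pole radius 0.975, unity DC gain
.design_notch <- function(f0, fs, r = 0.975) {
  w <- 2 * pi * f0 / fs
  b <- c(1, -2 * cos(w), 1)
  a <- c(1, -2 * r * cos(w), r^2)
  g <- sum(a) / sum(b)   # normalize at DC (z = 1)
  signal::Arma(b = b * g, a = a)
}

#' Split a recording into consecutive 15-second epochs
#'
#' Non-overlapping; a trailing remainder shorter than one epoch is dropped.
#'
#' @param rec an [ecg_recording()].
#' @param epoch_len epoch length, s.
#' @return list of [ecg_recording()] objects.
#' @export
segment_epochs <- function(rec, epoch_len = 15) {
  n <- ncol(rec$samples)
  len <- round(epoch_len * rec$fs)
  n_ep <- n %/% len
  if (n_ep < 1)
    stop(sprintf("recording is %.1f s; at least %g s required",
                 n / rec$fs, epoch_len), call. = FALSE)
  lapply(seq_len(n_ep), function(k) {
    idx <- ((k - 1) * len + 1):(k * len)
    out <- rec
    out$samples <- rec$samples[, idx, drop = FALSE]
    out$epoch_offset_ms <- (idx[1] - 1) / rec$fs * 1000
    if (!is.null(rec$annotations)) {
      t0 <- out$epoch_offset_ms
      t1 <- t0 + length(idx) / rec$fs * 1000
      keep <- rec$annotations$r_times >= t0 & rec$annotations$r_times < t1
      out$annotations <- lapply(rec$annotations, function(a)
        if (length(a) == length(keep)) a[keep] - t0 else a)
    }
    out
  })
}

#' Detect R peaks (Pan-Tompkins-style)
#'
#' Band-pass 5-15 Hz, differentiate, square, 150-ms moving-window integrate,
#' threshold, and refine each detection to the local maximum of the absolute
#' band-passed signal.  A 200-ms refractory period is enforced.
#'
#' @param epoch an [ecg_recording()] (one epoch).
#' @param lead lead label used for detection.
#' @return numeric vector of R-peak times (ms, within the epoch), possibly
#'   empty, with attribute `diagnostic` when empty.
#' @export
detect_r_peaks <- function(epoch, lead = "II") {
  fs <- epoch$fs
  li <- match(lead, epoch$lead_names)
  if (is.na(li)) li <- 1L
  x <- epoch$samples[li, ]
  if (sd(x) < 1e-12) {
    out <- numeric(0)
    attr(out, "diagnostic") <- "flat signal"
    return(out)
  }
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  d <- c(0, diff(xf)) * fs
  sq <- d^2
  w <- round(0.150 * fs)
  integ <- stats::filter(sq, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  thr <- 0.25 * quantile(integ, 0.995)
  above <- integ > thr
  if (!any(above)) {
    out <- numeric(0)
    attr(out, "diagnostic") <- "no suprathreshold activity"
    return(out)
  }
  ## candidate = local maxima of the integrated signal above threshold
  cand <- which(above & integ >= c(-Inf, head(integ, -1)) &
                  integ > c(tail(integ, -1), Inf))
  refr <- round(0.2 * fs)
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) && (i - tail(peaks, 1)) < refr) {
      ## within refractory: keep the larger
      if (integ[i] > integ[tail(peaks, 1)])
        peaks[length(peaks)] <- i
    } else peaks <- c(peaks, i)
  }
  ## refine to the raw-signal R peak within +/- 75 ms
  hw <- round(0.075 * fs)
  r_idx <- vapply(peaks, function(i) {
    lo <- max(1L, i - hw); hi <- min(length(x), i + hw)
    lo - 1L + which.max(abs(xf[lo:hi]))
  }, numeric(1))
  r_idx <- sort(unique(r_idx))
  ## re-apply refractory after refinement
  if (length(r_idx) > 1) {
    keep <- c(TRUE, diff(r_idx) >= refr)
    r_idx <- r_idx[keep]
  }
  (r_idx - 1) / fs * 1000
}

#' Extract candidate P-wave windows
#'
#' Each window spans \[R - 350 ms, R - 50 ms\] (length 300 ms by default).
#' Beats whose window falls outside the epoch are dropped.
#'
#' @param epoch an [ecg_recording()].
#' @param r_times R-peak times, ms.
#' @param cfg a [pwave_config()].
#' @return list with `windows` (array beats x samples x leads), `r_times`
#'   of the retained beats, and `start_times` (window starts, ms).
#' @export
extract_candidate_pwaves <- function(epoch, r_times, cfg = pwave_config()) {
  fs <- epoch$fs
  wlen <- round(cfg$window_len * fs / 1000)
  starts <- r_times - cfg$window_pre_r
  dur_ms <- ncol(epoch$samples) / fs * 1000
  ok <- starts >= 0 & (starts + cfg$window_len) <= dur_ms
  starts <- starts[ok]
  r_keep <- r_times[ok]
  nl <- nrow(epoch$samples)
  W <- array(NA_real_, dim = c(length(starts), wlen, nl),
             dimnames = list(NULL, NULL, epoch$lead_names))
  for (b in seq_along(starts)) {
    i0 <- round(starts[b] * fs / 1000) + 1
    W[b, , ] <- t(epoch$samples[, i0:(i0 + wlen - 1), drop = FALSE])
  }
  list(windows = W, r_times = r_keep, start_times = starts)
}

## normalized cross-correlation at the best lag within +/- max_lag samples
.best_lag_corr <- function(x, y, max_lag) {
  n <- length(x)
  best <- c(corr = -Inf, lag = 0)
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      xs <- x[(1 + lag):n]; ys <- y[1:(n - lag)]
    } else {
      xs <- x[1:(n + lag)]; ys <- y[(1 - lag):n]
    }
    if (sd(xs) < 1e-14 || sd(ys) < 1e-14) next
    r <- cor(xs, ys)
    if (r > best["corr"]) best <- c(corr = r, lag = lag)
  }
  best
}

## all-pairs best-lag correlations for the rows of W (beats x samples).
## Returns best correlation and signed lag matrices; corr[i, j] is the
## maximum Pearson correlation between row i and row j over lags, and
## lag[i, j] the lag by which row j must be shifted to align with row i.
.pairwise_lag_corr <- function(W, max_lag) {
  nb <- nrow(W); ns <- ncol(W)
  bestC <- matrix(-Inf, nb, nb)
  bestL <- matrix(0L, nb, nb)
  std <- function(M) {
    M <- M - rowMeans(M)
    s <- sqrt(rowSums(M^2))
    s[s < 1e-12] <- Inf
    M / s
  }
  for (lag in 0:max_lag) {
    len <- ns - lag
    A <- std(W[, (1 + lag):ns, drop = FALSE])   # rows advanced by lag
    B <- std(W[, 1:len, drop = FALSE])
    C <- tcrossprod(A, B)   # C[i,j] = cor(x_i advanced, x_j)
    ## x_j shifted by +lag aligns with x_i  <=>  cor(x_i[1:len], x_j[1+lag:])
    upd <- t(C) > bestC     # cor(x_i, x_j advanced): shift j by -lag
    bestL[upd] <- -lag
    bestC[upd] <- t(C)[upd]
    upd <- C > bestC
    bestL[upd] <- lag
    bestC[upd] <- C[upd]
  }
  diag(bestC) <- 1; diag(bestL) <- 0L
  list(corr = bestC, lag = bestL)
}

#' Build a per-lead averaged P-wave template
#'
#' For each lead independently: every candidate window is scored by its mean
#' best-lag cross-correlation against all others; the best-scoring beat is
#' the template seed; beats correlating below `corr_threshold` with it are
#' discarded; survivors are aligned at their best lag and averaged.
#'
#' @param candidates output of [extract_candidate_pwaves()].
#' @param cfg a [pwave_config()].
#' @param fs sampling rate, Hz.
#' @return list of class `pwave_template`: `template` (leads x samples
#'   matrix), `n_beats_used`, `n_beats_discarded` (per lead),
#'   `template_correlations` (per lead, list), `fs`.
#' @export
build_template <- function(candidates, cfg = pwave_config(), fs = 1000) {
  W <- candidates$windows
  nb <- dim(W)[1]; ns <- dim(W)[2]; nl <- dim(W)[3]
  .assert(nb >= 2, "need at least 2 candidate beats")
  max_lag <- round(cfg$max_lag_ms * fs / 1000)
  tmpl <- matrix(NA_real_, nrow = nl, ncol = ns,
                 dimnames = list(dimnames(W)[[3]], NULL))
  used <- integer(nl); disc <- integer(nl)
  corrs <- vector("list", nl)
  for (l in seq_len(nl)) {
    w <- W[, , l, drop = TRUE]
    if (nb == 1) w <- matrix(w, nrow = 1)
    pc <- .pairwise_lag_corr(w, max_lag)
    mean_r <- (rowSums(pc$corr) - 1) / (nb - 1)
    seed <- which.max(mean_r)
    corr_to_seed <- pc$corr[seed, ]
    lag_to_seed <- pc$lag[seed, ]    # positive = delay beat to align
    keep <- corr_to_seed >= cfg$corr_threshold
    keep[seed] <- TRUE
    if (!any(keep)) next
    aligned <- matrix(NA_real_, sum(keep), ns)
    ki <- which(keep)
    for (k in seq_along(ki)) {
      i <- ki[k]
      lag <- lag_to_seed[i]
      v <- w[i, ]
      if (lag > 0) v <- c(rep(v[1], lag), v[seq_len(ns - lag)])
      if (lag < 0) v <- c(v[-seq_len(-lag)], rep(v[ns], -lag))
      aligned[k, ] <- v
    }
    tmpl[l, ] <- colMeans(aligned)
    used[l] <- sum(keep)
    disc[l] <- nb - sum(keep)
    corrs[[l]] <- unname(corr_to_seed)
  }
  if (all(is.na(tmpl)))
    stop("all beats discarded in every lead; epoch unusable", call. = FALSE)
  structure(list(template = tmpl, n_beats_used = used,
                 n_beats_discarded = disc, template_correlations = corrs,
                 fs = fs),
            class = "pwave_template")
}

#' Delineate P-wave onset, offset and peak per lead
#'
#' Baseline is the median of the first `baseline_ms` of the window; onset and
#' offset are the outermost crossings of
#' `delineation_threshold_frac * peak` around the lead's absolute peak.
#' The global onset is the earliest per-lead onset and the global offset the
#' latest per-lead offset; flat leads are excluded.
#'
#' @param tmpl a `pwave_template`.
#' @param cfg a [pwave_config()].
#' @param flat_tol absolute amplitude (mV) below which a lead is flat.
#' @return list with per-lead `onset`, `offset`, `peak_time`, `baseline`
#'   (all ms within the window / mV) and `global_onset`, `global_offset`.
#' @export
delineate <- function(tmpl, cfg = pwave_config(), flat_tol = 1e-6) {
  X <- tmpl$template
  fs <- tmpl$fs
  nl <- nrow(X); ns <- ncol(X)
  nb <- max(2L, round(cfg$baseline_ms * fs / 1000))
  onset <- offset <- pk <- rep(NA_real_, nl)
  base <- rep(NA_real_, nl)
  for (l in seq_len(nl)) {
    if (anyNA(X[l, ])) next
    b <- median(X[l, seq_len(nb)])
    x <- X[l, ] - b
    p <- max(abs(x))
    base[l] <- b
    if (p < flat_tol) next      # flat lead: excluded
    ip <- which.max(abs(x))
    ## threshold: fraction of the lead peak, floored at 3x the baseline
    ## noise so low-amplitude leads are not delineated into their noise
    thr <- max(cfg$delineation_threshold_frac * p,
               3 * sd(x[seq_len(nb)]))
    if (thr >= p) next      # wave indistinguishable from baseline noise
    ## start from the suprathreshold run containing the peak, then bridge
    ## short sub-threshold gaps (< 20 ms) to adjacent sustained (>= 5 ms)
    ## runs, so both lobes of a biphasic wave are included while noise
    ## excursions far from the wave are not
    runs <- rle(abs(x) >= thr)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    min_run <- max(2L, round(0.005 * fs))
    gap_max <- round(0.020 * fs)
    up <- which(runs$values)
    sustained <- runs$values & runs$lengths >= min_run
    k <- up[starts[up] <= ip & ends[up] >= ip]
    lo_run <- hi_run <- k
    repeat {
      nxt <- which(sustained & starts > ends[hi_run] &
                     starts <= ends[hi_run] + gap_max)
      if (!length(nxt)) break
      hi_run <- max(nxt)
    }
    repeat {
      prv <- which(sustained & ends < starts[lo_run] &
                     ends >= starts[lo_run] - gap_max)
      if (!length(prv)) break
      lo_run <- min(prv)
    }
    lo <- starts[lo_run]
    hi <- ends[hi_run]
    onset[l] <- (lo - 1) / fs * 1000
    offset[l] <- (hi - 1) / fs * 1000
    pk[l] <- (ip - 1) / fs * 1000
  }
  if (all(is.na(onset)))
    stop("template flat in every lead; cannot delineate", call. = FALSE)
  list(onset = onset, offset = offset, peak_time = pk, baseline = base,
       global_onset = min(onset, na.rm = TRUE),
       global_offset = max(offset, na.rm = TRUE))
}

#' Global P-wave features
#'
#' P-wave duration, PR interval (QRS onset proxied by the window end,
#' `window_pre_r - window_len` ms before R, unless `qrs_onset_ms` is given),
#' P-wave terminal force in V1 (signed area of the terminal negative V1
#' deflection, always <= 0), FWHM of the dominant lead, and P-wave axis
#' from the net areas of leads I and aVF.
#'
#' @param tmpl a `pwave_template`.
#' @param delin output of [delineate()].
#' @param cfg a [pwave_config()].
#' @param qrs_onset_ms optional QRS-onset time in window coordinates, ms.
#' @return named numeric vector: `p_duration`, `pr_interval`, `ptfv1`,
#'   `fwhm`, `p_axis` (NA for `ptfv1` if V1 is absent).
#' @export
pwave_global_features <- function(tmpl, delin, cfg = pwave_config(),
                                  qrs_onset_ms = NULL) {
  X <- tmpl$template
  fs <- tmpl$fs
  dt <- 1000 / fs
  p_duration <- delin$global_offset - delin$global_onset
  if (is.null(qrs_onset_ms)) qrs_onset_ms <- (ncol(X) - 1) * dt
  pr_interval <- qrs_onset_ms - delin$global_onset

  ## PTFV1
  v1 <- match("V1", rownames(X))
  ptfv1 <- NA_real_
  if (!is.na(v1) && !is.na(delin$onset[v1])) {
    i0 <- round(delin$onset[v1] / dt) + 1
    i1 <- round(delin$offset[v1] / dt) + 1
    x <- X[v1, i0:i1] - delin$baseline[v1]
    ## terminal negative deflection: walk back from the offset while negative
    if (x[length(x)] < 0 || any(x < 0)) {
      j <- length(x)
      while (j >= 1 && x[j] >= 0) j <- j - 1
      if (j >= 1) {
        i <- j
        while (i > 1 && x[i - 1] < 0) i <- i - 1
        seg <- x[i:j]
        ptfv1 <- min(0, .trapz(seq_along(seg) * dt, seg))
      } else ptfv1 <- 0
    } else ptfv1 <- 0
  }

  ## FWHM on the dominant lead (largest baseline-corrected peak)
  peaks <- vapply(seq_len(nrow(X)), function(l) {
    if (anyNA(X[l, ]) || is.na(delin$onset[l])) return(0)
    max(abs(X[l, ] - delin$baseline[l]))
  }, numeric(1))
  dl <- which.max(peaks)
  xd <- X[dl, ] - delin$baseline[dl]
  s <- sign(xd[which.max(abs(xd))])
  xd <- xd * s
  fwhm <- sum(xd > 0.5 * max(xd)) * dt

  ## axis from net areas of I and aVF over the global P window
  gi0 <- round(delin$global_onset / dt) + 1
  gi1 <- round(delin$global_offset / dt) + 1
  area_of <- function(lead) {
    li <- match(lead, rownames(X))
    if (is.na(li) || anyNA(X[li, ])) return(NA_real_)
    .trapz((gi0:gi1) * dt, X[li, gi0:gi1] - delin$baseline[li])
  }
  aI <- area_of("I"); aF <- area_of("aVF")
  p_axis <- if (is.na(aI) || is.na(aF)) NA_real_ else atan2(aF, aI) * 180 / pi

  c(p_duration = p_duration, pr_interval = pr_interval, ptfv1 = ptfv1,
    fwhm = fwhm, p_axis = p_axis)
}

#' Per-lead (local) P-wave features
#'
#' Area (trapezoidal, signed, mV.ms), number of peaks (local maxima with
#' prominence at least `peak_prominence_frac` of the lead peak), maximum
#' absolute amplitude (mV), Shannon entropy (nats, histogram of amplitudes
#' over `entropy_bins` equal-width bins), and sample entropy
#' (m = `sampen_m`, r = `sampen_r_frac` x SD).
#'
#' @param x one lead of a template (numeric, mV).
#' @param onset_ms,offset_ms delineated bounds within the window, ms.
#' @param baseline baseline level, mV.
#' @param fs sampling rate, Hz.
#' @param cfg a [pwave_config()].
#' @return named numeric vector `area`, `n_peaks`, `max_amplitude`,
#'   `entropy`, `sample_entropy` (all NA if the segment is degenerate).
#' @export
pwave_local_features <- function(x, onset_ms, offset_ms, baseline, fs,
                                 cfg = pwave_config()) {
  empty <- c(area = NA_real_, n_peaks = NA_real_, max_amplitude = NA_real_,
             entropy = NA_real_, sample_entropy = NA_real_)
  if (is.na(onset_ms) || is.na(offset_ms) || offset_ms <= onset_ms)
    return(empty)
  dt <- 1000 / fs
  i0 <- round(onset_ms / dt) + 1
  i1 <- round(offset_ms / dt) + 1
  seg <- x[i0:i1] - baseline
  area <- .trapz(seq_along(seg) * dt, seg)
  maxamp <- max(abs(seg))
  n_peaks <- .count_peaks(seg, cfg$peak_prominence_frac * maxamp)
  entropy <- shannon_entropy(seg, bins = cfg$entropy_bins)
  sampen <- sample_entropy(seg, m = cfg$sampen_m,
                           r = cfg$sampen_r_frac * sd(seg))
  c(area = area, n_peaks = n_peaks, max_amplitude = maxamp,
    entropy = entropy, sample_entropy = sampen)
}

## count local maxima with topographic prominence >= min_prom
.count_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3 || min_prom <= 0) return(0L)
  is_max <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cnt <- 0L
  for (i in is_max) {
    ## walk left until a higher point; track the lowest valley
    lv <- x[i]; j <- i
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lv <- min(lv, x[j]) }
    left_min <- if (j == 1 && x[1] <= x[i]) min(lv, x[1]) else lv
    rv <- x[i]; j <- i
    while (j < n && x[j + 1] <= x[i]) { j <- j + 1; rv <- min(rv, x[j]) }
    right_min <- if (j == n && x[n] <= x[i]) min(rv, x[n]) else rv
    prom <- x[i] - max(left_min, right_min)
    if (prom >= min_prom) cnt <- cnt + 1L
  }
  cnt
}

#' Shannon entropy of an amplitude histogram
#'
#' Equal-width bins over the segment's amplitude range; natural logarithm.
#' A constant segment (zero range) has entropy 0.  The value is invariant to
#' positive amplitude scaling.
#'
#' @param x numeric vector.
#' @param bins number of histogram bins.
#' @return entropy in nats (>= 0).
#' @export
shannon_entropy <- function(x, bins = 10) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps * max(1, abs(r[2]))) return(0)
  cuts <- seq(r[1], r[2], length.out = bins + 1)
  h <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sample entropy
#'
#' SampEn(m, r): the negative log of the conditional probability that two
#' sequences matching for m points (Chebyshev distance <= r, self-matches
#' excluded) also match for m + 1 points.
#'
#' @param x numeric vector.
#' @param m embedding dimension.
#' @param r tolerance (absolute units of `x`).
#' @return sample entropy (unitless); NaN when no template matches exist.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n <= m + 1 || r <= 0) return(NaN)
  ## templates of length m restricted to the first n - m positions so that
  ## the m and m+1 counts run over the same index set
  nb <- n - m
  emb_m <- sapply(seq_len(m), function(k) x[k:(k + nb - 1)])
  if (is.null(dim(emb_m))) emb_m <- matrix(emb_m, ncol = m)
  emb_m1 <- sapply(seq_len(m + 1), function(k) x[k:(k + nb - 1)])
  if (is.null(dim(emb_m1))) emb_m1 <- matrix(emb_m1, ncol = m + 1)
  A <- 0; B <- 0
  for (i in seq_len(nb - 1)) {
    dm <- abs(sweep(emb_m[(i + 1):nb, , drop = FALSE], 2, emb_m[i, ]))
    dm1 <- abs(sweep(emb_m1[(i + 1):nb, , drop = FALSE], 2, emb_m1[i, ]))
    B <- B + sum(apply(dm, 1, max) <= r)
    A <- A + sum(apply(dm1, 1, max) <= r)
  }
  if (B == 0 || A == 0) return(NaN)
  -log(A / B)
}

#' Extract the full 65-entry feature vector for one epoch
#'
#' Runs R-peak detection, window extraction, template averaging, delineation
#' and feature extraction on one (preprocessed) epoch.
#'
#' @param epoch an [ecg_recording()].
#' @param cfg a [pwave_config()].
#' @return named numeric vector with 5 global features followed by
#'   5 features x 12 leads (`<lead>_<feature>`), plus attributes
#'   `n_beats_used` / `n_beats_discarded`; or NULL if the epoch is unusable.
#' @export
pwave_epoch_features <- function(epoch, cfg = pwave_config()) {
  r <- detect_r_peaks(epoch, lead = cfg$r_lead)
  if (length(r) < 2) return(NULL)
  cand <- extract_candidate_pwaves(epoch, r, cfg)
  if (dim(cand$windows)[1] < 2) return(NULL)
  tmpl <- tryCatch(build_template(cand, cfg, fs = epoch$fs),
                   error = function(e) NULL)
  if (is.null(tmpl)) return(NULL)
  delin <- tryCatch(delineate(tmpl, cfg), error = function(e) NULL)
  if (is.null(delin)) return(NULL)
  glob <- pwave_global_features(tmpl, delin, cfg)
  leads <- rownames(tmpl$template)
  loc <- lapply(seq_along(leads), function(l)
    pwave_local_features(tmpl$template[l, ], delin$onset[l], delin$offset[l],
                         delin$baseline[l], tmpl$fs, cfg))
  loc <- unlist(loc)
  names(loc) <- as.vector(outer(c("area", "n_peaks", "max_amplitude",
                                  "entropy", "sample_entropy"),
                                leads, function(f, l) paste(l, f, sep = "_")))
  out <- c(glob, loc)
  attr(out, "n_beats_used") <- tmpl$n_beats_used
  attr(out, "n_beats_discarded") <- tmpl$n_beats_discarded
  out
}

#' Average per-epoch feature vectors into patient-level features
#'
#' Arithmetic mean per feature, skipping NAs; the number of contributing
#' epochs per feature is reported as attribute `n`.
#'
#' @param feature_list list of named feature vectors (NULL entries allowed).
#' @return named numeric vector with attribute `n`.
#' @export
average_over_epochs <- function(feature_list) {
  feature_list <- Filter(Negate(is.null), feature_list)
  .assert(length(feature_list) >= 1, "no valid epochs to average")
  M <- do.call(rbind, lapply(feature_list, as.numeric))
  colnames(M) <- names(feature_list[[1]])
  out <- colMeans(M, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  attr(out, "n") <- colSums(!is.na(M))
  out
}

#' End-to-end P-wave feature extraction for one recording
#'
#' Preprocess, epoch, extract per-epoch features, and average to the patient
#' level.
#'
#' @param rec an [ecg_recording()].
#' @param cfg a [pwave_config()].
#' @return list with `patient` (65-entry named vector), `epochs` (list of
#'   per-epoch vectors) and `n_epochs_valid`.
#' @export
pwave_features <- function(rec, cfg = pwave_config()) {
  filt <- pwave_preprocess(rec, cfg)
  eps <- segment_epochs(filt, cfg$epoch_len)
  per <- lapply(eps, pwave_epoch_features, cfg = cfg)
  valid <- Filter(Negate(is.null), per)
  .assert(length(valid) >= 1, "no usable epochs in recording")
  list(patient = average_over_epochs(per), epochs = per,
       n_epochs_valid = length(valid))
}
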