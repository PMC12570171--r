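mk_rec <- function(x, fs = 1000, leads = "II") {
  ecg_recording(matrix(x, nrow = length(leads), byrow = TRUE), fs, leads)
}

test_that("preprocessing suppresses mains and preserves the passband", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  cfg <- pwave_config(notch_hz = 50)
  ## pure 50 Hz in -> nearly nothing out
  s50 <- sin(2 * pi * 50 * t)
  out <- pwave_preprocess(mk_rec(s50), cfg)
  mid <- seq(fs, 3 * fs)          # avoid filter edge transients
  expect_lt(sqrt(mean(out$samples[1, mid]^2)) / sqrt(mean(s50[mid]^2)), 0.03)
  ## 10 Hz preserved within 1 dB
  s10 <- sin(2 * pi * 10 * t)
  out10 <- pwave_preprocess(mk_rec(s10), cfg)
  gain <- sqrt(mean(out10$samples[1, mid]^2) / mean(s10[mid]^2))
  expect_gt(20 * log10(gain), -1)
  expect_lt(20 * log10(gain), 1)
  ## linearity: zeros in, zeros out
  out0 <- pwave_preprocess(mk_rec(rep(0, 2000)), cfg)
  expect_true(all(out0$samples == 0))
  ## cutoff above Nyquist rejected
  rec150 <- suppressWarnings(mk_rec(s10, fs = 150))
  expect_error(pwave_preprocess(rec150, pwave_config()), "Nyquist")
})

test_that("zero-phase filtering does not shift fiducial timing", {
  fs <- 1000
  t <- seq_len(3000)
  x <- exp(-((t - 1500) / 20)^2)    # symmetric bump at sample 1500
  out <- pwave_preprocess(mk_rec(x), pwave_config())
  expect_equal(which.max(out$samples[1, ]), 1500, tolerance = 1)
})

test_that("epoch segmentation drops trailing remainders", {
  rec <- mk_rec(rep(0, 30 * 1000))
  expect_length(segment_epochs(rec), 2)
  rec44 <- mk_rec(rep(0, 44 * 1000))
  expect_length(segment_epochs(rec44), 2)
  rec300 <- mk_rec(rep(0, 300 * 1000))
  expect_length(segment_epochs(rec300), 20)
  expect_error(segment_epochs(mk_rec(rep(0, 10 * 1000))), "15")
})

test_that("R-peak detection matches annotations and honors refractoriness", {
  spec <- ecg_synth_spec(duration = 15, noise_sd = 0, seed = 5)
  ep <- segment_epochs(gen_ecg(spec), 15)[[1]]
  r <- detect_r_peaks(ep)
  expect_length(r, length(ep$annotations$r_times))
  expect_lt(max(abs(r - ep$annotations$r_times)), 10)
  expect_true(all(diff(r) >= 200))
  ## same with mains interference
  specn <- ecg_synth_spec(duration = 15, noise_sd = 0, powerline_hz = 50,
                          powerline_amp = 0.25, seed = 5)
  epn <- segment_epochs(pwave_preprocess(gen_ecg(specn),
                                         pwave_config(notch_hz = 50)), 15)[[1]]
  expect_length(detect_r_peaks(epn), length(r))
  ## flat line -> empty with diagnostic
  r0 <- detect_r_peaks(mk_rec(rep(0, 15000)))
  expect_length(r0, 0)
  expect_match(attr(r0, "diagnostic"), "flat")
})

test_that("candidate windows span [R-350, R-50] and drop boundary beats", {
  rec <- mk_rec(seq_len(2000) / 1000)   # ramp; values encode time
  cand <- extract_candidate_pwaves(rec, c(200, 400, 1200), pwave_config())
  ## beat at 200 dropped (window would start at -150 ms)
  expect_equal(cand$r_times, c(400, 1200))
  expect_equal(cand$start_times, c(50, 850))
  expect_equal(dim(cand$windows)[2], 300)
  ## window content: samples 51..350 of the ramp for the first retained beat
  expect_equal(cand$windows[1, , 1], rec$samples[1, 51:350])
})

test_that("template building keeps consistent beats and rejects outliers", {
  base <- exp(-((1:300 - 150) / 25)^2)
  W <- array(rep(base, 10), dim = c(300, 10, 1))
  W <- aperm(W, c(2, 1, 3))
  dimnames(W) <- list(NULL, NULL, "II")
  tm <- build_template(list(windows = W), pwave_config(), fs = 1000)
  expect_equal(tm$template[1, ], base, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tm$n_beats_used[1], 10)
  expect_equal(tm$n_beats_discarded[1], 0)
  ## one inverted beat is discarded
  W2 <- W
  W2[10, , 1] <- -base
  tm2 <- build_template(list(windows = W2), pwave_config(), fs = 1000)
  expect_equal(tm2$n_beats_discarded[1], 1)
  expect_equal(tm2$template[1, ], base, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(build_template(list(windows = W[1, , , drop = FALSE])),
               "at least 2")
})

test_that("template averaging reduces noise roughly as 1/sqrt(N)", {
  base <- 0.2 * exp(-((1:300 - 150) / 25)^2)
  n_beats <- 20
  sigma <- 0.01
  ratios <- vapply(1:40, function(seed) {
    set.seed(seed)
    W <- array(NA_real_, dim = c(n_beats, 300, 1),
               dimnames = list(NULL, NULL, "II"))
    for (b in seq_len(n_beats)) W[b, , 1] <- base + rnorm(300, sd = sigma)
    tm <- build_template(list(windows = W), pwave_config(corr_threshold = 0.5),
                         fs = 1000)
    sd(tm$template[1, ] - base) / (sigma / sqrt(n_beats))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.3)
})

test_that("delineation recovers the generated P-wave support", {
  spec <- ecg_synth_spec(duration = 15, noise_sd = 0, p_duration = 120,
                         seed = 6)
  ep <- segment_epochs(gen_ecg(spec), 15)[[1]]
  r <- detect_r_peaks(ep)
  tm <- build_template(extract_candidate_pwaves(ep, r, pwave_config()),
                       pwave_config(), fs = 1000)
  delin <- delineate(tm, pwave_config())
  dur <- delin$global_offset - delin$global_onset
  expect_lt(abs(dur - 120) / 120, 0.10)
  ## identical waveforms on all leads -> global equals per-lead
  X <- tm$template
  X[] <- rep(X[2, ], each = nrow(X))
  tm2 <- tm; tm2$template <- X
  d2 <- delineate(tm2, pwave_config())
  expect_equal(d2$global_onset, d2$onset[1])
  expect_equal(d2$global_offset, d2$offset[1])
  ## a flat lead is excluded from the global extremes
  X3 <- tm$template
  X3[3, ] <- 0.5
  tm3 <- tm; tm3$template <- X3
  d3 <- delineate(tm3, pwave_config())
  expect_true(is.na(d3$onset[3]))
  expect_error(delineate(list(template = matrix(0, 2, 300), fs = 1000),
                         pwave_config()), "flat")
})

test_that("global features follow their analytic definitions", {
  fs <- 1000
  n <- 300
  mk_tmpl <- function(rows) {
    X <- do.call(rbind, rows)
    rownames(X) <- names(rows)
    list(template = X, fs = fs)
  }
  ## triangular P of base 160 ms, peak 1 -> FWHM = 80 ms
  tri <- rep(0, n)
  tri[101:260] <- c(seq(0, 1, length.out = 80), seq(1, 0, length.out = 80))
  tm <- mk_tmpl(list(II = tri))
  delin <- delineate(tm, pwave_config())
  g <- pwave_global_features(tm, delin, pwave_config())
  expect_equal(unname(g["fwhm"]), 80, tolerance = 4)
  ## monophasic positive V1 -> terminal force zero
  gaus <- 0.3 * exp(-((1:n - 180) / 20)^2)
  tmv <- mk_tmpl(list(V1 = gaus, II = gaus))
  dv <- delineate(tmv, pwave_config())
  gv <- pwave_global_features(tmv, dv, pwave_config())
  expect_equal(unname(gv["ptfv1"]), 0)
  ## biphasic V1 -> strictly negative terminal force
  bif <- 0.2 * exp(-((1:n - 150) / 15)^2) - 0.15 * exp(-((1:n - 200) / 15)^2)
  tmb <- mk_tmpl(list(V1 = bif, II = gaus))
  db <- delineate(tmb, pwave_config())
  gb <- pwave_global_features(tmb, db, pwave_config())
  expect_lt(unname(gb["ptfv1"]), 0)
  ## equal positive net areas in I and aVF -> axis 45 degrees
  tma <- mk_tmpl(list(I = gaus, aVF = gaus))
  da <- delineate(tma, pwave_config())
  ga <- pwave_global_features(tma, da, pwave_config())
  expect_equal(unname(ga["p_axis"]), 45, tolerance = 1e-6)
  ## missing V1 -> terminal force absent, not zero
  gm <- pwave_global_features(tma, da, pwave_config())
  expect_true(is.na(gm["ptfv1"]))
})

test_that("local features match their definitions on constructed segments", {
  cfg <- pwave_config()
  ## constant nonzero segment: entropy 0, no peaks
  f <- pwave_local_features(rep(0.5, 300), 50, 250, 0, 1000, cfg)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["n_peaks"]), 0)
  ## unit-amplitude Gaussian: one peak, max amplitude 1
  g <- exp(-((1:300 - 150) / 30)^2)
  fg <- pwave_local_features(g, 10, 290, 0, 1000, cfg)
  expect_equal(unname(fg["n_peaks"]), 1)
  expect_equal(unname(fg["max_amplitude"]), 1, tolerance = 1e-9)
  ## degenerate segment flagged
  fd <- pwave_local_features(g, 100, 100, 0, 1000, cfg)
  expect_true(all(is.na(fd)))
})

test_that("sample entropy matches a brute-force pairwise-count oracle", {
  brute_sampen <- function(x, m, r) {
    n <- length(x)
    nb <- n - m
    A <- 0; B <- 0
    for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
    -log(A / B)
  }
  set.seed(42)
  x <- rnorm(300)
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(x, 2, r), brute_sampen(x, 2, r),
               tolerance = 1e-12)
  set.seed(7)
  y <- cumsum(rnorm(200))
  expect_equal(sample_entropy(y, 2, 0.2 * sd(y)),
               brute_sampen(y, 2, 0.2 * sd(y)), tolerance = 1e-12)
})

test_that("entropy is invariant to positive amplitude scaling", {
  set.seed(3)
  x <- rnorm(250)
  for (a in c(0.01, 1, 250)) {
    expect_equal(shannon_entropy(a * x), shannon_entropy(x),
                 tolerance = 1e-12)
  }
})

test_that("epoch averaging skips failures and reports counts", {
  f1 <- c(p_duration = 120, pr_interval = 160)
  f2 <- c(p_duration = 130, pr_interval = NA)
  out <- average_over_epochs(list(f1, f2, NULL))
  expect_equal(unname(out["p_duration"]), 125)
  expect_equal(unname(out["pr_interval"]), 160)
  expect_equal(unname(attr(out, "n")), c(2, 1))
  expect_equal(unname(average_over_epochs(list(f1))["p_duration"]), 120)
  expect_error(average_over_epochs(list(NULL)), "no valid")
})

test_that("a processed epoch yields exactly 65 features", {
  spec <- ecg_synth_spec(duration = 15, noise_sd = 0.01, seed = 11)
  rec <- pwave_preprocess(gen_ecg(spec), pwave_config())
  ep <- segment_epochs(rec, 15)[[1]]
  f <- pwave_epoch_features(ep, pwave_config())
  expect_length(f, 65)
  expect_false(anyNA(f))
})
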