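test_that("conditioning removes drift without moving the deflection", {
  fs <- 953.6
  n <- 1200
  t <- (seq_len(n) - 1) / fs * 1000
  defl <- .egm_deflection <- atrialep:::.egm_deflection(t, 600, 10)
  drift <- 0.5 * ((t - 600) / 600)^2 + 0.3 * (t / 1000)
  x <- defl + drift
  y <- egm_condition(x, fs)
  ## drift RMS reduced by >= 90%
  yd <- egm_condition(drift, fs)
  expect_lt(sqrt(mean(yd^2)) / sqrt(mean(drift^2)), 0.1)
  ## steepest-slope time preserved within one sample
  l0 <- detect_lat(defl, 0, fs)$lat
  l1 <- detect_lat(y, 0, fs)$lat
  expect_lt(abs(l1 - l0), 1000 / fs)
  ## zeros in, zeros out
  expect_true(all(egm_condition(rep(0, n), fs) == 0))
  ## in-band 30 Hz tone preserved within 1 dB
  tone <- sin(2 * pi * 30 * t / 1000)
  yt <- egm_condition(tone, fs)
  mid <- seq(round(n / 4), round(3 * n / 4))
  gain <- sqrt(mean(yt[mid]^2) / mean(tone[mid]^2))
  expect_lt(abs(20 * log10(gain)), 1)
  expect_error(egm_condition(rep(0, 100), fs), "span")
})

test_that("LAT detection finds the maximum negative slope", {
  fs <- 953.6
  t <- (0:499) / fs * 1000
  x <- atrialep:::.egm_deflection(t, 100, 10)
  d <- detect_lat(x, cs_time = 0, fs = fs)
  expect_lt(abs(d$lat - 100), 0.5)
  expect_false(d$edge_flag)
  ## reference shift is exact
  d2 <- detect_lat(x, cs_time = 40, fs = fs)
  expect_equal(d2$lat, d$lat - 40)
  ## monotone ramp -> edge flag
  dr <- detect_lat(-seq_len(500) * 0.25, cs_time = 0, fs = fs)
  expect_true(dr$edge_flag)
})

test_that("projection assigns nearest vertices, averages shares, drops far points", {
  mesh <- flat_patch_mesh(10, 10, 5)   # 3 x 3 vertices
  el <- rbind(c(0.2, 0.1, 0),     # near vertex (0,0)
              c(-0.2, 0.2, 0),    # also nearest to (0,0)
              c(5, 5, 0),         # exactly on the center vertex
              c(10, 10, 9))       # 9 mm off the surface
  pr <- project_to_mesh(el, c(10, 20, 7, 99), mesh, egm_config())
  v00 <- which(mesh$vertices[, 1] == 0 & mesh$vertices[, 2] == 0)
  vc <- which(mesh$vertices[, 1] == 5 & mesh$vertices[, 2] == 5)
  expect_equal(pr$vertex_lat[v00], 15)       # mean of 10 and 20
  expect_equal(pr$vertex_lat[vc], 7)
  expect_equal(pr$n_dropped, 1)
  ## conservation: assigned source counts + dropped = electrodes
  expect_equal(sum(pr$vertex_count) + pr$n_dropped, nrow(el))
})

test_that("neighborhood outlier exclusion flags exactly the perturbed vertex", {
  mesh <- flat_patch_mesh(20, 20, 1)
  lat <- mesh$vertices[, 1] / 0.5          # planar wave, 0.5 m/s
  bad <- 150
  lat2 <- lat
  lat2[bad] <- lat2[bad] + 50
  ex <- exclude_lat_outliers(lat2, mesh, egm_config())
  expect_false(ex$valid[bad])
  expect_true(all(ex$valid[-bad]))
  ## noise-free planar wave: nothing excluded
  ex0 <- exclude_lat_outliers(lat, mesh, egm_config())
  expect_true(all(ex0$valid))
  ## sparse map: all isolated, none excluded
  sparse <- rep(NA_real_, nrow(mesh$vertices))
  idx <- seq(1, nrow(mesh$vertices), by = 70)
  sparse[idx] <- lat[idx]
  exs <- exclude_lat_outliers(sparse, mesh, egm_config())
  expect_true(all(exs$valid[idx]))
  expect_true(all(exs$isolated[idx]))
})

test_that("RBF LAT interpolation reproduces a planar field", {
  mesh <- flat_patch_mesh(40, 40, 2)
  nv <- nrow(mesh$vertices)
  lat <- rep(NA_real_, nv)
  set.seed(9)
  src <- sample.int(nv, 100)
  lat[src] <- mesh$vertices[src, 1] / 0.5
  lm <- interpolate_lat(mesh, lat, cfg = egm_config())
  truth <- mesh$vertices[, 1] / 0.5
  ok <- !is.na(lm$vertex_lat)
  expect_gt(mean(ok), 0.9)
  expect_lt(sqrt(mean((lm$vertex_lat[ok] - truth[ok])^2)), 1)
  ## interpolation honors the measured values at retained sources
  expect_lt(max(abs(lm$vertex_lat[src] - lat[src])), 1)
  ## duplicates with equal values collapse to the deduplicated solution
  X <- mesh$vertices[src, ]
  f1 <- rbf_fit(X, lat[src])
  f2 <- rbf_fit(rbind(X, X[1:5, ]), c(lat[src], lat[src][1:5]))
  expect_equal(f1$predict(mesh$vertices[1:20, ]),
               f2$predict(mesh$vertices[1:20, ]), tolerance = 1e-6)
  ## too few points rejected
  expect_error(rbf_fit(X[1:3, ], lat[src][1:3]), "at least 4")
})

test_that("TAAT arithmetic, flags, and linear scaling", {
  expect_equal(as.numeric(compute_taat(c(0, 30, 60), 120)), 120)
  expect_equal(as.numeric(compute_taat(c(-20, 10), 100)), 120)
  t3 <- compute_taat(c(50, 80), 40)
  expect_true(attr(t3, "physiology_flag"))
  expect_error(compute_taat(numeric(0), 100), "empty")
  ## uniform slowing by k scales TAAT by k exactly
  lats <- c(5, 12, 40, 63)
  base <- as.numeric(compute_taat(lats, 90))
  for (k in c(0.6, 1.3)) {
    expect_equal(as.numeric(compute_taat(lats * k, 90 * k)), k * base)
  }
})

test_that("end-to-end LAT maps recover synthetic wavefronts", {
  g <- gen_wavefront(wavefront_synth_spec(speed = 0.5, electrode_density = 8,
                                          noise_sd = 0, seed = 10))
  lm <- egm_lat_map(g$dataset, condition = FALSE)
  err <- lm$electrode_lat - (g$truth$lat - g$truth$cs_time)
  ## truth clock starts 50 ms into the recording; remove the common offset
  err <- err - median(err)
  expect_lt(max(abs(err)), 1000 / g$dataset$fs)
  ## with additive noise the median error stays small
  gn <- gen_wavefront(wavefront_synth_spec(speed = 0.5, electrode_density = 8,
                                           noise_sd = 0.05, seed = 10))
  lmn <- egm_lat_map(gn$dataset, condition = TRUE)
  errn <- lmn$electrode_lat - (gn$truth$lat - gn$truth$cs_time)
  errn <- errn - median(errn)
  expect_lt(median(abs(errn)), 2)
})
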