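test_that("local surface fits recover analytic gradients", {
  set.seed(1)
  nb <- cbind(runif(30, -4, 4), runif(30, -4, 4), 0)
  ## planar LAT with gradient 2 ms/mm along x (0.5 m/s wave)
  lat <- 2 * nb[, 1]
  fit <- fit_local_surface(c(0, 0, 0), nb, lat, cv_config())
  g3 <- fit$gradient[1] * fit$basis$e1 + fit$gradient[2] * fit$basis$e2
  expect_equal(g3, c(2, 0, 0), tolerance = 1e-9)
  ## exact quadratic field is reproduced to numerical precision
  latq <- 1.5 * nb[, 1] - 0.7 * nb[, 2] + 0.2 * nb[, 1]^2 -
    0.1 * nb[, 1] * nb[, 2] + 0.05 * nb[, 2]^2
  fq <- fit_local_surface(c(0, 0, 0), nb, latq, cv_config())
  gq <- fq$gradient[1] * fq$basis$e1 + fq$gradient[2] * fq$basis$e2
  expect_equal(gq, c(1.5, -0.7, 0), tolerance = 1e-9)
  ## constant LATs -> zero gradient -> undefined CV downstream
  fc <- fit_local_surface(c(0, 0, 0), nb, rep(5, 30), cv_config())
  expect_false(cv_from_gradient(fc$gradient, fc$basis)$ok)
})

test_that("CV is the inverse gradient with the right scaling law", {
  cv <- cv_from_gradient(c(2, 0))
  expect_equal(cv$cv, c(0.5, 0, 0), tolerance = 1e-12)
  expect_equal(cv$speed, 0.5)
  cv2 <- cv_from_gradient(c(4, 0))
  expect_equal(cv2$speed, cv$speed / 2)
  expect_false(cv_from_gradient(c(1e-8, 0))$ok)
})

test_that("divergence separates planar, focal, and colliding patterns", {
  cfg <- cv_config()
  set.seed(2)
  P <- cbind(runif(200, 0, 40), runif(200, 0, 40), 0)
  ## uniform planar field: |div| small
  V <- matrix(rep(c(0.5, 0, 0), each = 200), ncol = 3)
  divp <- cv_divergence(P, V, cfg)
  expect_lt(max(abs(divp), na.rm = TRUE), 0.05)
  expect_false(any(exclude_collisions(divp, cfg)))
  ## radial spread at speed s from a focus: div ~ s / r
  f <- c(20, 20, 0)
  d <- sweep(P[, 1:2], 2, f[1:2])
  r <- sqrt(rowSums(d^2))
  keep <- r > 5
  Vr <- cbind(0.5 * d / r, 0)
  divr <- cv_divergence(P[keep, ], Vr[keep, ], cfg)
  pred <- 1000 * 0.5 / r[keep]
  ok <- is.finite(divr)
  expect_lt(median(abs(divr[ok] - pred[ok]) / pred[ok]), 0.25)
  expect_true(all(divr[ok] > 0))
})

test_that("collision masking uses a strict -1.5/s threshold", {
  cfg <- cv_config()
  div <- c(-2.0, -1.5, 3.0, NaN)
  mask <- exclude_collisions(div, cfg)
  expect_identical(mask, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("end-to-end planar CV recovery is accurate and collision-specific", {
  g <- gen_wavefront(wavefront_synth_spec(speed = 0.5, electrode_density = 10,
                                          seed = 20))
  f <- cv_field(g$dataset$electrode_xyz, g$truth$lat, cv_config())
  expect_lt(abs(median(f$cv_magnitude, na.rm = TRUE) - 0.5) / 0.5, 0.02)
  expect_lt(mean(f$collision_mask), 0.01)
  ## colliding waves produce a masked band at the collision line
  gc <- gen_wavefront(wavefront_synth_spec(wave_kind = "collision",
                                           speed = 0.5,
                                           electrode_density = 10, seed = 21))
  fc <- cv_field(gc$dataset$electrode_xyz, gc$truth$lat, cv_config())
  expect_lt(min(fc$divergence, na.rm = TRUE), -1.5)
  masked_x <- gc$dataset$electrode_xyz[fc$collision_mask, 1]
  expect_gt(length(masked_x), 0)
  ## the mask covers the collision line and stays near it
  expect_lt(min(abs(masked_x - gc$truth$collision_coord)), 2)
  expect_lt(max(abs(masked_x - gc$truth$collision_coord)), 10)
})

test_that("CV errors grow monotonically with LAT noise", {
  err_at <- function(noise) {
    g <- gen_wavefront(wavefront_synth_spec(speed = 0.5,
                                            electrode_density = 10,
                                            seed = 30))
    set.seed(30)
    lat <- g$truth$lat + rnorm(length(g$truth$lat), sd = noise)
    f <- cv_field(g$dataset$electrode_xyz, lat, cv_config())
    abs(median(f$cv_magnitude, na.rm = TRUE) - 0.5)
  }
  errs <- vapply(c(0, 1, 2, 4), err_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("CV magnitude interpolation and summaries behave", {
  g <- gen_wavefront(wavefront_synth_spec(speed = 0.5, electrode_density = 10,
                                          seed = 22))
  f <- cv_field(g$dataset$electrode_xyz, g$truth$lat, cv_config())
  vmap <- interpolate_cv(g$dataset$mesh, f, egm_config())
  ok <- !is.na(vmap)
  expect_gt(mean(ok), 0.5)
  expect_lt(max(abs(vmap[ok] - 0.5)), 0.01)
  s <- cv_summary(f, cv_config())
  expect_equal(s$median, 0.5, tolerance = 0.01)
  ## plain-vector summaries with the physiological gate
  s2 <- cv_summary(c(0.3, 0.4, 0.5, 5), cv_config())
  expect_equal(s2$median, 0.4)
  expect_equal(s2$n_gated, 1)
  expect_equal(sum(s2$histogram), 3)
  expect_error(cv_summary(numeric(0), cv_config()), "no CV")
})

test_that("a too-small neighborhood or rank-deficient design is flagged", {
  cfg <- cv_config()
  ## collinear electrodes cannot support a quadratic surface
  nb <- cbind(seq(-4, 4, length.out = 12), 0, 0)
  fit <- fit_local_surface(c(0, 0, 0), nb, nb[, 1] * 2, cfg)
  expect_false(fit$ok)
  expect_error(cv_config(poly_degree = 2, min_neighbors = 3), "min_neighbors")
})
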