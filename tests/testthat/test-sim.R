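test_that("the ionic right-hand side matches an independent transcription", {
  set.seed(4)
  for (k in 1:8) {
    s <- crn_initial_state()
    s["V"] <- runif(1, -90, 30)
    s["Cai"] <- runif(1, 5e-5, 2e-3)
    s[c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f",
        "fCa", "u", "v", "w")] <- runif(15, 0.02, 0.98)
    for (rem in c(TRUE, FALSE)) {
      p <- ionic_params(remodeled = rem, gna_factor = 0.3)
      d1 <- crn_rhs(s, p)
      so <- s; names(so)[names(so) == "j"] <- "jj"
      d2 <- unlist(oracle_crn_derivs(0, so, list(
        gna_mult = 0.3,
        f_to = if (rem) 0.40 else 1, f_CaL = if (rem) 0.35 else 1,
        f_K1 = if (rem) 2.00 else 1)))
      expect_lt(max(abs(d1 - d2) / (abs(d1) + 1e-9)), 1e-10)
    }
  }
  bad <- crn_initial_state(); bad["Cai"] <- NA
  expect_error(crn_rhs(bad), "Cai")
})

test_that("the resting cell is stationary and the paced APD90 matches deSolve", {
  r <- crn_cell_run(1000, dt = 0.02, ionic = ionic_params(remodeled = FALSE))
  expect_lt(max(abs(r$vm - r$vm[1])), 1)
  ## APD90 of the compiled cell vs the deSolve-integrated oracle
  st <- c(50, 1050)
  rb <- crn_cell_run(2000, dt = 0.02, ionic = ionic_params(remodeled = FALSE),
                     stim_times = st, stim_amp = 20)
  apd_cpp <- apd90(rb$t, rb$vm)
  apd_ode <- oracle_apd90(remodeled = FALSE)
  expect_lt(abs(apd_cpp - apd_ode) / apd_ode, 0.10)
  ## electrical remodeling strictly shortens the action potential
  rr <- crn_cell_run(2000, dt = 0.02, ionic = ionic_params(remodeled = TRUE),
                     stim_times = st, stim_amp = 20)
  expect_lt(apd90(rr$t, rr$vm), apd_cpp)
})

test_that("tissue masks have exact counts and are seed-reproducible", {
  m <- build_tissue(width = 20, height = 20, spacing = 0.5,
                    brs_fraction = 0.5, fibrosis_fraction = 0.5, seed = 7)
  expect_equal(sum(m$brs_mask), floor(0.5 * m$n))
  expect_equal(sum(m$fibrosis_mask), floor(0.5 * m$nx * (m$ny - 1)))
  expect_true(all(m$wy[m$fibrosis_mask] == 0))
  expect_true(all(m$gna_factor[m$brs_mask] == 0.30))
  m2 <- build_tissue(width = 20, height = 20, spacing = 0.5,
                     brs_fraction = 0.5, fibrosis_fraction = 0.5, seed = 7)
  expect_identical(m$brs_mask, m2$brs_mask)
  expect_identical(m$fibrosis_mask, m2$fibrosis_mask)
  ## node-wise (uncorrelated) masks also hit the exact count
  m3 <- build_tissue(width = 20, height = 20, spacing = 0.5,
                     brs_fraction = 0.3, brs_patch_mm = 0, seed = 3)
  expect_equal(sum(m3$brs_mask), floor(0.3 * m3$n))
  m0 <- build_tissue(width = 20, height = 20, spacing = 0.5)
  expect_false(any(m0$brs_mask))
  expect_error(build_tissue(brs_fraction = 1.2), "0, 1")
})

test_that("pacing schedules ramp linearly and fill the train duration", {
  sch <- make_schedule(2.5, 200, 120)
  expect_true(all(diff(sch) < 0))
  expect_lt(abs(sum(sch) - 2500), 200)
  expect_equal(length(sch), 16)
  expect_warning(sch2 <- make_schedule(1, 100, 100), "constant")
  expect_equal(sch2, rep(100, 10))
  expect_error(make_schedule(2.5, 100, 150), "start_interval")
  expect_error(make_schedule(0.05, 100, 80), "shorter")
})

test_that("wave counting equals an independent connected-components oracle", {
  igraph_count <- function(vm, nx, ny, thr) {
    on <- which(as.vector(vm) > thr)
    if (!length(on)) return(0L)
    idx <- matrix(seq_len(nx * ny), nx, ny)
    edges <- rbind(cbind(as.vector(idx[-nx, ]), as.vector(idx[-1, ])),
                   cbind(as.vector(idx[, -ny]), as.vector(idx[, -1])))
    keep <- edges[, 1] %in% on & edges[, 2] %in% on
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges[keep, , drop = FALSE]), directed = FALSE,
      vertices = data.frame(name = on))
    igraph::components(g)$no
  }
  expect_equal(count_waves(matrix(-80, 10, 10)), 0L)
  two <- matrix(-80, 10, 10)
  two[2:3, 2:3] <- -20
  two[7:9, 7:8] <- 0
  expect_equal(count_waves(two), 2L)
  set.seed(99)
  for (k in 1:100) {
    vm <- matrix(ifelse(runif(12 * 15) < 0.4, -20, -80), 12, 15)
    expect_equal(count_waves(vm), igraph_count(vm, 12, 15, -60))
  }
})

test_that("uniform resting tissue stays uniform and within 1 mV for 1 s", {
  m <- build_tissue(width = 10, height = 10, spacing = 1, d_long = 0.15,
                    d_trans = 0.1125, ionic = ionic_params(remodeled = FALSE))
  s0 <- tissue_initial_states(m)
  s1 <- step_tissue(m, s0, dt = 0.05, n_steps = 20000)
  vm <- s1[1, ]
  expect_lt(max(vm) - min(vm), 0.01)
  expect_lt(max(abs(vm - s0[1, 1])), 1)
})

test_that("the explicit stepper enforces its stability bound", {
  m <- build_tissue(width = 10, height = 10, spacing = 0.25)
  expect_error(step_tissue(m, tissue_initial_states(m), dt = 0.2),
               "stability")
})

test_that("a point stimulus on a near-isotropic sheet gives round isochrones", {
  m <- build_tissue(width = 20, height = 20, spacing = 0.5, d_long = 0.15,
                    d_trans = 0.1495, ionic = ionic_params(remodeled = FALSE))
  center <- tissue_node_at(m, 10, 10)
  nodes <- atrialep:::.stim_patch(m, center, 1.5)
  out <- atrialep:::tissue_run_cpp(tissue_initial_states(m), m$ionic, m$gna_factor,
                        m$nx, m$ny, m$wx, m$wy, 0.05, 40, nodes - 1L,
                        5, 2, 60, -60, 1, FALSE)
  last <- matrix(out$snapshots[[length(out$snapshots)]], m$nx, m$ny)
  on <- which(last > -60, arr.ind = TRUE)
  spread_x <- diff(range(on[, 1]))
  spread_y <- diff(range(on[, 2]))
  expect_lt(max(spread_x, spread_y) / min(spread_x, spread_y), 1.1)
})

test_that("planar conduction velocity increases with sodium conductance", {
  cv_for <- function(gna) {
    m <- build_tissue(width = 30, height = 2, spacing = 0.5, d_long = 0.15,
                      d_trans = 0.1125,
                      ionic = ionic_params(remodeled = FALSE))
    m$gna_factor[] <- gna
    nodes <- atrialep:::.stim_patch(m, tissue_node_at(m, 0, 1), 3)
    out <- atrialep:::tissue_run_cpp(tissue_initial_states(m), m$ionic, m$gna_factor,
                          m$nx, m$ny, m$wx, m$wy, 0.05, 160, nodes - 1L,
                          5, 2, 60, -60, 1, FALSE)
    tt <- out$snapshot_t
    tact <- function(x) {
      v <- vapply(out$snapshots, function(f) f[tissue_node_at(m, x, 1)],
                  numeric(1))
      tt[which(v > -20)[1]]
    }
    10 / (tact(25) - tact(15))
  }
  cvs <- vapply(c(0.3, 0.5, 0.7, 1.0), cv_for, numeric(1))
  expect_false(anyNA(cvs))
  expect_true(all(diff(cvs) > 0))
})

test_that("the burst protocol aggregates per-site outcomes correctly", {
  ## healthy (unremodeled, homogeneous) tissue with a mild protocol: waves
  ## die out and nothing is inducible
  m <- build_tissue(width = 15, height = 15, spacing = 0.75,
                    ionic = ionic_params(remodeled = FALSE))
  res <- run_af_protocol(m, sites = tissue_node_at(m, 7.5, 7.5),
                         schedule = make_schedule(0.6, 300, 300) |>
                           suppressWarnings(),
                         dt = 0.05, post_pacing_ms = 400)
  expect_equal(res$inducibility_rate, 0)
  expect_false(res$sustained[1])
  expect_true(res$mean_wave_count_all < 1)
})

test_that("scenario comparison produces Bonferroni-adjusted pairwise tests", {
  mk <- function(sust, mwc) {
    structure(list(sustained = sust, mean_wave_count = mwc,
                   inducibility_rate = mean(sust)), class = "sim_result")
  }
  a <- mk(rep(c(TRUE, FALSE), 5), rnorm(10, 2, 0.3))
  b <- mk(rep(FALSE, 10), rnorm(10, 1, 0.3))
  c3 <- mk(rep(TRUE, 10), rnorm(10, 3, 0.3))
  tab <- compare_scenarios(list(a = a, b = b, c = c3))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$p_waves_bonferroni,
               pmin(1, 3 * tab$p_waves), tolerance = 1e-12)
  ## identical outcomes -> adjusted p of 1
  tab2 <- compare_scenarios(list(x = a, y = a))
  expect_equal(tab2$p_inducibility, 1)
  ## complete separation -> tiny Fisher p
  sep <- compare_scenarios(list(
    all = mk(rep(TRUE, 20), rnorm(20, 3, 0.2)),
    none = mk(rep(FALSE, 20), rnorm(20, 1, 0.2))))
  expect_lt(sep$p_inducibility, 1e-9)
  expect_error(compare_scenarios(list(a)), "2 scenarios")
})

test_that("grid refinement leaves planar conduction velocity stable", {
  ## halving the fine-end default spacing (0.25 mm) changes CV by < 10%
  cv_at <- function(spacing) {
    m <- build_tissue(width = 30, height = 2, spacing = spacing,
                      d_long = 0.15, d_trans = 0.1125,
                      ionic = ionic_params(remodeled = FALSE))
    nodes <- atrialep:::.stim_patch(m, tissue_node_at(m, 0, 1), 3)
    out <- atrialep:::tissue_run_cpp(tissue_initial_states(m), m$ionic, m$gna_factor,
                          m$nx, m$ny, m$wx, m$wy, 0.02, 120, nodes - 1L,
                          5, 2, 60, -60, 0.5, FALSE)
    tt <- out$snapshot_t
    tact <- function(x) {
      v <- vapply(out$snapshots, function(f) f[tissue_node_at(m, x, 1)],
                  numeric(1))
      tt[which(v > -20)[1]]
    }
    10 / (tact(25) - tact(15))
  }
  expect_lt(abs(cv_at(0.125) - cv_at(0.25)) / cv_at(0.125), 0.10)
})
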