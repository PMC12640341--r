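test_that("geometric closure resolves counts into a consistent cap", {
  pk <- packing_model()
  # a single plated cell
  cap <- resolve_geometry(1, 1, pk)
  expect_equal(cap$r_base, sqrt(1.2), tolerance = 1e-12)
  expect_equal(cap$V, 1.2^1.5 * 4 / 3 * pi, tolerance = 1e-12)
  expect_equal(cap$h, oracle_cap_height(cap$V, cap$r_base), tolerance = 1e-10)
  expect_equal(cap$h, 1.6571294783, tolerance = 1e-9)

  # cube-law scaling: x8 cells at fixed shape ratio doubles both dimensions
  cap1 <- resolve_geometry(100, 500, pk)
  cap2 <- resolve_geometry(400, 4000, pk)
  expect_equal(cap2$r_base / cap1$r_base, 2, tolerance = 1e-9)
  expect_equal(cap2$h / cap1$h, 2, tolerance = 1e-9)
  expect_equal(cap2$omega, cap1$omega, tolerance = 1e-9)

  # all-basal colonies flatten: height approaches the pancake constant
  # (8/3) r_C sqrt(F_2D), since volume and base area both scale linearly in N
  h_flat <- vapply(10^c(3, 5, 7), function(N) resolve_geometry(N, N, pk)$h, numeric(1))
  h_limit <- 8 / 3 * pk$r_C * sqrt(pk$F_2D)
  expect_true(all(diff(h_flat) > 0))
  expect_true(all(h_flat < h_limit))
  expect_equal(h_flat[3], h_limit, tolerance = 1e-3)
  # the residual geometric cap above one cell layer becomes a thin sliver:
  # its height stays bounded while the colony radius diverges
  uc <- upper_cap(resolve_geometry(1e7, 1e7, pk), pk)
  expect_lt(uc$h, h_limit - 2 * pk$r_C * sqrt(pk$F_2D) + 1e-6)

  expect_error(resolve_geometry(10, 5, pk), class = "colonycap_validation_error")
})

test_that("derivatives collapse to uninhibited exponential growth at gamma = 1", {
  pk <- packing_model()
  set.seed(42)
  for (i in 1:25) {
    NL1 <- 10^runif(1, 0, 6)
    NTOT <- NL1 * 10^runif(1, 0, 3)
    fz <- runif(1, 0.05, 0.95)
    r1 <- growth_rates(gamma = 1, f_z = fz)
    d <- colony_derivatives(NL1, NTOT, r1, pk)
    expect_equal(d$dN_TOT_dt, r1$k * NTOT, tolerance = 1e-12)
    expect_equal(d$dN_L1_dt, r1$k_par * NL1, tolerance = 1e-12)
    # partial inhibition always grows slower, never negative, never below basal
    r_part <- growth_rates(gamma = runif(1), f_z = fz)
    dp <- colony_derivatives(NL1, NTOT, r_part, pk)
    expect_lte(dp$dN_TOT_dt, r_part$k * NTOT * (1 + 1e-12))
    expect_gte(dp$dN_TOT_dt, dp$dN_L1_dt)
    expect_gte(dp$dN_L1_dt, 0)
  }
})

test_that("complete inhibition with planar growth reduces to frontier-only kinetics", {
  pk <- packing_model()
  r <- growth_rates(gamma = 0, f_z = 0)
  for (NL1 in c(3, 1000)) {
    d <- colony_derivatives(NL1, NL1 * 2, r, pk)
    per <- basal_inplane_split(NL1, pk$F_2D)$per
    expect_equal(d$dN_L1_dt, r$k_par * per, tolerance = 1e-12)
    # no vertical component, but the (uninhibited-perimeter) upper cap still divides
    expect_gte(d$dN_TOT_dt, d$dN_L1_dt)
  }
  # a vanishing lumped rate freezes the system
  r_tiny <- growth_rates(gamma = 0.5, k = 1e-15)
  sim <- simulate_colony(r_tiny, t_end = 100, dt = 1, output_times = c(0, 100))
  expect_equal(tidy(sim)$N_TOT, c(1, 1), tolerance = 1e-9)
})

test_that("RK4 integration is accurate, convergent and deterministic", {
  r <- growth_rates(gamma = 1, f_z = 1 / 3)
  sim <- simulate_colony(r, t_end = 600, dt = 0.5)
  tr <- tidy(sim)
  expect_equal(tr$N_TOT, exp(r$k * tr$t_min), tolerance = 1e-8)

  # step halving barely moves the answer (high-order convergence)
  r2 <- growth_rates(gamma = 0.25, f_z = 1 / 6)
  n_end <- function(dt) {
    tr <- tidy(simulate_colony(r2, t_end = 600, dt = dt, output_times = c(0, 600)))
    tr$N_TOT[2]
  }
  expect_equal(n_end(0.25), n_end(0.5), tolerance = 1e-9)

  # bit-reproducible: the model has no randomness
  s1 <- tidy(simulate_colony(r2, t_end = 300, dt = 0.5))
  s2 <- tidy(simulate_colony(r2, t_end = 300, dt = 0.5))
  expect_identical(s1, s2)
})

test_that("simulated trajectories agree with an independent adaptive ODE solver", {
  library(deSolve)
  pk <- packing_model()
  r <- growth_rates(gamma = 0.5, f_z = 1 / 3)
  rhs <- function(t, y, p) {
    d <- colony_derivatives(y[1], y[2], r, pk)
    list(c(d$dN_L1_dt, d$dN_TOT_dt))
  }
  times <- seq(0, 600, by = 100)
  ref <- deSolve::ode(c(1, 1), times, rhs, NULL,
    method = "lsoda", rtol = 1e-10, atol = 1e-10
  )
  tr <- tidy(simulate_colony(r, t_end = 600, dt = 0.5, output_times = times))
  expect_equal(tr$N_L1, unname(ref[, 2]), tolerance = 1e-7)
  expect_equal(tr$N_TOT, unname(ref[, 3]), tolerance = 1e-7)
})

test_that("emitted states keep the model invariants and monotone kinetics", {
  sim <- simulate_colony(growth_rates(gamma = 0.5, f_z = 1 / 6), t_end = 1000, dt = 0.5)
  tr <- tidy(sim)
  pk <- sim$packing
  expect_true(all(tr$N_L1 >= 1 - 1e-12))
  expect_true(all(tr$N_L1 <= tr$N_TOT * (1 + 1e-12)))
  expect_true(all(diff(tr$N_TOT) > 0))
  expect_true(all(diff(tr$N_L1) > 0))
  expect_true(all(diff(tr$r_L1_um) > 0))
  expect_true(all(diff(tr$h_COL_um) > 0))
  expect_true(all(tr$eta >= 0 & tr$eta <= 1))
  # geometry closure at every emitted state
  expect_equal(tr$r_L1_um, layer_radius(tr$N_L1, pk), tolerance = 1e-9)
  V <- colony_volume(tr$N_TOT, pk)
  expect_equal(cap_volume(tr$h_COL_um, tr$r_L1_um), V, tolerance = 1e-9)
  expect_equal(cap_sphere_radius(tr$h_COL_um, tr$r_L1_um), tr$R_um, tolerance = 1e-9)
})

test_that("dense output interpolation matches states computed on the grid", {
  r <- growth_rates(gamma = 0.25, f_z = 1 / 3)
  # off-grid emission times versus a run that lands on them exactly
  off <- simulate_colony(r, t_end = 400, dt = 0.5, output_times = c(123.4, 307.7))
  on <- simulate_colony(r, t_end = 400, dt = 0.1, output_times = c(123.4, 307.7))
  expect_equal(tidy(off)$N_TOT, tidy(on)$N_TOT, tolerance = 1e-9)
  expect_equal(tidy(off)$N_L1, tidy(on)$N_L1, tolerance = 1e-9)
})

test_that("profile snapshots trace growing on-circle outlines", {
  sim <- simulate_colony(growth_rates(gamma = 0.5), t_end = 1000, dt = 0.5)
  prof <- profile_snapshots(sim, times = c(250, 500, 1000), n_points = 61)
  expect_named(prof, c("time_min", "x_um", "z_um"))
  expect_equal(nrow(prof), 3 * 61)
  apex <- tapply(prof$z_um, prof$time_min, max)
  width <- tapply(prof$x_um, prof$time_min, max)
  expect_true(all(diff(apex) > 0))
  expect_true(all(diff(width) > 0))
  tr <- tidy(sim)
  expect_equal(unname(apex[3]), tr$h_COL_um[tr$t_min == 1000], tolerance = 1e-9)
})

test_that("tidy, glance and plotting interfaces expose the run", {
  sim <- simulate_colony(growth_rates(gamma = 0.75, f_z = 1 / 6), t_end = 300, dt = 0.5)
  tr <- tidy(sim)
  expect_s3_class(tr, "tbl_df")
  expect_named(tr, c(
    "t_min", "N_TOT", "N_L1", "r_L1_um", "h_COL_um", "R_um",
    "omega", "theta_deg", "eta", "dN_L1_dt", "dN_TOT_dt"
  ))
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_equal(g$Gamma, 2.5)
  expect_equal(g$N_TOT_final, tr$N_TOT[nrow(tr)])
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_profiles(sim, times = c(100, 300)), "ggplot")
})
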