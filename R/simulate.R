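#' Resolve colony geometry from the two cell counts
#'
#' The geometric closure of the model: the basal count fixes the base radius
#' `r_L1 = r_C sqrt(F_2D N_L1)`, the total count fixes the volume
#' `V = N_TOT F_3D (4/3) pi r_C^3`, and the cap height is recovered by
#' inverting the cap-volume relation at that base radius; the greater-sphere
#' radius follows from the chord relation.
#'
#' @param N_L1 Basal-layer cell count, in `[1, N_TOT]` (continuous).
#' @param N_TOT Total cell count (continuous).
#' @param packing A [packing_model()].
#' @return A resolved [spherical_cap()] for the whole colony.
#' @examples
#' resolve_geometry(1, 1, packing_model()) # a single plated cell
#' @export
resolve_geometry <- function(N_L1, N_TOT, packing = packing_model()) {
  stopifnot(inherits(packing, "packing_model"))
  if (!is.finite(N_L1) || !is.finite(N_TOT) || N_L1 <= 0 || N_TOT < N_L1) {
    abort("need 0 < N_L1 <= N_TOT", class = "colonycap_validation_error")
  }
  r_base <- layer_radius(N_L1, packing)
  V <- colony_volume(N_TOT, packing)
  h <- solve_cap_height(V, r_base)
  spherical_cap(h = h, r_base = r_base)
}

#' Growth derivatives of the coupled cell-count system
#'
#' Right-hand side of the two coupled ODEs. Lateral basal growth:
#' `dN_L1/dt = k_par (per + gamma int)` over the in-plane basal partition.
#' Total growth adds vertical basal division, `k_perp` over the
#' coverage-weighted vertical partition, and upper-cap division at the full
#' lumped `k` over the upper partition (perimeter at full rate, interior
#' scaled by `gamma`). The upper-cap total is the population bookkeeping
#' count `N_TOT - N_L1`; its interior part comes from the interior sub-cap
#' geometry. With `gamma = 1` the partitions telescope and
#' `dN_TOT/dt = k N_TOT` exactly.
#'
#' @param N_L1,N_TOT Current cell counts (continuous, `1 <= N_L1 <= N_TOT`).
#' @param rates A [growth_rates()].
#' @param packing A [packing_model()].
#' @return A one-row tibble with `dN_L1_dt` and `dN_TOT_dt` (cells/min).
#' @examples
#' colony_derivatives(50, 120, growth_rates(gamma = 0.5), packing_model())
#' @export
colony_derivatives <- function(N_L1, N_TOT, rates, packing = packing_model()) {
  stopifnot(inherits(rates, "growth_rates"))
  d <- deriv_core(
    N_L1, N_TOT, rates$k, rates$k_par, rates$k_perp, rates$gamma,
    packing$r_C, packing$F_2D, packing$cell_volume
  )
  tibble(dN_L1_dt = d[1], dN_TOT_dt = d[2])
}

# hot-path scalar derivative: no S3 dispatch, minimal allocation
deriv_core <- function(NL1, NTOT, k, k_par, k_perp, gamma, r_C, F_2D, cellvol) {
  if (NL1 > NTOT) NL1 <- NTOT # guard one-ulp roundoff
  # in-plane basal partition
  per_l <- (2 * sqrt(F_2D * NL1) - 1) / F_2D
  if (per_l < 0) per_l <- 0 else if (per_l > NL1) per_l <- NL1
  d1 <- k_par * (per_l + gamma * (NL1 - per_l))
  # vertical basal partition via coverage eta = 1 - NL1/NTOT
  per_v <- NL1 / 2 * (NL1 / NTOT)
  d2 <- d1 + k_perp * (per_v + gamma * (NL1 - per_v))
  # upper-cap partition: total from bookkeeping, interior from geometry
  n_up <- NTOT - NL1
  if (n_up > 0) {
    n_int <- 0
    if (gamma != 1) {
      # interior exists only if h > 2 r_C sqrt(F_2D) + r_C; h <= (6V/pi)^(1/3)
      V <- NTOT * cellvol
      h_min_int <- 2 * r_C * sqrt(F_2D) + r_C
      if ((6 * V / pi)^(1 / 3) > h_min_int) {
        r_base <- r_C * sqrt(F_2D * NL1)
        h <- cap_height_newton(V, r_base, 1e-14, 200L)
        h_pp <- h - h_min_int
        R_pp <- (r_base^2 + h^2) / (2 * h) - r_C
        if (h_pp > 0 && R_pp > 0) {
          if (h_pp > 2 * R_pp) h_pp <- 2 * R_pp
          r_pp2 <- R_pp^2 - (R_pp - h_pp)^2
          v_int <- pi / 6 * (h_pp^3 + 3 * h_pp * r_pp2)
          n_int <- v_int / cellvol
          if (n_int > n_up) n_int <- n_up
        }
      }
    }
    d2 <- d2 + k * (n_up - (1 - gamma) * n_int)
  }
  c(d1, d2)
}

#' Simulate contact-inhibited colony growth on a plate
#'
#' Integrates the coupled basal-layer/total cell-count ODEs with fixed-step
#' fourth-order Runge-Kutta, re-resolving the spherical-cap geometry at
#' every stage evaluation, from a single plated cell (or `N0` cells). States
#' are emitted at `output_times` by cubic Hermite interpolation of the step
#' grid and carry the fully resolved geometry and population splits. The
#' model is deterministic; repeated runs are identical.
#'
#' @param rates A [growth_rates()].
#' @param packing A [packing_model()].
#' @param t_end Horizon, minutes. Default 3000 (about two days of culture).
#' @param dt Integrator step, minutes. Default 0.5.
#' @param output_times Emission times, minutes, within `[t0, t_end]`.
#'   Default every 10 min.
#' @param N0 Initial cell count for both counts. Default 1.
#' @param t0 Start time, minutes. Default 0.
#' @return A `colony_sim` object; `tidy()` extracts the trajectory tibble
#'   (columns `t_min`, `N_TOT`, `N_L1`, `r_L1_um`, `h_COL_um`, `R_um`,
#'   `omega`, `theta_deg`, `eta`, `dN_L1_dt`, `dN_TOT_dt`), `glance()` the
#'   one-row run summary, `autoplot()` the kinetic panels.
#' @examples
#' sim <- simulate_colony(growth_rates(gamma = 0.5), t_end = 300)
#' tidy(sim)
#' @export
simulate_colony <- function(rates, packing = packing_model(), t_end = 3000,
                            dt = 0.5, output_times = NULL, N0 = 1, t0 = 0) {
  stopifnot(inherits(rates, "growth_rates"), inherits(packing, "packing_model"))
  check_scalar(t_end, "t_end")
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(N0, "N0", positive = TRUE)
  if (t_end <= t0) {
    abort("`t_end` must exceed `t0`", class = "colonycap_validation_error")
  }
  if (is.null(output_times)) output_times <- seq(t0, t_end, by = 10)
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < t0) || any(output_times > t_end)) {
    abort("`output_times` must lie in [t0, t_end]",
      class = "colonycap_validation_error"
    )
  }

  n_steps <- ceiling((t_end - t0) / dt - 1e-9)
  tg <- t0 + dt * (0:n_steps)
  tg[n_steps + 1] <- t_end # final (possibly short) step lands on t_end
  y1 <- numeric(n_steps + 1)
  y2 <- numeric(n_steps + 1)
  g1 <- numeric(n_steps + 1)
  g2 <- numeric(n_steps + 1)
  y1[1] <- N0
  y2[1] <- N0

  k <- rates$k; kp <- rates$k_par; kz <- rates$k_perp; gam <- rates$gamma
  r_C <- packing$r_C; F2 <- packing$F_2D; cv <- packing$cell_volume

  d <- deriv_core(y1[1], y2[1], k, kp, kz, gam, r_C, F2, cv)
  g1[1] <- d[1]; g2[1] <- d[2]
  for (i in seq_len(n_steps)) {
    h <- tg[i + 1] - tg[i]
    a1 <- y1[i]; a2 <- y2[i]
    k1 <- c(g1[i], g2[i])
    k2 <- deriv_core(a1 + h / 2 * k1[1], a2 + h / 2 * k1[2], k, kp, kz, gam, r_C, F2, cv)
    k3 <- deriv_core(a1 + h / 2 * k2[1], a2 + h / 2 * k2[2], k, kp, kz, gam, r_C, F2, cv)
    k4 <- deriv_core(a1 + h * k3[1], a2 + h * k3[2], k, kp, kz, gam, r_C, F2, cv)
    y1[i + 1] <- a1 + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    y2[i + 1] <- a2 + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    if (y1[i + 1] > y2[i + 1] * (1 + 1e-9)) {
      abort(
        sprintf(
          "invariant breach at t = %g min: N_L1 = %g exceeds N_TOT = %g",
          tg[i + 1], y1[i + 1], y2[i + 1]
        ),
        class = "colonycap_invariant_error"
      )
    }
    if (y1[i + 1] > y2[i + 1]) y1[i + 1] <- y2[i + 1]
    d <- deriv_core(y1[i + 1], y2[i + 1], k, kp, kz, gam, r_C, F2, cv)
    g1[i + 1] <- d[1]; g2[i + 1] <- d[2]
  }

  grid <- list(t = tg, N_L1 = y1, N_TOT = y2, dN_L1 = g1, dN_TOT = g2)
  states <- interp_states(grid, output_times)
  traj <- build_trajectory(states, rates, packing)

  structure(
    list(
      trajectory = traj,
      rates = rates,
      packing = packing,
      config = list(
        t0 = t0, t_end = t_end, dt = dt, N0 = N0,
        output_times = output_times
      ),
      grid = grid,
      diagnostics = list(
        n_steps = n_steps,
        integrator = "rk4-fixed",
        height_solver = "newton-bisection, rel tol 1e-14"
      )
    ),
    class = "colony_sim"
  )
}

# cubic Hermite interpolation of (N_L1, N_TOT) on the step grid
interp_states <- function(grid, times) {
  idx <- findInterval(times, grid$t, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > length(grid$t) - 1] <- length(grid$t) - 1
  t0 <- grid$t[idx]
  t1 <- grid$t[idx + 1]
  h <- t1 - t0
  s <- (times - t0) / h
  on_node <- abs(times - t0) < 1e-12 * pmax(abs(times), 1)
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  herm <- function(y, d) {
    v <- h00 * y[idx] + h10 * h * d[idx] + h01 * y[idx + 1] + h11 * h * d[idx + 1]
    v[on_node] <- y[idx][on_node]
    v
  }
  at_end <- abs(times - grid$t[length(grid$t)]) < 1e-12 * pmax(abs(times), 1)
  N_L1 <- herm(grid$N_L1, grid$dN_L1)
  N_TOT <- herm(grid$N_TOT, grid$dN_TOT)
  N_L1[at_end] <- grid$N_L1[length(grid$t)]
  N_TOT[at_end] <- grid$N_TOT[length(grid$t)]
  list(t = times, N_L1 = pmin(N_L1, N_TOT), N_TOT = N_TOT)
}

build_trajectory <- function(states, rates, packing) {
  rows <- purrr::map(seq_along(states$t), function(i) {
    NL1 <- states$N_L1[i]
    NTOT <- states$N_TOT[i]
    cap <- resolve_geometry(NL1, NTOT, packing)
    d <- deriv_core(
      NL1, NTOT, rates$k, rates$k_par, rates$k_perp, rates$gamma,
      packing$r_C, packing$F_2D, packing$cell_volume
    )
    tibble(
      t_min = states$t[i], N_TOT = NTOT, N_L1 = NL1,
      r_L1_um = cap$r_base, h_COL_um = cap$h, R_um = cap$R,
      omega = cap$omega, theta_deg = cap$theta,
      eta = 1 - NL1 / NTOT,
      dN_L1_dt = d[1], dN_TOT_dt = d[2]
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.colony_sim <- function(x, ...) {
  fin <- x$trajectory[nrow(x$trajectory), ]
  cat("<colony_sim>\n")
  cat(sprintf(
    "  gamma = %.3g, Gamma = %s, k = %.5g min^-1\n",
    x$rates$gamma,
    if (is.na(x$rates$anisotropy)) "undefined" else format(x$rates$anisotropy),
    x$rates$k
  ))
  cat(sprintf(
    "  t = [%g, %g] min, dt = %g min, %d states emitted\n",
    x$config$t0, x$config$t_end, x$config$dt, nrow(x$trajectory)
  ))
  cat(sprintf(
    "  final: N_TOT = %.5g, N_L1 = %.5g, r_L1 = %.4g um, h_COL = %.4g um, theta = %.4g deg\n",
    fin$N_TOT, fin$N_L1, fin$r_L1_um, fin$h_COL_um, fin$theta_deg
  ))
  invisible(x)
}

#' Midsection profiles along a simulated trajectory
#'
#' Resolves the colony cap at each snapshot time (interpolating the
#' integration grid) and samples its central-midsection outline.
#'
#' @param sim A `colony_sim`.
#' @param times Snapshot times, minutes, within the simulated range.
#'   Default every 500 min from 500 to the horizon.
#' @param n_points Arc samples per profile.
#' @return A tibble with columns `time_min`, `x_um`, `z_um`.
#' @export
profile_snapshots <- function(sim, times = NULL, n_points = 181L) {
  stopifnot(inherits(sim, "colony_sim"))
  if (is.null(times)) {
    times <- seq(500, sim$config$t_end, by = 500)
    times <- times[times >= sim$config$t0]
  }
  states <- interp_states(sim$grid, times)
  purrr::map_dfr(seq_along(times), function(i) {
    cap <- resolve_geometry(states$N_L1[i], states$N_TOT[i], sim$packing)
    prof <- midsection_profile(cap, n_points)
    dplyr::mutate(prof, time_min = times[i], .before = 1)
  })
}

#' Reference parameter grid: three anisotropy regimes by five inhibition levels
#'
#' Runs the model's reference study conditions: a 2-micron cell (r_C = 1 um),
#' 90-min doubling time, F_2D = 1.2, 3000-min horizon, with growth either
#' isotropic (f_z = 1/3, Gamma = 1), laterally favoured (f_z = 1/6,
#' Gamma = 2.5) or vertically favoured (f_z = 1/2, Gamma = 0.5), crossed
#' with contact inhibition gamma in {0, 0.25, 0.5, 0.75, 1}.
#'
#' @param gammas Contact-inhibition levels to sweep.
#' @param regimes Data frame with columns `regime` and `f_z`.
#' @param t_double Doubling time, min.
#' @param packing A [packing_model()].
#' @param t_end Horizon, min.
#' @param dt Integrator step, min.
#' @param output_times Emission times passed to [simulate_colony()].
#' @return A tibble with one row per run: `regime`, `f_z`, `gamma`,
#'   `Gamma`, and list-column `sim` of `colony_sim` objects.
#' @examples
#' \donttest{
#' grid <- run_growth_grid(t_end = 500)
#' }
#' @export
run_growth_grid <- function(gammas = c(0, 0.25, 0.5, 0.75, 1),
                            regimes = data.frame(
                              regime = c("isotropic", "horizontal", "vertical"),
                              f_z = c(1 / 3, 1 / 6, 1 / 2)
                            ),
                            t_double = 90,
                            packing = packing_model(),
                            t_end = 3000, dt = 0.5,
                            output_times = NULL) {
  runs <- tidyr::expand_grid(as_tibble(regimes), gamma = gammas)
  runs |>
    dplyr::mutate(
      sim = purrr::map2(.data$f_z, .data$gamma, function(fz, g) {
        simulate_colony(
          growth_rates(gamma = g, f_z = fz, t_double = t_double),
          packing = packing, t_end = t_end, dt = dt,
          output_times = output_times
        )
      }),
      Gamma = purrr::map_dbl(.data$sim, ~ .x$rates$anisotropy),
      .after = "gamma"
    )
}
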