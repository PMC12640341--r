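#' Tidy a simulated colony trajectory
#'
#' @param x A `colony_sim`.
#' @param ... Unused.
#' @return The trajectory tibble, one row per emitted state.
#' @export
tidy.colony_sim <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a colony simulation
#'
#' @param x A `colony_sim`.
#' @param ... Unused.
#' @return A one-row tibble: run parameters (`k`, `f_z`, `gamma`, `Gamma`),
#'   integration settings and the final state.
#' @export
glance.colony_sim <- function(x, ...) {
  fin <- x$trajectory[nrow(x$trajectory), ]
  tibble(
    k = x$rates$k,
    f_z = x$rates$f_z,
    gamma = x$rates$gamma,
    Gamma = x$rates$anisotropy,
    r_C = x$packing$r_C,
    F_2D = x$packing$F_2D,
    F_3D = x$packing$F_3D,
    t_end = x$config$t_end,
    dt = x$config$dt,
    n_steps = x$diagnostics$n_steps,
    N_TOT_final = fin$N_TOT,
    N_L1_final = fin$N_L1,
    r_L1_final_um = fin$r_L1_um,
    h_COL_final_um = fin$h_COL_um,
    omega_final = fin$omega,
    theta_final_deg = fin$theta_deg
  )
}

#' Kinetic panels for a colony simulation
#'
#' Four panels against time: log10 total cell number, log10 basal radius,
#' log10 colony height, and the receding contact angle.
#'
#' @param object A `colony_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.colony_sim <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$t_min > 0) |>
    dplyr::transmute(
      t_min = .data$t_min,
      `log10 N_TOT` = log10(.data$N_TOT),
      `log10 r_L1 (um)` = log10(.data$r_L1_um),
      `log10 h_COL (um)` = log10(.data$h_COL_um),
      `theta (deg)` = .data$theta_deg
    ) |>
    tidyr::pivot_longer(-"t_min", names_to = "panel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_bw()
}

#' Overlayed midsection outlines at snapshot times
#'
#' @param sim A `colony_sim`.
#' @param times Snapshot times, min; default every 500 min.
#' @param n_points Arc samples per outline.
#' @return A ggplot object with one outline per snapshot, equal axis scales.
#' @export
plot_profiles <- function(sim, times = NULL, n_points = 181L) {
  prof <- profile_snapshots(sim, times = times, n_points = n_points)
  ggplot2::ggplot(
    prof,
    ggplot2::aes(.data$x_um, .data$z_um, group = .data$time_min,
                 colour = factor(.data$time_min))
  ) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "z (um)", colour = "time (min)") +
    ggplot2::theme_bw()
}

#' Grid kinetics across inhibition levels
#'
#' @param grid A tibble from [run_growth_grid()].
#' @param var Trajectory column to display (log10-transformed where it is a
#'   size). One of `"N_TOT"`, `"r_L1_um"`, `"h_COL_um"`, `"theta_deg"`,
#'   `"omega"`.
#' @return A ggplot object faceted by regime, coloured by gamma.
#' @export
plot_grid_kinetics <- function(grid, var = "N_TOT") {
  var <- match.arg(var, c("N_TOT", "r_L1_um", "h_COL_um", "theta_deg", "omega"))
  df <- grid |>
    dplyr::mutate(traj = purrr::map(.data$sim, tidy)) |>
    dplyr::select("regime", "gamma", "traj") |>
    tidyr::unnest("traj") |>
    dplyr::filter(.data$t_min > 0)
  logit <- var %in% c("N_TOT", "r_L1_um", "h_COL_um")
  df$value <- if (logit) log10(df[[var]]) else df[[var]]
  ylab <- if (logit) paste0("log10 ", var) else var
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$value,
    colour = factor(.data$gamma)
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~regime) +
    ggplot2::labs(x = "time (min)", y = ylab, colour = "gamma") +
    ggplot2::theme_bw()
}
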