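config_defaults <- function() {
  list(
    r_C = 1, F_2D = 1.2, F_3D = NULL,
    k = NULL, t_double = 90,
    f_z = 1 / 3, gamma = 0.5,
    t0 = 0, t_end = 3000, dt = 0.5, N0 = 1,
    output_times = NULL,
    profile_times = seq(500, 3000, by = 500)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML key-value file describing one simulation run, validates it
#' against the configuration schema (unknown keys are rejected, ranges
#' checked) and fills in the reference defaults: a 2-micron cell
#' (`r_C = 1`), 90-min doubling time, `F_2D = 1.2`, isotropic growth
#' (`f_z = 1/3`), `gamma = 0.5`, `dt = 0.5` min and a 3000-min horizon. An
#' empty file (or `path = NULL`) therefore yields the isotropic reference
#' run. If both `k` and `t_double` are given and disagree, `t_double` wins
#' with a warning.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @return A `colony_config` object: list with `rates` ([growth_rates()]),
#'   `packing` ([packing_model()]), the integration settings and
#'   `profile_times`; the raw key-value set is kept in `$raw`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path),
        class = "colonycap_config_error"
      )
    }
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    if (!is.list(raw)) {
      abort("config file must contain a YAML mapping",
        class = "colonycap_config_error"
      )
    }
  }
  build_config(raw)
}

build_config <- function(raw) {
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    abort(
      sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
      class = "colonycap_config_error"
    )
  }
  cfg <- utils::modifyList(defaults, raw, keep.null = FALSE)
  # a user-supplied k without t_double should not silently lose to the
  # default doubling time
  if (!is.null(raw$k) && is.null(raw$t_double)) cfg$t_double <- NULL
  rates <- growth_rates(
    gamma = cfg$gamma, f_z = cfg$f_z,
    k = cfg$k, t_double = cfg$t_double
  )
  packing <- packing_model(r_C = cfg$r_C, F_2D = cfg$F_2D, F_3D = cfg$F_3D)
  structure(
    list(
      rates = rates, packing = packing,
      t0 = cfg$t0, t_end = cfg$t_end, dt = cfg$dt, N0 = cfg$N0,
      output_times = cfg$output_times,
      profile_times = cfg$profile_times,
      raw = cfg
    ),
    class = "colony_config"
  )
}

#' @export
print.colony_config <- function(x, ...) {
  cat("<colony_config>\n")
  print(x$rates)
  print(x$packing)
  cat(sprintf(
    "  t = [%g, %g] min, dt = %g min, N0 = %g\n",
    x$t0, x$t_end, x$dt, x$N0
  ))
  invisible(x)
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config A `colony_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "colony_config"))
  out <- config$raw
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Run a simulation from a configuration
#'
#' @param config A `colony_config` from [load_config()].
#' @return A `colony_sim`.
#' @export
simulate_from_config <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  simulate_colony(
    rates = config$rates, packing = config$packing,
    t_end = config$t_end, dt = config$dt,
    output_times = config$output_times,
    N0 = config$N0, t0 = config$t0
  )
}

#' Write a trajectory table as CSV at full float precision
#'
#' Values are written with 17 significant digits so that reading the file
#' back reproduces the in-memory doubles exactly.
#'
#' @param sim A `colony_sim` (or a trajectory tibble).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  df <- if (inherits(sim, "colony_sim")) tidy(sim) else as_tibble(sim)
  write_full_precision_csv(df, path)
}

#' Write midsection profile snapshots as CSV
#'
#' Columns `time_min`, `x_um`, `z_um`, full float precision.
#'
#' @param sim A `colony_sim`.
#' @param path Output CSV path.
#' @param times,n_points Passed to [profile_snapshots()].
#' @return `path`, invisibly.
#' @export
write_profiles <- function(sim, path, times = NULL, n_points = 181L) {
  write_full_precision_csv(profile_snapshots(sim, times, n_points), path)
}

write_full_precision_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }))
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#'
#' Echoes the run parameters, solver diagnostics and final state.
#'
#' @param sim A `colony_sim`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(sim, path) {
  stopifnot(inherits(sim, "colony_sim"))
  jsonlite::write_json(
    list(
      package = "colonycap",
      version = as.character(utils::packageVersion("colonycap")),
      rates = unclass(sim$rates),
      packing = unclass(sim$packing),
      config = sim$config,
      diagnostics = sim$diagnostics,
      final_state = as.list(glance(sim))
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Generate deterministic test fixtures
#'
#' Writes (i) a set of random resolved caps with brute-force disc-integrated
#' volumes for use as a geometry oracle, (ii) the 15 reference-grid YAML
#' configurations (three anisotropy regimes by five inhibition levels).
#'
#' @param out_dir Writable output directory (created if needed).
#' @param n_caps Number of random oracle caps.
#' @param seed RNG seed for the cap sample (fixtures are deterministic given
#'   the seed).
#' @return Character vector of written paths, invisibly.
#' @export
make_fixtures <- function(out_dir, n_caps = 50, seed = 42L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, globalenv())
      }
    )
    code
  }
  caps <- withr_seed({
    h <- 10^stats::runif(n_caps, -2, 2)
    ratio <- 10^stats::runif(n_caps, -1.5, 1.5)
    tibble(h = h, r_base = h * ratio)
  })
  caps$R <- cap_sphere_radius(caps$h, caps$r_base)
  caps$V <- cap_volume(caps$h, caps$r_base)
  caps$V_oracle <- vapply(seq_len(n_caps), function(i) {
    disc_integration_volume(caps$h[i], caps$r_base[i])
  }, numeric(1))
  cap_path <- file.path(out_dir, "oracle_caps.csv")
  write_full_precision_csv(caps, cap_path)
  paths <- c(paths, cap_path)

  regimes <- data.frame(
    regime = c("isotropic", "horizontal", "vertical"),
    f_z = c(1 / 3, 1 / 6, 1 / 2)
  )
  for (i in seq_len(nrow(regimes))) {
    for (g in c(0, 0.25, 0.5, 0.75, 1)) {
      p <- file.path(out_dir, sprintf("grid_%s_gamma%03d.yaml",
        regimes$regime[i], round(100 * g)
      ))
      yaml::write_yaml(
        list(
          r_C = 1, F_2D = 1.2, t_double = 90,
          f_z = regimes$f_z[i], gamma = g,
          t_end = 3000, dt = 0.5
        ),
        p,
        precision = 17
      )
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Brute-force spherical-cap volume by disc integration
#'
#' Independent numerical oracle: stacks horizontal discs of radius
#' `sqrt(R^2 - (z - (h - R))^2)` from the plane to the apex using adaptive
#' quadrature. Used to validate the closed-form cap volume; not used in the
#' simulator.
#'
#' @param h Cap height, um.
#' @param r_base Base-circle radius, um.
#' @return Cap volume, um^3.
#' @export
disc_integration_volume <- function(h, r_base) {
  R <- (r_base^2 + h^2) / (2 * h)
  zc <- h - R
  stats::integrate(function(z) pi * (R^2 - (z - zc)^2), 0, h,
    rel.tol = 1e-12
  )$value
}
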