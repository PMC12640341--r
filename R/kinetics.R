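#' Convert a doubling time to a lumped first-order rate constant
#'
#' An isolated cell dividing and maturing by a first-order process
#' `N(t) = N0 * exp(k t)` doubles every `ln(2)/k`; this inverts that law.
#'
#' @param t_double Doubling time in minutes (> 0).
#' @return Lumped rate constant `k` in min^-1.
#' @examples
#' rate_from_doubling_time(90)
#' @export
rate_from_doubling_time <- function(t_double) {
  check_scalar(t_double, "t_double", positive = TRUE)
  log(2) / t_double
}

#' Degree of growth anisotropy
#'
#' The anisotropy degree Gamma = 0.5 * k_par / k_perp compares the aggregate
#' division rate parallel to the surface against the perpendicular one.
#' Gamma = 1 is isotropic growth, Gamma > 1 laterally favoured, Gamma < 1
#' vertically favoured.
#'
#' @param k_par Rate constant parallel to the surface, min^-1.
#' @param k_perp Rate constant perpendicular to the surface, min^-1 (> 0).
#' @return Unitless anisotropy degree.
#' @examples
#' anisotropy_degree(2 / 3, 1 / 3) # isotropic, Gamma = 1
#' anisotropy_degree(5 / 6, 1 / 6) # laterally favoured, Gamma = 2.5
#' @export
anisotropy_degree <- function(k_par, k_perp) {
  check_scalar(k_par, "k_par", nonneg = TRUE)
  check_scalar(k_perp, "k_perp", nonneg = TRUE)
  if (k_perp == 0) {
    abort("undefined anisotropy: `k_perp` is zero (all growth lateral)",
      class = "colonycap_undefined_anisotropy"
    )
  }
  0.5 * k_par / k_perp
}

#' Directional growth-rate decomposition with contact inhibition
#'
#' Partitions the lumped division/growth rate constant `k` into aggregate
#' components parallel (`k_par = (f_x + f_y) k`) and perpendicular
#' (`k_perp = f_z k`) to the growth surface, assuming equal forward/backward
#' rates along each axis and `f_x = f_y`. The contact-inhibition transition
#' parameter `gamma` scales the division rate of internal (fully surrounded)
#' cells: `gamma = 0` is complete inhibition, `gamma = 1` none;
#' `beta = 1 - gamma` is the complementary inhibition extent.
#'
#' Exactly one of `k` or `t_double` sets the lumped rate; if both are given
#' and disagree, `t_double` wins with a warning.
#'
#' @param gamma Contact-inhibition transition parameter in `[0, 1]`.
#' @param f_z Fraction of the lumped rate directed perpendicular to the
#'   surface, in `[0, 1]`. Default `1/3` (isotropic).
#' @param k Lumped rate constant, min^-1 (> 0). Default derived from
#'   `t_double`.
#' @param t_double Doubling time, minutes. Default 90 min, characteristic of
#'   bacteria and yeasts.
#' @return A `growth_rates` object: list with fields `k`, `f_x`, `f_y`, `f_z`,
#'   `k_par`, `k_perp`, `gamma`, `beta` and `anisotropy` (Gamma; `NA` when
#'   `f_z = 0`, where it is undefined).
#' @examples
#' growth_rates(gamma = 0.5)                 # isotropic defaults
#' growth_rates(gamma = 0.5, f_z = 1 / 6)    # laterally favoured, Gamma = 2.5
#' @export
growth_rates <- function(gamma, f_z = 1 / 3, k = NULL, t_double = NULL) {
  check_scalar(gamma, "gamma", lo = 0, hi = 1)
  check_scalar(f_z, "f_z", lo = 0, hi = 1)
  if (is.null(k) && is.null(t_double)) t_double <- 90
  if (!is.null(t_double)) {
    check_scalar(t_double, "t_double", positive = TRUE)
    k_from_td <- rate_from_doubling_time(t_double)
    if (!is.null(k) && abs(k - k_from_td) > 1e-12 * k_from_td) {
      warn(sprintf(
        "`k` = %g min^-1 conflicts with `t_double` = %g min (ln2/t_double = %g); using `t_double`",
        k, t_double, k_from_td
      ))
    }
    k <- k_from_td
  }
  check_scalar(k, "k", positive = TRUE)
  f_x <- (1 - f_z) / 2
  k_perp <- f_z * k
  k_par <- k - k_perp # so the decomposition reassembles k exactly
  structure(
    list(
      k = k, f_x = f_x, f_y = f_x, f_z = f_z,
      k_par = k_par, k_perp = k_perp,
      gamma = gamma, beta = 1 - gamma,
      anisotropy = if (f_z > 0) 0.5 * k_par / k_perp else NA_real_
    ),
    class = "growth_rates"
  )
}

#' @export
print.growth_rates <- function(x, ...) {
  cat("<growth_rates>\n")
  cat(sprintf("  k      = %.6g min^-1 (doubling time %.4g min)\n", x$k, log(2) / x$k))
  cat(sprintf("  k_par  = %.6g min^-1  (f_x = f_y = %.4g)\n", x$k_par, x$f_x))
  cat(sprintf("  k_perp = %.6g min^-1  (f_z = %.4g)\n", x$k_perp, x$f_z))
  cat(sprintf(
    "  gamma  = %.4g (beta = %.4g)   Gamma = %s\n",
    x$gamma, x$beta,
    if (is.na(x$anisotropy)) "undefined (f_z = 0)" else format(x$anisotropy)
  ))
  invisible(x)
}

# scalar argument validation shared across constructors
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         lo = NULL, hi = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
      class = "colonycap_validation_error"
    )
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g)", name, x),
      class = "colonycap_validation_error"
    )
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be >= 0 (got %g)", name, x),
      class = "colonycap_validation_error"
    )
  }
  if (!is.null(lo) && (x < lo || x > hi)) {
    abort(sprintf("`%s` must be in [%g, %g] (got %g)", name, lo, hi, x),
      class = "colonycap_validation_error"
    )
  }
  invisible(x)
}
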