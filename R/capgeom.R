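#' Spherical-cap volume
#'
#' Volume of the solid cut from a sphere by a plane, written in terms of the
#' cap height `h` above the plane and the radius `r_base` of the circle of
#' intersection: `V = (pi/6) (h^3 + 3 h r_base^2)`. The single expression is
#' an algebraic identity valid for both minor caps (`h <= r_base`) and major
#' caps (`h > r_base`, more than a hemisphere), so no branch is needed at
#' `h = r_base`.
#'
#' @param h Cap height, um (> 0); vectorised.
#' @param r_base Base-circle radius, um (>= 0); vectorised.
#' @return Cap volume, um^3.
#' @examples
#' cap_volume(1, 1)   # hemisphere of unit radius: 2*pi/3
#' cap_volume(1.5, 1) # major cap
#' @export
cap_volume <- function(h, r_base) {
  check_cap_args(h, r_base)
  pi / 6 * (h^3 + 3 * h * r_base^2)
}

#' Greater-sphere radius of a spherical cap
#'
#' The chord relation `r_base^2 = h (2R - h)` inverts to
#' `R = (r_base^2 + h^2) / (2h)`, valid for minor and major caps alike.
#'
#' @inheritParams cap_volume
#' @return Greater-sphere (curvature) radius `R`, um.
#' @examples
#' cap_sphere_radius(0.5, 1) # 1.25
#' @export
cap_sphere_radius <- function(h, r_base) {
  check_cap_args(h, r_base)
  if (any(h == 0)) {
    abort("undefined curvature: `h` must be > 0", class = "colonycap_validation_error")
  }
  (r_base^2 + h^2) / (2 * h)
}

#' Base-circle radius from sphere radius and cap height
#'
#' `r_base = sqrt(R^2 - (R - h)^2)`, the circle cut on a sphere of radius `R`
#' by a plane at depth `h` from the cap apex side. Used to construct the
#' reduced sub-caps that share the colony's greater sphere.
#'
#' @param R Greater-sphere radius, um (> 0); vectorised.
#' @param h Cap height, um, in `(0, 2R]`; vectorised.
#' @return Base-circle radius, um.
#' @examples
#' cap_base_from_sphere(1.25, 0.5) # 1
#' @export
cap_base_from_sphere <- function(R, h) {
  if (any(!is.finite(R)) || any(R <= 0)) {
    abort("`R` must be finite and > 0", class = "colonycap_validation_error")
  }
  if (any(!is.finite(h)) || any(h <= 0) || any(h > 2 * R)) {
    abort("`h` must lie in (0, 2R]", class = "colonycap_validation_error")
  }
  sqrt(pmax(R^2 - (R - h)^2, 0))
}

#' Invert the cap-volume relation for the height
#'
#' Solves `(pi/6)(h^3 + 3 h r_base^2) = V` for the unique positive root.
#' The cubic is strictly increasing in `h`, so the root is unique; a
#' safeguarded Newton iteration (bisection fallback on the bracket
#' `[0, (6V/pi)^(1/3) + 2 r_base]`) drives the relative residual below
#' `tol`.
#'
#' @param V Cap volume, um^3 (> 0); vectorised.
#' @param r_base Base-circle radius, um (> 0); vectorised.
#' @param tol Relative convergence tolerance. Default 1e-14.
#' @param max_iter Iteration cap before a solver error is raised.
#' @return Cap height `h`, um, with `cap_volume(h, r_base) = V` to `tol`.
#' @examples
#' solve_cap_height(cap_volume(1.5, 1), 1) # 1.5
#' @export
solve_cap_height <- function(V, r_base, tol = 1e-14, max_iter = 200L) {
  if (any(!is.finite(V)) || any(V <= 0)) {
    abort("`V` must be finite and > 0", class = "colonycap_validation_error")
  }
  if (any(!is.finite(r_base)) || any(r_base <= 0)) {
    abort("`r_base` must be finite and > 0", class = "colonycap_validation_error")
  }
  n <- max(length(V), length(r_base))
  V <- rep_len(V, n)
  r_base <- rep_len(r_base, n)
  vapply(seq_len(n), function(i) {
    cap_height_newton(V[i], r_base[i], tol, max_iter)
  }, numeric(1))
}

# scalar safeguarded Newton on f(h) = (pi/6)(h^3 + 3 h r^2) - V
cap_height_newton <- function(V, r, tol, max_iter) {
  c6 <- 6 * V / pi
  lo <- 0
  hi <- c6^(1 / 3) + 2 * r
  h <- min(c6^(1 / 3), c6 / (3 * r^2)) # whichever regime bound is tighter
  if (h <= lo || h >= hi) h <- 0.5 * (lo + hi)
  for (iter in seq_len(max_iter)) {
    f <- h^3 + 3 * h * r^2 - c6
    if (f > 0) hi <- h else lo <- h
    df <- 3 * h^2 + 3 * r^2
    step <- f / df
    h_new <- h - step
    if (h_new <= lo || h_new >= hi) h_new <- 0.5 * (lo + hi)
    if (abs(h_new - h) <= tol * max(h_new, 1e-300)) {
      return(h_new)
    }
    h <- h_new
  }
  abort(
    sprintf(
      "cap height inversion did not converge: V = %g, r_base = %g, last h = %g, residual = %g",
      V, r, h, pi / 6 * (h^3 + 3 * h * r^2) - V
    ),
    class = "colonycap_solver_error"
  )
}

#' Construct a resolved spherical cap
#'
#' Bundles a cap's height and base radius with its derived greater-sphere
#' radius, volume, composite shape parameter `Omega = h/R` and receding
#' contact angle `theta`. `empty_cap()` is the degenerate zero-volume cap
#' used when a reduced sub-cap vanishes (monolayer regime).
#'
#' @param h Cap height, um (> 0).
#' @param r_base Base-circle radius, um (>= 0).
#' @return A `spherical_cap` object: list with `r_base`, `h`, `R`, `V`,
#'   `omega`, `theta` (degrees) and logical `empty`.
#' @examples
#' spherical_cap(h = 0.5, r_base = 1)
#' @export
spherical_cap <- function(h, r_base) {
  check_scalar(h, "h", positive = TRUE)
  check_scalar(r_base, "r_base", nonneg = TRUE)
  R <- cap_sphere_radius(h, r_base)
  cap <- structure(
    list(
      r_base = r_base, h = h, R = R,
      V = cap_volume(h, r_base),
      omega = h / R, theta = NA_real_, empty = FALSE
    ),
    class = "spherical_cap"
  )
  cap$theta <- contact_angle(cap)
  cap
}

#' @rdname spherical_cap
#' @export
empty_cap <- function() {
  structure(
    list(
      r_base = 0, h = 0, R = NA_real_, V = 0,
      omega = NA_real_, theta = NA_real_, empty = TRUE
    ),
    class = "spherical_cap"
  )
}

#' @export
print.spherical_cap <- function(x, ...) {
  if (x$empty) {
    cat("<spherical_cap> empty (V = 0)\n")
  } else {
    cat(sprintf(
      "<spherical_cap> r_base = %.5g um, h = %.5g um, R = %.5g um, V = %.5g um^3, Omega = %.4g, theta = %.4g deg\n",
      x$r_base, x$h, x$R, x$V, x$omega, x$theta
    ))
  }
  invisible(x)
}

#' Composite shape parameter Omega
#'
#' `Omega = h/R`: 1 for a hemisphere, approaching 2 as the cap closes into a
#' detached sphere, below 1 for flattened caps.
#'
#' @param cap A resolved [spherical_cap()].
#' @return Unitless shape parameter.
#' @export
shape_parameter <- function(cap) {
  stopifnot(inherits(cap, "spherical_cap"))
  if (cap$empty) {
    return(NA_real_)
  }
  cap$h / cap$R
}

#' Receding contact angle of a cap on the growth plane
#'
#' For caps no larger than a hemisphere,
#' `theta = 90 - asin((R - h)/R)` degrees; for major caps,
#' `theta = 90 + acos(r_base/R)`. Both branches give 90 degrees at `h = R`,
#' so theta is continuous and strictly increasing in `h` at fixed base.
#'
#' @param cap A resolved [spherical_cap()].
#' @return Contact angle in degrees, in `(0, 180)`.
#' @export
contact_angle <- function(cap) {
  stopifnot(inherits(cap, "spherical_cap"))
  if (cap$empty) {
    return(NA_real_)
  }
  deg <- 180 / pi
  if (cap$h <= cap$R) {
    90 - asin(pmin(pmax((cap$R - cap$h) / cap$R, -1), 1)) * deg
  } else {
    90 + acos(pmin(pmax(cap$r_base / cap$R, -1), 1)) * deg
  }
}

#' Upper sub-cap above the basal cell layer
#'
#' Removing one basal cell layer of thickness `2 r_C sqrt(F_2D)` from the
#' colony cap leaves a reduced cap on the same greater sphere with height
#' `h' = h - 2 r_C sqrt(F_2D)` and base radius
#' `r' = sqrt(R^2 - (R - h')^2)`. Colonies no taller than one layer return
#' the empty cap. The geometric basal-layer remainder
#' `V_L1 = V_COL - V_UC` is attached as attribute `"V_L1"`.
#'
#' @param colony A resolved colony [spherical_cap()].
#' @param packing A [packing_model()].
#' @return A `spherical_cap` (possibly empty) for the upper sub-volume.
#' @export
upper_cap <- function(colony, packing = packing_model()) {
  stopifnot(inherits(colony, "spherical_cap"), inherits(packing, "packing_model"))
  h_prime <- colony$h - 2 * packing$r_C * sqrt(packing$F_2D)
  if (colony$empty || h_prime <= 0) {
    out <- empty_cap()
    attr(out, "V_L1") <- colony$V
    return(out)
  }
  r_prime <- cap_base_from_sphere(colony$R, h_prime)
  out <- spherical_cap(h = h_prime, r_base = r_prime)
  attr(out, "V_L1") <- colony$V - out$V
  out
}

#' Interior sub-cap of the upper colony region
#'
#' Shrinking the upper cap inward by one cell radius gives the region whose
#' cells are fully surrounded: height `h'' = h - 2 r_C sqrt(F_2D) - r_C`,
#' greater sphere `R'' = R - r_C`, base `r'' = sqrt(R''^2 - (R'' - h'')^2)`.
#' Thin colonies (no interior) return the empty cap.
#'
#' @inheritParams upper_cap
#' @return A `spherical_cap` (possibly empty) for the interior region.
#' @export
interior_cap <- function(colony, packing = packing_model()) {
  stopifnot(inherits(colony, "spherical_cap"), inherits(packing, "packing_model"))
  if (colony$empty) {
    return(empty_cap())
  }
  h_pp <- colony$h - 2 * packing$r_C * sqrt(packing$F_2D) - packing$r_C
  R_pp <- colony$R - packing$r_C
  if (h_pp <= 0 || R_pp <= 0) {
    return(empty_cap())
  }
  h_pp <- min(h_pp, 2 * R_pp) # interior sphere fully enclosed
  r_pp <- cap_base_from_sphere(R_pp, h_pp)
  spherical_cap(h = h_pp, r_base = r_pp)
}

#' Midsection profile polyline of a cap
#'
#' Samples the circular arc bounding the colony's central vertical
#' cross-section: the circle of radius `R` centred at `(0, h - R)`, between
#' the contact points `x = -r_base` and `x = +r_base`, with the growth plane
#' at `z = 0` and the apex at `z = h`.
#'
#' @param cap A resolved [spherical_cap()].
#' @param n_points Number of arc samples (>= 3).
#' @return A tibble with columns `x_um`, `z_um`; endpoints lie on `z = 0`.
#' @examples
#' midsection_profile(spherical_cap(1, 1), n_points = 5)
#' @export
midsection_profile <- function(cap, n_points = 181L) {
  stopifnot(inherits(cap, "spherical_cap"))
  if (cap$empty) {
    return(tibble(x_um = numeric(), z_um = numeric()))
  }
  if (!is.numeric(n_points) || n_points < 3) {
    abort("`n_points` must be >= 3", class = "colonycap_validation_error")
  }
  zc <- cap$h - cap$R
  # sweep the polar angle from one contact point over the apex to the other
  phi_contact <- atan2(0 - zc, cap$r_base) # angle of (+r_base, 0) about centre
  phi <- seq(pi - phi_contact, phi_contact, length.out = as.integer(n_points))
  tibble(
    x_um = cap$R * cos(phi),
    z_um = pmax(zc + cap$R * sin(phi), 0)
  )
}

check_cap_args <- function(h, r_base) {
  if (any(!is.finite(h)) || any(h < 0)) {
    abort("`h` must be finite and >= 0", class = "colonycap_validation_error")
  }
  if (any(!is.finite(r_base)) || any(r_base < 0)) {
    abort("`r_base` must be finite and >= 0", class = "colonycap_validation_error")
  }
  invisible(NULL)
}
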