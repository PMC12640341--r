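#' Perimeter/internal partition of the basal layer for in-plane growth
#'
#' Cells in the outermost annulus of the basal disc (width one cell radius)
#' divide laterally at the full rate; cells inside it are contact-inhibited.
#' The perimeter count is the geometric estimate
#' `(2 sqrt(F_2D N_L1) - 1) / F_2D`, clamped to `[0, N_L1]` (the formula is
#' an area estimate, not an exact count), and the internal count is the
#' remainder, so the partition conserves `N_L1` exactly.
#'
#' @param N_L1 Basal-layer cell count (continuous, > 0); vectorised.
#' @param F_2D Two-dimensional packing efficiency (> 0).
#' @return A tibble with columns `per`, `int` (cells); rows follow `N_L1`.
#' @examples
#' basal_inplane_split(10000, F_2D = 1.2)
#' @export
basal_inplane_split <- function(N_L1, F_2D = 1.2) {
  if (any(!is.finite(N_L1)) || any(N_L1 <= 0)) {
    abort("`N_L1` must be finite and > 0", class = "colonycap_validation_error")
  }
  check_scalar(F_2D, "F_2D", positive = TRUE)
  per <- pmin(pmax((2 * sqrt(F_2D * N_L1) - 1) / F_2D, 0), N_L1)
  tibble(per = per, int = N_L1 - per)
}

#' Perimeter/internal partition of the basal layer for vertical growth
#'
#' Vertical division out of the basal layer is inhibited where layer two
#' already covers layer one. The coverage parameter
#' `eta = 1 - N_L1 / N_TOT` moves cells linearly from the perimeter class
#' `(N_L1/2)(1 - eta)` to the internal class `(N_L1/2)(1 + eta)`; an
#' uncovered layer (`N_L1 = N_TOT`) splits evenly, a fully covered one is
#' all internal.
#'
#' @param N_L1 Basal-layer cell count (> 0); vectorised.
#' @param N_TOT Total cell count (>= `N_L1`); vectorised.
#' @return A tibble with columns `per`, `int` (cells) and `eta`.
#' @examples
#' basal_vertical_split(100, 400) # eta = 0.75
#' @export
basal_vertical_split <- function(N_L1, N_TOT) {
  if (any(!is.finite(N_L1)) || any(N_L1 <= 0)) {
    abort("`N_L1` must be finite and > 0", class = "colonycap_validation_error")
  }
  if (any(!is.finite(N_TOT)) || any(N_TOT < N_L1)) {
    abort("`N_TOT` must be finite and >= `N_L1`",
      class = "colonycap_invariant_error"
    )
  }
  eta <- 1 - N_L1 / N_TOT
  tibble(
    per = N_L1 / 2 * (1 - eta),
    int = N_L1 / 2 * (1 + eta),
    eta = eta
  )
}

#' Perimeter/internal partition of the upper-cap cell population
#'
#' The interior count comes from the interior sub-cap (the upper region
#' shrunk inward by one cell radius) divided by the per-cell volume unit.
#' The upper-cap total is, under the simulator's volume bookkeeping, exactly
#' the cells not in the basal layer: pass `n_upper = N_TOT - N_L1` to use
#' that closure (the perimeter count is then `total - interior`). Without
#' `n_upper` the total is instead estimated from the geometric reduced
#' upper-cap volume — useful for a standalone cap, but it does not conserve
#' the simulator's cell count.
#'
#' @param colony A resolved colony [spherical_cap()].
#' @param packing A [packing_model()].
#' @param n_upper Optional upper-cap cell total `N_TOT - N_L1` (>= 0) from
#'   the population bookkeeping; `NULL` for the geometric estimate.
#' @return A one-row tibble with columns `per`, `int` (cells).
#' @examples
#' col <- spherical_cap(h = 4, r_base = 10)
#' upper_cap_split(col, packing_model())                # geometric estimate
#' upper_cap_split(col, packing_model(), n_upper = 294) # closure bookkeeping
#' @export
upper_cap_split <- function(colony, packing = packing_model(), n_upper = NULL) {
  stopifnot(inherits(colony, "spherical_cap"), inherits(packing, "packing_model"))
  if (is.null(n_upper)) {
    uc <- upper_cap(colony, packing)
    n_upper <- uc$V / packing$cell_volume
  } else {
    check_scalar(n_upper, "n_upper", nonneg = TRUE)
  }
  ic <- interior_cap(colony, packing)
  n_int <- min(ic$V / packing$cell_volume, n_upper)
  tibble(per = n_upper - n_int, int = n_int)
}
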