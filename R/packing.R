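#' Cell size and packing-efficiency model
#'
#' Cell counts are converted to occupied area and volume through unitless
#' packing-efficiency factors: the basal layer occupies
#' `N_L1 * F_2D * pi * r_C^2` of plate area and the colony occupies
#' `N_TOT * F_3D * (4/3) * pi * r_C^3` of volume. Unless overridden,
#' `F_3D = F_2D^(3/2)` (the 3-D analogue of the same imperfect packing).
#'
#' @param r_C Cell radius, micrometres (> 0). Default 1 (a 2-micron cell).
#' @param F_2D Two-dimensional packing efficiency (> 0). Default 1.2,
#'   reflective of imperfectly packed spheres.
#' @param F_3D Optional explicit three-dimensional packing efficiency;
#'   default `F_2D^(3/2)`.
#' @return A `packing_model` object with fields `r_C`, `F_2D`, `F_3D` and the
#'   derived `cell_volume = F_3D * (4/3) * pi * r_C^3` (volume bookkeeping
#'   unit per cell, um^3).
#' @examples
#' packing_model()          # paper-grid defaults: r_C = 1, F_2D = 1.2
#' packing_model(F_3D = 1.32)
#' @export
packing_model <- function(r_C = 1, F_2D = 1.2, F_3D = NULL) {
  check_scalar(r_C, "r_C", positive = TRUE)
  check_scalar(F_2D, "F_2D", positive = TRUE)
  if (is.null(F_3D)) F_3D <- F_2D^1.5
  check_scalar(F_3D, "F_3D", positive = TRUE)
  structure(
    list(
      r_C = r_C, F_2D = F_2D, F_3D = F_3D,
      cell_volume = F_3D * (4 / 3) * pi * r_C^3
    ),
    class = "packing_model"
  )
}

#' @export
print.packing_model <- function(x, ...) {
  cat(sprintf(
    "<packing_model> r_C = %g um, F_2D = %g, F_3D = %g (cell volume unit %.5g um^3)\n",
    x$r_C, x$F_2D, x$F_3D, x$cell_volume
  ))
  invisible(x)
}

#' Basal-layer radius from cell count
#'
#' The basal cell layer is modelled as a circle whose area accounts for
#' `N_L1` cells at packing efficiency `F_2D`:
#' `pi r_L1^2 = N_L1 F_2D pi r_C^2`, hence `r_L1 = r_C sqrt(N_L1 F_2D)`.
#'
#' @param N_L1 Basal-layer cell count (continuous, > 0); vectorised.
#' @param packing A [packing_model()].
#' @return Basal-layer radius in micrometres.
#' @examples
#' layer_radius(100, packing_model())
#' @export
layer_radius <- function(N_L1, packing = packing_model()) {
  stopifnot(inherits(packing, "packing_model"))
  if (any(!is.finite(N_L1)) || any(N_L1 <= 0)) {
    abort("`N_L1` must be finite and > 0", class = "colonycap_validation_error")
  }
  packing$r_C * sqrt(N_L1 * packing$F_2D)
}

#' Colony volume from total cell count
#'
#' `V_COL = N_TOT * F_3D * (4/3) * pi * r_C^3`, independent of any shape
#' assumption.
#'
#' @param N_TOT Total cell count (continuous, > 0); vectorised.
#' @param packing A [packing_model()].
#' @return Colony volume in cubic micrometres.
#' @examples
#' colony_volume(1000, packing_model())
#' @export
colony_volume <- function(N_TOT, packing = packing_model()) {
  stopifnot(inherits(packing, "packing_model"))
  if (any(!is.finite(N_TOT)) || any(N_TOT <= 0)) {
    abort("`N_TOT` must be finite and > 0", class = "colonycap_validation_error")
  }
  N_TOT * packing$cell_volume
}
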