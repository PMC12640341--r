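# Independent numerical oracles used across the suite.

# Spherical-cap volume by adaptive disc integration (independent of the
# closed-form expression under test).
oracle_disc_volume <- function(h, r_base) {
  R <- (r_base^2 + h^2) / (2 * h)
  zc <- h - R
  stats::integrate(function(z) pi * (R^2 - (z - zc)^2), 0, h,
    rel.tol = 1e-12
  )$value
}

# Unique positive root of (pi/6)(h^3 + 3 h r^2) = V via polyroot
# (independent of the Newton solver under test).
oracle_cap_height <- function(V, r_base) {
  roots <- polyroot(c(-6 * V / pi, 3 * r_base^2, 0, 1))
  Re(roots[abs(Im(roots)) < 1e-8 * Mod(roots) & Re(roots) > 0])[1]
}

# Random resolved caps spanning flat to nearly closed shapes.
random_caps <- function(n, seed = 1L) {
  set.seed(seed)
  h <- 10^runif(n, -2, 2)
  ratio <- 10^runif(n, -1.5, 1.5)
  data.frame(h = h, r_base = h * ratio)
}

# The reference 3 x 5 grid is expensive enough to share across tests.
.grid_cache <- new.env(parent = emptyenv())
reference_grid <- function() {
  if (is.null(.grid_cache$grid)) {
    .grid_cache$grid <- run_growth_grid(output_times = seq(0, 3000, by = 100))
  }
  .grid_cache$grid
}

paper_regimes <- function() {
  data.frame(
    regime = c("isotropic", "horizontal", "vertical"),
    f_z = c(1 / 3, 1 / 6, 1 / 2)
  )
}
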