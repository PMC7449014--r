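# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Closed-form second central moments of a continuous stadium
# (spherocylinder footprint): rectangle (L - D) x D plus two half-discs
# of radius D/2. Returns the 4*sqrt(variance) axis lengths the
# moment-ellipse convention should report in the fine-raster limit.
stadium_moment_axes <- function(L, D) {
  l <- L - D
  R <- D / 2
  a_rect <- l * D
  a_circ <- pi * R^2
  # along-axis: rectangle about centre + two shifted half-discs
  i_rect_x <- a_rect * l^2 / 12
  half_disc <- (l^2 / 4) * (a_circ / 2) + l * (2 * R^3 / 3) + pi * R^4 / 8
  var_x <- (i_rect_x + 2 * half_disc) / (a_rect + a_circ)
  # across-axis: rectangle + full disc about the centreline
  var_y <- (a_rect * D^2 / 12 + pi * R^4 / 4) / (a_rect + a_circ)
  c(major = 4 * sqrt(var_x), minor = 4 * sqrt(var_y))
}

# Central finite difference of f at x.
central_diff <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)

# Reduction-rate law r(L) = k(L) * pi * D * L * delta_c with everything
# in SI, written out directly from the correlation and the rod area --
# used as the target function for derivative checks.
rate_of_length_si <- function(L_m, D_m, delta_c, pp = physical_params()) {
  k <- 2 * pp$diffusivity_m2s / L_m +
    0.31 * (pp$diffusivity_m2s^2 * abs(pp$rho_p_kgm3 - pp$rho_c_kgm3) *
              pp$g_ms2 / pp$mu_c_kgms)^(1 / 3)
  k * pi * D_m * L_m * delta_c
}

# Build a pair of internally consistent culture snapshots where
# r = k * A * delta_c holds exactly on both sides.
consistent_snapshot <- function(day, condition, length_um, width_um,
                                delta_c_molm3) {
  a_um2 <- pi * width_um * length_um
  k <- 2 * 7.44e-10 / (length_um * 1e-6) +
    0.31 * (7.44e-10^2 * abs(1040 - 995.65) * 9.80665 / 7.9735e-4)^(1 / 3)
  culture_snapshot(day = day, condition = condition,
                   mean_length_um = length_um,
                   mean_width_um = width_um,
                   mean_area_um2 = a_um2,
                   k_ms = k,
                   rate_mol_cell_s = k * (a_um2 * 1e-12) * delta_c_molm3,
                   delta_c_molm3 = delta_c_molm3)
}
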