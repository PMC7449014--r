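#' Physical parameters for the mass-transfer correlation
#'
#' Bundles the constants needed to evaluate the liquid-to-cell
#' mass-transfer coefficient of ferricyanide for suspended cells.
#' Defaults are the values used for BG11 medium at 30 C: ferricyanide
#' diffusivity 7.44e-10 m^2/s, cell density 1040 kg/m^3, medium density
#' 995.65 kg/m^3 (assumed equal to pure water), standard gravity, and
#' water viscosity 7.9735e-4 kg/(m s).
#'
#' @param diffusivity_m2s Diffusivity D_AB of the mediator in the medium
#'   (m^2 s^-1).
#' @param rho_p_kgm3 Particle (cell) density (kg m^-3).
#' @param rho_c_kgm3 Continuous-phase (medium) density (kg m^-3).
#' @param g_ms2 Gravitational acceleration (m s^-2).
#' @param mu_c_kgms Continuous-phase dynamic viscosity (kg m^-1 s^-1).
#' @return An object of class `physical_params`.
#' @export
physical_params <- function(diffusivity_m2s = 7.44e-10,
                            rho_p_kgm3 = 1040,
                            rho_c_kgm3 = 995.65,
                            g_ms2 = 9.80665,
                            mu_c_kgms = 7.9735e-4) {
  vals <- c(diffusivity_m2s, rho_p_kgm3, rho_c_kgm3, g_ms2, mu_c_kgms)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physical parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(diffusivity_m2s = diffusivity_m2s,
                 rho_p_kgm3 = rho_p_kgm3,
                 rho_c_kgm3 = rho_c_kgm3,
                 g_ms2 = g_ms2,
                 mu_c_kgms = mu_c_kgms),
            class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat("<physical_params>\n")
  cat(sprintf("  D_AB  = %.4g m^2/s\n", x$diffusivity_m2s))
  cat(sprintf("  rho_p = %.6g kg/m^3, rho_c = %.6g kg/m^3\n",
              x$rho_p_kgm3, x$rho_c_kgm3))
  cat(sprintf("  g = %.6g m/s^2, mu_c = %.4g kg/(m s)\n",
              x$g_ms2, x$mu_c_kgms))
  invisible(x)
}

#' Validity range of the mass-transfer correlation
#'
#' The correlation is fitted for small suspended microorganisms with
#' characteristic length strictly between 1 and 600 um. Returns a status
#' rather than erroring, so callers can decide how to handle flagged
#' lengths.
#'
#' @param length_um Characteristic length d_p (um).
#' @return A list with logical `pass` and a human-readable `reason`.
#' @export
#' @examples
#' mt_validity_check(3.7)$pass # TRUE
mt_validity_check <- function(length_um) {
  if (!is.finite(length_um)) {
    return(list(pass = FALSE, reason = "length is not finite"))
  }
  if (length_um <= 1) {
    return(list(pass = FALSE,
                reason = sprintf("d_p = %g um <= 1 um lower bound", length_um)))
  }
  if (length_um >= 600) {
    return(list(pass = FALSE,
                reason = sprintf("d_p = %g um >= 600 um upper bound", length_um)))
  }
  list(pass = TRUE, reason = "1 um < d_p < 600 um")
}

#' Liquid-to-cell mass-transfer coefficient
#'
#' Evaluates the correlation for the external mass-transfer coefficient
#' of a small particle suspended in an agitated liquid:
#' `k = 2*D_AB/d_p + 0.31 * (D_AB^2 * |rho_p - rho_c| * g / mu_c)^(1/3)`.
#' The first term is molecular diffusion through the boundary layer and
#' decreases with particle size; the second accounts for free fall/rise
#' under gravity and is size-independent. The characteristic length d_p
#' is the projected cell length, since rod-shaped cells change volume
#' mainly by elongating.
#'
#' @param length_um Characteristic length d_p, the cell length (um).
#' @param params A [physical_params] object.
#' @return An object of class `mass_transfer_result` with fields `k_ms`,
#'   `diffusive_term_ms`, `gravitational_term_ms`,
#'   `characteristic_length_m` and the `validity` status.
#' @export
#' @examples
#' mass_transfer_coefficient(3.7)$k_ms
mass_transfer_coefficient <- function(length_um, params = physical_params()) {
  stopifnot(inherits(params, "physical_params"))
  if (!is.finite(length_um) || length_um <= 0) {
    stop("characteristic length must be positive and finite", call. = FALSE)
  }
  validity <- mt_validity_check(length_um)
  if (!validity$pass) {
    warning("mass-transfer correlation outside validity range: ",
            validity$reason, call. = FALSE)
  }
  d_p <- length_um * M_PER_UM
  diff_term <- 2 * params$diffusivity_m2s / d_p
  grav_term <- 0.31 * (params$diffusivity_m2s^2 *
                         abs(params$rho_p_kgm3 - params$rho_c_kgm3) *
                         params$g_ms2 / params$mu_c_kgms)^(1 / 3)
  structure(list(k_ms = diff_term + grav_term,
                 diffusive_term_ms = diff_term,
                 gravitational_term_ms = grav_term,
                 characteristic_length_m = d_p,
                 validity = validity),
            class = "mass_transfer_result")
}

#' @export
print.mass_transfer_result <- function(x, ...) {
  cat(sprintf("<mass_transfer_result> k = %.4g m/s (diffusive %.4g + gravitational %.4g) at d_p = %.3g um\n",
              x$k_ms, x$diffusive_term_ms, x$gravitational_term_ms,
              x$characteristic_length_m * UM_PER_M))
  invisible(x)
}

#' Average literature diffusivities
#'
#' Arithmetic mean of diffusivity values taken from the literature at
#' possibly different temperatures; the temperatures are carried as
#' metadata only (no temperature correction is applied).
#'
#' @param diffusivities_m2s Numeric vector of diffusivities (m^2 s^-1).
#' @param temperatures_c Optional matching temperatures (Celsius).
#' @return A list with `diffusivity_m2s` (the mean), `values` and
#'   `temperatures_c`.
#' @export
average_diffusivity <- function(diffusivities_m2s, temperatures_c = NULL) {
  if (length(diffusivities_m2s) == 0) {
    stop("empty diffusivity list", call. = FALSE)
  }
  stopifnot(all(is.finite(diffusivities_m2s)), all(diffusivities_m2s > 0))
  list(diffusivity_m2s = mean(diffusivities_m2s),
       values = diffusivities_m2s,
       temperatures_c = temperatures_c)
}

#' First-order error propagation for the mass-transfer coefficient
#'
#' The gravitational term does not depend on length, so only the
#' diffusive term contributes: `sigma_k = (2*D_AB/L^2) * sigma_L` with
#' everything in SI.
#'
#' @param length_um Mean characteristic length (um).
#' @param length_sem_um Standard error of the mean length (um).
#' @param params A [physical_params] object.
#' @return Standard error of k (m s^-1).
#' @export
propagate_k_error <- function(length_um, length_sem_um,
                              params = physical_params()) {
  stopifnot(inherits(params, "physical_params"))
  if (!is.finite(length_sem_um) || length_sem_um < 0) {
    stop("length SEM must be non-negative", call. = FALSE)
  }
  if (length_um <= 0) stop("length must be positive", call. = FALSE)
  L <- length_um * M_PER_UM
  (2 * params$diffusivity_m2s / L^2) * (length_sem_um * M_PER_UM)
}

#' Order of magnitude
#'
#' Defined as `floor(log10(x))`, e.g. 4.02e-4 has order -4.
#'
#' @param x Positive numeric.
#' @return Integer order of magnitude.
#' @export
order_of_magnitude <- function(x) {
  stopifnot(all(x > 0))
  as.integer(floor(log10(x)))
}
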