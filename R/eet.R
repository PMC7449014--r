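#' Bulk-to-surface mediator concentration difference
#'
#' Under mass-transfer limitation the per-cell reduction rate obeys
#' Fick's law, `r = k * A * ([Fe3+]_b - [Fe3+]_s)`; inverting gives the
#' concentration difference driving diffusion, `delta_c = r / (k * A)` in
#' mol m^-3. A negative value is physically suspect under mass-transfer
#' limitation and is flagged, not rejected. The standard error combines
#' the relative errors of r, k and A in quadrature (first-order,
#' uncorrelated).
#'
#' @param rate_mol_cell_s Per-cell reduction rate r (mol cell^-1 s^-1).
#' @param k_ms Mass-transfer coefficient k (m s^-1), or a
#'   `mass_transfer_result`.
#' @param area_m2 Geometric cell surface area A (m^2).
#' @param rate_sem,k_sem,area_sem Optional standard errors (same units as
#'   the respective quantity); default 0.
#' @return A list with `delta_c_molm3`, `sem` and logical `suspect`
#'   (negative difference).
#' @export
conc_difference <- function(rate_mol_cell_s, k_ms, area_m2,
                            rate_sem = 0, k_sem = 0, area_sem = 0) {
  if (inherits(k_ms, "mass_transfer_result")) k_ms <- k_ms$k_ms
  if (k_ms == 0 || area_m2 == 0) {
    stop("k and A must be non-zero", call. = FALSE)
  }
  dc <- rate_mol_cell_s / (k_ms * area_m2)
  if (!is.finite(dc)) stop("non-finite concentration difference", call. = FALSE)
  rel <- function(s, x) if (x == 0) 0 else s / abs(x)
  sem <- abs(dc) * sqrt(rel(rate_sem, rate_mol_cell_s)^2 +
                          rel(k_sem, k_ms)^2 +
                          rel(area_sem, area_m2)^2)
  suspect <- dc < 0
  if (suspect) {
    warning("negative bulk-to-surface concentration difference: ",
            "physically suspect under mass-transfer limitation",
            call. = FALSE)
  }
  list(delta_c_molm3 = dc, sem = sem, suspect = suspect)
}

#' Decoupled length-derivative of the reduction rate
#'
#' Elongation has two opposing effects on the mass-transfer-limited
#' reduction rate `r = k(L) * A(L) * delta_c`: the area `A = pi*D*L`
#' grows (`dA/dL = pi*D`), while the diffusive part of the mass-transfer
#' coefficient shrinks (`dk/dL = -2*D_AB/L^2`; the gravitational term is
#' length-independent). The chain rule separates the two channels:
#' `dr/dL = [A * (-2*D_AB/L^2) + k * pi*D] * delta_c`.
#'
#' All geometry is supplied in micrometres and converted internally; the
#' returned derivatives are in mol cell^-1 s^-1 per metre of length.
#'
#' @param length_um Cell length L (um).
#' @param width_um Cell width D (um).
#' @param k_ms Mass-transfer coefficient (m/s), or a
#'   `mass_transfer_result`.
#' @param area_m2 Cell surface area (m^2); checked against pi*D*L.
#' @param delta_c_molm3 Bulk-to-surface concentration difference
#'   (mol m^-3); use 1 for a unit-driving-force comparison.
#' @param diffusivity_m2s Mediator diffusivity D_AB (m^2 s^-1).
#' @return A list with `dr_dL` and its two channels `k_channel`
#'   (flux loss from the shrinking boundary-layer coefficient) and
#'   `a_channel` (gain from the growing area).
#' @export
rate_length_derivative <- function(length_um, width_um, k_ms, area_m2,
                                   delta_c_molm3,
                                   diffusivity_m2s = physical_params()$diffusivity_m2s) {
  if (inherits(k_ms, "mass_transfer_result")) k_ms <- k_ms$k_ms
  stopifnot(length_um > 0, width_um > 0, k_ms > 0, area_m2 > 0,
            diffusivity_m2s > 0)
  L <- length_um * M_PER_UM
  D <- width_um * M_PER_UM
  a_expect <- pi * D * L
  if (abs(area_m2 - a_expect) / a_expect > 1e-6) {
    warning(sprintf(
      "area %.6g m^2 inconsistent with pi*D*L = %.6g m^2", area_m2, a_expect),
      call. = FALSE)
  }
  k_channel <- area_m2 * (-2 * diffusivity_m2s / L^2) * delta_c_molm3
  a_channel <- k_ms * pi * D * delta_c_molm3
  list(dr_dL = k_channel + a_channel,
       k_channel = k_channel,
       a_channel = a_channel)
}

#' Per-timepoint culture summary
#'
#' One population snapshot of a culture at a sampling day: weighted mean
#' morphology, derived mass-transfer quantities and the measured EET
#' rate, each with its uncertainty. This is the interchange record
#' between the measurement pipeline and the fractional-difference / MER
#' analysis.
#'
#' @param day Sampling day.
#' @param condition Culture label (e.g. "diluted", "control").
#' @param mean_length_um,sem_length Weighted mean cell length (um) and
#'   its SEM.
#' @param mean_width_um Mean cell width (um).
#' @param mean_area_um2,sem_area Mean cell surface area (um^2) and its
#'   uncertainty.
#' @param k_ms,sem_k Mass-transfer coefficient (m/s) and SEM.
#' @param rate_mol_cell_s,sem_rate Per-cell reduction rate and SEM.
#' @param delta_c_molm3,sem_delta_c Bulk-to-surface concentration
#'   difference (mol m^-3) and SEM.
#' @return An object of class `culture_snapshot` (also a one-row data
#'   frame).
#' @export
culture_snapshot <- function(day, condition,
                             mean_length_um, sem_length = 0,
                             mean_width_um = NA_real_,
                             mean_area_um2 = NA_real_, sem_area = 0,
                             k_ms = NA_real_, sem_k = 0,
                             rate_mol_cell_s = NA_real_, sem_rate = 0,
                             delta_c_molm3 = NA_real_, sem_delta_c = 0) {
  df <- data.frame(day = day, condition = condition,
                   mean_length_um = mean_length_um, sem_length = sem_length,
                   mean_width_um = mean_width_um,
                   mean_area_um2 = mean_area_um2, sem_area = sem_area,
                   k_ms = k_ms, sem_k = sem_k,
                   rate_mol_cell_s = rate_mol_cell_s, sem_rate = sem_rate,
                   delta_c_molm3 = delta_c_molm3, sem_delta_c = sem_delta_c,
                   stringsAsFactors = FALSE)
  class(df) <- c("culture_snapshot", class(df))
  df
}

#' Fractional differences between test and control cultures
#'
#' For each quantity x in {k, A, k*A, delta_c, r} computes the fractional
#' difference `Delta x = (x_test - x_control) / x_control`. The product
#' term is composed multiplicatively, `Delta(k*A) = (1 + Delta k) *
#' (1 + Delta A) - 1`, so that when all five quantities derive from one
#' consistent dataset the identity `(1 + Delta r) = (1 + Delta k) *
#' (1 + Delta A) * (1 + Delta delta_c)` holds.
#'
#' @param test,control `culture_snapshot` rows at the same day (the
#'   "test" culture is conventionally the continuously diluted one).
#' @return A list with `dk`, `dA`, `dkA`, `ddc`, `dr`.
#' @export
fractional_differences <- function(test, control) {
  if (!is.na(test$day) && !is.na(control$day) && test$day != control$day) {
    stop("snapshots are not from matched timepoints", call. = FALSE)
  }
  frac <- function(xt, xc, what) {
    if (is.na(xc) || xc == 0) {
      stop("zero or missing control value for ", what, call. = FALSE)
    }
    (xt - xc) / xc
  }
  dk <- frac(test$k_ms, control$k_ms, "k")
  dA <- frac(test$mean_area_um2, control$mean_area_um2, "A")
  list(dk = dk,
       dA = dA,
       dkA = (1 + dk) * (1 + dA) - 1,
       ddc = frac(test$delta_c_molm3, control$delta_c_molm3, "delta_c"),
       dr = frac(test$rate_mol_cell_s, control$rate_mol_cell_s, "r"))
}

MER_THRESHOLD <- 1 / (1 + exp(-1)) # ~0.7311, equal contributions

#' Morphology effect ratio
#'
#' A single bounded measure of whether a difference in EET rate between
#' two cultures is driven by morphology or by physiology/metabolism:
#' `MER = 1 / (1 + exp(-|Delta(k*A)| / |Delta(delta_c)|))`. The sigmoid
#' constrains the raw ratio to (0.5, 1). At a ratio of 1 the MER is
#' ~0.7311 and the two contributions are equal; above that morphology
#' dominates, below it physiology/metabolism dominates.
#'
#' @param dkA Fractional difference in the morphology product k*A.
#' @param ddc Fractional difference in the bulk-to-surface concentration
#'   difference (the physiology channel).
#' @param tol Tolerance for calling the ratio balanced at the threshold.
#' @return A list with `mer`, `dominance` ("morphology", "physiology" or
#'   "balanced") and `denominator_zero`.
#' @export
#' @examples
#' morphology_effect_ratio(0.2, 0.2)$mer # 0.7310586
morphology_effect_ratio <- function(dkA, ddc, tol = 1e-6) {
  denom_zero <- abs(ddc) == 0
  if (denom_zero) {
    if (abs(dkA) == 0) {
      # no differences at all: sigmoid(0/0) taken as the balanced point
      return(list(mer = 0.5, dominance = "physiology",
                  denominator_zero = TRUE))
    }
    warning("denominator-zero: |Delta(delta_c)| = 0, MER taken as the ",
            "limit 1", call. = FALSE)
    return(list(mer = 1, dominance = "morphology", denominator_zero = TRUE))
  }
  ratio <- abs(dkA) / abs(ddc)
  mer <- 1 / (1 + exp(-ratio))
  dominance <- if (abs(mer - MER_THRESHOLD) <= tol) {
    "balanced"
  } else if (mer > MER_THRESHOLD) "morphology" else "physiology"
  list(mer = mer, dominance = dominance, denominator_zero = FALSE)
}

#' Correlate concentration differences with a morphological property
#'
#' Pearson product-moment correlation (two-tailed) between the estimated
#' bulk-to-surface concentration differences and a paired series of a
#' morphological property (length, width, area or surface-to-volume
#' ratio), used to check whether the physiology channel co-varies with
#' morphology.
#'
#' @param delta_c_series Numeric vector of concentration differences.
#' @param property_series Paired numeric vector of the property.
#' @return A list with `r`, `p` and `n`.
#' @export
correlate_with_properties <- function(delta_c_series, property_series) {
  n <- length(delta_c_series)
  if (n != length(property_series)) {
    stop("series must be paired (equal length)", call. = FALSE)
  }
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (sd(delta_c_series) == 0 || sd(property_series) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  ct <- cor.test(delta_c_series, property_series, method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
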