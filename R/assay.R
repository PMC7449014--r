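#' Ferricyanide assay time series
#'
#' Holds one filtrate-concentration time course from a mediator-reduction
#' assay: sampling times in minutes (starting at 0, strictly increasing),
#' ferricyanide concentration in mM at each time, and the cell
#' concentration of the assayed suspension. Concentrations only; the
#' analysis is volume-independent.
#'
#' @param times_min Sampling times (min), strictly increasing, first 0.
#' @param concentration_mM Filtrate ferricyanide concentrations (mM).
#' @param cell_conc_per_ml Cell concentration (cells ml^-1).
#' @return An object of class `assay_series`.
#' @export
assay_series <- function(times_min, concentration_mM, cell_conc_per_ml) {
  if (length(times_min) < 2) stop("need >= 2 time points", call. = FALSE)
  if (length(times_min) != length(concentration_mM)) {
    stop("times and concentrations must have equal length", call. = FALSE)
  }
  if (times_min[1] != 0) stop("first sampling time must be 0", call. = FALSE)
  if (any(diff(times_min) <= 0)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  if (any(concentration_mM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (!is.finite(cell_conc_per_ml) || cell_conc_per_ml <= 0) {
    stop("cell concentration must be positive", call. = FALSE)
  }
  structure(list(times_min = as.numeric(times_min),
                 concentration_mM = as.numeric(concentration_mM),
                 cell_conc_per_ml = as.numeric(cell_conc_per_ml)),
            class = "assay_series")
}

#' Convert filtrate absorbance to mediator concentration
#'
#' Beer-Lambert conversion `c = A / (epsilon * path)` with the
#' ferricyanide extinction coefficient 1.05204 mM^-1 cm^-1 A^-1 and a
#' 1 cm cuvette by default.
#'
#' @param absorbance Absorbance readings (A units), non-negative.
#' @param extinction_mM_cm Extinction coefficient (mM^-1 cm^-1 A^-1).
#' @param path_cm Optical path length (cm).
#' @return Concentration (mM).
#' @export
#' @examples
#' absorbance_to_conc(1.05204) # 1 mM
absorbance_to_conc <- function(absorbance, extinction_mM_cm = 1.05204,
                               path_cm = 1) {
  if (extinction_mM_cm <= 0 || path_cm <= 0) {
    stop("extinction coefficient and path length must be positive",
         call. = FALSE)
  }
  if (any(absorbance < 0)) {
    stop("absorbance must be non-negative", call. = FALSE)
  }
  absorbance / (extinction_mM_cm * path_cm)
}

#' Per-cell mediator reduction rate from an assay time course
#'
#' The average reduction rate over the assay window is the OLS slope of
#' the concentration-vs-time graph. The absolute slope (mM min^-1) is
#' converted to mol L^-1 s^-1 and divided by the cell concentration in
#' cells L^-1, giving a per-cell rate in mol cell^-1 s^-1.
#'
#' @param series An [assay_series].
#' @return A list with `rate_mol_cell_s`, the raw `slope_mM_min` (signed)
#'   and its standard error `slope_se_mM_min`.
#' @export
reduction_rate <- function(series) {
  stopifnot(inherits(series, "assay_series"))
  fit <- lm(concentration_mM ~ times_min,
            data = data.frame(times_min = series$times_min,
                              concentration_mM = series$concentration_mM))
  slope <- unname(coef(fit)["times_min"])
  # collinear fixtures fit perfectly; the summary warning is expected
  slope_se <- suppressWarnings(
    summary(fit)$coefficients["times_min", "Std. Error"])
  # mM/min -> mol/L/min (x 1e-3) -> mol/L/s (/60); cells/ml -> cells/L (x 1000)
  rate_mol_L_s <- abs(slope) * 1e-3 / S_PER_MIN
  cells_per_L <- series$cell_conc_per_ml * ML_PER_L
  list(rate_mol_cell_s = rate_mol_L_s / cells_per_L,
       slope_mM_min = slope,
       slope_se_mM_min = slope_se)
}

#' Summarise replicate reduction rates
#'
#' Mean and standard error of the per-cell rate across biological
#' replicates; replicate-level rates are the unit of error.
#'
#' @param rates_mol_cell_s Numeric vector of per-replicate rates.
#' @return List with `rate_mol_cell_s` (mean), `sem` and `n`.
#' @export
summarise_rates <- function(rates_mol_cell_s) {
  n <- length(rates_mol_cell_s)
  if (n == 0) stop("no replicate rates supplied", call. = FALSE)
  sem <- if (n > 1) sd(rates_mol_cell_s) / sqrt(n) else 0
  list(rate_mol_cell_s = mean(rates_mol_cell_s), sem = sem, n = n)
}

#' Normalise a reduction rate by chlorophyll a content
#'
#' Divides a concentration-basis rate (pM min^-1) by the chlorophyll a
#' concentration (nM) to give pM nM_ChlA^-1 min^-1.
#'
#' @param rate_pM_min Reduction rate on a concentration basis (pM min^-1).
#' @param chla_nM Chlorophyll a concentration (nM).
#' @return Rate in pM nM_ChlA^-1 min^-1.
#' @export
normalise_by_chla <- function(rate_pM_min, chla_nM) {
  if (chla_nM <= 0) stop("chlorophyll a concentration must be positive",
                         call. = FALSE)
  rate_pM_min / chla_nM
}

#' Convert a chlorophyll-normalised rate between reporting units
#'
#' `mM mM_ChlA^-1 h^-1` and `pM nM_ChlA^-1 min^-1` differ by a factor
#' 1000/60: the concentration ratio gains 1e9/1e6 = 1000 and the time
#' base changes from hours to minutes.
#'
#' @param rate_mM_per_mM_h Rate in mM mM_ChlA^-1 h^-1.
#' @return Rate in pM nM_ChlA^-1 min^-1.
#' @export
#' @examples
#' chla_rate_to_pM_nM_min(0.9) # 15
chla_rate_to_pM_nM_min <- function(rate_mM_per_mM_h) {
  rate_mM_per_mM_h * 1000 / 60
}

#' Convert a per-cell rate from nmol per 10^6 cells per hour
#'
#' Literature EET rates are often reported as nmol (10^6 cells)^-1 h^-1;
#' this converts to the coherent per-cell SI rate mol cell^-1 s^-1.
#'
#' @param rate_nmol_per_1e6cells_h Rate in nmol (10^6 cells)^-1 h^-1.
#' @return Rate in mol cell^-1 s^-1.
#' @export
#' @examples
#' cell_rate_to_mol_cell_s(3) # 8.33e-19
cell_rate_to_mol_cell_s <- function(rate_nmol_per_1e6cells_h) {
  rate_nmol_per_1e6cells_h * 1e-9 / 1e6 / S_PER_H
}
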