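## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
## state afterwards: generators are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("a seed is mandatory for every generator", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

rtruncnorm_rej <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) stop("infeasible truncation (empty support)", call. = FALSE)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("infeasible truncation (empty support)", call. = FALSE)
    }
    return(rep(mean, n))
  }
  out <- numeric(0)
  for (i in 1:1000) {
    draw <- rnorm(2 * n + 10, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("infeasible truncation (acceptance rate ~ 0)", call. = FALSE)
}

#' Sample a synthetic rod-cell population with known ground truth
#'
#' Draws projected lengths from a truncated Normal distribution and
#' widths from a linear width-length law with Gaussian noise, then
#' derives the true spherocylinder area, volume and surface-to-volume
#' ratio for every cell. Defaults emulate an exponential-phase
#' *Synechococcus* population: mean length 3.7 um with population SD
#' 0.8 um truncated to [1.8, 8] um, width ~ 1.05 + 0.04 L (so width
#' grows by under 0.2 um across the 3-7 um length range) with 0.08 um
#' noise.
#'
#' @param n_cells Number of cells.
#' @param length_mean_um,length_sd_um,length_bounds_um Truncated-Normal
#'   length distribution (um).
#' @param length_family `"normal"` (truncated) or `"lognormal"`
#'   (truncated; `length_mean_um`/`length_sd_um` are then the log-scale
#'   location/scale through `exp`).
#' @param width_intercept_um,width_slope,width_noise_sd_um Linear
#'   width model D = a + b L + eps.
#' @param min_width_um Lower clamp protecting D > 0.
#' @param seed Mandatory RNG seed.
#' @return A data frame `cell_id, length_um, width_um, orientation_deg,
#'   area_um2, volume_um3, sv_ratio_per_um`.
#' @export
sample_population <- function(n_cells = 3000,
                              length_mean_um = 3.7,
                              length_sd_um = 0.8,
                              length_bounds_um = c(1.8, 8),
                              length_family = c("normal", "lognormal"),
                              width_intercept_um = 1.05,
                              width_slope = 0.04,
                              width_noise_sd_um = 0.08,
                              min_width_um = 0.3,
                              seed) {
  length_family <- match.arg(length_family)
  stopifnot(n_cells >= 1, length_sd_um >= 0, width_noise_sd_um >= 0,
            min_width_um > 0)
  with_seed(seed, {
    L <- if (length_family == "normal") {
      rtruncnorm_rej(n_cells, length_mean_um, length_sd_um,
                     length_bounds_um[1], length_bounds_um[2])
    } else {
      exp(rtruncnorm_rej(n_cells, log(length_mean_um), length_sd_um,
                         log(length_bounds_um[1]), log(length_bounds_um[2])))
    }
    D <- width_intercept_um + width_slope * L +
      rnorm(n_cells, 0, width_noise_sd_um)
    D <- pmin(pmax(D, min_width_um), L) # keep L >= D > 0
    dims <- cell_dims(L, D)
    data.frame(cell_id = seq_len(n_cells),
               length_um = dims$length_um,
               width_um = dims$width_um,
               orientation_deg = runif(n_cells, 0, 180),
               area_um2 = rod_area(dims),
               volume_um3 = rod_volume(dims),
               sv_ratio_per_um = sv_ratio(dims))
  })
}

# Rasterise one spherocylinder footprint: pixels whose centre lies
# within D/2 of the central segment. Returns linear indices.
rasterise_rod <- function(nr, nc, centre_rc, length_px, width_px, theta_deg) {
  half_seg <- max((length_px - width_px) / 2, 0)
  radius <- width_px / 2
  th <- theta_deg * pi / 180
  ux <- cos(th); uy <- sin(th) # x = col, y = row
  ext <- ceiling(length_px / 2 + 1)
  rs <- max(1, floor(centre_rc[1] - ext)):min(nr, ceiling(centre_rc[1] + ext))
  cs <- max(1, floor(centre_rc[2] - ext)):min(nc, ceiling(centre_rc[2] + ext))
  if (!length(rs) || !length(cs)) return(integer(0))
  grid_r <- rep(rs, times = length(cs))
  grid_c <- rep(cs, each = length(rs))
  dx <- grid_c - centre_rc[2]
  dy <- grid_r - centre_rc[1]
  tproj <- pmin(pmax(dx * ux + dy * uy, -half_seg), half_seg)
  d2 <- (dx - tproj * ux)^2 + (dy - tproj * uy)^2
  inside <- d2 <= radius^2
  (grid_c[inside] - 1L) * nr + grid_r[inside]
}

gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-rad:rad)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  tmp <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) { # rows
    tmp <- tmp + k[i] * shift_matrix(m, (-rad:rad)[i], 0, 0)
  }
  for (i in seq_along(k)) { # cols
    out <- out + k[i] * shift_matrix(tmp, 0, (-rad:rad)[i], 0)
  }
  out
}

#' Render a synthetic fluorescence image of rod cells
#'
#' Places cells on a canvas (uniformly at random with a minimum
#' centre-to-centre separation, unless overlap is allowed), rasterises
#' their spherocylinder footprints, convolves with an isotropic Gaussian
#' point-spread function, and adds background plus Gaussian read noise
#' (optional Poisson shot noise). Ground-truth per-cell masks are
#' returned for recovery scoring.
#'
#' @param cells Data frame from [sample_population()] (uses `length_um`,
#'   `width_um`, `orientation_deg`), or any data frame with those
#'   columns.
#' @param canvas_px `c(rows, cols)` canvas size.
#' @param pixel_size_um Pixel size (um/px).
#' @param amplitude Foreground fluorescence amplitude above background.
#' @param background Background intensity level.
#' @param psf_sigma_px Gaussian PSF sigma (px); 0 disables blur.
#' @param noise_sd Gaussian read-noise SD; 0 disables.
#' @param poisson_noise Add Poisson shot noise on the noiseless image.
#' @param min_separation_um Minimum centre separation; ignored if
#'   `allow_overlap`.
#' @param allow_overlap Place cells without separation checks.
#' @param max_retries Placement retries per cell before failing.
#' @param seed Mandatory RNG seed.
#' @return A list: `image` (numeric matrix), `truth_labels` (integer
#'   matrix of ground-truth footprints; later cells overwrite earlier
#'   on overlap), `placements` (data frame with centres and true
#'   dimensions in px and um).
#' @export
render_image <- function(cells,
                         canvas_px = c(256, 256),
                         pixel_size_um = 0.1,
                         amplitude = 180,
                         background = 20,
                         psf_sigma_px = 1,
                         noise_sd = 4,
                         poisson_noise = FALSE,
                         min_separation_um = 6,
                         allow_overlap = FALSE,
                         max_retries = 200,
                         seed) {
  stopifnot(all(canvas_px >= 16), pixel_size_um > 0, noise_sd >= 0)
  nr <- canvas_px[1]; nc <- canvas_px[2]
  n <- nrow(cells)
  with_seed(seed, {
    len_px <- cells$length_um / pixel_size_um
    wid_px <- cells$width_um / pixel_size_um
    if (any(len_px > min(nr, nc) - 4)) {
      stop("cells do not fit the canvas", call. = FALSE)
    }
    sep_px <- min_separation_um / pixel_size_um
    centres <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      margin <- len_px[i] / 2 + 2
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
        if (allow_overlap || i == 1 ||
            all(sqrt(rowSums((centres[seq_len(i - 1), , drop = FALSE] -
                                matrix(cand, i - 1, 2, byrow = TRUE))^2)) >=
                sep_px)) {
          centres[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("placement failure: minimum separation infeasible after ",
             max_retries, " retries (cell ", i, ")", call. = FALSE)
      }
    }
    truth <- matrix(0L, nr, nc)
    signal <- matrix(0, nr, nc)
    for (i in seq_len(n)) {
      idx <- rasterise_rod(nr, nc, centres[i, ], len_px[i], wid_px[i],
                           cells$orientation_deg[i])
      truth[idx] <- i
      signal[idx] <- amplitude
    }
    img <- gaussian_blur(signal, psf_sigma_px) + background
    if (poisson_noise) img <- matrix(rpois(nr * nc, pmax(img, 0)), nr, nc)
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    list(image = img,
         truth_labels = truth,
         placements = data.frame(cell_id = seq_len(n),
                                 centre_row = centres[, 1],
                                 centre_col = centres[, 2],
                                 length_px = len_px,
                                 width_px = wid_px,
                                 orientation_deg = cells$orientation_deg,
                                 length_um = cells$length_um,
                                 width_um = cells$width_um))
  })
}

#' Simulate a ferricyanide assay time course
#'
#' Generates a linearly decaying filtrate-concentration trace whose
#' slope is implied by a known per-cell reduction rate and the cell
#' concentration, with additive Gaussian spectrophotometer noise.
#' Default sampling follows the standard assay protocol: 1 mM starting
#' ferricyanide, aliquots at 0, 10, 30 and 120 min.
#'
#' @param true_rate_mol_cell_s Ground-truth per-cell rate.
#' @param cell_conc_per_ml Cell concentration (cells ml^-1).
#' @param c0_mM Starting mediator concentration (mM).
#' @param times_min Sampling times (min).
#' @param noise_sd_mM Additive Gaussian noise SD (mM); 0 for noiseless.
#' @param seed Mandatory RNG seed.
#' @return An [assay_series]; the implied `slope_mM_min` is attached as
#'   an attribute.
#' @export
simulate_assay <- function(true_rate_mol_cell_s, cell_conc_per_ml,
                           c0_mM = 1.0, times_min = c(0, 10, 30, 120),
                           noise_sd_mM = 0.005, seed) {
  if (noise_sd_mM < 0) stop("negative noise SD", call. = FALSE)
  stopifnot(true_rate_mol_cell_s >= 0, cell_conc_per_ml > 0)
  cells_per_L <- cell_conc_per_ml * ML_PER_L
  slope_mM_min <- true_rate_mol_cell_s * cells_per_L * S_PER_MIN * 1e3
  conc <- c0_mM - slope_mM_min * times_min
  if (any(conc < 0)) {
    warning("decay exhausts the mediator within the assay window: ",
            "trace truncated at 0", call. = FALSE)
    conc <- pmax(conc, 0)
  }
  with_seed(seed, {
    if (noise_sd_mM > 0) {
      conc <- pmax(conc + rnorm(length(conc), 0, noise_sd_mM), 0)
    }
    out <- assay_series(times_min, conc, cell_conc_per_ml)
    attr(out, "slope_mM_min") <- -slope_mM_min
    out
  })
}

#' Simulate an OD750 growth curve from Gompertz parameters
#'
#' Evaluates the Gompertz log relative population at the sampling days,
#' converts to cell concentration and OD750, and applies multiplicative
#' log-normal noise. Default sampling every 2 days over 3 weeks mirrors
#' a typical batch-culture cadence (which is too sparse to pin down an
#' hours-scale lag time -- a feature, used in tests).
#'
#' @param a_log,mu_max,lambda_lag Gompertz parameters (see
#'   [gompertz_model()]).
#' @param sampling_days Sampling times (days).
#' @param n0_per_ml Inoculum concentration (cells ml^-1).
#' @param noise_cv Multiplicative noise coefficient of variation; 0 for
#'   noiseless.
#' @param conversion_ml_per_cell_cm OD conversion factor.
#' @param seed Mandatory RNG seed.
#' @return A data frame `day, od750, dilution_factor, cells_per_ml`
#'   (OD is the undiluted equivalent; `dilution_factor` 1).
#' @export
simulate_growth <- function(a_log = 3, mu_max = 0.5, lambda_lag = 1,
                            sampling_days = seq(0, 20, by = 2),
                            n0_per_ml = 1e6,
                            noise_cv = 0.05,
                            conversion_ml_per_cell_cm = 2.95e-9,
                            seed) {
  stopifnot(noise_cv >= 0, n0_per_ml > 0)
  y <- gompertz_model(sampling_days, a_log, mu_max, lambda_lag)
  cells <- n0_per_ml * exp(y)
  with_seed(seed, {
    if (noise_cv > 0) {
      cells <- cells * exp(rnorm(length(cells), 0, noise_cv))
    }
    data.frame(day = sampling_days,
               od750 = cells * conversion_ml_per_cell_cm,
               dilution_factor = 1,
               cells_per_ml = cells)
  })
}
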