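#' Projected cell dimensions
#'
#' Constructs a validated pair of projected pole-to-pole length `L` and
#' width `D` (micrometres) for one rod-shaped cell, as measured from a 2-D
#' fluorescence image. A rod's projected major axis is at least its minor
#' axis, so `length_um >= width_um > 0` is enforced.
#'
#' @param length_um Projected pole-to-pole length L (um).
#' @param width_um Projected width D (um).
#' @return An object of class `cell_dims` with fields `length_um`,
#'   `width_um`. Both arguments are recycled to a common length, so the
#'   object can hold a whole population.
#' @export
#' @examples
#' cell_dims(3.7, 1.2)
cell_dims <- function(length_um, width_um) {
  if (length(length_um) != length(width_um)) {
    n <- max(length(length_um), length(width_um))
    length_um <- rep_len(length_um, n)
    width_um <- rep_len(width_um, n)
  }
  if (any(!is.finite(length_um)) || any(!is.finite(width_um))) {
    stop("cell dimensions must be finite", call. = FALSE)
  }
  if (any(width_um <= 0)) {
    stop("shape violation: width must be strictly positive", call. = FALSE)
  }
  if (any(length_um < width_um)) {
    stop("shape violation: projected length must be >= width (degenerate rod)",
         call. = FALSE)
  }
  structure(list(length_um = as.numeric(length_um),
                 width_um = as.numeric(width_um)),
            class = "cell_dims")
}

#' @export
print.cell_dims <- function(x, ...) {
  n <- length(x$length_um)
  cat(sprintf("<cell_dims> %d cell%s, L %.3g-%.3g um, D %.3g-%.3g um\n",
              n, if (n == 1) "" else "s",
              min(x$length_um), max(x$length_um),
              min(x$width_um), max(x$width_um)))
  invisible(x)
}

as_cell_dims <- function(x) {
  if (inherits(x, "cell_dims")) return(x)
  if (is.data.frame(x)) return(cell_dims(x$length_um, x$width_um))
  stop("cannot interpret input as cell dimensions", call. = FALSE)
}

#' Spherocylinder outer-membrane surface area
#'
#' Geometric surface area of a rod-shaped cell modelled as a cylinder of
#' length `L - D` capped by two hemispheres of diameter `D`:
#' `A = pi*D*(L - D) + pi*D^2 = pi*D*L` (um^2). At `L = D` the model
#' degenerates to a sphere with `A = pi*D^2`.
#'
#' @param dims A [cell_dims] object (or data frame with `length_um`,
#'   `width_um` columns).
#' @return Numeric vector of areas (um^2).
#' @export
#' @examples
#' rod_area(cell_dims(4, 1)) # 4*pi
rod_area <- function(dims) {
  dims <- as_cell_dims(dims)
  pi * dims$width_um * dims$length_um
}

#' Spherocylinder cell volume
#'
#' Volume of the rod model: `V = pi/4 * D^2 * (L - D/3)` (um^3), i.e. the
#' capped cylinder `pi/4*D^2*(L - D) + pi/6*D^3`. At `L = D` this is the
#' sphere volume `pi*D^3/6`.
#'
#' @inheritParams rod_area
#' @return Numeric vector of volumes (um^3).
#' @export
rod_volume <- function(dims) {
  dims <- as_cell_dims(dims)
  pi / 4 * dims$width_um^2 * (dims$length_um - dims$width_um / 3)
}

#' Surface-to-volume ratio of the rod model
#'
#' `A/V = 4*L / (D * (L - D/3))` (um^-1). Decreases monotonically with
#' length at fixed width and approaches the cylinder limit `4/D`; at the
#' sphere limit `L = D` it equals `6/D`.
#'
#' @inheritParams rod_area
#' @return Numeric vector of ratios (um^-1).
#' @export
sv_ratio <- function(dims) {
  dims <- as_cell_dims(dims)
  rod_area(dims) / rod_volume(dims)
}

#' Correct projected dimensions for the periplasmic space
#'
#' When the mediator is reduced at the plasma membrane rather than the
#' outer membrane, measured outer dimensions overstate the reactive
#' surface: both `L` and `D` are reduced by twice the periplasmic-space
#' thickness. For *Synechococcus* the thickness is taken as that of the
#' peptidoglycan layer, 10 nm.
#'
#' @inheritParams rod_area
#' @param thickness_nm Periplasmic-space thickness (nm); default 10.
#' @return A corrected [cell_dims] object.
#' @export
periplasm_correct <- function(dims, thickness_nm = 10) {
  dims <- as_cell_dims(dims)
  if (thickness_nm < 0) stop("thickness must be non-negative", call. = FALSE)
  d_um <- 2 * thickness_nm * 1e-3
  L <- dims$length_um - d_um
  D <- dims$width_um - d_um
  if (any(L <= 0) || any(D <= 0)) {
    stop("dimension underflow: corrected dimension would be <= 0",
         call. = FALSE)
  }
  cell_dims(L, D)
}

cell_property <- function(dims, property_name) {
  switch(property_name,
         width = dims$width_um,
         area = rod_area(dims),
         sv_ratio = sv_ratio(dims),
         stop("unknown property: ", property_name, call. = FALSE))
}

#' Binned length-to-property regression
#'
#' Reproduces the population regressions relating cell length to width,
#' geometric surface area and surface-to-volume ratio. Cells are
#' discretised by projected length into bins of `bin_width_um` (default
#' 0.4 um, left-closed, anchored at the minimum observed length); bins
#' with fewer than `min_bin_count` cells (default 50) are dropped; the
#' per-bin mean property is regressed on the per-bin mean length by
#' least squares weighted by bin count (a bin mean of n cells has
#' variance proportional to 1/n), linear by default with an optional
#' quadratic term.
#'
#' @inheritParams rod_area
#' @param property_name One of `"width"`, `"area"`, `"sv_ratio"`.
#' @param bin_width_um Length-bin width (um).
#' @param min_bin_count Minimum number of cells per qualifying bin.
#' @param degree Polynomial degree of the OLS model (1 linear, 2
#'   quadratic).
#' @return An object of class `length_regression` holding the `lm` fit,
#'   the bin summary table, and the fitted length range.
#' @export
bin_regress <- function(dims, property_name,
                        bin_width_um = 0.4, min_bin_count = 50,
                        degree = 1) {
  dims <- as_cell_dims(dims)
  property_name <- match.arg(property_name, c("width", "area", "sv_ratio"))
  stopifnot(bin_width_um > 0, min_bin_count >= 1, degree %in% c(1, 2))
  L <- dims$length_um
  y <- cell_property(dims, property_name)
  idx <- floor((L - min(L)) / bin_width_um)
  # right edge: the maximum falls in the last true bin, not a new one
  idx[L == max(L) & idx > 0 & (L - min(L)) / bin_width_um == idx] <-
    idx[L == max(L)][1]
  counts <- tapply(L, idx, length)
  keep <- names(counts)[counts >= min_bin_count]
  if (length(keep) < 2) {
    stop("insufficient bins: need >= 2 bins with at least ", min_bin_count,
         " cells", call. = FALSE)
  }
  sel <- as.character(idx) %in% keep
  bins <- data.frame(
    bin = as.integer(keep),
    n = as.integer(counts[keep]),
    mean_length_um = as.numeric(tapply(L[sel], idx[sel], mean)),
    mean_property = as.numeric(tapply(y[sel], idx[sel], mean))
  )
  bins <- bins[order(bins$mean_length_um), , drop = FALSE]
  # each response is a bin mean with variance sigma^2/n, so weight by n
  fit <- if (degree == 1) {
    lm(mean_property ~ mean_length_um, data = bins, weights = bins$n)
  } else {
    lm(mean_property ~ mean_length_um + I(mean_length_um^2), data = bins,
       weights = bins$n)
  }
  structure(list(property_name = property_name,
                 bin_width_um = bin_width_um,
                 min_bin_count = min_bin_count,
                 degree = degree,
                 bins = bins,
                 fit = fit,
                 length_range = range(bins$mean_length_um)),
            class = "length_regression")
}

#' @export
print.length_regression <- function(x, ...) {
  cat(sprintf("<length_regression> %s ~ length (degree %d), %d bins of %.2g um\n",
              x$property_name, x$degree, nrow(x$bins), x$bin_width_um))
  print(coef(x$fit))
  invisible(x)
}

#' Predict a mean cell property from the length regression
#'
#' Evaluates the fitted regression at the supplied mean lengths and
#' reports, as the prediction's uncertainty, the half-width between the
#' prediction and its pointwise 95% confidence bound on the mean
#' response. Lengths outside the fitted range are extrapolations and are
#' flagged with a warning (not an error).
#'
#' @param reg A `length_regression` from [bin_regress()].
#' @param lengths_um Lengths (um) at which to predict.
#' @return A data frame with `length_um`, `predicted`, `ci95_lo`,
#'   `ci95_hi`, `uncertainty` (half-width to the 95% bound) and an
#'   `extrapolated` flag.
#' @export
predict_mean_property <- function(reg, lengths_um) {
  stopifnot(inherits(reg, "length_regression"))
  nd <- data.frame(mean_length_um = as.numeric(lengths_um))
  p <- predict(reg$fit, newdata = nd, interval = "confidence", level = 0.95)
  extra <- lengths_um < reg$length_range[1] | lengths_um > reg$length_range[2]
  if (any(extra)) {
    warning("prediction outside the fitted length range (",
            sprintf("%.3g-%.3g um", reg$length_range[1], reg$length_range[2]),
            "): extrapolation flagged", call. = FALSE)
  }
  data.frame(length_um = as.numeric(lengths_um),
             predicted = p[, "fit"],
             ci95_lo = p[, "lwr"],
             ci95_hi = p[, "upr"],
             uncertainty = (p[, "upr"] - p[, "lwr"]) / 2,
             extrapolated = extra,
             row.names = NULL)
}
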