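#' Binarise a fluorescence image
#'
#' Separates cell foreground from background by intensity thresholding.
#' Three methods are available:
#'
#' * `"otsu"` (default): Otsu's histogram threshold (256 bins,
#'   deterministic, parameter-free) followed by a contrast-to-noise
#'   guard -- if the two classes' means differ by less than `min_cnr`
#'   pooled within-class standard deviations the image is judged to
#'   contain no separable foreground (e.g. pure noise) and an empty
#'   mask is returned with a warning. Best when foreground occupies a
#'   substantial image fraction at good contrast.
#' * `"robust"`: for dim, sparse objects where Otsu's balanced-class
#'   assumption fails. The image is Gaussian-smoothed (`smooth_sigma_px`,
#'   a matched filter against read noise), candidate foreground is
#'   detected above `median + k_mad * MAD`, and the final threshold is
#'   refined to the half-way level between the background and
#'   foreground medians -- a half-maximum criterion that preserves the
#'   object boundary under symmetric blur.
#' * `"manual"`: a fixed threshold, no smoothing, no guards.
#'
#' A constant image yields an empty mask with a warning under either
#' automatic method. Convention: pixel centres at integer coordinates,
#' row-major, origin top-left (row 1, column 1).
#'
#' @param image Numeric matrix of intensities (rows x columns).
#' @param method `"otsu"`, `"robust"` or `"manual"`.
#' @param manual_threshold Threshold when `method = "manual"`; pixels
#'   strictly above it are foreground.
#' @param min_cnr Minimum contrast-to-noise ratio for the Otsu guard.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma for the robust
#'   method (px); 0 disables.
#' @param k_mad Robust detection threshold in MADs above the median.
#' @return Logical mask of the same dimensions, with the chosen
#'   threshold attached as attribute `"threshold"`.
#' @export
binarise <- function(image, method = c("otsu", "robust", "manual"),
                     manual_threshold = NULL, min_cnr = 3,
                     smooth_sigma_px = 1, k_mad = 3) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), all(is.finite(image)))
  empty <- function(reason) {
    warning(reason, call. = FALSE)
    mask <- matrix(FALSE, nrow(image), ncol(image))
    attr(mask, "threshold") <- NA_real_
    mask
  }
  if (method == "manual") {
    if (is.null(manual_threshold)) {
      stop("manual method requires manual_threshold", call. = FALSE)
    }
    mask <- image > manual_threshold
    attr(mask, "threshold") <- manual_threshold
    return(mask)
  }
  rng <- range(image)
  if (rng[1] == rng[2]) {
    return(empty("constant image: no threshold separable, returning empty mask"))
  }
  if (method == "robust") {
    xs <- gaussian_blur(image, smooth_sigma_px)
    med <- stats::median(xs)
    s <- stats::mad(xs)
    if (s == 0) {
      # flat majority background with exact levels: mid-range split
      thr <- (min(xs) + max(xs)) / 2
    } else {
      detect <- xs > med + k_mad * s
      if (!any(detect)) {
        return(empty("no pixels above the robust detection threshold: empty mask"))
      }
      thr <- (med + stats::median(xs[detect])) / 2
    }
    mask <- xs > thr
    attr(mask, "threshold") <- thr
    return(mask)
  }
  thr <- otsu_threshold(image)
  fg <- image > thr
  m_fg <- mean(image[fg]); m_bg <- mean(image[!fg])
  v_fg <- if (sum(fg) > 1) var(image[fg]) else 0
  v_bg <- if (sum(!fg) > 1) var(image[!fg]) else 0
  pooled_sd <- sqrt((v_fg + v_bg) / 2)
  # zero within-class variance means perfectly separated levels
  cnr <- if (pooled_sd == 0) Inf else (m_fg - m_bg) / pooled_sd
  if (is.nan(cnr) || cnr < min_cnr) {
    return(empty(sprintf(
      "no separable foreground (contrast-to-noise %.2f < %.2f): empty mask",
      cnr, min_cnr)))
  }
  attr(fg, "threshold") <- thr
  fg
}

# Otsu's method on a 256-bin histogram of the (min,max)-scaled image.
otsu_threshold <- function(image, n_bins = 256) {
  rng <- range(image)
  scaled <- (image - rng[1]) / (rng[2] - rng[1])
  h <- tabulate(pmin(floor(scaled * n_bins) + 1L, n_bins), nbins = n_bins)
  p <- h / sum(h)
  midpoints <- (seq_len(n_bins) - 0.5) / n_bins
  omega <- cumsum(p)
  mu <- cumsum(p * midpoints)
  mu_t <- mu[n_bins]
  sigma_b2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b2[!is.finite(sigma_b2)] <- -Inf
  k <- which.max(sigma_b2)
  # threshold on the original intensity scale
  rng[1] + (k / n_bins) * (rng[2] - rng[1])
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_matrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Label connected foreground components
#'
#' 8-connected component labelling by iterative minimum-label
#' propagation (labels flow to the smallest neighbouring label until a
#' fixed point), which is exact and needs no recursion.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same size; 0 is background, components
#'   are numbered 1..n in raster order of their first pixel.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask != 0
  labels <- matrix(Inf, nrow(mask), ncol(mask))
  labels[mask] <- which(mask) # unique seed label per pixel
  offsets <- cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, times = 3))
  offsets <- offsets[!(offsets[, 1] == 0 & offsets[, 2] == 0), , drop = FALSE]
  repeat {
    nxt <- labels
    for (i in seq_len(nrow(offsets))) {
      nxt <- pmin(nxt, shift_matrix(labels, offsets[i, 1], offsets[i, 2], Inf))
    }
    nxt[!mask] <- Inf
    if (identical(nxt, labels)) break
    labels <- nxt
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (any(mask)) {
    ids <- sort(unique(labels[mask]))
    out[mask] <- match(labels[mask], ids)
  }
  out
}

#' Fit moment-equivalent ellipses to labelled regions
#'
#' For each 8-connected foreground component, superimposes the ellipse
#' with the same normalised second central moments as the region and
#' reports its axis lengths: each axis is `4 * sqrt(eigenvalue)` of the
#' pixel-coordinate covariance matrix `[[mu20, mu11], [mu11, mu02]]`
#' (population-normalised, with the 1/12 unit-pixel-square correction
#' added to the diagonal so single-pixel-wide regions keep a positive
#' minor axis; for an exact ellipse this recovers its axes, for an
#' a x b rectangle it preserves the a/b axis ratio exactly).
#' Eccentricity is `sqrt(1 - lambda_minor/lambda_major)`.
#'
#' @param mask Logical matrix (or 0/1 matrix).
#' @return A data frame with one row per region: `region_id`, `area_px`,
#'   `centroid_row`, `centroid_col`, `major_axis_px`, `minor_axis_px`,
#'   `eccentricity`, `orientation_deg` (major axis vs. the column/x
#'   axis), `touches_border`. The label matrix is attached as attribute
#'   `"labels"`. Empty mask gives zero rows.
#' @export
fit_ellipses <- function(mask) {
  labels <- label_components(mask)
  n <- max(labels)
  cols <- c("region_id", "area_px", "centroid_row", "centroid_col",
            "major_axis_px", "minor_axis_px", "eccentricity",
            "orientation_deg", "touches_border")
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$touches_border <- logical(0)
    attr(out, "labels") <- labels
    return(out)
  }
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    sel <- lab == i
    ri <- r[sel]; ci <- c[sel]
    m <- length(ri)
    rbar <- mean(ri); cbar <- mean(ci)
    # population second central moments + unit-pixel spread
    mu_rr <- mean((ri - rbar)^2) + 1 / 12
    mu_cc <- mean((ci - cbar)^2) + 1 / 12
    mu_rc <- mean((ri - rbar) * (ci - cbar))
    tr <- mu_cc + mu_rr
    det_disc <- sqrt(((mu_cc - mu_rr) / 2)^2 + mu_rc^2)
    l_major <- tr / 2 + det_disc
    l_minor <- tr / 2 - det_disc
    theta <- 0.5 * atan2(2 * mu_rc, mu_cc - mu_rr) # vs. column (x) axis
    data.frame(region_id = i,
               area_px = m,
               centroid_row = rbar,
               centroid_col = cbar,
               major_axis_px = 4 * sqrt(l_major),
               minor_axis_px = 4 * sqrt(l_minor),
               eccentricity = sqrt(1 - l_minor / l_major),
               orientation_deg = theta * 180 / pi,
               touches_border = any(ri == 1 | ri == nr | ci == 1 | ci == nc))
  }))
  attr(out, "labels") <- labels
  out
}

#' Quality-control configuration for morphometry
#'
#' Cut-off criteria excluding regions that are out of focus (too
#' round), overlapping or dividing (too thick), too small (debris), or
#' clipped at the image border. The criteria are field-standard; the
#' default values are calibration choices against the package's
#' synthetic generator and should be tuned per microscope.
#'
#' @param min_eccentricity Minimum ellipse eccentricity (rods are
#'   elongated; out-of-focus blobs are round).
#' @param max_minor_axis_um Maximum minor axis (um); merged/dividing
#'   cells are thicker than a single rod.
#' @param min_area_px Minimum region area in pixels (rejects debris).
#' @param exclude_border Drop regions touching the image border.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(min_eccentricity = 0.6, max_minor_axis_um = 2.0,
                      min_area_px = 20, exclude_border = TRUE) {
  stopifnot(min_eccentricity >= 0, max_minor_axis_um >= 0, min_area_px >= 0)
  structure(list(min_eccentricity = min_eccentricity,
                 max_minor_axis_um = max_minor_axis_um,
                 min_area_px = min_area_px,
                 exclude_border = exclude_border),
            class = "qc_config")
}

#' Apply quality-control filters to fitted regions
#'
#' Each rejection is tagged with the first rule it failed, so the
#' rejection log partitions the removed regions exhaustively. Filtering
#' never increases the region count.
#'
#' @param regions Data frame from [fit_ellipses()].
#' @param cfg A [qc_config].
#' @param pixel_size_um Pixel size (um/px), needed for the minor-axis
#'   cut-off.
#' @return A list with `kept` (surviving rows) and `rejections` (data
#'   frame `region_id`, `rule_failed`, `value`).
#' @export
qc_filter <- function(regions, cfg = qc_config(), pixel_size_um = 1) {
  stopifnot(inherits(cfg, "qc_config"), pixel_size_um > 0)
  rej <- data.frame(region_id = integer(0), rule_failed = character(0),
                    value = numeric(0))
  keep <- rep(TRUE, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    if (cfg$exclude_border && rg$touches_border) {
      rej <- rbind(rej, data.frame(region_id = rg$region_id,
                                   rule_failed = "border", value = 1))
      keep[i] <- FALSE
    } else if (rg$area_px < cfg$min_area_px) {
      rej <- rbind(rej, data.frame(region_id = rg$region_id,
                                   rule_failed = "min_area_px",
                                   value = rg$area_px))
      keep[i] <- FALSE
    } else if (rg$eccentricity < cfg$min_eccentricity) {
      rej <- rbind(rej, data.frame(region_id = rg$region_id,
                                   rule_failed = "min_eccentricity",
                                   value = rg$eccentricity))
      keep[i] <- FALSE
    } else if (rg$minor_axis_px * pixel_size_um > cfg$max_minor_axis_um) {
      rej <- rbind(rej, data.frame(region_id = rg$region_id,
                                   rule_failed = "max_minor_axis_um",
                                   value = rg$minor_axis_px * pixel_size_um))
      keep[i] <- FALSE
    }
  }
  list(kept = regions[keep, , drop = FALSE], rejections = rej)
}

#' Convert fitted axis lengths to physical cell dimensions
#'
#' @param regions Data frame from [fit_ellipses()] (possibly QC
#'   filtered).
#' @param pixel_size_um Pixel size (um/px), positive.
#' @return A [cell_dims] object (lengths = major axes, widths = minor
#'   axes, both in um). Empty input gives an empty data frame.
#' @export
to_microns <- function(regions, pixel_size_um) {
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel size must be positive", call. = FALSE)
  }
  if (nrow(regions) == 0) {
    return(data.frame(length_um = numeric(0), width_um = numeric(0)))
  }
  cell_dims(regions$major_axis_px * pixel_size_um,
            regions$minor_axis_px * pixel_size_um)
}

#' Weighted population statistics across images
#'
#' Images contribute different numbers of cells, so the population mean
#' is the count-weighted mean of per-image means. The spread of the
#' per-image means (the sampling distribution of the mean) is summarised
#' by the count-weighted standard deviation, and the SEM by that SD over
#' the square root of the number of images.
#'
#' @param per_image_means Numeric vector of per-image mean values.
#' @param per_image_counts Matching vector of per-image cell counts
#'   (>= 1).
#' @return A list with `mean`, `sd`, `sem`, `n_images`, `n_cells` and a
#'   `degenerate` flag (single image: SD and SEM are 0 by convention).
#' @export
weighted_population_stats <- function(per_image_means, per_image_counts) {
  m <- length(per_image_means)
  if (m == 0) stop("empty input", call. = FALSE)
  if (m != length(per_image_counts)) {
    stop("means and counts must have equal length", call. = FALSE)
  }
  if (any(per_image_counts < 1)) stop("counts must be >= 1", call. = FALSE)
  w <- per_image_counts / sum(per_image_counts)
  mu <- sum(w * per_image_means)
  degenerate <- m == 1
  sdv <- if (degenerate) 0 else sqrt(sum(w * (per_image_means - mu)^2))
  list(mean = mu,
       sd = sdv,
       sem = if (degenerate) 0 else sdv / sqrt(m),
       n_images = m,
       n_cells = sum(per_image_counts),
       degenerate = degenerate)
}

#' Two-sample Student's t test for cell lengths
#'
#' Pooled-variance Student's t by default (Welch optional), with
#' one- or two-tailed alternatives. Identical groups give t = 0, p = 1
#' rather than an error, so degenerate comparisons in automated sweeps
#' are well-defined; two groups that are each constant but different
#' give |t| = Inf, p = 0.
#'
#' @param group_a,group_b Numeric vectors, n >= 2 each.
#' @param alternative `"two.sided"`, `"greater"` (A > B) or `"less"`.
#' @param var_equal Pool the variances (classic Student); `FALSE` for
#'   Welch.
#' @return A list with `t`, `df`, `p`.
#' @export
compare_lengths <- function(group_a, group_b,
                            alternative = c("two.sided", "greater", "less"),
                            var_equal = TRUE) {
  alternative <- match.arg(alternative)
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("need n >= 2 per group", call. = FALSE)
  if (!var_equal) {
    tt <- stats::t.test(group_a, group_b, alternative = alternative,
                        var.equal = FALSE)
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value))
  }
  va <- var(group_a); vb <- var(group_b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  diff <- mean(group_a) - mean(group_b)
  if (sp2 == 0) {
    if (diff == 0) {
      t_stat <- 0
    } else {
      t_stat <- sign(diff) * Inf
    }
  } else {
    t_stat <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t_stat), df),
              greater = pt(t_stat, df, lower.tail = FALSE),
              less = pt(t_stat, df))
  list(t = t_stat, df = df, p = p)
}
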