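# Builds a complete on-disk synthetic dataset for the pipeline: per-cell
# dimension tables for two conditions over several days, plus noiseless
# assay traces whose per-cell rates are constructed as r = k * A *
# delta_c from each condition's own measured morphology. With equal
# delta_c on both sides any rate difference is purely morphological.
make_pipeline_fixture <- function(dir, days = c(5, 9),
                                  delta_c = c(diluted = 4e-6, control = 4e-6),
                                  n_per_day = 1200, n_images = 6,
                                  cell_conc = 6.78e8, seed = 1,
                                  identical_conditions = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conds <- c("diluted", "control")
  spec <- list(
    diluted = list(length_mean = 3.7, width_int = 1.13),
    control = list(length_mean = 4.4, width_int = 1.05))
  if (identical_conditions) spec$control <- spec$diluted

  cell_rows <- list()
  pops <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    for (di in seq_along(days)) {
      s <- if (identical_conditions) 100 + seed + di else
        100 * ci + seed + di
      pop <- sample_population(n_cells = n_per_day,
                               length_mean_um = spec[[cond]]$length_mean,
                               length_sd_um = 0.5,
                               length_bounds_um = c(2, 7.5),
                               width_intercept_um = spec[[cond]]$width_int,
                               width_slope = 0.04,
                               width_noise_sd_um = 0.05,
                               seed = s)
      img_id <- paste0(cond, "_d", days[di], "_img",
                       rep(seq_len(n_images), length.out = n_per_day))
      cell_rows[[paste(cond, di)]] <- data.frame(
        sample_id = cond, day = days[di], replicate = 1,
        image_id = img_id, cell_id = pop$cell_id,
        length_um = pop$length_um, width_um = pop$width_um)
      pops[[paste(cond, days[di])]] <- pop
    }
  }
  cells <- do.call(rbind, cell_rows)
  cell_csv <- file.path(dir, "cells.csv")
  write_cell_dimensions(cells, cell_csv)

  # regressions exactly as the pipeline will fit them
  regs <- lapply(setNames(conds, conds), function(cond) {
    sub <- cells[cells$sample_id == cond, ]
    bin_regress(cell_dims(sub$length_um, sub$width_um), "area")
  })

  assay_rows <- list()
  meta_rows <- list()
  for (cond in conds) {
    for (d in days) {
      sub <- cells[cells$sample_id == cond & cells$day == d, ]
      per_image <- split(sub$length_um, sub$image_id)
      wl <- weighted_population_stats(vapply(per_image, mean, 0),
                                      vapply(per_image, length, 0L))
      area <- predict_mean_property(regs[[cond]], wl$mean)$predicted
      k <- mass_transfer_coefficient(wl$mean)$k_ms
      rate <- k * area * 1e-12 * delta_c[[cond]]
      trace <- simulate_assay(rate, cell_conc, noise_sd_mM = 0, seed = 1)
      sid <- paste0(cond, "_d", d)
      for (rep in 1:3) {
        assay_rows[[paste(sid, rep)]] <- data.frame(
          sample_id = sid, replicate = rep,
          time_min = trace$times_min,
          absorbance = trace$concentration_mM * 1.05204)
      }
      meta_rows[[sid]] <- data.frame(
        sample_id = sid, condition = cond, day = d,
        cell_conc_per_ml = cell_conc, extinction_mM_cm = 1.05204,
        path_cm = 1)
    }
  }
  assay_csv <- file.path(dir, "assay.csv")
  meta_csv <- file.path(dir, "assay_meta.csv")
  utils::write.csv(do.call(rbind, assay_rows), assay_csv,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, meta_rows), meta_csv,
                   row.names = FALSE, quote = FALSE)
  list(cell_csv = cell_csv, assay_csv = assay_csv, meta_csv = meta_csv,
       days = days)
}
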