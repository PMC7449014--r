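#' Pipeline configuration
#'
#' Validated configuration for the end-to-end analysis. Unknown keys are
#' rejected so typos cannot silently fall back to defaults. Can be built
#' in code or loaded from a JSON file.
#'
#' @param physical_params A [physical_params] object or a named list of
#'   overrides for its fields.
#' @param qc A [qc_config] or named list of overrides.
#' @param regression Named list: `bin_width_um` (default 0.4),
#'   `min_bin_count` (default 50), `degree` (1 or 2).
#' @param conventions Named list: `doubling_convention` ("decadic" or
#'   "natural"), `test_condition` (default "diluted"),
#'   `control_condition` (default "control"), `rate_alternative`
#'   (one-tailed test direction for rate comparisons, default
#'   "greater").
#' @param extinction_mM_cm Mediator extinction coefficient default used
#'   when the assay metadata omits it.
#' @param min_cell_conc_per_ml Below this cell concentration the assay
#'   is unlikely to be mass-transfer limited; a warning is issued.
#' @param output_dir Where `run_pipeline` writes its CSV/JSON outputs.
#' @param seed Seed recorded in the provenance and used by any
#'   stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(physical_params = eetmorph::physical_params(),
                            qc = qc_config(),
                            regression = list(),
                            conventions = list(),
                            extinction_mM_cm = 1.05204,
                            min_cell_conc_per_ml = 1e7,
                            output_dir = NULL,
                            seed = 1L) {
  if (is.list(physical_params) && !inherits(physical_params, "physical_params")) {
    physical_params <- do.call(eetmorph::physical_params, physical_params)
  }
  if (is.list(qc) && !inherits(qc, "qc_config")) {
    qc <- do.call(qc_config, qc)
  }
  reg_defaults <- list(bin_width_um = 0.4, min_bin_count = 50, degree = 1)
  unknown <- setdiff(names(regression), names(reg_defaults))
  if (length(unknown)) {
    stop("unknown regression key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  regression <- modifyList(reg_defaults, regression)
  conv_defaults <- list(doubling_convention = "decadic",
                        test_condition = "diluted",
                        control_condition = "control",
                        rate_alternative = "greater")
  unknown <- setdiff(names(conventions), names(conv_defaults))
  if (length(unknown)) {
    stop("unknown conventions key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  conventions <- modifyList(conv_defaults, conventions)
  structure(list(physical_params = physical_params,
                 qc = qc,
                 regression = regression,
                 conventions = conventions,
                 extinction_mM_cm = extinction_mM_cm,
                 min_cell_conc_per_ml = min_cell_conc_per_ml,
                 output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' The file may contain any subset of the [pipeline_config()] arguments;
#' unknown top-level keys are rejected.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("physical_params", "qc", "regression", "conventions",
               "extinction_mM_cm", "min_cell_conc_per_ml", "output_dir",
               "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

file_digest <- function(path) unname(tools::md5sum(path))

config_digest <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg$output_dir <- NULL # analysis settings only, not where they land
  jsonlite::write_json(unclass_deep(cfg), tmp, auto_unbox = TRUE, digits = NA)
  file_digest(tmp)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full morphology-vs-physiology analysis pipeline
#'
#' Executes the proposed algorithm end to end for a pair of cultures
#' (test vs control) sampled on matched days:
#' per-day weighted mean cell lengths from the per-cell table; pooled
#' length-to-area regression per condition; mean area predicted from
#' the regression at each day's mean length; mass-transfer coefficient
#' from the mean length; per-replicate assay slopes giving per-cell
#' reduction rates; inversion of the rate law for the bulk-to-surface
#' concentration difference; per-day fractional differences and the
#' MER. Choosing a mass-transfer-limiting cell/mediator concentration
#' combination is the experimenter's responsibility: the pipeline
#' records the concentrations used and warns when the cell
#' concentration falls below `min_cell_conc_per_ml`.
#'
#' @param cfg A [pipeline_config()].
#' @param cell_csv Per-cell dimension CSV (see
#'   [read_cell_dimensions()]); `sample_id` must match the conditions
#'   named in the config conventions.
#' @param assay_csv Assay readings CSV (see [read_assay()]).
#' @param assay_meta_csv Per-sample assay metadata CSV (see
#'   [read_assay_metadata()]).
#' @return A `run_report` list: `snapshots` (data frame), `mer` (data
#'   frame), `regressions` (per condition), and `provenance` (config
#'   hash, input digests, package version, seed). If
#'   `cfg$output_dir` is set, also writes `snapshots.csv`, `mer.csv`
#'   and `report.json` there.
#' @export
run_pipeline <- function(cfg, cell_csv, assay_csv, assay_meta_csv) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cells <- stage("cell-dimensions", read_cell_dimensions(cell_csv))
  assay <- stage("assay", read_assay(assay_csv))
  meta <- stage("assay-metadata", read_assay_metadata(assay_meta_csv))

  test_lab <- cfg$conventions$test_condition
  ctrl_lab <- cfg$conventions$control_condition
  conds <- c(test_lab, ctrl_lab)
  if (!all(conds %in% cells$sample_id)) {
    stop(sprintf("pipeline stage 'cell-dimensions' failed: conditions %s not both present in sample_id",
                 paste(conds, collapse = " & ")), call. = FALSE)
  }

  # pooled per-condition regressions over all days (population law)
  regs <- stage("stereology-regression", {
    lapply(setNames(conds, conds), function(cond) {
      sub <- cells[cells$sample_id == cond, ]
      dims <- cell_dims(sub$length_um, sub$width_um)
      list(area = bin_regress(dims, "area",
                              bin_width_um = cfg$regression$bin_width_um,
                              min_bin_count = cfg$regression$min_bin_count,
                              degree = cfg$regression$degree),
           sv_ratio = bin_regress(dims, "sv_ratio",
                                  bin_width_um = cfg$regression$bin_width_um,
                                  min_bin_count = cfg$regression$min_bin_count,
                                  degree = cfg$regression$degree))
    })
  })

  days <- sort(unique(cells$day))
  snapshots <- stage("snapshot-assembly", {
    do.call(rbind, lapply(days, function(d) {
      do.call(rbind, lapply(conds, function(cond) {
        sub <- cells[cells$sample_id == cond & cells$day == d, ]
        if (nrow(sub) == 0) return(NULL)
        per_image <- split(sub$length_um, sub$image_id)
        wstats <- weighted_population_stats(vapply(per_image, mean, 0),
                                            vapply(per_image, length, 0L))
        area_pred <- predict_mean_property(regs[[cond]]$area, wstats$mean)
        mt <- mass_transfer_coefficient(wstats$mean, cfg$physical_params)
        k_sem <- propagate_k_error(wstats$mean, wstats$sem,
                                   cfg$physical_params)

        m <- meta[meta$condition == cond & meta$day == d, ]
        if (nrow(m) == 0) {
          stop(sprintf("no assay metadata for condition '%s' day %g",
                       cond, d))
        }
        if (any(m$cell_conc_per_ml < cfg$min_cell_conc_per_ml)) {
          warning(sprintf(
            "condition '%s' day %g: cell concentration %.3g cells/ml is below %.3g; reduction may not be mass-transfer limited",
            cond, d, min(m$cell_conc_per_ml), cfg$min_cell_conc_per_ml),
            call. = FALSE)
        }
        rates <- unlist(lapply(m$sample_id, function(sid) {
          sm <- m[m$sample_id == sid, ]
          rows <- assay[assay$sample_id == sid, ]
          if (nrow(rows) == 0) stop("no assay readings for sample ", sid)
          vapply(split(rows, rows$replicate), function(rr) {
            rr <- rr[order(rr$time_min), ]
            conc <- absorbance_to_conc(rr$absorbance,
                                       extinction_mM_cm = sm$extinction_mM_cm,
                                       path_cm = sm$path_cm)
            reduction_rate(assay_series(rr$time_min, conc,
                                        sm$cell_conc_per_ml))$rate_mol_cell_s
          }, 0)
        }))
        rsum <- summarise_rates(rates)
        dc <- conc_difference(rsum$rate_mol_cell_s, mt$k_ms,
                              area_pred$predicted * M2_PER_UM2,
                              rate_sem = rsum$sem, k_sem = k_sem,
                              area_sem = area_pred$uncertainty * M2_PER_UM2)
        culture_snapshot(day = d, condition = cond,
                         mean_length_um = wstats$mean,
                         sem_length = wstats$sem,
                         mean_width_um = mean(sub$width_um),
                         mean_area_um2 = area_pred$predicted,
                         sem_area = area_pred$uncertainty,
                         k_ms = mt$k_ms, sem_k = k_sem,
                         rate_mol_cell_s = rsum$rate_mol_cell_s,
                         sem_rate = rsum$sem,
                         delta_c_molm3 = dc$delta_c_molm3,
                         sem_delta_c = dc$sem)
      }))
    }))
  })

  mer <- stage("mer", {
    do.call(rbind, lapply(days, function(d) {
      tsnap <- snapshots[snapshots$day == d & snapshots$condition == test_lab, ]
      csnap <- snapshots[snapshots$day == d & snapshots$condition == ctrl_lab, ]
      if (nrow(tsnap) == 0 || nrow(csnap) == 0) return(NULL)
      fd <- fractional_differences(tsnap, csnap)
      m <- morphology_effect_ratio(fd$dkA, fd$ddc)
      data.frame(day = d, dk = fd$dk, dA = fd$dA, dkA = fd$dkA,
                 ddc = fd$ddc, dr = fd$dr, mer = m$mer,
                 dominance = m$dominance, stringsAsFactors = FALSE)
    }))
  })

  provenance <- list(
    package_version = as.character(utils::packageVersion("eetmorph")),
    seed = cfg$seed,
    config_md5 = config_digest(cfg),
    inputs = list(cell_csv = file_digest(cell_csv),
                  assay_csv = file_digest(assay_csv),
                  assay_meta_csv = file_digest(assay_meta_csv)))

  report <- structure(list(snapshots = snapshots, mer = mer,
                           regressions = regs, provenance = provenance),
                      class = "run_report")

  if (!is.null(cfg$output_dir)) {
    stage("write-outputs", {
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      write_snapshots(snapshots, file.path(cfg$output_dir, "snapshots.csv"))
      write_mer_report(mer, file.path(cfg$output_dir, "mer.csv"))
      jsonlite::write_json(
        list(mer = mer, snapshots = snapshots, provenance = provenance),
        file.path(cfg$output_dir, "report.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    })
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d snapshot rows over %d day(s)\n",
              nrow(x$snapshots), length(unique(x$snapshots$day))))
  print(x$mer)
  invisible(x)
}
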