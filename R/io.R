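## Strict CSV readers/writers for the pipeline interchange formats.
## All files are UTF-8, comma-separated, '.' decimal, header required.
## Floating-point output is fixed at 9 significant digits so re-runs on
## identical inputs are byte-identical.

read_strict_csv <- function(path, required, numeric_cols, stage) {
  if (!file.exists(path)) {
    stop(sprintf("[%s] input file not found: %s", stage, path), call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("[%s] %s: malformed header, missing column(s): %s",
                 stage, basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (col in numeric_cols) {
    raw <- df[[col]]
    if (any(grepl(",", raw, fixed = TRUE))) {
      bad <- which(grepl(",", raw, fixed = TRUE))[1]
      stop(sprintf(
        "[%s] %s line %d, column '%s': locale comma decimal ('%s') rejected; use '.'",
        stage, basename(path), bad + 1, col, raw[bad]), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(raw))
    if (any(is.na(val) & !is.na(raw) & raw != "" & raw != "NA")) {
      bad <- which(is.na(val) & raw != "" & raw != "NA")[1]
      stop(sprintf("[%s] %s line %d, column '%s': not a number ('%s')",
                   stage, basename(path), bad + 1, col, raw[bad]),
           call. = FALSE)
    }
    df[[col]] <- val
  }
  df
}

fmt9 <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), NA,
                          formatC(signif(df[[col]], 9), format = "g",
                                  digits = 9))
    }
  }
  df
}

write_strict_csv <- function(df, path) {
  write.csv(fmt9(df), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-cell dimension table
#'
#' Schema: `sample_id, day, replicate, image_id, cell_id, length_um,
#' width_um` (header required, '.' decimal). Negative or zero
#' dimensions, and lengths smaller than widths, are rejected with the
#' offending line number.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_cell_dimensions <- function(path) {
  df <- read_strict_csv(
    path,
    required = c("sample_id", "day", "replicate", "image_id", "cell_id",
                 "length_um", "width_um"),
    numeric_cols = c("day", "length_um", "width_um"),
    stage = "cell-dimensions")
  bad <- which(df$width_um <= 0 | df$length_um < df$width_um)
  if (length(bad)) {
    stop(sprintf(
      "[cell-dimensions] %s line %d: invalid dimensions (L=%g, D=%g)",
      basename(path), bad[1] + 1, df$length_um[bad[1]], df$width_um[bad[1]]),
      call. = FALSE)
  }
  df
}

#' Write a per-cell dimension table
#'
#' @param cells Data frame with the cell-dimension schema columns (see
#'   [read_cell_dimensions()]); extra columns are dropped.
#' @param path Output CSV path.
#' @export
write_cell_dimensions <- function(cells, path) {
  cols <- c("sample_id", "day", "replicate", "image_id", "cell_id",
            "length_um", "width_um")
  missing <- setdiff(cols, names(cells))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  write_strict_csv(cells[cols], path)
}

#' Read ferricyanide assay readings
#'
#' Schema: `sample_id, replicate, time_min, absorbance`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_assay <- function(path) {
  df <- read_strict_csv(path,
                        required = c("sample_id", "replicate", "time_min",
                                     "absorbance"),
                        numeric_cols = c("time_min", "absorbance"),
                        stage = "assay")
  if (any(df$absorbance < 0)) {
    bad <- which(df$absorbance < 0)[1]
    stop(sprintf("[assay] %s line %d: negative absorbance", basename(path),
                 bad + 1), call. = FALSE)
  }
  df
}

#' Read per-sample assay metadata
#'
#' Schema: `sample_id, condition, day, cell_conc_per_ml,
#' extinction_mM_cm, path_cm`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_assay_metadata <- function(path) {
  df <- read_strict_csv(
    path,
    required = c("sample_id", "condition", "day", "cell_conc_per_ml",
                 "extinction_mM_cm", "path_cm"),
    numeric_cols = c("day", "cell_conc_per_ml", "extinction_mM_cm",
                     "path_cm"),
    stage = "assay-metadata")
  if (any(df$cell_conc_per_ml <= 0)) {
    stop("[assay-metadata] non-positive cell concentration", call. = FALSE)
  }
  df
}

#' Read an OD750 growth curve table
#'
#' Schema: `condition, replicate, day, od750, dilution_factor`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_growth <- function(path) {
  df <- read_strict_csv(path,
                        required = c("condition", "replicate", "day",
                                     "od750", "dilution_factor"),
                        numeric_cols = c("day", "od750", "dilution_factor"),
                        stage = "growth")
  if (any(df$od750 < 0)) stop("[growth] negative OD750", call. = FALSE)
  df
}

snapshot_columns <- c("day", "condition", "mean_length_um", "sem_length",
                      "mean_width_um", "mean_area_um2", "sem_area",
                      "k_ms", "sem_k", "rate_mol_cell_s", "sem_rate",
                      "delta_c_molm3", "sem_delta_c")

#' Read / write culture-snapshot tables
#'
#' The pipeline interchange record: one row per (day, condition) with
#' weighted mean morphology, mass-transfer coefficient, reduction rate
#' and concentration difference, each with uncertainty.
#'
#' @param path CSV file path.
#' @return `read_snapshots`: a validated data frame.
#' @export
read_snapshots <- function(path) {
  read_strict_csv(path, required = snapshot_columns,
                  numeric_cols = setdiff(snapshot_columns, "condition"),
                  stage = "snapshot")
}

#' @rdname read_snapshots
#' @param snapshots Data frame with the snapshot columns.
#' @export
write_snapshots <- function(snapshots, path) {
  missing <- setdiff(snapshot_columns, names(snapshots))
  if (length(missing)) {
    stop("missing snapshot column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  write_strict_csv(snapshots[snapshot_columns], path)
}

#' Write the per-day MER report
#'
#' Schema: `day, dk, dA, dkA, ddc, dr, mer, dominance`.
#'
#' @param report Data frame of fractional differences and MER per day.
#' @param path Output CSV path.
#' @export
write_mer_report <- function(report, path) {
  cols <- c("day", "dk", "dA", "dkA", "ddc", "dr", "mer", "dominance")
  missing <- setdiff(cols, names(report))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  write_strict_csv(report[cols], path)
}

#' Export a fitted length regression as a prediction table
#'
#' Schema: `length_um, predicted, ci95_lo, ci95_hi`.
#'
#' @param reg A `length_regression`.
#' @param lengths_um Lengths at which to evaluate.
#' @param path Output CSV path.
#' @export
write_regression <- function(reg, lengths_um, path) {
  p <- predict_mean_property(reg, lengths_um)
  write_strict_csv(p[c("length_um", "predicted", "ci95_lo", "ci95_hi")], path)
}

#' Read / write an image as a plain-text matrix
#'
#' Images are exchanged as headerless CSV matrices of intensities (one
#' image row per line), a text-only stand-in for single-channel TIFF.
#'
#' @param path File path.
#' @return `read_image_matrix`: a numeric matrix.
#' @export
read_image_matrix <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  as.matrix(read.csv(path, header = FALSE))
}

#' @rdname read_image_matrix
#' @param image Numeric matrix.
#' @export
write_image_matrix <- function(image, path) {
  stopifnot(is.matrix(image))
  write.table(fmt9(as.data.frame(image)), path, sep = ",",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
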