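#' Read a per-lane EMSA band-intensity table
#'
#' Reads a CSV of densitometry results, one row per gel lane, and validates
#' it as a titration series. Required columns (exact names): `condition`,
#' `conc_nM`, `replicate`, `band0`, `band1`, `band2`, where `band0` is the
#' free-probe band, `band1` the single-shift band and `band2` the
#' double-shift (supershift) band.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A validated titration tibble (see [validate_titration()]).
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Input file not found: %s", path),
                 class = "emsacoop_io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_titration(x)
}

#' Write a titration table
#'
#' Writes lanes in the same CSV schema [read_titration()] reads, so a series
#' round-trips bit-exactly through `write_titration()` / `read_titration()`.
#'
#' @param x A titration tibble.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_titration <- function(x, path) {
  x <- validate_titration(x)
  cols <- c("condition", "conc_nM", "replicate", "band0", "band1", "band2")
  readr::write_csv(x[, cols], path, progress = FALSE)
  invisible(x)
}

#' Validate a per-lane titration table
#'
#' Checks the schema and the per-lane invariants: all required columns
#' present, concentrations and intensities finite and nonnegative, and no
#' all-zero lane (a lane with `band0 + band1 + band2 = 0` carries no
#' information and indicates a densitometry failure).
#'
#' @param x A data frame of lanes.
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_titration <- function(x) {
  required <- c("condition", "conc_nM", "replicate", "band0", "band1", "band2")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Missing required column(s): %s", paste(missing, collapse = ", ")),
      class = "emsacoop_schema_error"
    )
  }
  x <- tibble::as_tibble(x)
  num_cols <- c("conc_nM", "band0", "band1", "band2")
  for (col in num_cols) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      rlang::abort(sprintf("Column `%s` must be numeric.", col),
                   class = "emsacoop_schema_error")
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      rlang::abort(
        sprintf("Column `%s` has negative or non-finite values in row(s): %s",
                col, paste(bad, collapse = ", ")),
        class = "emsacoop_validation_error"
      )
    }
  }
  zero <- which(x$band0 + x$band1 + x$band2 <= 0)
  if (length(zero) > 0) {
    rlang::abort(
      sprintf("All-zero band intensities (degenerate lane) in row(s): %s",
              paste(zero, collapse = ", ")),
      class = "emsacoop_validation_error"
    )
  }
  x
}

#' Normalize band intensities to per-lane fractions
#'
#' Divides each lane's three band intensities by their sum, yielding the
#' observed occupancy fractions `(p0, p1, p2)` that the binding model
#' predicts. Normalization is per lane (probe is conserved within a lane);
#' no cross-lane loading correction is applied.
#'
#' @param x A titration tibble.
#' @return `x` with columns `p0`, `p1`, `p2` added; each lane's fractions
#'   sum to 1.
#' @examples
#' lanes <- tibble::tibble(condition = "demo", conc_nM = 40, replicate = 1,
#'                         band0 = 30, band1 = 50, band2 = 20)
#' normalize_lanes(lanes)
#' @export
normalize_lanes <- function(x) {
  x <- validate_titration(x)
  total <- x$band0 + x$band1 + x$band2
  dplyr::mutate(x,
    p0 = .data$band0 / total,
    p1 = .data$band1 / total,
    p2 = .data$band2 / total
  )
}

#' Summarize replicate lanes per concentration
#'
#' Computes, for each concentration and band, the mean and standard
#' deviation of the normalized fractions across replicate lanes. This
#' (mean, SD) table is the statistical description the bootstrap resampler
#' draws from. With a single replicate the SD is reported as 0 and the
#' `single_replicate` flag is set; such a summary cannot seed a bootstrap
#' without a user-supplied SD.
#'
#' @param x A titration tibble (single condition).
#' @return A tibble with one row per concentration: `conc_nM`, `n_reps`,
#'   `mean0`, `mean1`, `mean2`, `sd0`, `sd1`, `sd2`, `single_replicate`.
#' @export
summarize_replicates <- function(x) {
  x <- normalize_lanes(x)
  if (nrow(x) == 0) {
    rlang::abort("Empty titration series.", class = "emsacoop_validation_error")
  }
  if (length(unique(x$condition)) != 1L) {
    rlang::abort("`summarize_replicates()` expects a single condition.",
                 class = "emsacoop_validation_error")
  }
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  x |>
    dplyr::group_by(.data$conc_nM) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      mean0 = mean(.data$p0), mean1 = mean(.data$p1), mean2 = mean(.data$p2),
      sd0 = sd0(.data$p0), sd1 = sd0(.data$p1), sd2 = sd0(.data$p2),
      .groups = "drop"
    ) |>
    dplyr::mutate(single_replicate = .data$n_reps < 2L) |>
    dplyr::arrange(.data$conc_nM)
}

#' Read a titration table from an XLSX workbook
#'
#' Thin adapter for spreadsheet densitometry exports (for example a
#' supplementary-data workbook). The sheet must contain the same six
#' columns as the CSV schema, or a `mapping` must rename the sheet's
#' columns onto them.
#'
#' @param path XLSX file path.
#' @param sheet Sheet name or index (default first sheet).
#' @param mapping Optional named character vector mapping required column
#'   names to the sheet's column names, e.g.
#'   `c(conc_nM = "RBPj (nM)", band0 = "free")`.
#' @return A validated titration tibble.
#' @export
read_titration_xlsx <- function(path, sheet = 1, mapping = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    rlang::abort("Package `readxl` is required for XLSX input.",
                 class = "emsacoop_io_error")
  }
  if (!file.exists(path)) {
    rlang::abort(sprintf("Input file not found: %s", path),
                 class = "emsacoop_io_error")
  }
  x <- readxl::read_excel(path, sheet = sheet)
  if (!is.null(mapping)) {
    for (target in names(mapping)) {
      src <- mapping[[target]]
      if (!src %in% names(x)) {
        rlang::abort(sprintf("Mapped column `%s` not found in sheet.", src),
                     class = "emsacoop_schema_error")
      }
      names(x)[names(x) == src] <- target
    }
  }
  validate_titration(x)
}
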