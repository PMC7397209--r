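# Readers and writers for the pipeline's tab-separated tables.
# One dialect throughout: tab delimiter, "." decimal point, UTF-8.
# Readers reject rather than coerce; every rejection names file, row and rule.

abort_io <- function(path, row, rule) {
  rlang::abort(sprintf("%s: row %s: %s", path, as.character(row), rule),
               class = "dimslipids_io_error")
}

#' Read a centroided peak table
#'
#' A peak table holds one row per centroided peak with columns `sample_id`,
#' `polarity` (`+`/`-`), `mz`, `intensity` and optionally `noise`. Peaks are
#' returned grouped per (sample, polarity) and sorted ascending by m/z. A
#' missing `noise` column yields `NA` noise; the signal-to-noise filter then
#' requires an explicit global noise floor.
#'
#' @param path Path to a tab-separated peak table.
#' @return A tibble with columns `sample_id`, `polarity`, `mz`, `intensity`,
#'   `noise`, sorted by sample, polarity and m/z.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("Peak table '%s' does not exist.", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "polarity", "mz", "intensity")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort_io(path, "header", sprintf("missing column(s) %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"noise" %in% names(x)) x$noise <- NA_real_
  for (col in c("mz", "intensity", "noise")) {
    v <- x[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & v != "NA")
      if (length(bad) > 0) {
        abort_io(path, bad[1] + 1, sprintf("non-numeric value '%s' in column %s", v[bad[1]], col))
      }
      x[[col]] <- parsed
    }
  }
  validate_peaks(x, path = path)
}

validate_peaks <- function(x, path = "<peaks>") {
  bad <- which(!x$polarity %in% c("+", "-"))
  if (length(bad) > 0) {
    abort_io(path, bad[1] + 1, sprintf("polarity must be '+' or '-', got '%s'", x$polarity[bad[1]]))
  }
  bad <- which(is.na(x$mz) | x$mz <= 0)
  if (length(bad) > 0) abort_io(path, bad[1] + 1, "m/z must be positive")
  bad <- which(is.na(x$intensity) | x$intensity < 0)
  if (length(bad) > 0) {
    abort_io(path, bad[1] + 1,
             sprintf("intensity must be >= 0, got '%s'", x$intensity[bad[1]]))
  }
  bad <- which(!is.na(x$noise) & x$noise < 0)
  if (length(bad) > 0) abort_io(path, bad[1] + 1, "noise must be >= 0")
  dplyr::arrange(tibble::as_tibble(x), .data$sample_id, .data$polarity, .data$mz)
}

#' @rdname read_peak_table
#' @param peaks A peak tibble as returned by [read_peak_table()] or
#'   [simulate_experiment()].
#' @export
write_peak_table <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  readr::write_tsv(as.data.frame(peaks), path)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet carries one row per injection: `sample_id`, `well`,
#' `matrix` (biological matrix token), `method` (extraction method token),
#' `role` (`sample`, `blank` or `QC`), `qc_level` (dilution factor, present
#' exactly for QC rows) and `group` (replicate group / subtype label).
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A validated tibble. The QC design (levels present and replicate
#'   counts per level) is attached as attribute `"qc_design"`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("Sample sheet '%s' does not exist.", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         sample_id = "c", well = "c", matrix = "c", method = "c",
                         role = "c", qc_level = "d", group = "c"
                       ))
  validate_sample_sheet(x, path = path)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet data frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet, path = "<sheet>") {
  required <- c("sample_id", "well", "matrix", "method", "role", "qc_level", "group")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    abort_io(path, "header", sprintf("missing column(s) %s", paste(missing_cols, collapse = ", ")))
  }
  dup <- which(duplicated(sheet$sample_id))
  if (length(dup) > 0) {
    abort_io(path, dup[1] + 1, sprintf("duplicate sample_id '%s'", sheet$sample_id[dup[1]]))
  }
  bad <- which(!sheet$role %in% c("sample", "blank", "QC"))
  if (length(bad) > 0) {
    abort_io(path, bad[1] + 1, sprintf("role must be sample/blank/QC, got '%s'", sheet$role[bad[1]]))
  }
  bad <- which(sheet$role == "QC" & is.na(sheet$qc_level))
  if (length(bad) > 0) abort_io(path, bad[1] + 1, "QC row without qc_level")
  bad <- which(sheet$role != "QC" & !is.na(sheet$qc_level))
  if (length(bad) > 0) abort_io(path, bad[1] + 1, "qc_level set on a non-QC row")
  sheet <- tibble::as_tibble(sheet)
  qc <- sheet[sheet$role == "QC", ]
  attr(sheet, "qc_design") <- dplyr::count(qc, .data$matrix, .data$qc_level, name = "n_injections")
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  readr::write_tsv(as.data.frame(sheet), path)
  invisible(path)
}

#' Write / read an intensity matrix
#'
#' The matrix is a wide tibble: first column `sample_id`, one numeric column
#' per annotated variable. Zero means "not measured". Values round-trip
#' losslessly at 6 significant figures; absent cells on read become 0.
#'
#' @param mat A wide intensity tibble (`sample_id` plus numeric columns).
#' @param path File path.
#' @return `read_intensity_matrix()` returns the wide tibble.
#' @export
write_intensity_matrix <- function(mat, path) {
  check_intensity_matrix(mat)
  out <- mat
  for (col in setdiff(names(out), "sample_id")) {
    out[[col]] <- formatC(out[[col]], digits = 6, format = "g")
  }
  readr::write_tsv(as.data.frame(out), path)
  invisible(path)
}

#' @rdname write_intensity_matrix
#' @export
read_intensity_matrix <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("Matrix file '%s' does not exist.", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(sample_id = "c", .default = "c"))
  if (!identical(names(x)[1], "sample_id")) {
    abort_io(path, "header", "first column must be sample_id")
  }
  if (anyDuplicated(names(x))) {
    abort_io(path, "header", "duplicate variable ids")
  }
  for (col in setdiff(names(x), "sample_id")) {
    v <- x[[col]]
    v[is.na(v)] <- "0"
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(parsed))
    if (length(bad) > 0) {
      abort_io(path, bad[1] + 1,
               sprintf("non-numeric cell '%s' in column '%s'", v[bad[1]], col))
    }
    x[[col]] <- parsed
  }
  check_intensity_matrix(x, path = path)
  x
}

check_intensity_matrix <- function(mat, path = "<matrix>") {
  if (!is.data.frame(mat) || !identical(names(mat)[1], "sample_id")) {
    rlang::abort(sprintf("%s: an intensity matrix is a data frame whose first column is sample_id.",
                         path))
  }
  vars <- setdiff(names(mat), "sample_id")
  for (col in vars) {
    if (!is.numeric(mat[[col]])) {
      rlang::abort(sprintf("%s: column '%s' is not numeric.", path, col))
    }
    if (any(mat[[col]] < 0, na.rm = TRUE)) {
      rlang::abort(sprintf("%s: column '%s' holds negative intensities.", path, col))
    }
  }
  invisible(mat)
}

# wide tibble -> base matrix with sample_id rownames
mat_values <- function(mat) {
  m <- as.matrix(mat[setdiff(names(mat), "sample_id")])
  rownames(m) <- mat$sample_id
  storage.mode(m) <- "double"
  m
}

# base matrix -> wide tibble
mat_tibble <- function(m) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
}
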