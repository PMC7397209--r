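# Per-mille total-signal normalization and the per-sample summary metrics.

#' Per-mille normalization of an intensity matrix
#'
#' Divides every measured value by its sample's total signal and expresses it
#' in parts per thousand, so each sample row sums to 1000 permille. Zeros
#' (not measured) stay zero.
#'
#' @param mat Wide intensity tibble.
#' @return The normalized wide tibble, same shape.
#' @examples
#' mat <- tibble::tibble(sample_id = "s1", a = 2, b = 3, c = 5)
#' normalize_per_mille(mat)
#' @export
normalize_per_mille <- function(mat) {
  check_intensity_matrix(mat)
  m <- mat_values(mat)
  totals <- rowSums(m)
  zero_rows <- mat$sample_id[totals == 0]
  if (length(zero_rows) > 0) {
    rlang::abort(sprintf("Sample(s) with all-zero rows cannot be normalized: %s",
                         paste(zero_rows, collapse = ", ")))
  }
  mat_tibble(1000 * m / totals)
}

#' Number of variables measured per sample
#'
#' A variable counts as identified in a sample when its intensity is strictly
#' positive (zero means not measured). The count is invariant under per-mille
#' normalization.
#'
#' @param mat Wide intensity tibble (raw or normalized).
#' @return A tibble with columns `sample_id`, `n_variables`.
#' @export
count_variables <- function(mat) {
  check_intensity_matrix(mat)
  m <- mat_values(mat)
  tibble::tibble(sample_id = mat$sample_id, n_variables = unname(rowSums(m > 0)))
}

#' Total (uncorrected) signal per sample
#'
#' Sum of raw, pre-normalization intensities per sample row.
#'
#' @param mat Wide raw intensity tibble.
#' @return A tibble with columns `sample_id`, `total_signal`.
#' @export
total_signal <- function(mat) {
  check_intensity_matrix(mat)
  m <- mat_values(mat)
  tibble::tibble(sample_id = mat$sample_id, total_signal = unname(rowSums(m)))
}
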