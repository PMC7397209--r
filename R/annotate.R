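# Annotation of centroided peaks against a target list with ppm tolerance.

#' Signed parts-per-million mass error
#'
#' @param observed_mz Observed m/z (vectorised).
#' @param expected_mz Expected m/z (> 0, recycled).
#' @return Signed ppm error `1e6 * (observed - expected) / expected`.
#' @examples
#' ppm_error(700.0007, 700)
#' @export
ppm_error <- function(observed_mz, expected_mz) {
  if (any(expected_mz <= 0)) rlang::abort("expected_mz must be positive.")
  1e6 * (observed_mz - expected_mz) / expected_mz
}

# Greedy one-to-one assignment of peaks to targets by ascending |ppm|,
# ties broken by lower expected m/z. Candidate pairs are found by a sorted
# window search (findInterval), so the overall cost is O((P + T) log P) plus
# the (small) number of in-tolerance pairs.
match_peaks_one <- function(mz, targets, tol_ppm) {
  t_mz <- targets$expected_mz
  # 1e-12 relative guard keeps peaks sitting exactly on the tolerance
  # boundary inside the search window despite floating-point rounding
  lo <- findInterval(t_mz * (1 - tol_ppm * 1e-6 - 1e-12), mz) + 1L
  hi <- findInterval(t_mz * (1 + tol_ppm * 1e-6 + 1e-12), mz)
  keep <- which(hi >= lo)
  if (length(keep) == 0) {
    return(tibble::tibble(target = integer(0), peak = integer(0), ppm = double(0)))
  }
  n_cand <- hi[keep] - lo[keep] + 1L
  target_idx <- rep.int(keep, n_cand)
  peak_idx <- unlist(lapply(keep, function(i) seq.int(lo[i], hi[i])), use.names = FALSE)
  ppm <- ppm_error(mz[peak_idx], t_mz[target_idx])
  in_tol <- abs(ppm) <= tol_ppm + 1e-6
  target_idx <- target_idx[in_tol]; peak_idx <- peak_idx[in_tol]; ppm <- ppm[in_tol]
  ord <- order(abs(ppm), t_mz[target_idx])
  target_idx <- target_idx[ord]; peak_idx <- peak_idx[ord]; ppm <- ppm[ord]

  used_peak <- logical(length(mz))
  used_target <- logical(length(t_mz))
  sel <- logical(length(ppm))
  for (k in seq_along(ppm)) {
    ti <- target_idx[k]; pi <- peak_idx[k]
    if (!used_peak[pi] && !used_target[ti]) {
      used_peak[pi] <- TRUE
      used_target[ti] <- TRUE
      sel[k] <- TRUE
    }
  }
  tibble::tibble(target = target_idx[sel], peak = peak_idx[sel], ppm = ppm[sel])
}

#' Annotate centroided peaks against a target list
#'
#' Assigns peaks to target-list entries within a ppm mass tolerance. The
#' assignment is one-to-one: pairs are taken in order of ascending absolute
#' ppm error (ties broken towards the lower expected m/z), so when two targets
#' fall within tolerance of one peak the smaller |ppm| wins. A matched
#' variable's intensity is the matched peak's intensity; targets without a
#' peak in tolerance are absent (not measured) for that sample.
#'
#' @param peaks A peak tibble (columns `sample_id`, `polarity`, `mz`,
#'   `intensity`, `noise`); may hold many samples of one polarity.
#' @param targets A `target_list` of the same polarity.
#' @param tol_ppm Mass tolerance in ppm; a deviation strictly greater than
#'   this is not annotated. Default 9.
#' @return A tibble of annotations: `sample_id`, `variable_id`, `lipid_class`,
#'   `adduct`, `expected_mz`, `observed_mz`, `ppm_error`, `intensity`, `snr`.
#'   The set of input sample ids is attached as attribute `"samples"`.
#' @export
annotate_peaks <- function(peaks, targets, tol_ppm = 9) {
  peaks <- validate_peaks(peaks)
  pol <- attr(targets, "polarity")
  if (is.null(pol)) pol <- unique(targets$polarity)
  bad <- unique(peaks$polarity[peaks$polarity != pol])
  if (length(bad) > 0) {
    rlang::abort(sprintf("Polarity mismatch: peaks are '%s' but target list is '%s'.",
                         bad[1], pol))
  }
  samples <- unique(peaks$sample_id)
  ann <- peaks |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(p, key) {
      m <- match_peaks_one(p$mz, targets, tol_ppm)
      if (nrow(m) == 0) return(NULL)
      tibble::tibble(
        sample_id = key$sample_id,
        variable_id = targets$variable_id[m$target],
        lipid_class = targets$lipid_class[m$target],
        adduct = targets$adduct[m$target],
        expected_mz = targets$expected_mz[m$target],
        observed_mz = p$mz[m$peak],
        ppm_error = m$ppm,
        intensity = p$intensity[m$peak],
        snr = p$intensity[m$peak] / p$noise[m$peak]
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(ann) == 0) {
    ann <- tibble::tibble(sample_id = character(0), variable_id = character(0),
                          lipid_class = character(0), adduct = character(0),
                          expected_mz = double(0), observed_mz = double(0),
                          ppm_error = double(0), intensity = double(0), snr = double(0))
  }
  attr(ann, "samples") <- samples
  attr(ann, "tol_ppm") <- tol_ppm
  ann
}

#' Build a wide intensity (or S/N) matrix from annotations
#'
#' @param annotations Output of [annotate_peaks()].
#' @param samples Sample ids to include as rows; defaults to the samples the
#'   annotations were computed from. Samples without any annotation get
#'   all-zero rows.
#' @param value Which value to spread: `"intensity"` or `"snr"`.
#' @return A wide tibble (`sample_id` + one column per annotated variable,
#'   columns in ascending expected m/z order); 0 = not measured. For
#'   `value = "snr"`, unmeasured cells are `NA`.
#' @export
build_intensity_matrix <- function(annotations, samples = attr(annotations, "samples"),
                                   value = c("intensity", "snr")) {
  value <- match.arg(value)
  fill <- if (value == "intensity") 0 else NA_real_
  if (is.null(samples)) samples <- unique(annotations$sample_id)
  var_order <- annotations |>
    dplyr::distinct(.data$variable_id, .data$expected_mz) |>
    dplyr::arrange(.data$expected_mz, .data$variable_id)
  wide <- annotations |>
    dplyr::select("sample_id", "variable_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "variable_id", values_from = dplyr::all_of(value),
                       values_fill = fill)
  missing_samples <- setdiff(samples, wide$sample_id)
  if (length(missing_samples) > 0) {
    wide <- dplyr::bind_rows(wide, tibble::tibble(sample_id = missing_samples))
    if (value == "intensity") {
      wide <- dplyr::mutate(wide, dplyr::across(-"sample_id", ~ tidyr::replace_na(.x, fill)))
    }
  }
  wide <- wide[match(samples, wide$sample_id), , drop = FALSE]
  wide[c("sample_id", var_order$variable_id)]
}
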