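# Variable-acceptance filters: signal/noise, presence, QC dilution linearity,
# and the full cascade. All filters are variable-wise: each removes whole
# matrix columns, so the cascade's surviving set equals the intersection of
# the per-rule surviving sets.

filter_result <- function(mat, removed, stage, detail = NULL) {
  structure(
    list(matrix = mat, removed = removed,
         report = tibble::tibble(stage = stage,
                                 candidates = length(removed) + (ncol(mat) - 1L),
                                 removed = length(removed),
                                 surviving = ncol(mat) - 1L),
         detail = detail),
    class = "dims_filter")
}

#' Signal-to-noise filter
#'
#' Removes variables whose median signal-to-noise ratio across the samples in
#' which they were measured is strictly below the threshold (S/N exactly at
#' the threshold is retained).
#'
#' @param mat Wide intensity tibble.
#' @param snr_mat Matching wide S/N tibble (from
#'   `build_intensity_matrix(..., value = "snr")`); `NA` where unmeasured. If
#'   the peak data carried no noise estimates, supply `noise_floor` instead.
#' @param noise_floor Global noise floor in intensity units, used as
#'   `S/N = intensity / noise_floor` when `snr_mat` is absent.
#' @param threshold Minimum acceptable median S/N. Default 3.
#' @return A `dims_filter` object: `$matrix` (filtered tibble), `$removed`
#'   (variable ids), `$report` (one-row count tibble).
#' @export
snr_filter <- function(mat, snr_mat = NULL, noise_floor = NULL, threshold = 3) {
  check_intensity_matrix(mat)
  vars <- setdiff(names(mat), "sample_id")
  if (is.null(snr_mat)) {
    if (is.null(noise_floor)) {
      rlang::abort("No per-peak noise available: supply snr_mat or a global noise_floor.")
    }
    m <- mat_values(mat)
    s <- m / noise_floor
    s[m == 0] <- NA_real_
  } else {
    s <- mat_values(snr_mat[c("sample_id", intersect(vars, names(snr_mat)))])
    s <- s[match(mat$sample_id, rownames(s)), vars, drop = FALSE]
  }
  med <- apply(s, 2, stats::median, na.rm = TRUE)
  drop <- vars[is.na(med) | med < threshold]
  filter_result(mat[c("sample_id", setdiff(vars, drop))], drop, "snr")
}

#' Presence filter
#'
#' Removes variables measured in fewer than `min_fraction` of the eligible
#' samples (measured in exactly that fraction is retained). Blanks and QC
#' injections are excluded from the denominator by default: the rule judges
#' how consistently a lipid is seen across study samples.
#'
#' @param mat Wide intensity tibble.
#' @param sheet Sample sheet; used to restrict the denominator to
#'   `eligible_roles`. `NULL` makes every row eligible.
#' @param min_fraction Minimum fraction of eligible samples. Default 0.5.
#' @param eligible_roles Roles counted in the denominator.
#' @return A `dims_filter` object.
#' @export
presence_filter <- function(mat, sheet = NULL, min_fraction = 0.5,
                            eligible_roles = "sample") {
  check_intensity_matrix(mat)
  vars <- setdiff(names(mat), "sample_id")
  if (is.null(sheet)) {
    eligible <- mat$sample_id
  } else {
    eligible <- intersect(mat$sample_id, sheet$sample_id[sheet$role %in% eligible_roles])
  }
  if (length(eligible) == 0) rlang::abort("No eligible samples for the presence filter.")
  m <- mat_values(mat[mat$sample_id %in% eligible, , drop = FALSE])
  frac <- colMeans(m > 0)
  drop <- vars[frac < min_fraction]
  filter_result(mat[c("sample_id", setdiff(vars, drop))], drop, "presence")
}

# Pearson r between QC intensity and nominal dilution level. Zero-variance
# intensity vectors (or < 2 distinct levels) give NA.
qc_cor <- function(intensity, level) {
  if (length(intensity) < 2 || length(unique(level)) < 2) return(NA_real_)
  if (stats::sd(intensity) == 0 || stats::sd(level) == 0) return(NA_real_)
  stats::cor(intensity, level)
}

#' QC dilution-series linearity filter
#'
#' Retains variables whose signal scales linearly with abundance, judged by
#' the Pearson correlation between QC intensity and nominal dilution level
#' (e.g. 0.25/0.5/1.0x) across QC injections. Variables with `r >= r_min` are
#' retained; `r` exactly at the threshold passes; variables with undefined `r`
#' (zero variance) are discarded.
#'
#' With `qc_mode = "per_material"` the correlation is computed within each QC
#' reference material (its `matrix` token) and a variable passes if it passes
#' in at least one material where it was measured; `"pooled"` computes one
#' correlation over all QC injections.
#'
#' @param mat Wide intensity tibble.
#' @param sheet Sample sheet; rows with `role == "QC"` define the dilution
#'   design. At least 2 distinct levels are required.
#' @param r_min Acceptance threshold on signed Pearson r. Default 0.75.
#' @param qc_mode `"per_material"` (default) or `"pooled"`.
#' @return A `dims_filter` object; `$detail` holds the per-variable r used for
#'   the decision.
#' @export
qc_linearity_filter <- function(mat, sheet, r_min = 0.75,
                                qc_mode = c("per_material", "pooled")) {
  qc_mode <- match.arg(qc_mode)
  check_intensity_matrix(mat)
  vars <- setdiff(names(mat), "sample_id")
  qc <- sheet[sheet$role == "QC" & sheet$sample_id %in% mat$sample_id, ]
  if (length(unique(qc$qc_level)) < 2) {
    rlang::abort("QC linearity filter needs >= 2 distinct QC dilution levels.")
  }
  m <- mat_values(mat)
  m <- m[match(qc$sample_id, rownames(m)), , drop = FALSE]
  if (qc_mode == "pooled") {
    r <- apply(m, 2, function(v) qc_cor(v, qc$qc_level))
  } else {
    materials <- split(seq_len(nrow(qc)), qc$matrix)
    r <- apply(m, 2, function(v) {
      per_mat <- vapply(materials, function(idx) {
        vi <- v[idx]
        if (all(vi == 0)) return(NA_real_)  # material never measured: skip
        qc_cor(vi, qc$qc_level[idx])
      }, numeric(1))
      if (all(is.na(per_mat))) NA_real_ else max(per_mat, na.rm = TRUE)
    })
  }
  # 1e-9 guard: a correlation sitting exactly on the threshold passes even
  # when floating point lands it infinitesimally below
  drop <- vars[is.na(r) | r < r_min - 1e-9]
  filter_result(mat[c("sample_id", setdiff(vars, drop))], drop, "qc_linearity",
                detail = tibble::tibble(variable_id = vars, qc_r = unname(r)))
}

#' Run the full variable-acceptance cascade
#'
#' Annotates the peak lists against the target list and applies, in order:
#' mass-tolerance annotation (a target with no peak within `tol_ppm` in enough
#' samples never becomes a variable), the signal-to-noise rule, the presence
#' rule and the QC dilution-linearity rule. The rules are variable-wise and
#' combined by OR: a variable failing any rule is discarded. The surviving
#' matrix is the "passes" matrix on which all downstream statistics run.
#'
#' If the sheet holds no usable QC design (fewer than 2 dilution levels) the
#' QC stage is skipped with a warning and recorded as skipped in the report.
#'
#' @param peaks Peak tibble (one polarity).
#' @param targets `target_list` of the same polarity.
#' @param sheet Sample sheet covering the peak samples.
#' @param tol_ppm,snr_threshold,min_fraction,qc_r Filter thresholds, with
#'   defaults 9 ppm, 3, 0.5 and 0.75.
#' @param noise_floor Optional global noise floor when peaks carry no noise.
#' @param qc_mode See [qc_linearity_filter()].
#' @return A `filter_cascade` object: `$matrix` (surviving raw intensity
#'   tibble), `$report` (per-stage counts), `$qc_r` (per-variable QC r),
#'   `$annotations` (the annotation table), `$params`.
#' @export
run_filter_cascade <- function(peaks, targets, sheet,
                               tol_ppm = 9, snr_threshold = 3,
                               min_fraction = 0.5, qc_r = 0.75,
                               noise_floor = NULL,
                               qc_mode = c("per_material", "pooled")) {
  qc_mode <- match.arg(qc_mode)
  sheet <- validate_sample_sheet(sheet)
  ann <- annotate_peaks(peaks, targets, tol_ppm = tol_ppm)
  mat <- build_intensity_matrix(ann)
  n_targets <- length(unique(targets$variable_id))
  n_annotated <- ncol(mat) - 1L
  report <- tibble::tibble(stage = "annotation", candidates = n_targets,
                           removed = n_targets - n_annotated, surviving = n_annotated)

  have_noise <- any(!is.na(ann$snr))
  if (have_noise) {
    snr_mat <- build_intensity_matrix(ann, value = "snr")
    step <- snr_filter(mat, snr_mat = snr_mat, threshold = snr_threshold)
  } else {
    step <- snr_filter(mat, noise_floor = noise_floor, threshold = snr_threshold)
  }
  mat <- step$matrix
  report <- dplyr::bind_rows(report, step$report)

  step <- presence_filter(mat, sheet, min_fraction = min_fraction)
  mat <- step$matrix
  report <- dplyr::bind_rows(report, step$report)

  qc_detail <- NULL
  qc_sheet <- sheet[sheet$role == "QC" & sheet$sample_id %in% mat$sample_id, ]
  if (length(unique(qc_sheet$qc_level)) >= 2) {
    step <- qc_linearity_filter(mat, sheet, r_min = qc_r, qc_mode = qc_mode)
    mat <- step$matrix
    report <- dplyr::bind_rows(report, step$report)
    qc_detail <- step$detail
  } else {
    rlang::warn("No usable QC dilution design (fewer than 2 levels); QC linearity filter skipped.")
    report <- dplyr::bind_rows(report, tibble::tibble(
      stage = "qc_linearity (skipped)", candidates = ncol(mat) - 1L,
      removed = 0L, surviving = ncol(mat) - 1L))
  }

  structure(
    list(matrix = mat, report = report, qc_r = qc_detail, annotations = ann,
         params = list(tol_ppm = tol_ppm, snr_threshold = snr_threshold,
                       min_fraction = min_fraction, qc_r = qc_r, qc_mode = qc_mode)),
    class = "filter_cascade")
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat("DI-MS variable-acceptance cascade\n")
  print(x$report)
  invisible(x)
}

#' Tidy a filter cascade into its per-stage report
#'
#' @param x A `filter_cascade` object.
#' @param ... Unused.
#' @return The per-stage report tibble (stage, candidates, removed, surviving).
#' @method tidy filter_cascade
#' @export
tidy.filter_cascade <- function(x, ...) {
  x$report
}
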