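# Coefficient-of-variance machinery and the three-layer extraction-efficiency
# assessment: variable counts, total signal strength, CV stratification.

#' Coefficient of variance (CV, %)
#'
#' `100 * sd / mean` with the n-1 standard deviation. The CV is undefined
#' (returns `NA`) for fewer than 2 values or a non-positive mean; undefined
#' CVs are excluded from stratification and counted separately.
#'
#' @param values Numeric replicate measurements.
#' @return CV in percent, or `NA` where undefined.
#' @examples
#' coefficient_of_variance(c(8, 12))
#' @export
coefficient_of_variance <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(values) / m
}

.CV_BINS <- c("0-10%", "10-20%", "20-30%", "30-50%", ">50%")

#' Stratify per-variable CVs into the standard precision bins
#'
#' Bins are half-open `[lo, hi)` with breaks at 10, 20, 30 and 50%, the last
#' bin open-ended (a CV of exactly 10 falls in the 10-20% bin). Fractions sum
#' to 100% over the defined CVs; undefined (`NA`) CVs are excluded and counted
#' in the `n_undefined` attribute.
#'
#' @param cvs Numeric vector of CVs in percent (`NA` allowed).
#' @return A tibble of class `cv_strata` with columns `bin`, `n`,
#'   `fraction_pct`.
#' @examples
#' cv_strata(c(5, 15, 25, 40, 60))
#' @export
cv_strata <- function(cvs) {
  defined <- cvs[!is.na(cvs)]
  if (length(defined) == 0) rlang::abort("No defined CV values to stratify.")
  if (any(defined < 0)) rlang::abort("CV values must be non-negative.")
  bin <- cut(defined, breaks = c(0, 10, 20, 30, 50, Inf), labels = .CV_BINS,
             right = FALSE, include.lowest = TRUE)
  counts <- table(bin)
  out <- tibble::tibble(
    bin = factor(.CV_BINS, levels = .CV_BINS),
    n = as.integer(counts[.CV_BINS]),
    fraction_pct = 100 * as.integer(counts[.CV_BINS]) / length(defined)
  )
  class(out) <- c("cv_strata", class(out))
  attr(out, "n_defined") <- length(defined)
  attr(out, "n_undefined") <- sum(is.na(cvs))
  out
}

#' Per-variable CVs within replicate groups
#'
#' Computes the CV of each variable's normalized values within each replicate
#' group (e.g. a matrix subtype measured 16-20 times). A variable is excluded
#' from a group's CV when it was measured in no more than half of that group's
#' replicates: with zeros meaning "not measured", a CV over a mostly-missing
#' vector reflects detection, not measurement precision. The CV itself is
#' computed over the measured (positive) values.
#'
#' @param norm_mat Normalized wide tibble (see [normalize_per_mille()]).
#' @param sheet Sample sheet; only `role == "sample"` rows enter.
#' @param group_col Sheet column defining the replicate groups. Default
#'   `"group"`.
#' @param min_support Minimum fraction of a group's replicates in which the
#'   variable must be measured. Default 0.5 (strictly more than half).
#' @return A tibble: `group`, `variable_id`, `n_used`, `cv`; one row per
#'   (group, variable) with sufficient support.
#' @export
group_cvs <- function(norm_mat, sheet, group_col = "group", min_support = 0.5) {
  check_intensity_matrix(norm_mat)
  sheet <- sheet[sheet$role == "sample" & sheet$sample_id %in% norm_mat$sample_id, ]
  if (nrow(sheet) == 0) rlang::abort("No study samples shared between matrix and sheet.")
  m <- mat_values(norm_mat)
  m <- m[match(sheet$sample_id, rownames(m)), , drop = FALSE]
  groups <- split(seq_len(nrow(sheet)), sheet[[group_col]])
  purrr::imap_dfr(groups, function(idx, grp) {
    sub <- m[idx, , drop = FALSE]
    measured <- colSums(sub > 0)
    keep <- which(measured > min_support * length(idx))
    if (length(keep) == 0) return(NULL)
    cv <- vapply(keep, function(j) {
      v <- sub[, j]
      coefficient_of_variance(v[v > 0])
    }, numeric(1))
    tibble::tibble(group = grp, variable_id = colnames(sub)[keep],
                   n_used = unname(as.integer(measured[keep])), cv = unname(cv))
  })
}

#' Per-class abundance and variable counts
#'
#' Sums each sample's values over the variables of each lipid class and counts
#' the class's measured variables. Run it on the normalized matrix for
#' relative abundance in permille, or on the raw matrix for uncorrected class
#' signal.
#'
#' @param mat Wide intensity tibble (raw or normalized).
#' @param targets `target_list` (or any tibble with `variable_id` and
#'   `lipid_class`) mapping every matrix variable to exactly one class.
#' @return A long tibble: `sample_id`, `lipid_class`, `abundance`,
#'   `n_variables`.
#' @export
class_abundance <- function(mat, targets) {
  check_intensity_matrix(mat)
  vars <- setdiff(names(mat), "sample_id")
  map <- targets$lipid_class[match(vars, targets$variable_id)]
  if (anyNA(map)) {
    rlang::abort(sprintf("Variable(s) with unknown class: %s",
                         paste(utils::head(vars[is.na(map)], 3), collapse = ", ")))
  }
  m <- mat_values(mat)
  purrr::map_dfr(unique(map), function(cl) {
    sub <- m[, map == cl, drop = FALSE]
    tibble::tibble(sample_id = mat$sample_id, lipid_class = cl,
                   abundance = unname(rowSums(sub)), n_variables = unname(rowSums(sub > 0)))
  }) |>
    dplyr::arrange(.data$sample_id, .data$lipid_class)
}

#' Two-group comparison with the printed significance tiers
#'
#' Two-sided Welch two-sample t-test (or Mann-Whitney) between two sets of
#' per-replicate metric values, with the significance tier conventions used on
#' the efficiency figures: `^` for p < 0.05, `*` for p < 0.01, `**` for
#' p < 0.001 (strict inequalities), empty otherwise.
#'
#' @param a,b Numeric metric values for the two groups (>= 2 each).
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return A one-row tibble: `estimate` (mean difference a - b), `p_value`,
#'   `tier`.
#' @export
compare_groups <- function(a, b, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    rlang::abort("compare_groups needs >= 2 values per group.")
  }
  if (test == "welch") {
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  if (is.na(p)) p <- 1  # degenerate (e.g. both groups constant and equal)
  tibble::tibble(estimate = mean(a) - mean(b), p_value = p,
                 tier = significance_tier(p))
}

#' @rdname compare_groups
#' @param p A p-value (vectorised).
#' @export
significance_tier <- function(p) {
  dplyr::case_when(p < 0.001 ~ "**", p < 0.01 ~ "*", p < 0.05 ~ "^", TRUE ~ "")
}

#' Extraction-efficiency report
#'
#' The objective efficiency measure for ranking extraction methods: for each
#' (matrix, method) cell it reports the number of variables identified and the
#' total uncorrected signal strength (mean and sd over replicates), the
#' per-class relative abundance (mean permille and standard error) with class
#' variable counts, and pairwise Welch p-values between methods within each
#' matrix on both headline metrics.
#'
#' @param raw_mat Raw (uncorrected) surviving intensity tibble.
#' @param norm_mat Its per-mille normalized counterpart.
#' @param targets `target_list` mapping variables to classes.
#' @param sheet Sample sheet; only `role == "sample"` rows enter.
#' @param polarity Polarity label stored in the report.
#' @return An `efficiency_report` object: `$cells`, `$class_profiles`,
#'   `$pairwise`, `$polarity`.
#' @export
efficiency_report <- function(raw_mat, norm_mat, targets, sheet, polarity = NA_character_) {
  sheet <- sheet[sheet$role == "sample", ]
  keep <- intersect(raw_mat$sample_id, sheet$sample_id)
  if (length(keep) == 0) rlang::abort("No study samples to report on.")
  raw_mat <- raw_mat[match(keep, raw_mat$sample_id), , drop = FALSE]
  norm_mat <- norm_mat[match(keep, norm_mat$sample_id), , drop = FALSE]
  meta <- sheet[match(keep, sheet$sample_id), c("sample_id", "matrix", "method", "group")]

  per_sample <- meta |>
    dplyr::left_join(count_variables(raw_mat), by = "sample_id") |>
    dplyr::left_join(total_signal(raw_mat), by = "sample_id")

  cells <- per_sample |>
    dplyr::group_by(.data$matrix, .data$method) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_variables_mean = mean(.data$n_variables),
      n_variables_sd = stats::sd(.data$n_variables),
      total_signal_mean = mean(.data$total_signal),
      total_signal_sd = stats::sd(.data$total_signal),
      .groups = "drop"
    ) |>
    dplyr::mutate(polarity = polarity, .before = 1)

  class_profiles <- class_abundance(norm_mat, targets) |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::group_by(.data$matrix, .data$method, .data$lipid_class) |>
    dplyr::summarise(
      abundance_mean = mean(.data$abundance),
      abundance_se = stats::sd(.data$abundance) / sqrt(dplyr::n()),
      n_variables = max(.data$n_variables),
      .groups = "drop"
    ) |>
    dplyr::mutate(polarity = polarity, .before = 1)

  pairwise <- per_sample |>
    dplyr::group_by(.data$matrix) |>
    dplyr::group_map(function(d, key) {
      methods <- sort(unique(d$method))
      if (length(methods) < 2) return(NULL)
      pairs <- utils::combn(methods, 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(pr) {
        a <- d[d$method == pr[1], ]; b <- d[d$method == pr[2], ]
        dplyr::bind_rows(
          dplyr::mutate(compare_groups(a$n_variables, b$n_variables),
                        metric = "n_variables"),
          dplyr::mutate(compare_groups(a$total_signal, b$total_signal),
                        metric = "total_signal")
        ) |>
          dplyr::mutate(matrix = key$matrix, method_a = pr[1], method_b = pr[2],
                        .before = 1)
      })
    }) |>
    dplyr::bind_rows()
  if (nrow(pairwise) > 0) pairwise$polarity <- polarity

  structure(list(cells = cells, class_profiles = class_profiles,
                 pairwise = pairwise, polarity = polarity),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("Extraction-efficiency report (polarity %s)\n", x$polarity))
  print(x$cells)
  invisible(x)
}

#' Tidy an efficiency report
#'
#' @param x An `efficiency_report`.
#' @param which `"cells"` (default), `"classes"` or `"pairwise"`.
#' @param ... Unused.
#' @return The requested component tibble.
#' @method tidy efficiency_report
#' @export
tidy.efficiency_report <- function(x, which = c("cells", "classes", "pairwise"), ...) {
  which <- match.arg(which)
  switch(which, cells = x$cells, classes = x$class_profiles, pairwise = x$pairwise)
}
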