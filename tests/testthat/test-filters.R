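# Variable-acceptance rules: exact boundary conventions, cascade behaviour,
# cascade = intersection, monotonicity in thresholds.

snr_fixture <- function(snr_values) {
  n <- length(snr_values)
  mat <- tibble::tibble(sample_id = sprintf("s%d", 1:n), v1 = snr_values * 100)
  snr <- tibble::tibble(sample_id = sprintf("s%d", 1:n), v1 = snr_values)
  list(mat = mat, snr = snr)
}

test_that("signal-to-noise discards strictly below the threshold", {
  f <- snr_fixture(c(10, 10, 10))
  expect_identical(snr_filter(f$mat, f$snr)$removed, character(0))
  f <- snr_fixture(c(2, 2, 2))
  expect_identical(snr_filter(f$mat, f$snr)$removed, "v1")
  # exactly 3 is retained ("< 3" is strict)
  f <- snr_fixture(c(3, 3, 3))
  expect_identical(snr_filter(f$mat, f$snr)$removed, character(0))
  f <- snr_fixture(c(2.99, 2.99))
  expect_identical(snr_filter(f$mat, f$snr)$removed, "v1")
  # a global noise floor substitutes for per-peak noise
  mat <- tibble::tibble(sample_id = c("s1", "s2"), v1 = c(600, 0), v2 = c(100, 120))
  out <- snr_filter(mat, noise_floor = 100)
  expect_identical(out$removed, "v2")
  expect_error(snr_filter(mat), "noise_floor")
})

test_that("presence keeps variables in at least half the eligible samples", {
  n <- 20
  mat <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n),
    in10 = c(rep(5, 10), rep(0, 10)),
    in9 = c(rep(5, 9), rep(0, 11)),
    allzero = 0
  )
  out <- presence_filter(mat)
  expect_setequal(out$removed, c("in9", "allzero"))
  expect_identical(setdiff(names(out$matrix), "sample_id"), "in10")

  # blanks are excluded from the denominator
  sheet <- make_sheet(mat$sample_id,
                      roles = c(rep("sample", 10), rep("blank", 10)))
  out <- presence_filter(mat, sheet)  # in10 now 10/10, in9 9/10
  expect_identical(out$removed, "allzero")
})

test_that("QC linearity thresholds on signed Pearson r, undefined r discards", {
  levels <- rep(c(0.25, 0.5, 1.0), each = 2)
  sheet <- make_sheet(sprintf("qc%d", 1:6), roles = "QC", matrices = "ref",
                      qc_levels = levels, groups = "QC")
  mat <- tibble::tibble(
    sample_id = sheet$sample_id,
    perfect = 1000 * levels,
    constant = 500,
    inverse = 1000 * (1.25 - levels),
    r075 = vector_with_cor(levels, 0.75),
    r0749 = vector_with_cor(levels, 0.749)
  )
  out <- qc_linearity_filter(mat, sheet)
  expect_setequal(out$removed, c("constant", "inverse", "r0749"))
  expect_setequal(setdiff(names(out$matrix), "sample_id"), c("perfect", "r075"))
  r <- out$detail
  expect_equal(r$qc_r[r$variable_id == "perfect"], 1, tolerance = 1e-12)
  expect_true(is.na(r$qc_r[r$variable_id == "constant"]))
  expect_equal(r$qc_r[r$variable_id == "inverse"], -1, tolerance = 1e-12)

  one_level <- make_sheet("qc1", roles = "QC", qc_levels = 1, groups = "QC")
  expect_error(qc_linearity_filter(mat[1, ], one_level), "2 distinct QC")
})

test_that("per-material QC gating skips materials where a variable is absent", {
  levels <- c(0.25, 0.5, 1.0)
  sheet <- make_sheet(sprintf("qc%d", 1:6), roles = "QC",
                      matrices = rep(c("milk", "serum"), each = 3),
                      qc_levels = rep(levels, 2), groups = "QC")
  mat <- tibble::tibble(
    sample_id = sheet$sample_id,
    milk_only = c(250, 500, 1000, 0, 0, 0),   # linear in milk, absent in serum
    noisy_mix = c(250, 500, 1000, 900, 500, 100)  # linear in milk, inverse in serum
  )
  out <- qc_linearity_filter(mat, sheet, qc_mode = "per_material")
  expect_identical(out$removed, character(0))
  pooled <- qc_linearity_filter(mat, sheet, qc_mode = "pooled")
  expect_true("noisy_mix" %in% pooled$removed)
})

test_that("the cascade equals the intersection of the per-rule survivors", {
  set.seed(23)
  for (i in 1:15) {
    n_samp <- 12; n_qc <- 6; n_vars <- 12
    ids <- c(sprintf("s%02d", 1:n_samp), sprintf("qc%d", 1:n_qc))
    sheet <- dplyr::bind_rows(
      make_sheet(sprintf("s%02d", 1:n_samp)),
      make_sheet(sprintf("qc%d", 1:n_qc), roles = "QC", matrices = "ref",
                 qc_levels = rep(c(0.25, 0.5, 1.0), 2), groups = "QC")
    )
    m <- matrix(stats::runif(length(ids) * n_vars, 0, 1000), length(ids), n_vars)
    m[stats::runif(length(m)) < 0.3] <- 0
    colnames(m) <- sprintf("v%02d", 1:n_vars)
    mat <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                            tibble::as_tibble(as.data.frame(m)))
    snr <- mat
    snr[-1] <- lapply(snr[-1], function(v) ifelse(v > 0, v / 50, NA))

    surv_snr <- setdiff(names(snr_filter(mat, snr)$matrix), "sample_id")
    surv_pres <- setdiff(names(presence_filter(mat, sheet)$matrix), "sample_id")
    surv_qc <- setdiff(names(qc_linearity_filter(mat, sheet)$matrix), "sample_id")
    want <- intersect(intersect(surv_snr, surv_pres), surv_qc)

    # chained in cascade order
    s1 <- snr_filter(mat, snr)$matrix
    s2 <- presence_filter(s1, sheet)$matrix
    s3 <- qc_linearity_filter(s2, sheet)$matrix
    expect_setequal(setdiff(names(s3), "sample_id"), want)
    # and in a shuffled order
    t1 <- presence_filter(mat, sheet)$matrix
    t2 <- qc_linearity_filter(t1, sheet)$matrix
    t3 <- snr_filter(t2, snr[names(t2)])$matrix
    expect_setequal(setdiff(names(t3), "sample_id"), want)
  }
})

test_that("surviving counts are monotone in the thresholds", {
  set.seed(31)
  ids <- c(sprintf("s%02d", 1:10), sprintf("qc%d", 1:6))
  sheet <- dplyr::bind_rows(
    make_sheet(sprintf("s%02d", 1:10)),
    make_sheet(sprintf("qc%d", 1:6), roles = "QC", matrices = "ref",
               qc_levels = rep(c(0.25, 0.5, 1.0), 2), groups = "QC")
  )
  m <- matrix(stats::runif(16 * 20, 0, 1000), 16, 20)
  m[stats::runif(length(m)) < 0.25] <- 0
  colnames(m) <- sprintf("v%02d", 1:20)
  mat <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                          tibble::as_tibble(as.data.frame(m)))
  snr <- mat
  snr[-1] <- lapply(snr[-1], function(v) ifelse(v > 0, v / 100, NA))

  n_snr <- vapply(c(1, 3, 5, 8), function(th)
    ncol(snr_filter(mat, snr, threshold = th)$matrix), numeric(1))
  expect_true(all(diff(n_snr) <= 0))
  n_pres <- vapply(c(0.2, 0.5, 0.8, 1), function(f)
    ncol(presence_filter(mat, sheet, min_fraction = f)$matrix), numeric(1))
  expect_true(all(diff(n_pres) <= 0))
  n_qc <- vapply(c(-1, 0, 0.5, 0.75, 0.95), function(r)
    ncol(qc_linearity_filter(mat, sheet, r_min = r)$matrix), numeric(1))
  expect_true(all(diff(n_qc) <= 0))
})

test_that("decoy targets are removed exactly at the annotation stage", {
  cfg <- simulation_config(
    matrices = list(m1 = c(PC = 0.6, TG = 0.4)),
    methods = list(A = list(recovery = c(PC = 0.9, TG = 0.9, PE = 0.9, SM = 0.9,
                                         DG = 0.9, CE = 0.9, Chol = 0.9),
                            dropout = 0)),
    replicates = 8, subtypes = 2, blanks = 0, sigma = 0.05,
    baseline_noise = 1, total_signal = 1e6, panel_size = 15, seed = 99
  )
  tl <- build_target_list(small_class_config(), polarity = "+")
  ex <- simulate_experiment(cfg, targets = tl)
  with_decoys <- make_decoy_targets(tl, n = 5, min_offset_ppm = 50)
  casc <- run_filter_cascade(ex$peaks, with_decoys, ex$sheet)
  ann_row <- casc$report[casc$report$stage == "annotation", ]
  expect_identical(ann_row$removed, 5L)
  expect_false(any(grepl("^DECOY", casc$annotations$variable_id)))
})
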