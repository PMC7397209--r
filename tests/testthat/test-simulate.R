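# The synthetic experiment generator: determinism, configured composition,
# QC linearity, method degradation and ground-truth consistency.

fast_config <- function(...) {
  args <- list(
    matrices = default_matrix_profiles()[c("milk", "serum")],
    methods = default_method_recoveries()[c("DMT", "XMI")],
    replicates = 6, subtypes = 2, qc_replicates = 2, blanks = 2,
    panel_size = 6, seed = 202
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

fast_targets <- function() {
  dplyr::bind_rows(build_target_list(small_class_config(), polarity = "+"),
                   build_target_list(small_class_config(), polarity = "-"))
}

test_that("identical config and seed reproduce the experiment bit for bit", {
  tl <- fast_targets()
  a <- simulate_experiment(fast_config(), targets = tl)
  b <- simulate_experiment(fast_config(), targets = tl)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_experiment(fast_config(seed = 203), targets = tl)
  expect_false(identical(a$peaks, c$peaks))
})

test_that("milk ground truth carries the configured glyceride dominance", {
  gt <- simulate_experiment(fast_config(), targets = fast_targets())$ground_truth
  comp <- gt$matrix_composition
  milk <- comp[comp$matrix == "milk", ]
  expect_equal(milk$glyceride_fraction, 0.98, tolerance = 0.005)
  expect_equal(milk$tg_over_phospholipid, 49, tolerance = 0.5)
})

test_that("simulated QC series regress on dilution level", {
  cfg <- fast_config(sigma = 0.02)
  ex <- simulate_experiment(cfg, targets = fast_targets())
  qc <- ex$sheet[ex$sheet$role == "QC", ]
  peaks <- ex$peaks[ex$peaks$sample_id %in% qc$sample_id, ]
  totals <- dplyr::summarise(peaks, total = sum(intensity),
                             .by = "sample_id") |>
    dplyr::left_join(qc[c("sample_id", "qc_level", "matrix")], by = "sample_id")
  per_material <- dplyr::summarise(totals, r = stats::cor(total, qc_level),
                                   .by = "matrix")
  expect_true(all(per_material$r > 0.99))
})

test_that("every variable passes the QC filter in the zero-noise limit", {
  cfg <- fast_config(sigma = 0, mz_jitter_ppm = 0)
  ex <- simulate_experiment(cfg, targets = fast_targets())
  tl_pos <- build_target_list(small_class_config(), polarity = "+")
  casc <- run_filter_cascade(ex$peaks[ex$peaks$polarity == "+", ], tl_pos, ex$sheet)
  qc_row <- casc$report[casc$report$stage == "qc_linearity", ]
  expect_identical(qc_row$removed, 0L)

  # QC pass rate decreases as multiplicative noise grows
  removed_at <- vapply(c(0, 0.6, 1.2), function(s) {
    exn <- simulate_experiment(fast_config(sigma = s), targets = fast_targets())
    cn <- run_filter_cascade(exn$peaks[exn$peaks$polarity == "+", ], tl_pos, exn$sheet)
    row <- cn$report[cn$report$stage == "qc_linearity", ]
    row$removed / row$candidates
  }, numeric(1))
  expect_true(all(diff(removed_at) >= 0))
})

test_that("degrading a method scales signal linearly and reduces counts", {
  tl <- fast_targets()
  cfg <- fast_config()
  expect_identical(degrade_method(cfg, "DMT", 1)$methods, cfg$methods)
  half <- degrade_method(cfg, "DMT", 0.5)
  expect_equal(half$methods$DMT$recovery, cfg$methods$DMT$recovery * 0.5)
  expect_gt(half$methods$DMT$dropout, cfg$methods$DMT$dropout)

  gt_full <- simulate_experiment(cfg, targets = tl)$ground_truth$cells
  gt_half <- simulate_experiment(half, targets = tl)$ground_truth$cells
  full_dmt <- gt_full[gt_full$method == "DMT", ]
  half_dmt <- gt_half[gt_half$method == "DMT", ]
  expect_equal(half_dmt$expected_total_signal, full_dmt$expected_total_signal / 2,
               tolerance = 1e-9)
  expect_true(all(half_dmt$expected_n_variables < full_dmt$expected_n_variables))
  expect_error(degrade_method(cfg, "nope", 0.5), "Unknown method")
})

test_that("observed per-sample variable counts match the analytic expectation", {
  cfg <- fast_config(replicates = 40, subtype_sd = 0)
  tl <- fast_targets()
  ex <- simulate_experiment(cfg, targets = tl)
  study <- ex$sheet[ex$sheet$role == "sample", ]
  obs <- ex$peaks |>
    dplyr::filter(.data$sample_id %in% study$sample_id) |>
    dplyr::summarise(n = dplyr::n(), .by = c("sample_id", "polarity")) |>
    dplyr::left_join(study[c("sample_id", "matrix", "method")], by = "sample_id") |>
    dplyr::summarise(mean_n = mean(.data$n), sd_n = stats::sd(.data$n),
                     reps = dplyr::n(), .by = c("matrix", "method", "polarity"))
  gt <- ex$ground_truth$cells
  joined <- dplyr::inner_join(obs, gt, by = c("matrix", "method", "polarity"))
  expect_gt(nrow(joined), 4)
  for (i in seq_len(nrow(joined))) {
    se <- max(joined$sd_n[i] / sqrt(joined$reps[i]), 0.5)
    expect_lt(abs(joined$mean_n[i] - joined$expected_n_variables[i]), 4 * se)
  }
})

test_that("better recovery stochastically dominates in count and signal", {
  flat <- function(x) stats::setNames(rep(x, 7), lipid_class_rules()$lipid_class)
  cfg <- simulation_config(
    matrices = default_matrix_profiles()["serum"],
    methods = list(good = list(recovery = flat(0.9), dropout = 0.05),
                   poor = list(recovery = flat(0.45), dropout = 0.05)),
    replicates = 25, subtypes = 1, qc_replicates = 2, blanks = 0,
    panel_size = 6, seed = 404
  )
  ex <- simulate_experiment(cfg, targets = fast_targets())
  study <- ex$sheet[ex$sheet$role == "sample", ]
  per_sample <- ex$peaks |>
    dplyr::filter(.data$sample_id %in% study$sample_id, .data$polarity == "+") |>
    dplyr::summarise(n = dplyr::n(), total = sum(.data$intensity), .by = "sample_id") |>
    dplyr::left_join(study[c("sample_id", "method")], by = "sample_id")
  means <- dplyr::summarise(per_sample, n = mean(n), total = mean(total),
                            .by = "method")
  expect_gt(means$n[means$method == "good"], means$n[means$method == "poor"])
  expect_gt(means$total[means$method == "good"], means$total[means$method == "poor"])
})

test_that("decoy construction respects offsets and the trivial cases", {
  tl <- build_target_list(small_class_config(), polarity = "+")
  none <- make_decoy_targets(tl, 0)
  expect_identical(nrow(none), nrow(tl))
  with5 <- make_decoy_targets(tl, 5, min_offset_ppm = 50)
  expect_identical(nrow(with5), nrow(tl) + 5L)
  decoy_mz <- with5$expected_mz[grepl("^DECOY", with5$variable_id)]
  real_mz <- tl$expected_mz
  for (d in decoy_mz) {
    expect_gt(min(abs(1e6 * (d - real_mz) / real_mz)), 50)
  }
  # a peak placed exactly on a decoy m/z is annotated to it (positive control)
  ann <- annotate_peaks(peaks_at(decoy_mz[1]), with5)
  expect_match(ann$variable_id, "^DECOY")
  expect_error(make_decoy_targets(tl, 1e6), "admit")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(matrices = list(m = c(PC = 0.5, TG = 0.4))),
               "sum to 1")
  expect_error(simulation_config(methods = list(A = list(recovery = c(PC = 1.2),
                                                         dropout = 0))),
               "recoveries")
  expect_error(simulation_config(qc_levels = 1), "2 distinct")
  expect_error(simulation_config(sigma = -1), "sigma")
})
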