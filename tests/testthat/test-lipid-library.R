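# Target-list construction: formulas, monoisotopic masses, adduct m/z.

test_that("monoisotopic masses match the independent atomic-mass oracle", {
  expect_identical(monoisotopic_mass(""), 0)
  expect_identical(monoisotopic_mass(stats::setNames(numeric(0), character(0))), 0)

  # water, frozen from the oracle: 2 x 1.0078250319 + 15.9949146221
  expect_equal(monoisotopic_mass("H2O"), 18.0105647, tolerance = 1e-6)

  for (f in c("C40H80NO8P", "C51H98O6", "C27H46O", "H2O", "C2H4")) {
    expect_equal(monoisotopic_mass(f), oracle_formula_mass(f), tolerance = 1e-4)
  }
  expect_equal(monoisotopic_mass(species_formula("PC", 32, 0)), 733.5622,
               tolerance = 1e-4)
  expect_error(monoisotopic_mass(c(C = 1, Xe = 2)), "Xe")
  expect_error(monoisotopic_mass(c(C = -1)), "non-negative")
})

test_that("mass is additive over disjoint element sums", {
  set.seed(42)
  els <- c("C", "H", "N", "O", "P", "S", "Na")
  for (i in 1:20) {
    f1 <- stats::setNames(sample(0:30, 7, replace = TRUE), els)
    f2 <- stats::setNames(sample(0:30, 7, replace = TRUE), els)
    expect_equal(monoisotopic_mass(f1 + f2),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9)
  }
})

test_that("sum-composition formulas follow the class rules", {
  expect_identical(species_formula("PC", 32, 0), "C40H80NO8P")
  expect_identical(species_formula("TG", 48, 0), "C51H98O6")
  expect_identical(species_formula("Chol", 0, 0), "C27H46O")
  # known reference structures
  expect_identical(species_formula("PE", 34, 1), "C39H76NO8P")
  expect_identical(species_formula("SM", 34, 1), "C39H79N2O6P")
  expect_identical(species_formula("DG", 32, 0), "C35H68O5")
  expect_identical(species_formula("CE", 16, 0), "C43H76O2")

  expect_error(species_formula("TG", 48, 25), "chemical maximum")
  expect_error(species_formula("PX", 32, 0), "Unsupported")
  expect_error(species_formula("Chol", 10, 0), "fixed-formula")
})

test_that("homologue and double-bond spacing are exact within a class", {
  # frozen from the oracle: C2H4 = 28.0313, H2 = 2.0157 Da
  for (cl in c("PC", "TG", "CE", "SM")) {
    m0 <- monoisotopic_mass(species_formula(cl, 34, 1))
    m2 <- monoisotopic_mass(species_formula(cl, 36, 1))
    expect_equal(m2 - m0, 28.0313, tolerance = 1e-4)
    m_db <- monoisotopic_mass(species_formula(cl, 34, 2))
    expect_equal(m0 - m_db, 2.01565, tolerance = 1e-4)
  }
})

test_that("adduct m/z applies the signed shift at unit charge", {
  pc_mass <- monoisotopic_mass("C40H80NO8P")
  proton <- ORACLE_MASS[["H"]] - 0.00054858
  expect_equal(adduct_mz(pc_mass, "[M+H]+"), pc_mass + proton, tolerance = 1e-4)
  expect_equal(adduct_mz(pc_mass, "[M-H]-"), pc_mass - proton, tolerance = 1e-4)
  expect_equal(adduct_mz(733.5622, "[M+H]+"), 734.5695, tolerance = 2e-4)
  expect_equal(adduct_mz(806.7363, "[M+NH4]+"), 824.7701, tolerance = 2e-4)
  nh4 <- ORACLE_MASS[["N"]] + 4 * ORACLE_MASS[["H"]] - 0.00054858
  expect_equal(adduct_mz(806.7363, "[M+NH4]+") - 806.7363, nh4, tolerance = 1e-4)
  expect_error(adduct_mz(-1, "[M+H]+"), "positive")
  expect_error(adduct_mz(700, "[M+K]+"), "Unknown adduct")
  ad <- adducts()
  expect_true(all(ad$charge == 1L))
  expect_true(all(abs(ad$mass_shift) < 100))
  expect_true(all(ifelse(grepl("\\+$", ad$adduct), ad$polarity == "+", ad$polarity == "-")))
})

test_that("target-list size follows the configuration combinatorics", {
  cfg <- tibble::tibble(lipid_class = "PC", carbons_min = 30L, carbons_max = 32L,
                        db_min = 0L, db_max = 1L, carbons_step = 2L)
  one_adduct <- adducts()[adducts()$adduct == "[M+H]+", ]
  expect_identical(nrow(build_target_list(cfg, one_adduct, "+")), 4L)
  expect_identical(nrow(build_target_list(cfg, adducts(), "+")), 12L)
  two_neg <- build_target_list(cfg, adducts(), "-")
  expect_identical(nrow(two_neg), 8L)

  # default configuration: entry count equals its own combinatorics and the
  # two polarities together are on the ~8.5k scale
  dc <- default_class_config()
  n_species <- sum((dc$carbons_max - dc$carbons_min + 1) * (dc$db_max - dc$db_min + 1))
  n_pos <- nrow(build_target_list(polarity = "+"))
  n_neg <- nrow(build_target_list(polarity = "-"))
  expect_equal(n_pos, n_species * 3)
  expect_equal(n_neg, n_species * 2)
  expect_gt(n_pos + n_neg, 8000)
  expect_lt(n_pos + n_neg, 9000)
})

test_that("target lists are sorted, unique and polarity-consistent", {
  set.seed(7)
  for (i in 1:10) {
    classes <- sample(c("PC", "PE", "SM", "DG", "TG", "CE"), sample(2:4, 1))
    cmin <- sample(seq(26L, 40L, 2L), length(classes), replace = TRUE)
    cfg <- tibble::tibble(
      lipid_class = classes,
      carbons_min = cmin, carbons_max = cmin + sample(2:8, length(classes), TRUE),
      db_min = 0L, db_max = sample(1:6, length(classes), TRUE)
    )
    pol <- sample(c("+", "-"), 1)
    tl <- build_target_list(cfg, polarity = pol)
    expect_false(is.unsorted(tl$expected_mz))
    expect_identical(anyDuplicated(tl$variable_id), 0L)
    expect_true(all(tl$polarity == pol))
    expect_true(all(tl$double_bonds <= tl$carbons / 2))
  }
})

test_that("target lists round-trip through TSV", {
  tl <- small_targets("+")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_target_list(tl, path)
  back <- read_target_list(path)
  expect_equal(back$expected_mz, tl$expected_mz, tolerance = 1e-9)
  expect_identical(back$variable_id, tl$variable_id)
  expect_identical(attr(back, "polarity"), "+")
})
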