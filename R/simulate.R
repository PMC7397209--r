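# Synthetic DI-MS experiment generator with analytic ground truth.
#
# The generator emulates the study design the pipeline is meant to process:
# four biological matrices (milk, serum, liver and heart homogenate) times
# four extraction methods, 20 replicate measurements per cell split over
# replicate subtypes, QC dilution series at 0.25/0.5/1.0x, blanks, and two
# ionisation modes. Intensities follow base abundance x class-wise method
# recovery x multiplicative log-normal noise with Bernoulli dropout; a
# centroided peak is emitted only when its intensity reaches the noise floor,
# which couples recovery to the number of variables detected.

#' Default matrix class profiles
#'
#' Class-wise fractions of total lipid signal per biological matrix. The milk
#' profile is parameterised so that glycerides (TG + DG) carry 98% of the
#' signal and the phospholipid:triglyceride ratio is 1:49; the serum, liver
#' and heart profiles are plausible compositions for those tissues and are
#' meant to be edited to taste.
#'
#' @return Named list of named numeric vectors (fractions summing to 1).
#' @export
default_matrix_profiles <- function() {
  list(
    milk  = c(TG = 0.931, DG = 0.049, PC = 0.012, PE = 0.004, SM = 0.003,
              CE = 0.0005, Chol = 0.0005),
    serum = c(PC = 0.35, TG = 0.25, CE = 0.20, SM = 0.08, PE = 0.05,
              Chol = 0.05, DG = 0.02),
    liver = c(PC = 0.40, TG = 0.30, PE = 0.15, SM = 0.05, DG = 0.04,
              CE = 0.03, Chol = 0.03),
    heart = c(PC = 0.45, PE = 0.20, TG = 0.18, SM = 0.08, DG = 0.03,
              CE = 0.03, Chol = 0.03)
  )
}

#' Default extraction-method recovery parameters
#'
#' Class-wise recovery fractions and per-variable dropout probabilities for
#' the four high-throughput extraction methods. The aqueous-wash methods (DMT,
#' TBME) recover more than the non-aqueous ones, and the ethereal TBME solvent
#' recovers ionic phospholipid classes less well than the chlorinated DMT
#' mixture.
#'
#' @return Named list; each element has `recovery` (named by class) and
#'   `dropout`.
#' @export
default_method_recoveries <- function() {
  classes <- .CLASS_RULES$lipid_class
  flat <- function(x) stats::setNames(rep(x, length(classes)), classes)
  list(
    DMT  = list(recovery = flat(0.90), dropout = 0.04),
    TBME = list(recovery = c(TG = 0.85, DG = 0.85, CE = 0.85, Chol = 0.85,
                             PC = 0.70, PE = 0.70, SM = 0.70),
                dropout = 0.08),
    BuMe = list(recovery = flat(0.65), dropout = 0.10),
    XMI  = list(recovery = flat(0.50), dropout = 0.15)
  )
}

# Class-wise positive-mode ionisation preference: glycerides and sterols
# ionise almost exclusively in positive mode, PE mostly in negative.
.POS_FRACTION <- c(TG = 0.98, DG = 0.98, CE = 0.95, Chol = 0.95,
                   PC = 0.65, SM = 0.65, PE = 0.35)

# Relative adduct intensity within each polarity.
.ADDUCT_WEIGHTS <- c("[M+H]+" = 0.6, "[M+NH4]+" = 0.3, "[M+Na]+" = 0.1,
                     "[M-H]-" = 0.7, "[M+CH3COO]-" = 0.3)

#' Build a simulation configuration
#'
#' Collects all tunable parameters of the synthetic experiment. The defaults
#' reproduce the study design: 4 matrices x 4 methods x 20 replicates, the
#' replicates split over 4 subtypes per matrix, QC dilution series at
#' 0.25/0.5/1.0x with 3 injections per level and matrix, and blanks.
#'
#' @param matrices Named list of class profiles; see
#'   [default_matrix_profiles()].
#' @param methods Named list of recovery/dropout parameters; see
#'   [default_method_recoveries()].
#' @param replicates Replicate measurements per (matrix, method) cell.
#' @param subtypes Replicate groups (matrix subtypes) the replicates cycle
#'   through.
#' @param subtype_sd Log-scale sd of the per-(subtype, species) abundance
#'   perturbation that differentiates subtypes. 0 makes subtypes identical.
#' @param qc_levels QC dilution levels.
#' @param qc_replicates QC injections per (matrix, level).
#' @param blanks Number of blank injections.
#' @param blank_peaks Baseline-only peaks emitted per blank and polarity.
#' @param sigma Multiplicative log-normal noise (sd of log intensity).
#' @param baseline_noise Noise floor in intensity units; peaks below it are
#'   not detected, and it is the per-peak noise estimate.
#' @param total_signal Total lipid signal per undegraded sample, intensity
#'   units.
#' @param mz_jitter_ppm Half-width of the bounded-uniform m/z error in ppm.
#' @param panel_size Species per class in each matrix's lipid panel.
#' @param panel_decay Geometric decay of within-class species abundance.
#' @param seed Integer seed; every simulated quantity is reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(matrices = default_matrix_profiles(),
                              methods = default_method_recoveries(),
                              replicates = 20,
                              subtypes = 4,
                              subtype_sd = 0.15,
                              qc_levels = c(0.25, 0.5, 1.0),
                              qc_replicates = 3,
                              blanks = 4,
                              blank_peaks = 25,
                              sigma = 0.25,
                              baseline_noise = 100,
                              total_signal = 1e6,
                              mz_jitter_ppm = 3,
                              panel_size = 15,
                              panel_decay = 0.7,
                              seed = 1) {
  cfg <- structure(
    list(matrices = matrices, methods = methods, replicates = replicates,
         subtypes = subtypes, subtype_sd = subtype_sd, qc_levels = qc_levels,
         qc_replicates = qc_replicates, blanks = blanks, blank_peaks = blank_peaks,
         sigma = sigma, baseline_noise = baseline_noise, total_signal = total_signal,
         mz_jitter_ppm = mz_jitter_ppm, panel_size = panel_size,
         panel_decay = panel_decay, seed = seed),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  for (nm in names(cfg$matrices)) {
    p <- cfg$matrices[[nm]]
    if (abs(sum(p) - 1) > 1e-8) {
      rlang::abort(sprintf("Matrix '%s': class-profile fractions must sum to 1.", nm))
    }
    if (any(p < 0)) rlang::abort(sprintf("Matrix '%s': negative class fraction.", nm))
  }
  for (nm in names(cfg$methods)) {
    m <- cfg$methods[[nm]]
    if (any(m$recovery < 0 | m$recovery > 1)) {
      rlang::abort(sprintf("Method '%s': recoveries must lie in [0, 1].", nm))
    }
    if (m$dropout < 0 || m$dropout > 1) {
      rlang::abort(sprintf("Method '%s': dropout must lie in [0, 1].", nm))
    }
  }
  if (cfg$sigma < 0) rlang::abort("sigma must be >= 0.")
  if (cfg$mz_jitter_ppm < 0) rlang::abort("mz_jitter_ppm must be >= 0.")
  if (length(unique(cfg$qc_levels)) < 2) {
    rlang::abort("At least 2 distinct QC dilution levels are required.")
  }
  invisible(cfg)
}

#' Degrade one extraction method in a configuration
#'
#' Multiplies the named method's class recoveries by `factor` and increases
#' its dropout correspondingly (the per-variable survival probability is
#' scaled by the same factor), producing the "worse method" contrast used to
#' validate the efficiency ranking.
#'
#' @param config A `simulation_config`.
#' @param method Method name to degrade.
#' @param factor Multiplier in (0, 1].
#' @return The modified configuration.
#' @export
degrade_method <- function(config, method, factor) {
  if (!method %in% names(config$methods)) {
    rlang::abort(sprintf("Unknown method '%s'.", method))
  }
  if (factor <= 0 || factor > 1) rlang::abort("factor must lie in (0, 1].")
  m <- config$methods[[method]]
  m$recovery <- m$recovery * factor
  m$dropout <- m$dropout + (1 - m$dropout) * (1 - factor)
  config$methods[[method]] <- m
  validate_simulation_config(config)
  config
}

# Deterministic per-matrix lipid panel: panel_size species per class, evenly
# spaced through the class's composition grid; within-class abundance follows
# a geometric decay scaled by the matrix's class fraction. All matrices share
# the same species (biological samples share their lipid complement); they
# differ by class profile and by the subtype perturbations.
build_panels <- function(cfg, targets) {
  species <- dplyr::distinct(tibble::as_tibble(targets),
                             .data$name, .data$lipid_class, .data$carbons,
                             .data$double_bonds)
  purrr::imap_dfr(cfg$matrices, function(profile, mx) {
    purrr::imap_dfr(profile[profile > 0], function(frac, cl) {
      grid <- species[species$lipid_class == cl, ]
      grid <- grid[order(grid$carbons, grid$double_bonds), ]
      k <- min(cfg$panel_size, nrow(grid))
      if (k == 0) return(NULL)
      sel <- grid[unique(round(seq(1, nrow(grid), length.out = k))), ]
      w <- cfg$panel_decay^(seq_len(nrow(sel)) - 1)
      sel$matrix <- mx
      sel$base_abundance <- cfg$total_signal * frac * w / sum(w)
      sel
    })
  })
}

# Expand species panels to per-variable expected intensities using the
# polarity preference of each class and the adduct weights.
panel_variables <- function(panels, targets) {
  t <- tibble::as_tibble(targets)[c("variable_id", "name", "lipid_class", "adduct",
                                    "polarity", "expected_mz")]
  out <- dplyr::inner_join(panels, t, by = c("name", "lipid_class"),
                           relationship = "many-to-many")
  w <- .ADDUCT_WEIGHTS[out$adduct]
  pol_pref <- .POS_FRACTION[out$lipid_class]
  pol_pref[is.na(pol_pref)] <- 0.5
  share <- ifelse(out$polarity == "+", pol_pref, 1 - pol_pref) * w
  out$mean_intensity <- out$base_abundance * share
  out
}

#' Simulate a DI-MS experiment
#'
#' Generates centroided peak lists for every injection of the configured
#' design (study samples, QC dilution series, blanks) in both ionisation
#' modes, plus the matching sample sheet and the analytic ground truth.
#' Identical configuration and seed give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @param targets Target list covering both polarities (rows of `"+"` and
#'   `"-"` entries); defaults to the full default lists. Panels are drawn from
#'   these species.
#' @return A `dims_experiment` list: `$peaks` (peak tibble over all samples
#'   and polarities), `$sheet` (sample sheet), `$ground_truth`, `$config`.
#'   Ground truth holds `$cells` (per matrix, method, polarity: recovered
#'   class fractions, expected variable count and expected total signal),
#'   `$matrix_composition` (per matrix: glyceride signal fraction and
#'   triglyceride:phospholipid ratio) and `$true_cv_pct` (the noise-model CV
#'   of any measured variable).
#' @export
simulate_experiment <- function(config = simulation_config(),
                                targets = NULL) {
  validate_simulation_config(config)
  if (is.null(targets)) {
    targets <- dplyr::bind_rows(build_target_list(polarity = "+"),
                                build_target_list(polarity = "-"))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed, kind = "Mersenne-Twister")

  panels <- build_panels(config, targets)
  pvars <- panel_variables(panels, targets)

  # deterministic subtype perturbation factors (drawn first, fixed order)
  subtype_grid <- tidyr::expand_grid(
    matrix = names(config$matrices),
    subtype = seq_len(config$subtypes),
    name = sort(unique(panels$name))
  )
  subtype_grid$subtype_factor <- exp(stats::rnorm(nrow(subtype_grid), 0, config$subtype_sd))

  sheet <- build_design_sheet(config)
  study <- sheet[sheet$role == "sample", ]
  qc <- sheet[sheet$role == "QC", ]

  grid_study <- dplyr::inner_join(
    study[c("sample_id", "matrix", "method", "subtype")],
    pvars, by = "matrix", relationship = "many-to-many")
  grid_study <- dplyr::left_join(grid_study, subtype_grid,
                                 by = c("matrix", "subtype", "name"))
  rec_tbl <- purrr::imap_dfr(config$methods, function(m, nm) {
    tibble::tibble(method = nm, lipid_class = names(m$recovery),
                   recovery = unname(m$recovery), dropout = m$dropout)
  })
  grid_study <- dplyr::left_join(grid_study, rec_tbl, by = c("method", "lipid_class"))
  if (anyNA(grid_study$recovery)) {
    missing <- unique(grid_study$lipid_class[is.na(grid_study$recovery)])
    rlang::abort(sprintf("Method recovery not configured for class(es): %s",
                         paste(missing, collapse = ", ")))
  }
  grid_study$mu <- grid_study$mean_intensity * grid_study$subtype_factor * grid_study$recovery

  grid_qc <- dplyr::inner_join(
    qc[c("sample_id", "matrix", "qc_level")],
    pvars, by = "matrix", relationship = "many-to-many")
  grid_qc$mu <- grid_qc$mean_intensity * grid_qc$qc_level
  grid_qc$dropout <- 0  # pooled reference extracts are not subject to dropout

  grid <- dplyr::bind_rows(
    grid_study[c("sample_id", "variable_id", "polarity", "expected_mz", "mu", "dropout")],
    grid_qc[c("sample_id", "variable_id", "polarity", "expected_mz", "mu", "dropout")]
  )
  grid <- dplyr::arrange(grid, .data$sample_id, .data$polarity, .data$expected_mz)

  n <- nrow(grid)
  intensity <- grid$mu * exp(stats::rnorm(n, 0, config$sigma))
  dropped <- stats::runif(n) < grid$dropout
  eps <- stats::runif(n, -config$mz_jitter_ppm, config$mz_jitter_ppm) * 1e-6
  detected <- !dropped & intensity >= config$baseline_noise
  peaks <- tibble::tibble(
    sample_id = grid$sample_id[detected],
    polarity = grid$polarity[detected],
    mz = grid$expected_mz[detected] * (1 + eps[detected]),
    intensity = intensity[detected],
    noise = config$baseline_noise
  )

  blanks <- sheet[sheet$role == "blank", ]
  if (nrow(blanks) > 0 && config$blank_peaks > 0) {
    bl <- tidyr::expand_grid(sample_id = blanks$sample_id, polarity = c("+", "-"),
                             i = seq_len(config$blank_peaks))
    bl$mz <- stats::runif(nrow(bl), 200, 1000)
    bl$intensity <- config$baseline_noise * stats::runif(nrow(bl), 1, 2)
    bl$noise <- config$baseline_noise
    peaks <- dplyr::bind_rows(peaks, bl[c("sample_id", "polarity", "mz", "intensity", "noise")])
  }
  peaks <- dplyr::arrange(peaks, .data$sample_id, .data$polarity, .data$mz)

  gt <- ground_truth(config, pvars, subtype_grid)
  sheet$subtype <- NULL
  structure(list(peaks = peaks, sheet = validate_sample_sheet(sheet),
                 ground_truth = gt, config = config),
            class = "dims_experiment")
}

# Sample sheet for the configured design, with sequential 96-well plate
# coordinates. Replicates cycle through the matrix subtypes.
build_design_sheet <- function(cfg) {
  study <- tidyr::expand_grid(matrix = names(cfg$matrices),
                              method = names(cfg$methods),
                              replicate = seq_len(cfg$replicates))
  study$subtype <- ((study$replicate - 1) %% cfg$subtypes) + 1
  study <- tibble::tibble(
    sample_id = sprintf("%s_%s_%02d", study$matrix, study$method, study$replicate),
    matrix = study$matrix, method = study$method, role = "sample",
    qc_level = NA_real_,
    group = sprintf("%s_set%d", study$matrix, study$subtype),
    subtype = study$subtype
  )
  qc <- tidyr::expand_grid(matrix = names(cfg$matrices),
                           qc_level = cfg$qc_levels,
                           replicate = seq_len(cfg$qc_replicates))
  qc <- tibble::tibble(
    sample_id = sprintf("QC_%s_%.2fx_%02d", qc$matrix, qc$qc_level, qc$replicate),
    matrix = qc$matrix, method = "pooled", role = "QC",
    qc_level = qc$qc_level, group = "QC", subtype = NA_integer_
  )
  blank <- if (cfg$blanks > 0) {
    tibble::tibble(
      sample_id = sprintf("blank_%02d", seq_len(cfg$blanks)),
      matrix = "blank", method = "none", role = "blank",
      qc_level = NA_real_, group = "blank", subtype = NA_integer_
    )
  }
  out <- dplyr::bind_rows(study, qc, blank)
  n <- nrow(out)
  idx <- seq_len(n) - 1
  out$well <- sprintf("P%d-%s%02d", idx %/% 96 + 1,
                      LETTERS[(idx %% 96) %% 8 + 1], (idx %% 96) %/% 8 + 1)
  out[c("sample_id", "well", "matrix", "method", "role", "qc_level", "group", "subtype")]
}

# Analytic ground truth of the generator. Detection probability of a variable
# is (1 - dropout) * P(lognormal intensity >= noise floor); expected total
# signal uses the lognormal mean and ignores below-floor censoring (a slight
# overestimate, adequate for the ratio and monotonicity checks it serves).
ground_truth <- function(cfg, pvars, subtype_grid) {
  p_above <- function(mu) {
    if (cfg$sigma == 0) return(as.numeric(mu >= cfg$baseline_noise))
    ifelse(mu <= 0, 0, 1 - stats::plnorm(cfg$baseline_noise, log(pmax(mu, 1e-300)), cfg$sigma))
  }
  cells <- tidyr::expand_grid(matrix = names(cfg$matrices),
                              method = names(cfg$methods),
                              polarity = c("+", "-"))
  cells <- purrr::pmap_dfr(cells, function(matrix, method, polarity) {
    vars <- pvars[pvars$matrix == matrix & pvars$polarity == polarity, ]
    rec <- cfg$methods[[method]]$recovery[vars$lipid_class]
    dropout <- cfg$methods[[method]]$dropout
    sub <- subtype_grid[subtype_grid$matrix == matrix, ]
    per_subtype <- vapply(split(sub, sub$subtype), function(s) {
      f <- s$subtype_factor[match(vars$name, s$name)]
      mu <- vars$mean_intensity * f * rec
      # expected signal is over the recovered material (linear in recovery);
      # dropout and the detection floor enter the expected count only
      c(n = sum((1 - dropout) * p_above(mu)),
        signal = sum(mu) * exp(cfg$sigma^2 / 2))
    }, numeric(2))
    profile <- cfg$matrices[[matrix]]
    rec_cls <- cfg$methods[[method]]$recovery[names(profile)]
    recovered <- profile * rec_cls / sum(profile * rec_cls)
    tibble::tibble(
      matrix = matrix, method = method, polarity = polarity,
      expected_n_variables = mean(per_subtype["n", ]),
      expected_total_signal = mean(per_subtype["signal", ]),
      recovered_class_fraction = list(recovered)
    )
  })
  comp <- purrr::imap_dfr(cfg$matrices, function(profile, mx) {
    gly <- sum(profile[intersect(c("TG", "DG"), names(profile))])
    pl <- sum(profile[intersect(c("PC", "PE", "SM"), names(profile))])
    tibble::tibble(matrix = mx, glyceride_fraction = gly,
                   tg_over_phospholipid = unname(profile["TG"] / pl))
  })
  list(cells = cells, matrix_composition = comp,
       true_cv_pct = 100 * sqrt(exp(cfg$sigma^2) - 1))
}

#' Append decoy targets as negative annotation controls
#'
#' Inserts `n` synthetic target entries into the widest gaps of the target
#' list, each at least `min_offset_ppm` (plus a jitter guard) away from every
#' m/z at which the simulator can emit a peak for a real target. With the
#' default 9 ppm tolerance none of them can ever be annotated, so each decoy
#' must be removed at the annotation stage of the cascade.
#'
#' @param targets A single-polarity `target_list`.
#' @param n Number of decoys (0 allowed).
#' @param min_offset_ppm Minimum ppm distance from every real target; must
#'   exceed the annotation tolerance in use.
#' @param guard_ppm Extra margin covering the simulator's m/z jitter.
#' @return The target list with decoy entries (class `"DECOY"`) appended and
#'   re-sorted; decoy variable ids in attribute `"decoys"`.
#' @export
make_decoy_targets <- function(targets, n, min_offset_ppm = 50, guard_ppm = 9) {
  pol <- attr(targets, "polarity")
  if (is.null(pol) || length(unique(targets$polarity)) != 1) {
    rlang::abort("make_decoy_targets needs a single-polarity target list.")
  }
  if (n == 0) {
    attr(targets, "decoys") <- character(0)
    return(targets)
  }
  mz <- sort(targets$expected_mz)
  mid <- (mz[-1] + mz[-length(mz)]) / 2
  d_lo <- 1e6 * (mid - mz[-length(mz)]) / mz[-length(mz)]
  d_hi <- 1e6 * (mz[-1] - mid) / mz[-1]
  clearance <- pmin(d_lo, d_hi)
  ok <- which(clearance >= min_offset_ppm + guard_ppm)
  if (length(ok) < n) {
    rlang::abort(sprintf("Only %d gap(s) admit a decoy at >= %g ppm; %g requested.",
                         length(ok), min_offset_ppm, n))
  }
  pick <- ok[order(clearance[ok], decreasing = TRUE)][seq_len(n)]
  adduct <- .ADDUCTS$adduct[.ADDUCTS$polarity == pol][1]
  decoys <- tibble::tibble(
    variable_id = sprintf("DECOY_%03d %s", seq_len(n), adduct),
    name = sprintf("DECOY_%03d", seq_len(n)),
    lipid_class = "DECOY", carbons = 0L, double_bonds = 0L,
    formula = "", mass = NA_real_, adduct = adduct, polarity = pol,
    expected_mz = mid[pick]
  )
  out <- dplyr::bind_rows(tibble::as_tibble(targets), decoys)
  out <- out[order(out$expected_mz, out$variable_id), ]
  out <- new_target_list(out, pol)
  attr(out, "decoys") <- decoys$variable_id
  out
}
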