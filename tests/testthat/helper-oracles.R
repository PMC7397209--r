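# Shared fixtures and independent oracles for the test suite.

# --- independent atomic-mass oracle ------------------------------------------
# CODATA monoisotopic masses, entered here independently of the package's
# constant table (more digits, different source transcription).
ORACLE_MASS <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928
)

oracle_formula_mass <- function(formula_string) {
  counts <- parse_formula(formula_string)
  sum(ORACLE_MASS[names(counts)] * counts)
}

# --- small target lists -------------------------------------------------------
small_class_config <- function() {
  tibble::tribble(
    ~lipid_class, ~carbons_min, ~carbons_max, ~db_min, ~db_max,
    "PC", 30L, 34L, 0L, 2L,
    "TG", 48L, 52L, 0L, 2L
  )
}

small_targets <- function(polarity = "+") {
  build_target_list(small_class_config(), polarity = polarity)
}

# --- random matrix fixtures ---------------------------------------------------
random_matrix <- function(n_samples = 5, n_vars = 8, zero_frac = 0.2, max_val = 1000) {
  m <- matrix(stats::runif(n_samples * n_vars, 1, max_val), n_samples, n_vars)
  m[stats::runif(length(m)) < zero_frac] <- 0
  colnames(m) <- sprintf("var%02d", seq_len(n_vars))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(n_samples))),
    tibble::as_tibble(as.data.frame(m))
  )
}

make_sheet <- function(sample_ids, roles = "sample", matrices = "m1",
                       methods = "A", qc_levels = NA_real_, groups = "g1") {
  tibble::tibble(
    sample_id = sample_ids,
    well = sprintf("P1-A%02d", seq_along(sample_ids)),
    matrix = rep_len(matrices, length(sample_ids)),
    method = rep_len(methods, length(sample_ids)),
    role = rep_len(roles, length(sample_ids)),
    qc_level = rep_len(qc_levels, length(sample_ids)),
    group = rep_len(groups, length(sample_ids))
  )
}

# --- brute-force annotation oracle -------------------------------------------
# Exhaustive all-pairs minimum-|ppm| assignment: repeatedly pick the globally
# smallest |ppm| pair within tolerance (ties towards the lower expected m/z),
# removing both members. Independent of the package's windowed matcher.
brute_force_match <- function(peak_mz, target_mz, tol_ppm) {
  ppm <- outer(peak_mz, target_mz, function(p, t) 1e6 * (p - t) / t)
  ppm[abs(ppm) > tol_ppm + 1e-6] <- NA
  pairs <- list()
  while (any(!is.na(ppm))) {
    ab <- abs(ppm)
    best <- min(ab, na.rm = TRUE)
    cand <- which(ab <= best + 0e-16, arr.ind = TRUE)
    cand <- cand[order(target_mz[cand[, 2]]), , drop = FALSE]
    i <- unname(cand[1, 1]); j <- unname(cand[1, 2])
    pairs[[length(pairs) + 1]] <- c(peak = i, target = j)
    ppm[i, ] <- NA
    ppm[, j] <- NA
  }
  if (length(pairs) == 0) {
    return(tibble::tibble(peak = integer(0), target = integer(0)))
  }
  out <- tibble::as_tibble(do.call(rbind, pairs))
  out[order(out$target), ]
}

# --- PCA oracle ---------------------------------------------------------------
# Eigendecomposition of the covariance matrix of the (centred, optionally
# scaled) data; scores by projection.
pca_eigen_oracle <- function(m, scale = FALSE) {
  x <- scale(m, center = TRUE, scale = scale)
  e <- eigen(stats::cov(x), symmetric = TRUE)
  list(scores = x %*% e$vectors, loadings = e$vectors,
       explained = e$values / sum(e$values))
}

# vector with exact Pearson correlation r against x (n >= 3)
vector_with_cor <- function(x, r, seed = 1) {
  set.seed(seed)
  dx <- x - mean(x)
  repeat {
    z <- stats::rnorm(length(x))
    z <- z - mean(z)
    z <- z - sum(z * dx) / sum(dx * dx) * dx
    if (sum(z^2) > 1e-12) break
  }
  y <- r * dx / sqrt(sum(dx^2)) + sqrt(1 - r^2) * z / sqrt(sum(z^2))
  y - min(y) + 1  # shift positive; correlation is shift-invariant
}

# peaks tibble for one sample from explicit m/z values
peaks_at <- function(mz, intensity = 1000, noise = 10, sample_id = "s1",
                     polarity = "+") {
  tibble::tibble(sample_id = sample_id, polarity = polarity,
                 mz = mz, intensity = rep_len(intensity, length(mz)),
                 noise = rep_len(noise, length(mz)))
}
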