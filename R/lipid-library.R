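# Sum-composition lipid target lists for DI-MS annotation.

# Monoisotopic atomic masses, IUPAC/CODATA values to 7 decimal places.
.ATOMIC_MASS <- c(
  C  = 12.0000000,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  P  = 30.9737615,
  S  = 31.9720707,
  Na = 22.9897693
)
.ELECTRON_MASS <- 0.0005486

#' Parse a molecular formula string
#'
#' Converts a condensed formula such as `"C40H80NO8P"` into a named integer
#' vector of element counts. Only the elements C, H, N, O, P, S and Na are
#' recognised (the elements occurring in the supported lipid classes and
#' adducts).
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C40H80NO8P")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (formula == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    rlang::abort(sprintf("Cannot parse formula '%s'.", formula))
  }
  el <- gsub("[0-9]", "", tokens)
  n <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", tokens)))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  out <- stats::setNames(as.integer(counts), names(counts))
  out[order(names(out))]
}

#' Render element counts as a condensed formula string
#'
#' Elements are printed in Hill order (C, H, then remaining elements
#' alphabetically); counts of one are implicit and zero-count elements are
#' dropped.
#'
#' @param counts Named numeric vector of element counts.
#' @return A formula string.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0) return("")
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums monoisotopic atomic masses over the element counts of a formula.
#' Supported elements: C, H, N, O, P, S, Na.
#'
#' @param formula A formula string (e.g. `"C40H80NO8P"`) or a named numeric
#'   vector of element counts. An empty formula has mass 0.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass(c(C = 40, H = 80, N = 1, O = 8, P = 1))
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0) return(0)
  if (is.null(names(formula)) || any(names(formula) == "")) {
    rlang::abort("Formula counts must be named by element.")
  }
  unknown <- setdiff(names(formula), names(.ATOMIC_MASS))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown element(s): %s", paste(unknown, collapse = ", ")))
  }
  if (any(formula < 0) || any(formula != round(formula))) {
    rlang::abort("Element counts must be non-negative integers.")
  }
  sum(.ATOMIC_MASS[names(formula)] * formula)
}

# Sum-composition formula rules. For a class with total acyl carbons c and
# total double bonds d the formula is C(c + c_offset) H(2c - 2d + h_offset)
# plus the fixed heteroatoms. Cholesterol is a fixed-formula species.
.CLASS_RULES <- tibble::tribble(
  ~lipid_class, ~c_offset, ~h_offset, ~n, ~o, ~p, ~fixed_formula,
  "PC",         8L,        16L,       1L, 8L, 1L, NA_character_,
  "PE",         5L,        10L,       1L, 8L, 1L, NA_character_,
  "SM",         5L,        13L,       2L, 6L, 1L, NA_character_,
  "DG",         3L,        4L,        0L, 5L, 0L, NA_character_,
  "TG",         3L,        2L,        0L, 6L, 0L, NA_character_,
  "CE",         27L,       44L,       0L, 2L, 0L, NA_character_,
  "Chol",       0L,        0L,        0L, 0L, 0L, "C27H46O"
)

#' Supported lipid classes and their sum-composition formula rules
#'
#' The diacyl glycerophospholipids (PC, PE), sphingomyelin (SM), the
#' glycerides (DG, TG), cholesteryl esters (CE) and cholesterol are supported.
#' For each class the molecular formula is linear in the total acyl carbon
#' count and total double-bond count; cholesterol is a fixed-formula species.
#'
#' @return A tibble with one row per class: the carbon and hydrogen offsets of
#'   the backbone rule and the fixed heteroatom counts.
#' @export
lipid_class_rules <- function() {
  .CLASS_RULES
}

#' Canonical sum-composition lipid name
#'
#' @param lipid_class Class token, e.g. `"PC"`.
#' @param carbons Total acyl carbons.
#' @param double_bonds Total acyl double bonds.
#' @return Name of the form `Class(C:D)`, e.g. `"PC(32:0)"`; fixed-formula
#'   species (cholesterol) render as the bare class token.
#' @export
lipid_name <- function(lipid_class, carbons, double_bonds) {
  ifelse(lipid_class == "Chol", "Chol",
         sprintf("%s(%d:%d)", lipid_class, as.integer(carbons), as.integer(double_bonds)))
}

#' Molecular formula of a sum-composition lipid species
#'
#' Assembles the formula from the class backbone rule plus the acyl
#' contribution. The total double-bond count may not exceed half the carbon
#' count (the chemical maximum for acyl chains).
#'
#' @inheritParams lipid_name
#' @return A formula string.
#' @examples
#' species_formula("PC", 32, 0) # dipalmitoyl glycerophosphocholine
#' species_formula("TG", 48, 0) # tripalmitin
#' @export
species_formula <- function(lipid_class, carbons, double_bonds) {
  rule <- .CLASS_RULES[.CLASS_RULES$lipid_class == lipid_class, ]
  if (nrow(rule) == 0) {
    rlang::abort(sprintf("Unsupported lipid class '%s'.", lipid_class))
  }
  if (!is.na(rule$fixed_formula)) {
    if (carbons != 0 || double_bonds != 0) {
      rlang::abort(sprintf("'%s' is a fixed-formula species; carbons and double_bonds must be 0.",
                           lipid_class))
    }
    return(rule$fixed_formula)
  }
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (carbons < 0 || double_bonds < 0) {
    rlang::abort("carbons and double_bonds must be non-negative.")
  }
  if (double_bonds > carbons / 2) {
    rlang::abort(sprintf("%s(%d:%d): %d double bonds exceed the chemical maximum for %d acyl carbons.",
                         lipid_class, carbons, double_bonds, double_bonds, carbons))
  }
  counts <- c(
    C = carbons + rule$c_offset,
    H = 2L * carbons - 2L * double_bonds + rule$h_offset,
    N = rule$n, O = rule$o, P = rule$p
  )
  if (any(counts < 0)) {
    rlang::abort(sprintf("%s(%d:%d): composition outside the class rule's valid range.",
                         lipid_class, carbons, double_bonds))
  }
  format_formula(counts)
}

# Ionisation adducts supported by an ammonium-acetate infusion buffer.
# mass_shift is the signed Da difference between the observed ion and the
# neutral species (electron mass included), charge is the absolute charge.
.ADDUCTS <- tibble::tibble(
  adduct = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+CH3COO]-"),
  polarity = c("+", "+", "+", "-", "-"),
  mass_shift = c(
    .ATOMIC_MASS[["H"]] - .ELECTRON_MASS,
    .ATOMIC_MASS[["N"]] + 4 * .ATOMIC_MASS[["H"]] - .ELECTRON_MASS,
    .ATOMIC_MASS[["Na"]] - .ELECTRON_MASS,
    -(.ATOMIC_MASS[["H"]] - .ELECTRON_MASS),
    2 * .ATOMIC_MASS[["C"]] + 3 * .ATOMIC_MASS[["H"]] + 2 * .ATOMIC_MASS[["O"]] + .ELECTRON_MASS
  ),
  charge = c(1L, 1L, 1L, 1L, 1L)
)

#' Supported ionisation adducts
#'
#' Singly charged adducts observable under an ammonium-acetate infusion
#' buffer: protonated, ammoniated and sodiated species in positive mode;
#' deprotonated and acetate adducts in negative mode. Mass shifts include the
#' electron mass.
#'
#' @return A tibble with columns `adduct`, `polarity`, `mass_shift`, `charge`.
#' @export
adducts <- function() {
  .ADDUCTS
}

#' Expected m/z of an adduct of a neutral species
#'
#' @param mass Neutral monoisotopic mass in Da (> 0). Vectorised.
#' @param adduct Adduct name, one of `adducts()$adduct`. Vectorised (recycled
#'   against `mass`).
#' @return Expected m/z in Da: `(mass + mass_shift) / charge`.
#' @examples
#' adduct_mz(733.5622, "[M+H]+")
#' @export
adduct_mz <- function(mass, adduct) {
  if (any(mass <= 0)) rlang::abort("Neutral mass must be positive.")
  i <- match(adduct, .ADDUCTS$adduct)
  if (anyNA(i)) {
    rlang::abort(sprintf("Unknown adduct(s): %s",
                         paste(unique(adduct[is.na(i)]), collapse = ", ")))
  }
  (mass + .ADDUCTS$mass_shift[i]) / .ADDUCTS$charge[i]
}

#' Default target-list class configuration
#'
#' Carbon and double-bond ranges per lipid class. Ranges are chosen so that no
#' composition violates the chemical double-bond maximum (entry counts are
#' then exact products of range sizes) and so that the default list over both
#' polarities holds roughly 8,500 (species, adduct) entries, the scale of a
#' typical DI-MS annotation list.
#'
#' @return A tibble with columns `lipid_class`, `carbons_min`, `carbons_max`,
#'   `db_min`, `db_max`.
#' @export
default_class_config <- function() {
  tibble::tribble(
    ~lipid_class, ~carbons_min, ~carbons_max, ~db_min, ~db_max,
    "PC",         24L,          44L,          0L,      12L,
    "PE",         24L,          44L,          0L,      12L,
    "SM",         28L,          44L,          0L,      8L,
    "DG",         24L,          44L,          0L,      12L,
    "TG",         36L,          68L,          0L,      18L,
    "CE",         12L,          24L,          0L,      6L,
    "Chol",       0L,           0L,           0L,      0L
  )
}

#' Build a lipid annotation target list for one polarity
#'
#' Enumerates every sum-composition species allowed by the class
#' configuration, derives its molecular formula and monoisotopic mass, and
#' applies every adduct of the requested polarity to yield expected m/z
#' values. The returned list is sorted ascending by expected m/z and carries a
#' `variable_id` (`"name adduct"`) that stays unique when like species are
#' observed under different adducts.
#'
#' @param class_config Tibble as returned by [default_class_config()]; an
#'   optional `carbons_step` column (default 1) restricts the carbon grid,
#'   e.g. 2 for even-carbon species only.
#' @param adduct_config Tibble as returned by [adducts()]; rows of other
#'   polarities are ignored.
#' @param polarity `"+"` or `"-"`.
#' @return A tibble of class `target_list` with columns `variable_id`, `name`,
#'   `lipid_class`, `carbons`, `double_bonds`, `formula`, `mass`, `adduct`,
#'   `polarity`, `expected_mz`.
#' @examples
#' tl <- build_target_list(polarity = "+")
#' nrow(tl)
#' @export
build_target_list <- function(class_config = default_class_config(),
                              adduct_config = adducts(),
                              polarity = c("+", "-")) {
  polarity <- match.arg(polarity)
  adduct_config <- adduct_config[adduct_config$polarity == polarity, , drop = FALSE]
  if (nrow(adduct_config) == 0) {
    rlang::abort(sprintf("No adducts configured for polarity '%s'.", polarity))
  }
  if (nrow(class_config) == 0) {
    rlang::abort("Empty class configuration.")
  }

  species <- purrr::pmap_dfr(class_config, function(lipid_class, carbons_min, carbons_max,
                                                   db_min, db_max, carbons_step = 1L, ...) {
    grid <- tidyr::expand_grid(carbons = seq.int(carbons_min, carbons_max, by = max(carbons_step, 1L)),
                               double_bonds = seq.int(db_min, db_max))
    grid <- grid[grid$double_bonds <= grid$carbons / 2 | lipid_class == "Chol", , drop = FALSE]
    grid$lipid_class <- lipid_class
    grid
  })
  if (nrow(species) == 0) {
    rlang::abort("Class configuration yields no species; check the ranges.")
  }
  species$formula <- purrr::pmap_chr(
    species[c("lipid_class", "carbons", "double_bonds")],
    function(lipid_class, carbons, double_bonds) species_formula(lipid_class, carbons, double_bonds)
  )
  species$mass <- purrr::map_dbl(species$formula, monoisotopic_mass)
  species$name <- lipid_name(species$lipid_class, species$carbons, species$double_bonds)

  entries <- tidyr::expand_grid(species, adduct_config["adduct"])
  entries$polarity <- polarity
  entries$expected_mz <- adduct_mz(entries$mass, entries$adduct)
  entries$variable_id <- paste(entries$name, entries$adduct)
  entries <- entries[order(entries$expected_mz, entries$variable_id), ]
  entries <- entries[c("variable_id", "name", "lipid_class", "carbons", "double_bonds",
                       "formula", "mass", "adduct", "polarity", "expected_mz")]
  if (anyDuplicated(entries$variable_id)) {
    rlang::abort("Duplicate (species, adduct) pairs in target list.")
  }
  new_target_list(entries, polarity)
}

new_target_list <- function(x, polarity) {
  x <- tibble::as_tibble(x)
  class(x) <- c("target_list", class(x))
  attr(x, "polarity") <- polarity
  x
}

#' Write / read a target list as a tab-separated table
#'
#' m/z values are written in 10-decimal-place fixed point so the round trip is
#' lossless at annotation precision.
#'
#' @param targets A `target_list` tibble.
#' @param path File path.
#' @return `read_target_list()` returns the `target_list` tibble.
#' @export
write_target_list <- function(targets, path) {
  out <- targets
  out$expected_mz <- sprintf("%.10f", out$expected_mz)
  out$mass <- sprintf("%.10f", out$mass)
  readr::write_tsv(as.data.frame(out), path)
  invisible(path)
}

#' @rdname write_target_list
#' @export
read_target_list <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         variable_id = "c", name = "c", lipid_class = "c",
                         carbons = "i", double_bonds = "i", formula = "c",
                         mass = "d", adduct = "c", polarity = "c", expected_mz = "d"
                       ))
  pol <- unique(x$polarity)
  if (length(pol) != 1 || !pol %in% c("+", "-")) {
    rlang::abort(sprintf("Target list at '%s' must carry exactly one polarity.", path))
  }
  x <- x[order(x$expected_mz, x$variable_id), ]
  new_target_list(x, pol)
}
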