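# Principal component analysis of normalized lipid profiles, and a
# silhouette-based summary of group separation in score space.

#' Principal component analysis of a lipid intensity matrix
#'
#' Column-mean-centred (optionally unit-variance-scaled) PCA by singular value
#' decomposition of the samples-by-variables matrix. Zeros are taken as zero
#' abundance by default (the standard DI-MS convention after per-mille
#' normalization); `zero_handling = "half_min"` instead imputes each
#' variable's zeros as half its smallest measured value before decomposition.
#' Constant (zero-variance) variables carry no information and are dropped
#' with a message; a matrix left with fewer than 2 variables is degenerate and
#' rejected.
#'
#' @param mat Wide (normalized) intensity tibble, >= 2 samples and variables.
#' @param n_components Number of components to keep; at most
#'   `min(n_samples - 1, n_variables)`.
#' @param scaling `"unit"` (centre and scale to unit variance, the common
#'   metabolomics default) or `"center"` (centre only).
#' @param zero_handling `"zero"` (default) or `"half_min"`.
#' @return A `dims_pca` object: `$scores` (tibble `sample_id`, `PC1`, ...),
#'   `$loadings` (tibble `variable_id`, `PC1`, ...), `$explained_variance`
#'   (fraction per kept component), `$sdev` (all singular-value sds),
#'   `$params`.
#' @export
dims_pca <- function(mat, n_components = 2,
                     scaling = c("unit", "center"),
                     zero_handling = c("zero", "half_min")) {
  scaling <- match.arg(scaling)
  zero_handling <- match.arg(zero_handling)
  if (!is.data.frame(mat) || !identical(names(mat)[1], "sample_id")) {
    rlang::abort("PCA input is a wide data frame whose first column is sample_id.")
  }
  m <- mat_values(mat)
  if (nrow(m) < 2 || ncol(m) < 2) {
    rlang::abort("PCA needs at least 2 samples and 2 variables.")
  }
  if (zero_handling == "half_min") {
    m <- apply(m, 2, function(v) {
      pos <- v[v > 0]
      if (length(pos) > 0) v[v == 0] <- min(pos) / 2
      v
    })
  }
  constant <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (all(constant)) {
    rlang::abort("Degenerate input: every variable is constant across samples.")
  }
  if (any(constant)) {
    rlang::inform(sprintf("Dropping %d constant variable(s) before PCA.", sum(constant)))
    m <- m[, !constant, drop = FALSE]
  }
  if (ncol(m) < 2) rlang::abort("Fewer than 2 informative variables; PCA is degenerate.")
  max_comp <- min(nrow(m) - 1L, ncol(m))
  if (n_components > max_comp) {
    rlang::abort(sprintf("n_components must be <= min(n_samples - 1, n_variables) = %d.",
                         max_comp))
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = (scaling == "unit"), rank. = n_components)
  var_all <- fit$sdev^2
  explained <- (var_all / sum(var_all))[seq_len(n_components)]
  scores <- tibble::as_tibble(fit$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), scores)
  loadings <- tibble::as_tibble(fit$rotation[, seq_len(n_components), drop = FALSE])
  loadings <- dplyr::bind_cols(tibble::tibble(variable_id = colnames(m)), loadings)
  structure(
    list(scores = scores, loadings = loadings, explained_variance = explained,
         sdev = fit$sdev,
         params = list(n_components = n_components, scaling = scaling,
                       zero_handling = zero_handling,
                       n_dropped_constant = sum(constant))),
    class = "dims_pca")
}

#' @export
print.dims_pca <- function(x, ...) {
  cat(sprintf("PCA: %d samples x %d variables, %d component(s)\n",
              nrow(x$scores), nrow(x$loadings), length(x$explained_variance)))
  cat("Explained variance:", paste0(sprintf("%.1f%%", 100 * x$explained_variance),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Tidy / glance methods for a PCA fit
#'
#' `tidy()` returns scores, loadings or the eigenvalue table;
#' `glance()` a one-row model summary.
#'
#' @param x A `dims_pca` object.
#' @param matrix Which component to return: `"scores"`, `"loadings"` or
#'   `"eigenvalues"`.
#' @param ... Unused.
#' @method tidy dims_pca
#' @export
tidy.dims_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") return(x$scores)
  if (matrix == "loadings") return(x$loadings)
  tibble::tibble(
    component = seq_along(x$sdev),
    std_dev = x$sdev,
    explained_variance = x$sdev^2 / sum(x$sdev^2),
    cumulative = cumsum(x$sdev^2) / sum(x$sdev^2)
  )
}

#' @rdname tidy.dims_pca
#' @method glance dims_pca
#' @export
glance.dims_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_variables = nrow(x$loadings),
    n_components = length(x$explained_variance),
    explained_variance_total = sum(x$explained_variance),
    scaling = x$params$scaling
  )
}

#' Silhouette-style group-separation score
#'
#' Mean silhouette coefficient of the labelled groups in PCA score space
#' (Euclidean distance). Ranges over [-1, 1]; values near 0 indicate
#' overlapping groups, values above ~0.5 clearly separated ones.
#'
#' @param scores A scores tibble (`sample_id` + numeric score columns), e.g.
#'   `tidy(fit, "scores")`.
#' @param labels Group label per score row (>= 2 distinct groups).
#' @return Mean silhouette width (single number).
#' @export
group_separation <- function(scores, labels) {
  s <- as.matrix(scores[setdiff(names(scores), "sample_id")])
  labels <- as.factor(labels)
  if (length(labels) != nrow(s)) {
    rlang::abort("labels must have one entry per score row.")
  }
  if (nlevels(droplevels(labels)) < 2) {
    rlang::abort("group_separation needs >= 2 distinct groups.")
  }
  sil <- cluster::silhouette(as.integer(droplevels(labels)), stats::dist(s))
  mean(sil[, "sil_width"])
}
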