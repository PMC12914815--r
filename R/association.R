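#' Classify a variable as ordinal or continuous
#'
#' A variable is treated as ordinal when every value is an integer and it
#' takes at most 7 distinct levels — the coarseness typical of questionnaire
#' scores. Everything else is continuous. Constant variables cannot be
#' correlated and raise an error.
#'
#' @param values numeric vector.
#' @return `"ordinal"` or `"continuous"`.
#' @export
classify_variable <- function(values) {
  if (anyNA(values)) stop("missing values are not supported (complete cases only)")
  u <- unique(values)
  if (length(u) < 2L) stop("constant variable: zero variance cannot be correlated")
  if (all(u == round(u)) && length(u) <= 7L) "ordinal" else "continuous"
}

# Shapiro-Wilk normality screen; deterministic evenly-spaced subsample above
# the test's n = 5000 limit (the statistic is order-invariant)
passes_normality <- function(x, alpha = 0.05) {
  if (length(x) > 5000L) x <- x[round(seq(1L, length(x), length.out = 5000L))]
  if (length(unique(x)) < 3L) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

#' Automatic mixed-type correlation matrix
#'
#' Emulates automatic correlation-type selection for mixed
#' ordinal/continuous data: a pair is correlated by Spearman's rank
#' correlation when either member is ordinal or fails a Shapiro-Wilk
#' normality screen (at 0.05), and by Pearson otherwise. The assembled
#' matrix is symmetrized, given a unit diagonal and, if indefinite, projected
#' to the nearest positive semi-definite correlation matrix (see
#' [nearest_psd()]).
#'
#' @param table a [cohort_table()] or numeric matrix (participants x nodes).
#' @return object of class `association_matrix`: `matrix` (correlations),
#'   `method` (node x node matrix of "pearson"/"spearman"), `psd_corrected`.
#' @export
auto_correlate <- function(table) {
  vals <- if (inherits(table, "cohort_table")) table$values else as.matrix(table)
  if (is.null(colnames(vals))) colnames(vals) <- paste0("V", seq_len(ncol(vals)))
  if (nrow(vals) < 3L) stop("need at least 3 participants to correlate")
  types <- vapply(colnames(vals), function(v) classify_variable(vals[, v]), "")
  normal <- vapply(colnames(vals), function(v)
    types[v] == "continuous" && passes_normality(vals[, v]), TRUE)
  rank_based <- types == "ordinal" | !normal

  Rp <- stats::cor(vals, method = "pearson")
  Rs <- stats::cor(vals, method = "spearman")
  use_s <- outer(rank_based, rank_based, `|`)
  R <- ifelse(use_s, Rs, Rp)
  R <- (R + t(R)) / 2
  diag(R) <- 1

  method <- matrix(ifelse(use_s, "spearman", "pearson"), ncol(vals),
                   dimnames = dimnames(R))
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  corrected <- ev_min < -1e-8
  if (corrected) R <- nearest_psd(R)
  structure(list(matrix = R, method = method, psd_corrected = corrected),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  p <- ncol(x$matrix)
  n_s <- sum(x$method[upper.tri(x$method)] == "spearman")
  cat("Association matrix:", p, "nodes;", n_s, "of", possible_edges(p),
      "pairs rank-based (Spearman)",
      if (x$psd_corrected) "; PSD-corrected" else "", "\n", sep = "")
  invisible(x)
}

#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below a small floor are raised to it, the
#' matrix is reconstructed and rescaled back to unit diagonal. A matrix that
#' is already positive semi-definite is returned unchanged.
#'
#' @param m symmetric matrix with unit diagonal.
#' @param floor smallest admissible eigenvalue before rescaling.
#' @return symmetric PSD matrix with unit diagonal.
#' @export
nearest_psd <- function(m, floor = 1e-8) {
  if (max(abs(m - t(m))) > 1e-12) stop("'m' must be symmetric")
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) return(m)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}
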