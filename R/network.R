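#' Estimation settings for the regularized network
#'
#' @param gamma EBIC hyperparameter; 0.5 (the default) prefers sparser
#'   models, 0 reduces EBIC to BIC.
#' @param n_lambdas length of the penalty path.
#' @param lambda_min_ratio smallest/largest penalty on the path.
#' @param convergence_tol relative convergence tolerance of the graphical
#'   lasso (scaled by the mean absolute off-diagonal of the input matrix).
#' @param max_iter maximum outer iterations of the block coordinate descent.
#' @param edge_zero_tol absolute partial correlations at or below this value
#'   are treated as exact zeros ("no edge").
#' @return list of class `estimation_config`.
#' @export
estimation_config <- function(gamma = 0.5, n_lambdas = 100L,
                              lambda_min_ratio = 0.01,
                              convergence_tol = 1e-4, max_iter = 200L,
                              edge_zero_tol = 1e-6) {
  stopifnot(gamma >= 0, n_lambdas >= 2L,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(gamma = gamma, n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio,
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter),
                 edge_zero_tol = edge_zero_tol),
            class = "estimation_config")
}

#' Penalty path for the graphical lasso
#'
#' Log-spaced descending sequence from `lambda_max` (the largest absolute
#' off-diagonal correlation, at which the estimated graph is empty) down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param S correlation matrix.
#' @param config an [estimation_config()].
#' @return numeric vector of penalties, strictly decreasing; a single `0`
#'   (with a warning) when all off-diagonals are zero.
#' @export
lambda_path <- function(S, config = estimation_config()) {
  off <- abs(S[upper.tri(S)])
  lmax <- if (length(off)) max(off) else 0
  if (lmax <= 0) {
    warning("all off-diagonal correlations are zero; degenerate single-point path")
    return(0)
  }
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$n_lambdas))
}

#' L1-penalized precision-matrix estimate
#'
#' Solves the graphical-lasso problem
#' `max_K  log det K - tr(SK) - lambda * sum_{i != j} |K_ij|`
#' (diagonal unpenalized) by block coordinate descent. At `lambda = 0` and a
#' well-conditioned `S` this is the unpenalized Gaussian MLE `solve(S)`.
#'
#' @param S positive semi-definite correlation (or covariance) matrix.
#' @param lambda non-negative penalty.
#' @param config an [estimation_config()] (convergence controls).
#' @return symmetric positive-definite precision matrix.
#' @export
graphical_lasso <- function(S, lambda, config = estimation_config()) {
  S <- as.matrix(S)
  if (lambda < 0) stop("'lambda' must be non-negative")
  fit <- .glasso_cpp(S, lambda, tol = config$convergence_tol,
                     max_iter = config$max_iter)
  if (!fit$converged)
    stop(sprintf("graphical lasso did not converge at lambda = %.4g within %d iterations",
                 lambda, config$max_iter))
  K <- fit$K
  dimnames(K) <- dimnames(S)
  K
}

#' Extended Bayesian Information Criterion of a fitted precision matrix
#'
#' `EBIC = -2 L + E log(n) + 4 E gamma log(p)` with Gaussian log-likelihood
#' `L = (n/2) (log det K - tr(SK) + p)`, `E` the number of nonzero
#' off-diagonal pairs and `p` the node count. The additive constant `np/2`
#' normalizes L so that the empty independence model (`K = S = I`) scores
#' exactly zero; being constant in `K` it cannot affect model selection.
#' `gamma = 0` recovers the ordinary BIC.
#'
#' @param K positive-definite precision matrix.
#' @param S the correlation matrix the model was fitted to.
#' @param n sample size.
#' @param gamma EBIC hyperparameter.
#' @param edge_zero_tol threshold below which entries count as zero.
#' @return the EBIC score (smaller is better).
#' @export
ebic_score <- function(K, S, n, gamma = 0.5, edge_zero_tol = 1e-6) {
  ch <- tryCatch(chol(K), error = function(e) stop("'K' must be positive definite"))
  p <- ncol(K)
  E <- sum(abs(K[upper.tri(K)]) > edge_zero_tol)
  logdet <- 2 * sum(log(diag(ch)))
  L <- (n / 2) * (logdet - sum(S * K) + p)
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

#' Partial correlations from a precision matrix
#'
#' Standard Gaussian graphical model identity
#' `w_ij = -K_ij / sqrt(K_ii K_jj)`, diagonal set to 0. The zero pattern of
#' `K` is preserved and the result is invariant to scaling of `K`.
#'
#' @param K symmetric precision matrix with positive diagonal.
#' @return symmetric partial-correlation matrix with zero diagonal.
#' @export
precision_to_pcor <- function(K) {
  d <- diag(K)
  if (any(d <= 0)) stop("precision diagonal must be positive")
  W <- -K / sqrt(tcrossprod(d))
  diag(W) <- 0
  (W + t(W)) / 2
}

#' Fit a regularized partial-correlation network
#'
#' The package's central fitting function. Runs the full estimation chain on
#' a (residualized, complete-case) cohort: mixed-type correlation matrix
#' ([auto_correlate()]), penalty path ([lambda_path()]), graphical lasso per
#' penalty ([graphical_lasso()]), EBIC model selection ([ebic_score()]; ties
#' resolved toward the larger penalty, i.e. the sparser model), and
#' conversion to partial correlations ([precision_to_pcor()]).
#'
#' @param table a [cohort_table()] (typically the output of [residualize()]).
#' @param config an [estimation_config()].
#' @return object of class `pcor_network` with elements `weights` (symmetric
#'   partial-correlation matrix, zero diagonal), `precision`, `layers`,
#'   `lambda` (selected penalty), `ebic_path` (data.frame: lambda, ebic,
#'   n_edges), `n`, `density`, `band`, `association`, `config`.
#' @seealso [density_band()], [bridge_strength()], [case_drop_bootstrap()]
#' @export
estimate_network <- function(table, config = estimation_config()) {
  stopifnot(inherits(table, "cohort_table"))
  p <- ncol(table$values)
  if (table$n <= p)
    warning("sample size does not exceed node count; estimates will be unstable")
  assoc <- auto_correlate(table)
  S <- assoc$matrix
  path <- lambda_path(S, config)

  fits <- lapply(path, function(l) graphical_lasso(S, l, config))
  ebic <- vapply(fits, function(K)
    ebic_score(K, S, table$n, config$gamma, config$edge_zero_tol), 0)
  n_edges <- vapply(fits, function(K)
    sum(abs(precision_to_pcor(K)[upper.tri(K)]) > config$edge_zero_tol), 0L)
  best <- which.min(ebic)   # path is descending, so first minimum = larger lambda

  K <- fits[[best]]
  W <- precision_to_pcor(K)
  W[abs(W) <= config$edge_zero_tol] <- 0
  E <- sum(W[upper.tri(W)] != 0)
  dens <- E / possible_edges(p)

  structure(list(weights = W, precision = K, layers = table$layers,
                 lambda = path[best],
                 ebic_path = data.frame(lambda = path, ebic = ebic,
                                        n_edges = n_edges),
                 n = table$n, density = dens,
                 band = density_band(dens)$band,
                 association = assoc, config = config),
            class = "pcor_network")
}

#' Network density and its interpretive band
#'
#' Density is the fraction of possible node pairs carrying a nonzero edge.
#' Bands: `high` at 50% or more, `medium` from 30% to below 50%, `low`
#' below 30%.
#'
#' @param x a `pcor_network`, or a number: an edge count (with `possible`
#'   given) or a density fraction in `[0, 1]`.
#' @param possible total possible edges, required when `x` is an edge count.
#' @return list with `fraction`, `percent`, `band` and, when available,
#'   `n_edges`, `n_possible`.
#' @examples
#' density_band(28, possible = 45)  # 62.2%, high
#' @export
density_band <- function(x, possible = NULL) {
  if (inherits(x, "pcor_network")) {
    E <- sum(x$weights[upper.tri(x$weights)] != 0)
    return(density_band(E, possible_edges(ncol(x$weights))))
  }
  if (!is.null(possible)) {
    frac <- x / possible
    out <- list(fraction = frac, percent = 100 * frac,
                n_edges = x, n_possible = possible)
  } else {
    if (x < 0 || x > 1) stop("a bare density must lie in [0, 1]")
    out <- list(fraction = x, percent = 100 * x)
  }
  out$band <- if (out$fraction >= 0.5) "high"
              else if (out$fraction >= 0.3) "medium" else "low"
  out
}

#' @export
print.pcor_network <- function(x, ...) {
  p <- ncol(x$weights)
  db <- density_band(x)
  cat("Regularized partial-correlation network\n")
  cat(sprintf("  %d nodes (%d layers), n = %d\n",
              p, length(unique(x$layers$layer)), x$n))
  cat(sprintf("  edges: %d / %d (density %.1f%%, %s)\n",
              db$n_edges, db$n_possible, db$percent, db$band))
  cat(sprintf("  selected lambda = %.4f (EBIC %.1f, gamma = %g)\n",
              x$lambda, min(x$ebic_path$ebic), x$config$gamma))
  invisible(x)
}

#' @export
summary.pcor_network <- function(object, ...) {
  es <- edge_summary(object)
  bp <- designate_bridges(bridge_strength(object))
  out <- list(network = object, edges = es, bridges = bp)
  class(out) <- "summary.pcor_network"
  out
}

#' @export
print.summary.pcor_network <- function(x, ...) {
  print(x$network)
  a <- x$edges$all_pairs; nz <- x$edges$nonzero
  cat(sprintf("  edge weights (all pairs): mean %.3f (SD %.3f), range [%.2f, %.2f]\n",
              a$mean, a$sd, a$min, a$max))
  if (!is.na(nz$mean))
    cat(sprintf("  edge weights (nonzero):   mean %.3f (SD %.3f), range [%.2f, %.2f]\n",
                nz$mean, nz$sd, nz$min, nz$max))
  cat("\n")
  print(x$bridges)
  invisible(x)
}

#' @export
coef.pcor_network <- function(object, ...) object$weights

#' Simulate data from a fitted network
#'
#' Draws multivariate-normal samples whose precision matrix equals the
#' fitted (correlation-scale) precision — a parametric bootstrap of the
#' selected Gaussian graphical model.
#'
#' @param object a `pcor_network`.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return numeric matrix (`nsim` x nodes).
#' @export
simulate.pcor_network <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  Sigma <- solve(object$precision)
  L <- chol((Sigma + t(Sigma)) / 2)
  Z <- matrix(stats::rnorm(nsim * ncol(Sigma)), nsim) %*% L
  colnames(Z) <- colnames(object$weights)
  Z
}
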