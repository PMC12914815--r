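#' Generate a ground-truth multilayer precision matrix
#'
#' Builds a sparse symmetric positive-definite precision matrix over a set of
#' layers, with dense within-layer connectivity and sparse, weaker
#' between-layer connectivity — the generative structure a multilayer Gaussian
#' graphical model analysis assumes. Optionally, between-layer edges can be
#' concentrated on a designated set of "planted" bridge nodes, which gives a
#' known answer for recovery experiments.
#'
#' Positive definiteness is enforced by diagonal inflation: starting from a
#' unit diagonal, a ridge `delta * I` is added with `delta` doubling until the
#' smallest eigenvalue reaches `spd_margin`. This preserves the sampled
#' sparsity pattern exactly.
#'
#' @param layer_sizes integer vector of nodes per layer (e.g. `c(4, 6, 8)`).
#' @param within_density fraction of within-layer pairs that receive an edge
#'   (recycled per layer).
#' @param between_density fraction of eligible between-layer pairs that
#'   receive an edge (recycled per layer pair).
#' @param weight_range interval (length-2 numeric) from which off-diagonal
#'   precision magnitudes are drawn; must not contain 0.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @param layer_names optional layer labels; defaults to
#'   mental_health/cognition/gmv for 3 layers, else `L1, L2, ...`.
#' @param node_names optional node names; defaults to the standard tri-layer
#'   names when the sizes are `c(4, 6, 8)`.
#' @param bridge_nodes optional node names (or indices) on which all
#'   between-layer edges are concentrated; each receives
#'   `bridge_edges_per_node` guaranteed interlayer edges and no between-layer
#'   edge touches a non-bridge pair.
#' @param bridge_edges_per_node interlayer edges guaranteed per planted
#'   bridge node.
#' @param mix_signs if `TRUE` each off-diagonal entry's sign is flipped with
#'   probability 1/2 (edge signs in empirical networks are mixed).
#' @param between_weight_scale multiplier applied to between-layer magnitudes
#'   (interlayer edges are typically weaker than intralayer ones).
#' @param spd_margin required smallest eigenvalue after diagonal inflation.
#' @param age_effect,tiv_effect,site_sd,n_sites confounder structure stored in
#'   the model: a standardized-age coefficient for every node (negated on gmv
#'   nodes, where volume declines with age), a standardized-TIV coefficient
#'   and additive per-site shifts (SD `site_sd`, `n_sites` sites) for gmv
#'   nodes only.
#' @param ordinal_levels number of levels for ordinal (questionnaire-like)
#'   nodes; `0` disables discretization.
#' @param ordinal_layers layers whose nodes are discretized into ordinal
#'   scores (default: the mental-health layer if present).
#' @return An object of class `true_model`: `precision`, `layers`
#'   (a [layer_spec()]), `confounders` (per-node `age`, `tiv` coefficients and
#'   a `site_shift` matrix), `ordinal` (per-node latent cutpoints),
#'   `bridge_nodes`.
#' @seealso [sample_cohort()]
#' @export
make_multilayer_precision <- function(layer_sizes,
                                      within_density = 0.5,
                                      between_density = 0.08,
                                      weight_range = c(0.2, 0.4),
                                      seed = 1L,
                                      layer_names = NULL,
                                      node_names = NULL,
                                      bridge_nodes = NULL,
                                      bridge_edges_per_node = 3L,
                                      mix_signs = TRUE,
                                      between_weight_scale = 0.6,
                                      spd_margin = 0.05,
                                      age_effect = 0.25,
                                      tiv_effect = 0.5,
                                      site_sd = 0.3,
                                      n_sites = 4L,
                                      ordinal_levels = 5L,
                                      ordinal_layers = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) stop("need at least 2 layers")
  if (any(layer_sizes < 1L)) stop("layer sizes must be positive")
  if (length(weight_range) != 2L || diff(weight_range) < 0)
    stop("'weight_range' must be an interval c(lo, hi)")
  if (weight_range[1] <= 0 && weight_range[2] >= 0)
    stop("'weight_range' must exclude 0")
  stopifnot(all(within_density >= 0 & within_density <= 1),
            all(between_density >= 0 & between_density <= 1))

  nl <- length(layer_sizes)
  if (is.null(layer_names))
    layer_names <- if (nl == 3L) c("mental_health", "cognition", "gmv")
                   else paste0("L", seq_len(nl))
  if (is.null(node_names)) {
    node_names <- if (identical(layer_sizes, c(4L, 6L, 8L)))
      mtbi_layer_spec()$nodes
    else unlist(lapply(seq_len(nl), function(i)
      paste0(layer_names[i], "_", seq_len(layer_sizes[i]))))
  }
  p <- sum(layer_sizes)
  stopifnot(length(node_names) == p)
  lay <- split(node_names, rep(seq_len(nl), layer_sizes))
  names(lay) <- layer_names
  spec <- layer_spec(lay)
  memb <- match(spec$layer, layer_names)   # layer index per node

  within_density <- rep_len(within_density, nl)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  if (!is.null(bridge_nodes)) {
    if (is.numeric(bridge_nodes)) bridge_nodes <- node_names[bridge_nodes]
    if (!all(bridge_nodes %in% node_names))
      stop("unknown bridge node(s): ",
           paste(setdiff(bridge_nodes, node_names), collapse = ", "))
  }

  draw_weight <- function(k, scale = 1) {
    w <- stats::runif(k, weight_range[1], weight_range[2]) * scale
    if (mix_signs) w <- w * sample(c(-1, 1), k, replace = TRUE)
    w
  }

  K <- matrix(0, p, p, dimnames = list(node_names, node_names))
  # within-layer blocks
  for (l in seq_len(nl)) {
    id <- which(memb == l)
    if (length(id) < 2L) next
    prs <- utils::combn(id, 2L)
    on_edge <- stats::runif(ncol(prs)) < within_density[l]
    w <- draw_weight(sum(on_edge))
    K[t(prs[, on_edge, drop = FALSE])] <- w
  }
  # between-layer blocks
  if (is.null(bridge_nodes)) {
    pair_k <- 0L
    bd <- rep_len(between_density, nl * (nl - 1L) / 2L)
    for (l1 in seq_len(nl - 1L)) for (l2 in seq(l1 + 1L, nl)) {
      pair_k <- pair_k + 1L
      prs <- as.matrix(expand.grid(which(memb == l1), which(memb == l2)))
      on_edge <- stats::runif(nrow(prs)) < bd[pair_k]
      w <- draw_weight(sum(on_edge), between_weight_scale)
      K[prs[on_edge, , drop = FALSE]] <- w
    }
  } else {
    # all between-layer structure is concentrated on the planted bridge
    # nodes: each gets bridge_edges_per_node interlayer edges, with partners
    # chosen load-balanced so no single non-bridge node accumulates enough
    # interlayer weight to rival a planted bridge
    inter_deg <- integer(p)
    for (b in sample(bridge_nodes)) {
      bi <- match(b, node_names)
      others <- which(memb != memb[bi])
      for (k in seq_len(as.integer(bridge_edges_per_node))) {
        free <- others[K[pmin(bi, others) + p * (pmax(bi, others) - 1L)] == 0]
        free <- setdiff(free, bi)
        if (!length(free)) break
        cand <- free[inter_deg[free] == min(inter_deg[free])]
        pick <- cand[sample.int(length(cand), 1L)]
        K[min(bi, pick), max(bi, pick)] <- draw_weight(1L, between_weight_scale)
        inter_deg[pick] <- inter_deg[pick] + 1L
        inter_deg[bi] <- inter_deg[bi] + 1L
      }
    }
  }
  K[lower.tri(K)] <- 0
  K <- K + t(K)
  diag(K) <- 1

  # diagonal inflation to SPD
  delta <- spd_margin
  while (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < spd_margin) {
    diag(K) <- diag(K) + delta
    delta <- 2 * delta
  }

  # confounder structure
  gmv_layer <- if ("gmv" %in% layer_names) "gmv" else layer_names[nl]
  is_gmv <- spec$layer == gmv_layer
  age <- rep(age_effect, p) * ifelse(is_gmv, -1, 1)
  tiv <- ifelse(is_gmv, tiv_effect, 0)
  names(age) <- names(tiv) <- node_names
  site_shift <- matrix(0, n_sites, p,
                       dimnames = list(paste0("site", seq_len(n_sites)), node_names))
  site_shift[, is_gmv] <- stats::rnorm(n_sites * sum(is_gmv), sd = site_sd)

  # ordinal nodes: latent-normal cutpoints at fixed cumulative probabilities,
  # right-skewed as questionnaire sum-scores are
  ordinal <- list()
  if (ordinal_levels >= 2L) {
    if (is.null(ordinal_layers))
      ordinal_layers <- intersect("mental_health", layer_names)
    ord_nodes <- node_names[spec$layer %in% ordinal_layers]
    if (length(ord_nodes)) {
      probs <- stats::qnorm(seq(0.5, 0.97, length.out = ordinal_levels - 1L))
      Sigma <- solve(K)
      for (nd in ord_nodes) {
        sd_j <- sqrt(Sigma[nd, nd] + age[nd]^2)
        ordinal[[nd]] <- probs * sd_j
      }
    }
  }

  structure(list(precision = K, layers = spec,
                 confounders = list(age = age, tiv = tiv, site_shift = site_shift),
                 ordinal = ordinal, bridge_nodes = bridge_nodes,
                 seed = as.integer(seed)),
            class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  p <- ncol(x$precision)
  E <- sum(x$precision[upper.tri(x$precision)] != 0)
  cat("True multilayer model:", p, "nodes,", E, "of", possible_edges(p),
      "possible edges\n")
  if (!is.null(x$bridge_nodes))
    cat("Planted bridge nodes:", paste(x$bridge_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Model-implied partial correlations of a true model
#'
#' @param model a `true_model`.
#' @return symmetric matrix of true partial correlations (zero diagonal).
#' @export
true_pcor <- function(model) precision_to_pcor(model$precision)

#' Sample a synthetic cohort from a true model
#'
#' Draws latent multivariate-normal scores with covariance equal to the
#' inverse of the model precision, adds the model's confounder effects
#' (standardized age on all nodes; standardized TIV and additive site shifts
#' on gray-matter nodes), then discretizes ordinal nodes at their fixed
#' latent cutpoints into small-integer scores.
#'
#' @param model a `true_model` from [make_multilayer_precision()].
#' @param n number of participants.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param covariate_config optional list overriding the covariate
#'   distributions: `age_mean`, `age_sd`, `age_range`, `tiv_mean`, `tiv_sd`.
#'   Defaults emulate a middle-aged adult trauma cohort
#'   (age ~ N(38.3, 16.0) truncated to 17-83 years; TIV ~ N(1.55e6, 1.5e5) mm^3).
#' @return A [cohort_table()].
#' @export
sample_cohort <- function(model, n, seed = 1L, covariate_config = list()) {
  stopifnot(inherits(model, "true_model"))
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  cfg <- utils::modifyList(list(age_mean = 38.3, age_sd = 16.0,
                                age_range = c(17, 83),
                                tiv_mean = 1.55e6, tiv_sd = 1.5e5),
                           covariate_config)
  p <- ncol(model$precision)
  Sigma <- solve(model$precision)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  age <- pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd),
                   cfg$age_range[1]), cfg$age_range[2])
  tiv <- stats::rnorm(n, cfg$tiv_mean, cfg$tiv_sd)
  sites <- rownames(model$confounders$site_shift)
  site <- sites[sample.int(length(sites), n, replace = TRUE)]

  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% L
  colnames(Z) <- colnames(model$precision)

  z_age <- if (isTRUE(stats::sd(age) > 0)) (age - mean(age)) / stats::sd(age) else age * 0
  z_tiv <- if (isTRUE(stats::sd(tiv) > 0)) (tiv - mean(tiv)) / stats::sd(tiv) else tiv * 0
  X <- Z +
    outer(z_age, model$confounders$age) +
    outer(z_tiv, model$confounders$tiv) +
    model$confounders$site_shift[site, , drop = FALSE]

  for (nd in names(model$ordinal))
    X[, nd] <- findInterval(X[, nd], model$ordinal[[nd]])

  cohort_table(X, model$layers,
               data.frame(age = age, tiv = tiv, site = site,
                          stringsAsFactors = FALSE))
}
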