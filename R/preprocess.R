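#' Global Severity Index from BSI-18 subscales
#'
#' The GSI is the sum of the anxiety, somatization and depression subscale
#' scores of the Brief Symptom Inventory 18. By linearity the same identity
#' holds for subscale means.
#'
#' @param anx,som,dep non-negative subscale scores (or subscale means).
#' @return `anx + som + dep`.
#' @examples compute_gsi(2.74, 2.54, 2.83)
#' @export
compute_gsi <- function(anx, som, dep) {
  if (any(c(anx, som, dep) < 0)) stop("BSI-18 subscale scores cannot be negative")
  anx + som + dep
}

#' Insomnia Severity Index category
#'
#' Bands a total ISI score (0-28) using the instrument's standard published
#' cutpoints: 0-7 no clinically significant insomnia, 8-14 subthreshold,
#' 15-21 moderate, 22-28 severe.
#'
#' @param total_isi integer score(s) in 0-28.
#' @return factor with levels `none`, `subthreshold`, `moderate`, `severe`.
#' @export
isi_category <- function(total_isi) {
  if (any(total_isi != round(total_isi)) || any(total_isi < 0) || any(total_isi > 28))
    stop("ISI total must be an integer in [0, 28]")
  cut(total_isi, breaks = c(-1, 7, 14, 21, 28),
      labels = c("none", "subthreshold", "moderate", "severe"))
}

#' Covariate specification for residualization
#'
#' Lists, per node, the covariates regressed out before network estimation.
#' The default mirrors the standard multilayer-network protocol: age for every
#' node, plus total intracranial volume and scanning site for gray-matter
#' volume nodes.
#'
#' @param layers a [layer_spec()].
#' @param all_nodes covariates removed from every node.
#' @param gmv_extra additional covariates removed from nodes of `gmv_layer`.
#' @param gmv_layer layer label treated as the gray-matter layer (ignored if
#'   absent from the spec).
#' @return named list node -> character vector of covariate names, class
#'   `covariate_spec`.
#' @export
covariate_spec <- function(layers, all_nodes = "age",
                           gmv_extra = c("tiv", "site"), gmv_layer = "gmv") {
  spec <- lapply(layers$nodes, function(nd) {
    if (identical(unname(layers$layer[nd]), gmv_layer))
      c(all_nodes, gmv_extra) else all_nodes
  })
  names(spec) <- layers$nodes
  structure(spec, class = "covariate_spec")
}

# design matrix for one node's covariate set; factors are dummy-expanded
# (reference cell = first level alphabetically)
build_design <- function(covariates, covs, node) {
  missing <- setdiff(covs, names(covariates))
  if (length(missing))
    stop(sprintf("node '%s': covariate(s) %s not present in the cohort table",
                 node, paste(sQuote(missing), collapse = ", ")))
  X <- matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covs) {
    v <- covariates[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v, levels = sort(unique(as.character(v))))
      if (nlevels(v) < 2L)
        stop(sprintf("node '%s': categorical covariate '%s' has a single level; design is rank deficient",
                     node, cv))
      D <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(D) <- paste0(cv, levels(v)[-1])
      X <- cbind(X, D)
    } else {
      X <- cbind(X, as.numeric(v))
      colnames(X)[ncol(X)] <- cv
    }
  }
  X
}

#' Residualize cohort nodes on their covariates
#'
#' Replaces each node by its least-squares residual from an ordinary
#' regression on that node's covariate set (intercept always included;
#' categorical covariates dummy-expanded). Residuals are exactly orthogonal
#' to every covariate column; node names, order and layers are unchanged.
#' Residualizing twice on the same specification is a no-op.
#'
#' @param table a [cohort_table()].
#' @param spec a [covariate_spec()]; defaults to the standard specification
#'   built from the table's layers.
#' @return the residualized [cohort_table()].
#' @export
residualize <- function(table, spec = covariate_spec(table$layers)) {
  stopifnot(inherits(table, "cohort_table"))
  vals <- table$values
  for (nd in colnames(vals)) {
    covs <- spec[[nd]]
    if (is.null(covs)) covs <- character()
    X <- build_design(table$covariates, covs, nd)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X))
      stop(sprintf("node '%s': rank-deficient design for covariates {%s}",
                   nd, paste(covs, collapse = ", ")))
    vals[, nd] <- qr.resid(qr_x, vals[, nd])
  }
  cohort_table(vals, table$layers, table$covariates)
}

#' Compare two cohorts variable by variable
#'
#' Welch two-sample t-tests per shared variable, with Benjamini-Hochberg
#' false-discovery-rate adjustment across the family of variables compared in
#' the call, flagged at the adjusted level `alpha`. Variables with zero
#' variance in both groups are reported with `t = 0`, `p = 1` and a
#' degenerate flag.
#'
#' @param table_a,table_b [cohort_table()]s (or numeric matrices/data.frames)
#'   with the same variable set; each group needs at least 2 participants.
#' @param alpha significance level applied to adjusted p-values.
#' @return data.frame of class `group_comparison`: per variable the group
#'   means, Welch t, raw and BH-adjusted p, and significance flag.
#' @export
group_compare <- function(table_a, table_b, alpha = 0.05) {
  va <- if (inherits(table_a, "cohort_table")) table_a$values else as.matrix(table_a)
  vb <- if (inherits(table_b, "cohort_table")) table_b$values else as.matrix(table_b)
  if (!setequal(colnames(va), colnames(vb)))
    stop("both groups must share the same variable set")
  vb <- vb[, colnames(va), drop = FALSE]
  if (nrow(va) < 2L || nrow(vb) < 2L) stop("each group needs >= 2 participants")

  res <- lapply(colnames(va), function(v) {
    x <- va[, v]; y <- vb[, v]
    degenerate <- stats::var(x) == 0 && stats::var(y) == 0
    if (degenerate) {
      warning(sprintf("variable '%s' has zero variance in both groups; p set to 1", v))
      data.frame(variable = v, mean_a = mean(x), mean_b = mean(y),
                 t = 0, p = 1, degenerate = TRUE)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      data.frame(variable = v, mean_a = mean(x), mean_b = mean(y),
                 t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
    }
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj <= alpha
  attr(res, "alpha") <- alpha
  class(res) <- c("group_comparison", class(res))
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (Welch t, BH-FDR at alpha =",
      attr(x, "alpha"), ")\n")
  df <- as.data.frame(x)
  df$p <- signif(df$p, 3); df$p_adj <- signif(df$p_adj, 3)
  df$t <- round(df$t, 2)
  df$mean_a <- round(df$mean_a, 2); df$mean_b <- round(df$mean_b, 2)
  print(df[, c("variable", "mean_a", "mean_b", "t", "p", "p_adj", "significant")],
        row.names = FALSE)
  invisible(x)
}
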