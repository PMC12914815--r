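#' Declare the layer membership of network nodes
#'
#' A layer specification assigns every node (variable) of a multilayer network
#' to exactly one layer, e.g. `mental_health`, `cognition` or `gmv`. The layer
#' partition is fixed a priori: it defines the communities used by bridge
#' centrality and the covariate sets used during residualization.
#'
#' @param layers a named list mapping layer label to a character vector of
#'   node names, e.g. `list(mental_health = c("ANX","DEP"), cognition = "ProcS")`.
#' @return An object of class `layer_spec` with elements `nodes` (ordered
#'   character vector) and `layer` (named character vector, node -> layer).
#' @examples
#' sp <- layer_spec(list(A = c("x1", "x2"), B = c("y1", "y2")))
#' sp$layer["y1"]
#' @export
layer_spec <- function(layers) {
  if (!is.list(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("'layers' must be a named list of node-name vectors")
  if (length(layers) < 2L)
    stop("a multilayer specification needs at least 2 layers")
  nodes <- unlist(layers, use.names = FALSE)
  if (anyDuplicated(nodes))
    stop("node names must be unique across layers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  layer <- rep(names(layers), vapply(layers, length, 1L))
  names(layer) <- nodes
  structure(list(nodes = nodes, layer = layer), class = "layer_spec")
}

#' @export
print.layer_spec <- function(x, ...) {
  cat("Layer specification:", length(x$nodes), "nodes in",
      length(unique(x$layer)), "layers\n")
  for (l in unique(x$layer))
    cat(sprintf("  %-14s %s\n", l, paste(x$nodes[x$layer == l], collapse = ", ")))
  invisible(x)
}

#' Default tri-layer specification for an mTBI-style cohort
#'
#' The 4 + 6 + 8 node layout used throughout the package's examples and
#' synthetic cohorts: four mental-health questionnaire scores, six cognitive
#' test scores, and eight regional gray-matter volumes from the
#' central-executive and salience systems.
#'
#' @param layers which layers to include (subset of
#'   `c("mental_health", "cognition", "gmv")`); the first two give the
#'   psychometric bi-layer layout.
#' @return A [layer_spec()].
#' @export
mtbi_layer_spec <- function(layers = c("mental_health", "cognition", "gmv")) {
  all <- list(
    mental_health = c("ANX", "DEP", "SOM", "INSOM"),
    cognition     = c("ProcS", "PsyS", "CogFl", "vIMM", "vINTER", "vDELAY"),
    gmv           = c("dlPFC", "dmPFC", "PPC", "CAU", "AntINS", "dACC", "AMYG", "THAL")
  )
  layers <- match.arg(layers, names(all), several.ok = TRUE)
  layer_spec(all[layers])
}

#' Assemble a cohort table
#'
#' The unit of data every pipeline stage consumes and produces: a complete
#' participants-by-nodes value matrix plus participant covariates (age in
#' years, total intracranial volume in mm^3, scanning site) and the layer
#' specification of the nodes.
#'
#' @param values numeric matrix (participants x nodes) with column names
#'   matching `layers$nodes`; no missing values are allowed (the analysis is
#'   complete-case by design).
#' @param layers a [layer_spec()].
#' @param covariates data.frame with one row per participant; columns used by
#'   the default covariate specification are `age`, `tiv` and `site`.
#' @return An object of class `cohort_table` with elements `values`,
#'   `covariates`, `layers` and `n`.
#' @export
cohort_table <- function(values, layers, covariates = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (anyNA(values)) stop("cohort values contain missing entries; only complete cases are supported")
  if (is.null(colnames(values))) colnames(values) <- layers$nodes
  if (!identical(sort(colnames(values)), sort(layers$nodes)))
    stop("column names of 'values' must match the layer-spec nodes")
  values <- values[, layers$nodes, drop = FALSE]
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(nrow(values)))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(values))
    stop("covariates must have one row per participant")
  structure(list(values = values, covariates = covariates,
                 layers = layers, n = nrow(values)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", x$n, "participants x", ncol(x$values), "nodes\n")
  print(x$layers)
  if (ncol(x$covariates))
    cat("Covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.cohort_table <- function(x, ...) {
  cbind(as.data.frame(x$values), x$covariates)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

# subset participants, keeping covariates aligned
subset_cohort <- function(table, idx) {
  cohort_table(table$values[idx, , drop = FALSE], table$layers,
               table$covariates[idx, , drop = FALSE])
}

#' Number of possible undirected edges among p nodes
#'
#' @param p node count.
#' @return `p * (p - 1) / 2`.
#' @examples possible_edges(10) # 45
#' @export
possible_edges <- function(p) {
  p <- as.integer(p)
  if (any(p < 0)) stop("'p' must be non-negative")
  p * (p - 1L) / 2
}
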