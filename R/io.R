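# Delimited-text, YAML/JSON and GraphML serialization of the pipeline's
# objects. Every writer has a reader that round-trips within float tolerance.

is_yaml_path <- function(path) grepl("\\.ya?ml$", path, ignore.case = TRUE)

#' Write / read a layer specification sidecar
#'
#' YAML or JSON (by file extension) mapping node -> layer plus a node ->
#' ordinal flag block.
#'
#' @param spec a [layer_spec()].
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @param ordinal optional character vector of ordinal node names.
#' @return `path`, invisibly.
#' @export
write_layer_spec <- function(spec, path, ordinal = character()) {
  obj <- list(layer = as.list(spec$layer),
              ordinal = as.list(stats::setNames(spec$nodes %in% ordinal,
                                                spec$nodes)))
  if (is_yaml_path(path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layer_spec
#' @return `read_layer_spec()`: a [layer_spec()] with attribute `ordinal`.
#' @export
read_layer_spec <- function(path) {
  if (!file.exists(path)) stop("layer-spec file not found: ", path)
  obj <- if (is_yaml_path(path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  lab <- unlist(obj$layer)
  groups <- split(names(lab), factor(lab, levels = unique(lab)))
  spec <- layer_spec(groups)
  # restore original node order
  spec$nodes <- names(lab)
  spec$layer <- lab[spec$nodes]
  attr(spec, "ordinal") <- names(which(unlist(obj$ordinal)))
  spec
}

#' Write / read a cohort table as delimited text
#'
#' Tab-separated values with a header row of node then covariate names, plus
#' a layer-spec sidecar written next to it (or at `spec_path`).
#'
#' @param table a [cohort_table()].
#' @param path output `.tsv`/`.csv` path (delimiter chosen by extension).
#' @param spec_path sidecar path; default replaces the extension with
#'   `.layers.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, spec_path = NULL) {
  if (is.null(spec_path))
    spec_path <- sub("\\.[^.]+$", ".layers.json", path)
  ordinal <- names(which(vapply(colnames(table$values), function(v)
    classify_variable(table$values[, v]) == "ordinal", TRUE)))
  write_layer_spec(table$layers, spec_path, ordinal = ordinal)
  df <- as.data.frame(table)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @return `read_cohort()`: a [cohort_table()].
#' @export
read_cohort <- function(path, spec_path = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.null(spec_path))
    spec_path <- sub("\\.[^.]+$", ".layers.json", path)
  spec <- read_layer_spec(spec_path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(spec$nodes, names(df))
  if (length(missing))
    stop("cohort file lacks node column(s): ", paste(missing, collapse = ", "))
  vals <- as.matrix(df[, spec$nodes, drop = FALSE])
  covs <- df[, setdiff(names(df), spec$nodes), drop = FALSE]
  cohort_table(vals, spec, covs)
}

#' Serialize a fitted network
#'
#' Writes three artifacts into `dir`: a square weight-matrix CSV
#' (`<prefix>_weights.csv`), a long-form edge list TSV
#' (`<prefix>_edges.tsv`: node_i, node_j, weight, layer_i, layer_j,
#' intra/inter flag), and a GraphML file with the layer as node attribute.
#'
#' @param network a `pcor_network`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_network <- function(network, dir, prefix = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  W <- network$weights
  wpath <- file.path(dir, paste0(prefix, "_weights.csv"))
  utils::write.csv(as.data.frame(W), wpath, row.names = TRUE)

  lab <- network$layers$layer[colnames(W)]
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  edges <- data.frame(node_i = colnames(W)[idx[, 1]],
                      node_j = colnames(W)[idx[, 2]],
                      weight = W[idx],
                      layer_i = unname(lab[idx[, 1]]),
                      layer_j = unname(lab[idx[, 2]]))
  edges$type <- ifelse(edges$layer_i == edges$layer_j, "intra", "inter")
  edges <- edges[order(-abs(edges$weight), edges$node_i, edges$node_j), ]
  epath <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(edges, epath, sep = "\t", row.names = FALSE, quote = FALSE)

  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$layer <- unname(lab)
  gpath <- file.path(dir, paste0(prefix, ".graphml"))
  igraph::write_graph(g, gpath, format = "graphml")
  invisible(c(weights = wpath, edges = epath, graphml = gpath))
}

#' Read a square weight-matrix CSV written by [write_network()]
#'
#' @param path the `*_weights.csv` file.
#' @return symmetric numeric matrix with node dimnames.
#' @export
read_weight_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write a bridge profile as TSV
#'
#' Columns: node, layer, bridge_strength, rank, is_bridge.
#'
#' @param profile a `bridge_profile`.
#' @param layers the [layer_spec()] of the network.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bridge_profile <- function(profile, layers, path) {
  df <- profile$ranking
  df$layer <- unname(layers$layer[df$node])
  df <- df[, c("node", "layer", "strength", "rank", "is_bridge")]
  names(df)[3] <- "bridge_strength"
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a stability result as TSV plus JSON summary
#'
#' @param result a `stability_result` (after [cs_coefficient()]).
#' @param path output TSV of (proportion, replicate, correlation); a
#'   `.summary.json` with cs, band, n_boot and seed is written next to it.
#' @return `path`, invisibly.
#' @export
write_stability <- function(result, path) {
  utils::write.table(result$correlations, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summ <- list(cs = result$cs, band = result$band,
               r_threshold = result$r_threshold, prob = result$prob,
               n_boot = result$n_boot, seed = result$seed)
  jsonlite::write_json(summ, sub("\\.[^.]+$", ".summary.json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
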