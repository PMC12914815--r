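#' Bridge-strength centrality
#'
#' A node's bridge strength is its total connectivity with layers other than
#' its own: the sum of the absolute weights of every edge linking it to a
#' node of another layer. Within-layer edges contribute nothing; a node with
#' no interlayer edges scores 0.
#'
#' @param network a `pcor_network` (or a symmetric weight matrix).
#' @param layers a [layer_spec()]; defaults to the network's own.
#' @return named numeric vector of bridge strengths, in node order.
#' @export
bridge_strength <- function(network, layers = NULL) {
  W <- if (inherits(network, "pcor_network")) network$weights else as.matrix(network)
  if (is.null(layers)) {
    if (!inherits(network, "pcor_network"))
      stop("'layers' must be supplied for a bare weight matrix")
    layers <- network$layers
  }
  nodes <- colnames(W)
  missing <- setdiff(nodes, names(layers$layer))
  if (length(missing))
    stop("node(s) missing from the layer specification: ",
         paste(missing, collapse = ", "))
  lab <- layers$layer[nodes]
  inter <- outer(lab, lab, `!=`)
  s <- rowSums(abs(W) * inter)
  names(s) <- nodes
  s
}

#' Designate bridge nodes by percentile threshold
#'
#' The threshold is the given percentile (default 80th, linear interpolation
#' between closest ranks) of the raw bridge strengths; bridge nodes are the
#' nodes strictly above it. With all strengths tied no node is designated.
#'
#' @param strengths named numeric vector from [bridge_strength()].
#' @param percentile threshold percentile in (0, 100).
#' @return object of class `bridge_profile`: `strength` (descending-sorted),
#'   `threshold`, `bridges` (character vector), `percentile`, `ranking`
#'   (data.frame: node, layer-free rank, strength, is_bridge).
#' @export
designate_bridges <- function(strengths, percentile = 80) {
  if (!length(strengths)) stop("empty strength map")
  if (length(strengths) < 2L) stop("need at least 2 nodes to designate bridges")
  thr <- unname(stats::quantile(strengths, percentile / 100, type = 7))
  ord <- order(-strengths, names(strengths))
  sorted <- strengths[ord]
  ranking <- data.frame(node = names(sorted), rank = seq_along(sorted),
                        strength = unname(sorted),
                        is_bridge = unname(sorted) > thr)
  structure(list(strength = sorted, threshold = thr,
                 bridges = ranking$node[ranking$is_bridge],
                 percentile = percentile, ranking = ranking),
            class = "bridge_profile")
}

#' @export
print.bridge_profile <- function(x, ...) {
  cat(sprintf("Bridge profile (%gth percentile threshold = %.4f)\n",
              x$percentile, x$threshold))
  df <- x$ranking
  df$strength <- round(df$strength, 4)
  df$bridge <- ifelse(df$is_bridge, "*", "")
  print(df[, c("rank", "node", "strength", "bridge")], row.names = FALSE)
  cat("Bridge nodes:",
      if (length(x$bridges)) paste(x$bridges, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Rank interlayer edges by absolute weight
#'
#' All nonzero edges joining different layers, strongest first; ties are
#' broken lexicographically by the (node_i, node_j) name pair.
#'
#' @inheritParams bridge_strength
#' @return data.frame: node_i, node_j, weight, layer_i, layer_j.
#' @export
rank_interlayer_edges <- function(network, layers = NULL) {
  W <- if (inherits(network, "pcor_network")) network$weights else as.matrix(network)
  if (is.null(layers)) layers <- network$layers
  nodes <- colnames(W)
  lab <- layers$layer[nodes]
  idx <- which(upper.tri(W) & W != 0 & outer(lab, lab, `!=`), arr.ind = TRUE)
  df <- data.frame(node_i = nodes[idx[, 1]], node_j = nodes[idx[, 2]],
                   weight = W[idx],
                   layer_i = unname(lab[idx[, 1]]),
                   layer_j = unname(lab[idx[, 2]]),
                   stringsAsFactors = FALSE)
  df[order(-abs(df$weight), df$node_i, df$node_j), , drop = FALSE]
}
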