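#' Edge-weight summary statistics
#'
#' Mean, SD, min and max of edge weights, reported twice: over all possible
#' unordered node pairs (structural zeros included — the convention under
#' which sparse networks show small means with wide ranges) and over the
#' nonzero edges only.
#'
#' @param network a `pcor_network` (or symmetric weight matrix).
#' @return list with `all_pairs` and `nonzero`, each
#'   `list(mean, sd, min, max)`; `nonzero` is all-`NA` for an empty network.
#' @export
edge_summary <- function(network) {
  W <- if (inherits(network, "pcor_network")) network$weights else as.matrix(network)
  w <- W[upper.tri(W)]
  stat <- function(v) {
    if (!length(v)) return(list(mean = NA_real_, sd = NA_real_,
                                min = NA_real_, max = NA_real_))
    list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
         min = min(v), max = max(v))
  }
  list(all_pairs = stat(w), nonzero = stat(w[w != 0]))
}

#' Deterministic Fruchterman-Reingold layout
#'
#' Force-directed 2-D coordinates computed on the absolute edge weights
#' (strongly tied nodes land close together, layers separate naturally).
#' The same seed always yields the same coordinates.
#'
#' @param network a `pcor_network` (or symmetric weight matrix).
#' @param seed integer seed for the random initial placement.
#' @param iterations force-directed iterations.
#' @return numeric matrix (nodes x 2) of finite coordinates, rownames =
#'   node names.
#' @export
layout_fruchterman_reingold <- function(network, seed = 42L, iterations = 500L) {
  W <- if (inherits(network, "pcor_network")) network$weights else as.matrix(network)
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  wts <- igraph::E(g)$weight
  coords <- igraph::layout_with_fr(g, niter = as.integer(iterations),
                                   weights = wts)
  rownames(coords) <- colnames(W)
  colnames(coords) <- c("x", "y")
  stopifnot(all(is.finite(coords)))
  coords
}

#' Plot a fitted network
#'
#' Base-graphics rendering on a Fruchterman-Reingold layout: edge colour by
#' sign (blue positive, red negative), width proportional to |weight|, node
#' colour by layer, bridge nodes outlined.
#'
#' @param x a `pcor_network`.
#' @param bridges optional `bridge_profile` whose bridge nodes are outlined.
#' @param seed layout seed.
#' @param ... further arguments passed to [graphics::plot()].
#' @return the layout coordinates, invisibly.
#' @export
plot.pcor_network <- function(x, bridges = NULL, seed = 42L, ...) {
  W <- x$weights
  xy <- layout_fruchterman_reingold(x, seed = seed)
  lab <- x$layers$layer[colnames(W)]
  pal <- grDevices::hcl.colors(length(unique(lab)), "Dark 3")
  names(pal) <- unique(lab)
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "", ...)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      graphics::segments(xy[i, 1], xy[i, 2], xy[j, 1], xy[j, 2],
                         col = if (W[i, j] > 0) "#2166ac88" else "#b2182b88",
                         lwd = 0.5 + 6 * abs(W[i, j]))
    }
  }
  is_bridge <- colnames(W) %in% (if (!is.null(bridges)) bridges$bridges else character())
  graphics::points(xy, pch = 21, cex = 3, bg = pal[lab],
                   col = ifelse(is_bridge, "magenta", "grey20"),
                   lwd = ifelse(is_bridge, 3, 1))
  graphics::text(xy, labels = colnames(W), cex = 0.6)
  invisible(xy)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings. Defaults reproduce the standard protocol:
#' EBIC gamma 0.5, 80th-percentile bridge designation, 2000 case-dropping
#' bootstraps with the 0.70-correlation / 95%-probability CS rule.
#'
#' @param cohort path to a cohort TSV/CSV (with its layer sidecar) or a
#'   [cohort_table()].
#' @param out_dir output directory for all artifacts; `NULL` disables
#'   writing.
#' @param residualize run covariate residualization first.
#' @param covariates a [covariate_spec()]; `NULL` uses the default built
#'   from the cohort's layers.
#' @param estimation an [estimation_config()].
#' @param percentile bridge-designation percentile.
#' @param stability `list(run =, drop_grid =, n_boot =, seed =,
#'   r_threshold =, prob =)`; set `run = FALSE` to skip the bootstrap.
#' @param control optional second cohort (path or [cohort_table()]) for a
#'   descriptive group comparison.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, out_dir = NULL, residualize = TRUE,
                            covariates = NULL,
                            estimation = estimation_config(),
                            percentile = 80,
                            stability = list(),
                            control = NULL) {
  stab <- utils::modifyList(list(run = TRUE,
                                 drop_grid = seq(0.05, 0.75, by = 0.05),
                                 n_boot = 2000L, seed = 1L,
                                 r_threshold = 0.70, prob = 0.95),
                            stability)
  structure(list(cohort = cohort, out_dir = out_dir,
                 residualize = residualize, covariates = covariates,
                 estimation = estimation, percentile = percentile,
                 stability = stab, control = control),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' File values are passed to [pipeline_config()]; anything not present keeps
#' its default.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- if (is_yaml_path(path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  est <- do.call(estimation_config, as.list(obj$estimation))
  args <- obj[setdiff(names(obj), "estimation")]
  args$estimation <- est
  if (!is.null(args$stability)) args$stability <- as.list(args$stability)
  do.call(pipeline_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full multilayer-network pipeline
#'
#' Executes residualization, network estimation, density banding, bridge
#' centrality, bridge designation, interlayer-edge ranking and (optionally)
#' the case-dropping stability bootstrap, writing every artifact under the
#' configured output directory and logging each stage with its parameters.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config file.
#' @param quiet suppress stage logging.
#' @return object of class `analysis_report`: the fitted objects plus the
#'   summary structure (edge statistics over all pairs and nonzero edges,
#'   density and band, bridge profile, strongest intra- and interlayer
#'   edges, stability summary, provenance).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_ <- function(...) if (!quiet) message(sprintf(...))

  table <- stage("load", {
    if (inherits(config$cohort, "cohort_table")) config$cohort
    else read_cohort(config$cohort)
  })
  log_("[load] cohort: n = %d, p = %d", table$n, ncol(table$values))

  if (config$residualize) {
    cspec <- if (is.null(config$covariates)) covariate_spec(table$layers)
             else config$covariates
    table <- stage("residualize", residualize(table, cspec))
    log_("[residualize] covariates removed per node: %s",
         paste(unique(vapply(cspec, paste, "", collapse = "+")), collapse = " | "))
  }

  net <- stage("estimate", estimate_network(table, config$estimation))
  db <- density_band(net)
  log_("[estimate] lambda = %.4f, %d/%d edges (%.1f%%, %s)",
       net$lambda, db$n_edges, db$n_possible, db$percent, db$band)

  strengths <- stage("bridge", bridge_strength(net))
  profile <- stage("bridge", designate_bridges(strengths, config$percentile))
  inter <- stage("bridge", rank_interlayer_edges(net))
  log_("[bridge] %d bridge node(s) above the %gth percentile: %s",
       length(profile$bridges), config$percentile,
       paste(profile$bridges, collapse = ", "))

  stab <- NULL
  if (isTRUE(config$stability$run)) {
    stab <- stage("stability", {
      r <- case_drop_bootstrap(table, config$estimation,
                               drop_grid = config$stability$drop_grid,
                               n_boot = config$stability$n_boot,
                               seed = config$stability$seed)
      cs_coefficient(r, config$stability$r_threshold, config$stability$prob)
    })
    log_("[stability] CS = %.2f (%s) over %d bootstraps",
         stab$cs, stab$band, stab$n_boot)
  }

  comparison <- NULL
  if (!is.null(config$control)) {
    ctrl <- stage("compare", {
      if (inherits(config$control, "cohort_table")) config$control
      else read_cohort(config$control)
    })
    comparison <- stage("compare", group_compare(table, ctrl))
    log_("[compare] %d variable(s) significant after FDR",
         sum(comparison$significant))
  }

  es <- edge_summary(net)
  intra <- {
    lab <- net$layers$layer[colnames(net$weights)]
    W <- net$weights
    idx <- which(upper.tri(W) & W != 0 & outer(lab, lab, `==`), arr.ind = TRUE)
    df <- data.frame(node_i = colnames(W)[idx[, 1]],
                     node_j = colnames(W)[idx[, 2]], weight = W[idx])
    df[order(-abs(df$weight), df$node_i, df$node_j), , drop = FALSE]
  }

  report <- structure(list(
    network = net, bridge_profile = profile, stability = stab,
    comparison = comparison,
    summary = list(
      n = net$n, p = ncol(net$weights),
      density = db[c("fraction", "percent", "n_edges", "n_possible", "band")],
      edge_weights = es,
      bridges = profile$bridges,
      bridge_threshold = profile$threshold,
      strongest_intralayer = utils::head(intra, 5),
      strongest_interlayer = utils::head(inter, 5),
      stability = if (!is.null(stab))
        list(cs = stab$cs, band = stab$band, n_boot = stab$n_boot,
             seed = stab$seed) else NULL,
      provenance = list(
        package_version = as.character(utils::packageVersion("mlbridge")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        gamma = config$estimation$gamma,
        percentile = config$percentile,
        stability_seed = config$stability$seed,
        config_hash = config_hash(config))
    )), class = "analysis_report")

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    stage("write", {
      write_cohort(table, file.path(out, "cohort_residualized.tsv"))
      write_network(net, out, "network")
      write_bridge_profile(profile, net$layers,
                           file.path(out, "bridge_profile.tsv"))
      coords <- layout_fruchterman_reingold(net)
      utils::write.table(data.frame(node = rownames(coords), coords),
                         file.path(out, "layout.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      if (!is.null(stab)) write_stability(stab, file.path(out, "stability.tsv"))
      jsonlite::write_json(report$summary, file.path(out, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    log_("[write] artifacts under %s", out)
  }
  report
}

# stable hash of the analysis parameters (provenance only); the output
# location must not change the hash
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("==== Multilayer network analysis report ====\n")
  print(x$network)
  s <- x$summary
  a <- s$edge_weights$all_pairs
  cat(sprintf("Edge weight mean (SD), [range] over all pairs: %.2f (%.2f), [%.2f %.2f]\n",
              a$mean, a$sd, a$min, a$max))
  cat("\n"); print(x$bridge_profile)
  if (!is.null(x$stability))
    cat(sprintf("\nBridge-strength stability: CS = %.2f (%s)\n",
                x$stability$cs, x$stability$band))
  invisible(x)
}
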