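#' Case-dropping bootstrap of bridge-strength centrality
#'
#' Assesses how stable the bridge-strength ranking is to sample composition.
#' For each bootstrap replicate a drop proportion is sampled from the grid, a
#' subsample of participants is drawn without replacement, the network and
#' its bridge strengths are re-estimated, and the Pearson correlation between
#' the full-sample and subsample strength vectors (over all nodes) is
#' recorded. Replicates with a constant strength vector have no defined
#' correlation and are excluded from that proportion's tally.
#'
#' Grid proportions whose subsample would not leave at least `p + 3`
#' participants are skipped with a warning.
#'
#' @param table a (residualized) [cohort_table()].
#' @param config an [estimation_config()].
#' @param drop_grid ordered drop proportions (default 0.05 to 0.75 by 0.05).
#' @param n_boot number of bootstrap replicates (2000 for a full run; smaller
#'   values such as 250 give a fast, still seeded, approximation).
#' @param seed integer seed making the whole bootstrap deterministic.
#' @return object of class `stability_result`: `correlations` (data.frame:
#'   proportion, replicate, correlation), `drop_grid`, `full_strength`,
#'   `n_boot`, `seed`; `cs` and `band` are filled in by [cs_coefficient()].
#' @export
case_drop_bootstrap <- function(table, config = estimation_config(),
                                drop_grid = seq(0.05, 0.75, by = 0.05),
                                n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  if (n_boot < 1L) stop("'n_boot' must be >= 1")
  n <- table$n
  p <- ncol(table$values)
  keep <- vapply(drop_grid, function(q) floor((1 - q) * n) > p + 2L, TRUE)
  if (!all(keep)) {
    warning(sprintf("dropping grid proportions {%s}: subsample would leave <= p + 2 participants",
                    paste(drop_grid[!keep], collapse = ", ")))
    drop_grid <- drop_grid[keep]
  }
  if (!length(drop_grid)) stop("no usable drop proportions for this sample size")

  full <- bridge_strength(estimate_network(table, config))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  props <- drop_grid[sample.int(length(drop_grid), n_boot, replace = TRUE)]
  cors <- vapply(seq_len(n_boot), function(b) {
    m <- floor((1 - props[b]) * n)
    idx <- sample.int(n, m)
    sub <- subset_cohort(table, idx)
    s <- tryCatch(bridge_strength(estimate_network(sub, config)),
                  error = function(e) NULL)
    if (is.null(s) || stats::sd(s) == 0 || stats::sd(full) == 0) return(NA_real_)
    stats::cor(full, s)
  }, 0)

  structure(list(correlations = data.frame(proportion = props,
                                           replicate = seq_len(n_boot),
                                           correlation = cors),
                 drop_grid = drop_grid, full_strength = full,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 cs = NULL, band = NULL),
            class = "stability_result")
}

#' Correlation-stability (CS) coefficient
#'
#' The CS coefficient is the largest drop proportion `q` such that for every
#' tested proportion up to and including `q`, at least `prob` (default 95%)
#' of the bootstrap correlations with the full-sample centralities are at
#' least `r_threshold` (default 0.70). Requiring all smaller proportions to
#' pass prevents non-monotone flukes from inflating CS. The value 0 means
#' even the smallest tested proportion fails.
#'
#' Interpretive bands: CS >= 0.5 `stable`; 0.25 <= CS < 0.5 `caution`;
#' CS < 0.25 `uninterpretable`.
#'
#' @param result a `stability_result` from [case_drop_bootstrap()].
#' @param r_threshold correlation that must be retained.
#' @param prob required probability of retaining it.
#' @return the `stability_result` with `cs`, `band`, `pass_by_proportion`
#'   filled in.
#' @export
cs_coefficient <- function(result, r_threshold = 0.70, prob = 0.95) {
  stopifnot(inherits(result, "stability_result"))
  df <- result$correlations
  if (!nrow(df)) stop("empty stability result")
  grid <- sort(result$drop_grid)
  # a proportion whose replicates all have undefined correlations offers no
  # evidence of stability and fails the retention rule
  pass <- vapply(grid, function(q) {
    cc <- df$correlation[df$proportion == q]
    cc <- cc[!is.na(cc)]
    length(cc) > 0 && mean(cc >= r_threshold) >= prob
  }, TRUE)
  cs <- 0
  for (i in seq_along(grid)) {
    if (!pass[i]) break
    cs <- grid[i]
  }
  result$cs <- cs
  result$band <- if (cs >= 0.5) "stable" else if (cs >= 0.25) "caution"
                 else "uninterpretable"
  result$r_threshold <- r_threshold
  result$prob <- prob
  result$pass_by_proportion <- data.frame(proportion = grid, pass = pass)
  result
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Case-dropping bootstrap of bridge strength\n")
  cat(sprintf("  %d replicates over drop proportions %.2f-%.2f (seed %d)\n",
              x$n_boot, min(x$drop_grid), max(x$drop_grid), x$seed))
  med <- stats::aggregate(correlation ~ proportion, x$correlations, stats::median,
                          na.action = stats::na.omit)
  cat("  median correlation by proportion:\n")
  cat(paste0("    ", sprintf("%.2f: %.3f", med$proportion, med$correlation),
             collapse = "\n"), "\n")
  if (!is.null(x$cs))
    cat(sprintf("  CS(cor = %.2f) = %.2f  [%s]\n", x$r_threshold, x$cs, x$band))
  invisible(x)
}

#' @export
plot.stability_result <- function(x, ...) {
  df <- x$correlations[!is.na(x$correlations$correlation), ]
  med <- stats::aggregate(correlation ~ proportion, df, stats::median)
  q05 <- stats::aggregate(correlation ~ proportion, df,
                          function(v) stats::quantile(v, 0.05))
  graphics::plot(med$proportion, med$correlation, type = "b", pch = 16,
                 ylim = c(-1, 1), xlab = "proportion of cases dropped",
                 ylab = "correlation with full-sample bridge strength", ...)
  graphics::lines(q05$proportion, q05$correlation, lty = 2)
  graphics::abline(h = if (!is.null(x$r_threshold)) x$r_threshold else 0.7,
                   col = "grey50")
  if (!is.null(x$cs)) graphics::abline(v = x$cs, col = "red3", lty = 3)
  graphics::legend("bottomleft", c("median", "5th percentile"),
                   lty = c(1, 2), pch = c(16, NA), bty = "n")
  invisible(x)
}
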