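# Independent brute-force oracles used across the suite. Each deliberately
# avoids the code path it checks.

# Benjamini-Hochberg by direct monotonization of p * m / rank
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# bridge strength by explicit enumeration of interlayer edges
brute_bridge_strength <- function(W, layer) {
  nodes <- colnames(W)
  s <- setNames(numeric(length(nodes)), nodes)
  for (i in nodes) for (j in nodes)
    if (i != j && layer[i] != layer[j]) s[i] <- s[i] + abs(W[i, j])
  s
}

# count of values strictly above the interpolated percentile
brute_bridge_count <- function(v, pct = 80) {
  sum(v > quantile(v, pct / 100, type = 7))
}

# residuals via explicit normal equations
normal_eq_resid <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# symmetric weight matrix with named nodes
named_weights <- function(W, nodes) {
  dimnames(W) <- list(nodes, nodes)
  W
}

# the worked 4-node two-layer example: layers A = {n1, n2}, B = {n3, n4}
example4 <- function() {
  nodes <- c("n1", "n2", "n3", "n4")
  W <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  W["n1", "n3"] <- W["n3", "n1"] <- 0.3
  W["n1", "n4"] <- W["n4", "n1"] <- -0.2
  W["n1", "n2"] <- W["n2", "n1"] <- 0.9
  W["n3", "n4"] <- W["n4", "n3"] <- 0.5
  list(W = W, spec = layer_spec(list(A = c("n1", "n2"), B = c("n3", "n4"))))
}

# small well-separated planted-bridge model shared by recovery/stability tests
planted_bridges <- c("INSOM", "SOM", "vIMM", "ProcS")
planted_model <- function(seed = 7) {
  make_multilayer_precision(c(4, 6, 8), bridge_nodes = planted_bridges,
                            seed = seed)
}

# fabricate a stability_result with stipulated pass/fail pattern:
# proportions in `passing` get correlations above 0.9, the rest below 0.1
stipulated_stability <- function(grid = seq(0.05, 0.75, by = 0.05),
                                 passing = grid, n_per = 40) {
  df <- do.call(rbind, lapply(grid, function(q)
    data.frame(proportion = q, replicate = seq_len(n_per),
               correlation = if (q %in% passing) 0.95 else 0.05)))
  structure(list(correlations = df, drop_grid = grid,
                 full_strength = setNames(1:4, paste0("v", 1:4)),
                 n_boot = nrow(df), seed = 1L, cs = NULL, band = NULL),
            class = "stability_result")
}
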