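# small reproducible correlation matrix for oracle checks
random_corr <- function(p, n = 8 * p, seed = 1) {
  set.seed(seed)
  stats::cov2cor(crossprod(matrix(rnorm(n * p), n, p)) / n)
}

test_that("lambda path endpoints, ordering and degenerate input", {
  S <- matrix(c(1, .8, .8, 1), 2)
  path <- lambda_path(S, estimation_config(n_lambdas = 2, lambda_min_ratio = 0.01))
  expect_equal(path, c(0.8, 0.008))
  path100 <- lambda_path(random_corr(5), estimation_config())
  expect_length(path100, 100)
  expect_true(all(diff(path100) < 0))
  expect_warning(dp <- lambda_path(diag(4)), "degenerate")
  expect_equal(dp, 0)
})

test_that("graphical lasso reduces to the matrix inverse at lambda = 0", {
  S <- random_corr(5, seed = 3)
  cfg <- estimation_config(convergence_tol = 1e-8)
  K <- graphical_lasso(S, 0, cfg)
  expect_lt(max(abs(K - solve(S))), 1e-6)
  # and the resulting weights equal the classical partial correlations
  W <- precision_to_pcor(K)
  classical <- -stats::cov2cor(solve(S)); diag(classical) <- 0
  expect_equal(W, classical, tolerance = 1e-6)
})

test_that("p = 2 closed form: the edge vanishes when lambda >= |r|", {
  S <- matrix(c(1, .5, .5, 1), 2)
  expect_equal(graphical_lasso(S, 0.6)[1, 2], 0)
  expect_equal(graphical_lasso(S, 0.5)[1, 2], 0)
  # below |r| the off-diagonal weight is the soft-thresholded correlation
  K <- graphical_lasso(S, 0.2, estimation_config(convergence_tol = 1e-8))
  expect_equal(precision_to_pcor(K)[1, 2], 0.3, tolerance = 1e-6)
})

test_that("diagonal input stays diagonal at any penalty", {
  S <- diag(4)
  for (lam in c(0, 0.1, 1))
    expect_true(all(abs(graphical_lasso(S, lam)[upper.tri(S)]) < 1e-10))
})

test_that("solutions satisfy the KKT conditions of the penalized objective", {
  S <- random_corr(4, seed = 9)
  cfg <- estimation_config(convergence_tol = 1e-8)
  for (lam in c(0.05, 0.15, 0.3)) {
    K <- graphical_lasso(S, lam, cfg)
    G <- solve(K) - S
    up <- upper.tri(K)
    zero <- up & abs(K) <= 1e-8
    active <- up & abs(K) > 1e-8
    if (any(zero)) expect_lte(max(abs(G[zero])), lam + 1e-5)
    if (any(active))
      expect_lt(max(abs(G[active] - lam * sign(K[active]))), 1e-5)
  }
})

test_that("EBIC matches a hand-computed oracle and its limits", {
  # empty model on independent data scores exactly zero
  expect_equal(ebic_score(diag(2), diag(2), n = 100, gamma = 1), 0)
  # gamma = 0 reduces to BIC
  S <- random_corr(3, seed = 4)
  K <- graphical_lasso(S, 0.05)
  E <- sum(abs(K[upper.tri(K)]) > 1e-6)
  L <- (457 / 2) * (log(det(K)) - sum(diag(S %*% K)) + 3)  # direct formula oracle
  expect_equal(ebic_score(K, S, 457, gamma = 0), -2 * L + E * log(457),
               tolerance = 1e-8)
  expect_equal(ebic_score(K, S, 457, gamma = 0.5),
               -2 * L + E * log(457) + 4 * E * 0.5 * log(3), tolerance = 1e-8)
  expect_error(ebic_score(matrix(c(1, 2, 2, 1), 2), diag(2), 10),
               "positive definite")
})

test_that("precision-to-partial-correlation identity and invariances", {
  expect_equal(precision_to_pcor(diag(c(2, 3, 4))), matrix(0, 3, 3))
  K <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_pcor(K)[1, 2], 0.5)
  expect_equal(precision_to_pcor(5 * K), precision_to_pcor(K))
  expect_error(precision_to_pcor(matrix(c(-1, 0, 0, 1), 2)), "positive")
})

test_that("network fit selects the EBIC minimum and is deterministic", {
  m <- planted_model(seed = 2)
  co <- residualize(sample_cohort(m, 400, seed = 4))
  net <- estimate_network(co)
  path <- net$ebic_path
  expect_equal(min(path$ebic), path$ebic[path$lambda == net$lambda])
  # sparsity ordering along the path endpoints
  expect_lte(path$n_edges[1], path$n_edges[nrow(path)])
  # ties (if any) resolve toward the larger penalty
  expect_equal(net$lambda, max(path$lambda[path$ebic == min(path$ebic)]))
  net2 <- estimate_network(co)
  expect_identical(coef(net), coef(net2))
  # weight matrix structure
  W <- coef(net)
  expect_equal(W, t(W))
  expect_equal(unname(diag(W)), rep(0, 18))
  expect_true(all(abs(W[upper.tri(W)]) < 1))
})

test_that("a diagonal true model estimates to a near-empty network", {
  m <- make_multilayer_precision(c(4, 6), within_density = 0,
                                 between_density = 0, seed = 6,
                                 age_effect = 0, tiv_effect = 0, site_sd = 0,
                                 ordinal_levels = 0)
  co <- residualize(sample_cohort(m, 2000, seed = 13))
  net <- estimate_network(co)
  expect_lte(density_band(net)$fraction, 0.05)
})

test_that("dense within-layer structure is recovered with correct signs", {
  m <- make_multilayer_precision(c(3, 3), within_density = 1,
                                 between_density = 0, seed = 15,
                                 age_effect = 0, tiv_effect = 0, site_sd = 0,
                                 ordinal_levels = 0)
  co <- residualize(sample_cohort(m, 2000, seed = 16))
  net <- estimate_network(co)
  tw <- true_pcor(m); ew <- coef(net)
  lay <- m$layers$layer
  within <- which(outer(lay, lay, `==`) & upper.tri(tw))
  expect_true(all(ew[within] != 0))
  expect_true(all(sign(ew[within]) == sign(tw[within])))
})

test_that("density banding applies the stated cutoffs", {
  d1 <- density_band(28, possible = 45)
  expect_equal(round(d1$percent, 1), 62.2)
  expect_equal(d1$band, "high")
  d2 <- density_band(53, possible = 153)
  expect_equal(round(d2$percent, 1), 34.6)
  expect_equal(d2$band, "medium")
  expect_equal(density_band(0, possible = 45)$band, "low")
  expect_equal(density_band(0.3)$band, "medium")
  expect_equal(density_band(0.5)$band, "high")
  expect_equal(density_band(0.299)$band, "low")
})

test_that("simulated draws from a fit reproduce its covariance structure", {
  m <- make_multilayer_precision(c(3, 3), within_density = 0.8,
                                 between_density = 0.2, seed = 20,
                                 ordinal_levels = 0)
  co <- residualize(sample_cohort(m, 1500, seed = 21))
  net <- estimate_network(co)
  sims <- simulate(net, nsim = 30000, seed = 99)
  expect_lt(max(abs(cor(sims) - stats::cov2cor(solve(net$precision)))), 0.03)
})
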