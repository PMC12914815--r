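# compact estimation settings keep the resampling tests quick without
# touching the exported defaults
fast_cfg <- estimation_config(n_lambdas = 30)

small_planted_cohort <- function(n, seed = 50) {
  m <- make_multilayer_precision(c(3, 3), within_density = 0.8,
                                 between_density = 0.4, seed = 44,
                                 ordinal_levels = 0)
  residualize(sample_cohort(m, n, seed = seed))
}

test_that("near-identical subsamples reproduce bridge strengths almost exactly", {
  base <- small_planted_cohort(20)
  # duplicate the cohort 100x: any 5% subsample carries the same information
  dup <- cohort_table(base$values[rep(1:20, 100), ], base$layers,
                      base$covariates[rep(1:20, 100), ])
  res <- case_drop_bootstrap(dup, fast_cfg, drop_grid = 0.05,
                             n_boot = 25, seed = 2)
  med <- median(res$correlations$correlation, na.rm = TRUE)
  expect_gte(med, 0.99)
})

test_that("the bootstrap is deterministic in its seed", {
  tab <- small_planted_cohort(300)
  a <- case_drop_bootstrap(tab, fast_cfg, drop_grid = c(0.1, 0.3),
                           n_boot = 12, seed = 7)
  b <- case_drop_bootstrap(tab, fast_cfg, drop_grid = c(0.1, 0.3),
                           n_boot = 12, seed = 7)
  expect_identical(a$correlations, b$correlations)
  c_ <- case_drop_bootstrap(tab, fast_cfg, drop_grid = c(0.1, 0.3),
                            n_boot = 12, seed = 8)
  expect_false(identical(a$correlations$correlation,
                         c_$correlations$correlation))
})

test_that("infeasible drop proportions are skipped with a warning", {
  tab <- small_planted_cohort(30)
  expect_warning(res <- case_drop_bootstrap(tab, fast_cfg,
                                            drop_grid = c(0.1, 0.9),
                                            n_boot = 5, seed = 1),
                 "p \\+ 2")
  expect_equal(res$drop_grid, 0.1)
  expect_error(case_drop_bootstrap(tab, fast_cfg, n_boot = 0), "n_boot")
})

test_that("CS coefficient applies the retention rule to a stipulated summary", {
  grid <- seq(0.05, 0.75, by = 0.05)
  # proportions up to 0.30 pass, later ones fail -> CS = 0.30, caution band
  r <- cs_coefficient(stipulated_stability(grid, passing = grid[grid <= 0.30]))
  expect_equal(r$cs, 0.30)
  expect_equal(r$band, "caution")
  # everything passes -> CS = upper grid bound, stable
  r2 <- cs_coefficient(stipulated_stability(grid, passing = grid))
  expect_equal(r2$cs, 0.75)
  expect_equal(r2$band, "stable")
  # the smallest proportion fails -> CS = 0, uninterpretable
  r3 <- cs_coefficient(stipulated_stability(grid, passing = grid[-1]))
  expect_equal(r3$cs, 0)
  expect_equal(r3$band, "uninterpretable")
  # a non-monotone fluke cannot inflate CS past the first failure
  r4 <- cs_coefficient(stipulated_stability(grid,
                                            passing = grid[grid != 0.10]))
  expect_equal(r4$cs, 0.05)
})

test_that("CS is monotone in the correlation threshold and bounded by the grid", {
  grid <- seq(0.05, 0.75, by = 0.05)
  df <- do.call(rbind, lapply(grid, function(q)
    data.frame(proportion = q, replicate = 1:50,
               correlation = 1 - q + seq(-0.25, 0.25, length.out = 50))))
  res <- structure(list(correlations = df, drop_grid = grid,
                        full_strength = setNames(1:4, letters[1:4]),
                        n_boot = nrow(df), seed = 1L, cs = NULL, band = NULL),
                   class = "stability_result")
  thresholds <- c(0.4, 0.6, 0.8, 0.95)
  cs_vals <- vapply(thresholds, function(t) cs_coefficient(res, t)$cs, 0)
  expect_true(all(diff(cs_vals) <= 0))
  expect_true(all(cs_vals <= max(grid)))
  expect_true(all(cs_vals %in% c(0, grid)))
})

test_that("median bootstrap correlation does not increase with the drop proportion", {
  tab <- small_planted_cohort(800)
  res <- case_drop_bootstrap(tab, fast_cfg,
                             drop_grid = c(0.1, 0.4, 0.7),
                             n_boot = 90, seed = 5)
  med <- aggregate(correlation ~ proportion, res$correlations, median)
  med <- med[order(med$proportion), ]
  expect_true(all(diff(med$correlation) <= 0.05))
})
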