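test_that("GSI is the sum of the three BSI-18 subscales", {
  expect_equal(compute_gsi(2.74, 2.54, 2.83), 8.11)
  expect_equal(compute_gsi(0, 0, 0), 0)
  # per-scale maxima sum above the observed per-person maximum
  expect_gte(compute_gsi(23, 19, 21), 61)
  expect_equal(compute_gsi(23, 19, 21), 63)
  expect_error(compute_gsi(-1, 0, 0), "negative")
})

test_that("ISI categories follow the instrument's published cutpoints", {
  expect_equal(as.character(isi_category(c(0, 7, 8, 14, 15, 21, 22, 28))),
               c("none", "none", "subthreshold", "subthreshold",
                 "moderate", "moderate", "severe", "severe"))
  expect_error(isi_category(29), "0, 28")
  expect_error(isi_category(-1), "0, 28")
  expect_error(isi_category(3.5), "integer")
})

make_simple_cohort <- function(values, covariates) {
  nodes <- colnames(values)
  cohort_table(values, layer_spec(list(A = nodes[1], B = nodes[-1])),
               covariates)
}

test_that("residualization matches a normal-equations oracle and is idempotent", {
  set.seed(31)
  n <- 20
  covs <- data.frame(age = rnorm(n, 40, 10), tiv = rnorm(n, 1.5e6, 1e5))
  vals <- cbind(y = rnorm(n), z = rnorm(n))
  tab <- make_simple_cohort(vals, covs)
  spec <- structure(list(y = c("age", "tiv"), z = c("age", "tiv")),
                    class = "covariate_spec")
  res <- residualize(tab, spec)
  X <- cbind(1, covs$age, covs$tiv)
  expect_equal(unname(res$values[, "y"]), normal_eq_resid(vals[, "y"], X),
               tolerance = 1e-10)
  # orthogonal to every covariate column
  expect_lt(max(abs(crossprod(X, res$values))), 1e-8)
  # idempotent
  res2 <- residualize(res, spec)
  expect_equal(res2$values, res$values, tolerance = 1e-10)
  # variance never increases
  expect_true(all(apply(res$values, 2, var) <= apply(vals, 2, var) + 1e-12))
})

test_that("degenerate residualization cases behave as linear algebra dictates", {
  covs <- data.frame(age = c(1, 2, 3))
  tab <- make_simple_cohort(cbind(y = c(1, 2, 3), z = c(5, 1, 3)), covs)
  spec <- structure(list(y = "age", z = character()), class = "covariate_spec")
  res <- residualize(tab, spec)
  expect_equal(unname(res$values[, "y"]), c(0, 0, 0))          # collinear node
  expect_equal(unname(res$values[, "z"]), c(5, 1, 3) - 3)      # centering only
})

test_that("rank-deficient designs raise an error naming node and covariate", {
  covs <- data.frame(age = rnorm(10), site = rep("siteA", 10))
  tab <- make_simple_cohort(cbind(y = rnorm(10), z = rnorm(10)), covs)
  spec <- structure(list(y = c("age", "site"), z = "age"),
                    class = "covariate_spec")
  expect_error(residualize(tab, spec), "y.*site")
})

test_that("site dummy coding removes additive site shifts", {
  set.seed(8)
  n <- 120
  site <- sample(c("a", "b", "c"), n, replace = TRUE)
  shift <- c(a = 0, b = 2, c = -1)
  covs <- data.frame(age = rnorm(n), site = site)
  y <- rnorm(n) + shift[site]
  tab <- make_simple_cohort(cbind(y = y, z = rnorm(n)), covs)
  spec <- structure(list(y = c("age", "site"), z = "age"),
                    class = "covariate_spec")
  res <- residualize(tab, spec)
  by_site <- tapply(res$values[, "y"], site, mean)
  expect_lt(max(abs(by_site)), 1e-10)
})

test_that("group comparison: Welch t with BH correction against brute-force oracles", {
  set.seed(77)
  n <- 50
  nodes <- paste0("v", 1:6)
  base <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, nodes))
  spec <- layer_spec(list(A = nodes[1:3], B = nodes[4:6]))
  a <- cohort_table(base, spec)
  shifted <- base + matrix(rnorm(n * 6, 0, 1), n, 6)
  shifted[, "v1"] <- shifted[, "v1"] + 10   # one overwhelming difference
  b <- cohort_table(shifted, spec)
  res <- group_compare(a, b)
  expect_equal(res$p_adj, bh_oracle(res$p), tolerance = 1e-12)
  expect_true(res$significant[res$variable == "v1"])
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_true(all(res$p_adj <= 1 & res$p_adj >= 0))
  # flags are consistent with the adjusted p at the declared level
  expect_identical(res$significant, res$p_adj <= attr(res, "alpha"))
})

test_that("identical groups yield null statistics and zero-variance is degenerate", {
  nodes <- c("x", "y")
  vals <- cbind(x = rnorm(10), y = rnorm(10))
  spec <- layer_spec(list(A = "x", B = "y"))
  a <- cohort_table(vals, spec)
  res <- group_compare(a, a)
  expect_equal(res$t, c(0, 0), tolerance = 1e-12)
  expect_equal(res$p, c(1, 1), tolerance = 1e-12)
  expect_false(any(res$significant))

  const <- cohort_table(cbind(x = rep(1, 5), y = rnorm(5)), spec)
  expect_warning(res2 <- group_compare(const, const), "zero variance")
  expect_equal(res2$p[res2$variable == "x"], 1)
  expect_true(res2$degenerate[res2$variable == "x"])
})
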