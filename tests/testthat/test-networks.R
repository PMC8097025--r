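test_that("standardized residuals match the internally studentized form", {
  # intercept-only: raw residuals (-1, 0, 1), sigma 1, leverage 1/3
  tab <- scan_table_from_matrix(cbind(A = c(1, 2, 3)),
                                sex = c(0L, 1L, 0L))
  res <- suppressWarnings(residualize(tab, covariates = character(0)))
  expect_equal(res$A, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$A, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_lt(abs(mean(res$A)), 1e-8)
})

test_that("standardized residuals agree with stats::rstandard", {
  set.seed(5)
  Y <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("A", "B", "C")))
  tab <- scan_table_from_matrix(Y, sex = rep(0:1, 20),
                                cohort = rep(c(0L, 0L, 1L, 1L), 10),
                                scanner = c(rep(0L, 30), rep(1L, 10)))
  res <- residualize(tab)
  for (rc in c("A", "B", "C")) {
    ref <- rstandard(lm(tab[[rc]] ~ sex + cohort + scanner, data = tab))
    expect_equal(res[[rc]], unname(ref), tolerance = 1e-10)
  }
})

test_that("degenerate fits and covariates are handled", {
  # covariate identical to the region values: perfect fit, zero residuals
  tab <- scan_table_from_matrix(cbind(A = c(1, 2, 3, 4)),
                                sex = c(1L, 2L, 3L, 4L))
  res <- suppressWarnings(residualize(tab, covariates = "sex"))
  expect_equal(res$A, rep(0, 4))
  # binary covariate with values equal within level: zero residuals
  tab2 <- scan_table_from_matrix(cbind(A = c(5, 5, 9, 9)),
                                 sex = c(0L, 0L, 1L, 1L))
  res2 <- residualize(tab2, covariates = "sex")
  expect_equal(res2$A, rep(0, 4))
  # constant covariate dropped with a warning
  tab3 <- scan_table_from_matrix(cbind(A = rnorm(10)))
  expect_warning(residualize(tab3, covariates = "scanner"), "constant")
  # more parameters than scans
  tab4 <- scan_table_from_matrix(cbind(A = c(1, 2)), sex = c(0L, 1L))
  expect_error(residualize(tab4, covariates = "sex"), "more scans")
})

test_that("residualization is idempotent on a balanced design", {
  set.seed(7)
  Y <- matrix(rnorm(24 * 2), 24, 2, dimnames = list(NULL, c("A", "B")))
  tab <- scan_table_from_matrix(Y, sex = rep(0:1, each = 12))
  once <- residualize(tab, "sex")
  twice <- residualize(once, "sex")
  for (rc in c("A", "B")) {
    a <- once[[rc]] / sd(once[[rc]])
    b <- twice[[rc]] / sd(twice[[rc]])
    expect_lt(max(abs(a - b)), 1e-8)
  }
})

test_that("bin correlation matrices match hand-computed Pearson values", {
  Y <- cbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(3, 2, 1), D = c(1, 3, 2))
  tab <- scan_table_from_matrix(Y)
  net <- bin_correlation(tab, bin_of(tab))
  expect_equal(net$r["A", "B"], 1)
  expect_equal(net$r["A", "C"], -1)
  expect_equal(net$r["A", "D"], 0.5)
  expect_equal(diag(net$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(net$r, t(net$r))
})

test_that("zero-variance regions are flagged and given zero correlation", {
  Y <- cbind(A = c(1, 2, 3), B = c(2, 2, 2), C = c(5, 1, 4))
  tab <- scan_table_from_matrix(Y)
  net <- bin_correlation(tab, bin_of(tab))
  expect_equal(net$r["A", "B"], 0)
  expect_equal(net$diagnostics$zero_variance_regions, c(B = 2L))
})

test_that("mean correlation follows the positive / all conventions", {
  r <- diag(3)
  r[upper.tri(r)] <- c(0.5, -0.2, 0.3)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  expect_equal(mean_correlation(r, "positive"), 0.4)
  expect_equal(mean_correlation(r, "all"), 0.2, tolerance = 1e-12)
  expect_equal(suppressWarnings(mean_correlation(diag(3), "positive")), 0)
  expect_equal(mean_correlation(diag(3), "all"), 0)
})

test_that("bootstrap thresholding retains forced-positive edges", {
  set.seed(1)
  x <- rnorm(80)
  Y <- cbind(A = x, B = x, C = rnorm(80))   # A and B exact duplicates
  tab <- scan_table_from_matrix(Y)
  net <- bootstrap_threshold(tab, bin_of(tab), B = 200, seed = 2)
  expect_equal(net$retained["A", "B"], 1L)
  expect_equal(diag(net$retained), rep(0L, 3), ignore_attr = TRUE)
  expect_equal(net$retained, t(net$retained))
  # retained implies positive point estimate
  expect_true(all(net$r[net$retained == 1] > 0))
  expect_error(bootstrap_threshold(tab, bin_of(tab), B = 0), "B must be")
})

test_that("thresholding under the complete null retains almost nothing", {
  set.seed(3)
  Y <- matrix(rnorm(80 * 20), 80, 20)
  tab <- scan_table_from_matrix(Y)
  net <- bootstrap_threshold(tab, bin_of(tab), B = 200, seed = 3)
  expect_lt(global_density(net), 0.05)
})

test_that("retention increases with the true common correlation", {
  frac <- vapply(c(0, 0.3, 0.6), function(rho) {
    set.seed(17)
    n <- 70; P <- 15
    f <- rnorm(n)
    Y <- sqrt(rho) * matrix(f, n, P) + sqrt(1 - rho) * matrix(rnorm(n * P), n, P)
    tab <- scan_table_from_matrix(Y)
    net <- bootstrap_threshold(tab, bin_of(tab), B = 200, seed = 17)
    global_density(net)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_lt(frac[1], 0.1)
  expect_gt(frac[3], 0.9)
})

test_that("the BH step behind thresholding matches a brute-force oracle", {
  set.seed(9)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- fdr_correct(p, alpha = 0.05)$reject
    expect_identical(got, bh_reject_oracle(p, 0.05))
  }
})
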