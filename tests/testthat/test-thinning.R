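make_longitudinal <- function(n_sub = 30, slope = -0.05, noise = 0,
                              subject_sd = 0, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_sub), function(s) {
    ages <- sort(runif(2, 9, 14))
    d <- rnorm(1, 0, subject_sd)
    data.frame(participant_id = sprintf("P%02d", s),
               scan_id = sprintf("P%02d_%d", s, 1:2),
               age = ages, sex = s %% 2L, cohort = 0L, scanner = 0L,
               A = 3.0 + d + slope * ages + rnorm(2, 0, noise),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("a noiseless linear panel recovers the exact thinning rate", {
  tab <- make_longitudinal()
  rates <- suppressWarnings(fit_thinning_rates(tab, covariates = "sex"))
  expect_equal(rates$beta_age, -0.05, tolerance = 1e-6)
})

test_that("single-scan participants fall back to an equivalent OLS fit", {
  tab <- make_longitudinal(n_sub = 25, noise = 0.05, seed = 3)
  singles <- tab[!duplicated(tab$participant_id), ]
  rates <- suppressWarnings(fit_thinning_rates(singles, covariates = "sex"))
  ols <- lm(A ~ sex + age, data = singles)
  expect_equal(rates$beta_age, unname(coef(ols)[["age"]]), tolerance = 1e-6)
})

test_that("mixed-model slopes recover generator ground truth per region", {
  parc <- generate_parcellation(20L, 4L, seed = 6)
  cfg <- scn_sim_config(n_regions = 20L, n_modules = 4L, hub_modules = 1:2,
                        noise_sd = 0.05, subject_sd = 0.3, seed = 8)
  ds <- generate_dataset(cfg, parc)
  rates <- fit_thinning_rates(ds$scans)
  expect_false(any(rates$ols_fallback))
  rmse <- sqrt(mean((rates$beta_age - ds$truth$slope)^2))
  expect_lt(rmse, 0.01)
  # random-intercept SD is estimated near its generating value
  expect_equal(median(rates$random_intercept_sd), 0.3, tolerance = 0.15)
})

test_that("slope estimates are unbiased across replicates", {
  parc <- generate_parcellation(12L, 3L, seed = 2)
  set.seed(123)
  bias <- replicate(25, {
    cfg <- scn_sim_config(n_regions = 12L, n_modules = 3L, hub_modules = 1L,
                          seed = sample.int(1e6, 1))
    ds <- generate_dataset(cfg, parc)
    mean(fit_thinning_rates(ds$scans)$beta_age - ds$truth$slope)
  })
  expect_lt(abs(mean(bias)), 0.002)
})

test_that("surrogates preserve the value multiset and spatial structure", {
  parc <- generate_parcellation(60L, 7L, seed = 5)
  d <- parc$distance$L
  lat <- parc$coords[parc$hemisphere == "L", 3]
  set.seed(9)
  map <- 2 * lat + rnorm(30, 0, 0.3)       # strongly autocorrelated map
  ens <- build_surrogates(map, d, n_surr = 200, seed = 9)
  # multiset equality, every surrogate
  for (s in seq_len(nrow(ens$maps))) {
    expect_equal(sort(ens$maps[s, ]), sort(map))
  }
  # variogram of matched surrogates closer to empirical than naive permutations
  vg <- scnet:::variogram_setup(d, 10)
  emp <- scnet:::binned_variogram(map, vg)
  sur_gamma <- mean(apply(ens$maps, 1, function(x)
    scnet:::binned_variogram(x, vg)[1]))
  set.seed(10)
  perm_gamma <- mean(replicate(200, scnet:::binned_variogram(sample(map), vg)[1]))
  expect_lt(abs(sur_gamma - emp[1]), abs(perm_gamma - emp[1]))
})

test_that("degenerate surrogate inputs are handled", {
  d <- as.matrix(dist(cbind(1:5, 0)))
  expect_warning(ens <- build_surrogates(rep(1, 5), d, n_surr = 10), "constant")
  expect_true(all(ens$maps == 1))
  expect_error(build_surrogates(1:4, d), "dimensions")
})

test_that("the surrogate correlation test behaves at its extremes", {
  parc <- generate_parcellation(40L, 4L, seed = 4)
  d <- parc$distance$L
  set.seed(2)
  map <- rnorm(20)
  ens <- build_surrogates(map, d, n_surr = 99, seed = 2)
  res <- surrogate_correlation_test(map, map, ens)
  expect_equal(res$r_empirical, 1)
  expect_equal(res$p, 1 / 100)             # no surrogate beats |r| = 1
  expect_gt(res$p, 0)                      # add-one convention
  expect_error(surrogate_correlation_test(rnorm(10), rnorm(10), ens),
               "built for")
  res0 <- surrogate_correlation_test(map, rep(1, 20), ens)
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p))
})

test_that("planted thinning-degree coupling is detected in the oldest bin", {
  st <- default_study()
  resid <- residualize(st$scans)
  bins <- build_bins(resid, 80, 0.25)
  oldest <- bins[[length(bins)]]
  net <- bootstrap_threshold(resid, oldest, B = 200,
                             seed = scnet:::derive_seed(11, "boot", "b80_s25",
                                                        length(bins)))
  z <- standardized_degree(net)
  rates <- fit_thinning_rates(st$scans)
  tests <- thinning_degree_association(rates, z, st$parcellation,
                                       n_surr = 500, seed = 11)
  expect_true(all(vapply(tests, function(t) t$r_empirical < 0, logical(1))))
  expect_lt(min(vapply(tests, function(t) t$p, numeric(1))), 0.05)
})
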