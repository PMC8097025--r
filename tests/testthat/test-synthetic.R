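test_that("parcellation geometry and module labels satisfy their invariants", {
  parc <- generate_parcellation(60L, 7L, seed = 7)
  expect_length(parc$region_ids, 60L)
  expect_equal(sum(parc$hemisphere == "L"), 30L)
  expect_equal(sum(parc$hemisphere == "R"), 30L)
  expect_setequal(unique(parc$modules), 1:7)
  for (h in c("L", "R")) {
    d <- parc$distance[[h]]
    expect_equal(d, t(d))
    expect_equal(diag(d), rep(0, 30))
    expect_true(all(d[upper.tri(d)] > 0))
    expect_true(all(d <= pi + 1e-12))
    # every module present within each hemisphere (construction loop)
    expect_setequal(unique(parc$modules[parc$hemisphere == h]), 1:7)
  }
  tiny <- generate_parcellation(4L, 2L, seed = 1)
  expect_equal(table(tiny$hemisphere)[["L"]], 2L)
  expect_true(all(tiny$modules %in% 1:2))
})

test_that("invalid parcellation sizes are rejected", {
  expect_error(generate_parcellation(61L, 7L), "even")
  expect_error(generate_parcellation(12L, 7L), "at least")
})

test_that("generated datasets respect the design invariants", {
  st <- default_study()
  tab <- st$scans
  expect_true(all(tab$age >= 8.5 & tab$age <= 14.5))
  per <- table(tab$participant_id)
  expect_true(all(per >= 1 & per <= 3))
  expect_equal(length(per), 192L)
  # within +/- 5% of the target scan count
  expect_lt(abs(nrow(tab) - 366) / 366, 0.05)
  # per-participant ages strictly increasing (rows are in wave order)
  incr <- tapply(tab$age, tab$participant_id, function(a) all(diff(a) > 0))
  expect_true(all(incr))
  expect_true(all(as.matrix(tab[, region_columns(tab)]) > 0))
  # two-wave cohort never exceeds 2 scans
  coh <- tapply(tab$cohort, tab$participant_id, function(x) x[1])
  expect_true(all(per[names(coh)[coh == 0]] <= 2))
  # scanner flag only on the multi-wave cohort's final wave
  expect_true(all(tab$cohort[tab$scanner == 1] == 1))
})

test_that("regeneration with the same seed is bit-for-bit identical", {
  parc <- generate_parcellation(20L, 4L, seed = 3)
  cfg <- scn_sim_config(n_participants = 40L, target_scans = 70L,
                        n_regions = 20L, n_modules = 4L, seed = 5)
  a <- generate_dataset(cfg, parc)
  b <- generate_dataset(cfg, parc)
  expect_identical(a, b)
  parc2 <- generate_parcellation(20L, 4L, seed = 3)
  expect_identical(parc, parc2)
})

test_that("noise-free linear configuration yields exact within-person thinning", {
  parc <- generate_parcellation(10L, 2L, seed = 2)
  cfg <- scn_sim_config(n_participants = 30L, target_scans = 55L,
                        n_regions = 10L, n_modules = 2L,
                        thinning_slopes = rep(-0.05, 10),
                        noise_sd = 0, subject_sd = 0,
                        baseline_thickness_sd = 0,
                        global_loading_base = 0, global_loading_bump = 0,
                        hub_loading_boost = 0, module_loading_base = 0,
                        module_loading_bump = 0, beta_scanner = 0,
                        seed = 4)
  ds <- generate_dataset(cfg, parc)
  tab <- ds$scans
  for (pid in unique(tab$participant_id)) {
    rows <- tab[tab$participant_id == pid, ]
    if (nrow(rows) < 2) next
    for (rc in region_columns(tab)) {
      slope <- diff(rows[[rc]]) / diff(rows$age)
      expect_equal(slope, rep(-0.05, nrow(rows) - 1), tolerance = 1e-10)
    }
  }
})

test_that("with all loadings and subject effects off, residual correlations are null", {
  parc <- generate_parcellation(60L, 7L, seed = 9)
  cfg <- scn_sim_config(subject_sd = 0,
                        global_loading_base = 0, global_loading_bump = 0,
                        hub_loading_boost = 0, module_loading_base = 0,
                        module_loading_bump = 0, seed = 21)
  ds <- generate_dataset(cfg, parc)
  # remove covariate and age structure region-wise, then correlate
  resid <- residualize(ds$scans, c("sex", "cohort", "scanner", "age"))
  r <- cor(as.matrix(resid[, region_columns(resid)]))
  expect_lt(abs(mean(r[upper.tri(r)])), 0.02)
})

test_that("between-region correlation is stronger near the planted peak age", {
  st <- default_study()
  resid <- residualize(st$scans)
  X <- as.matrix(resid[, region_columns(resid)])
  near <- abs(st$scans$age - st$truth$peak_age) < 0.5
  far <- abs(st$scans$age - st$truth$peak_age) > 2
  mean_r <- function(rows) {
    r <- cor(X[rows, ])
    mean(r[upper.tri(r)])
  }
  expect_gt(mean_r(near), mean_r(far))
})

test_that("infeasible or degenerate configurations are rejected", {
  expect_error(scn_sim_config(n_participants = 10L, target_scans = 100L),
               "exceeds")
  expect_error(scn_sim_config(noise_sd = -1), "non-negative")
  expect_error(scn_sim_config(n_participants = 10L, target_scans = 5L),
               "at least")
  parc <- generate_parcellation(10L, 2L, seed = 1)
  cfg <- scn_sim_config(n_participants = 20L, target_scans = 35L,
                        n_regions = 12L, n_modules = 2L)
  expect_error(generate_dataset(cfg, parc), "regions")
})
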