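#' Configuration for the synthetic longitudinal thickness generator
#'
#' Builds a validated configuration for [generate_dataset()]. The defaults
#' emulate a two-cohort accelerated-longitudinal design: ~192 participants
#' contributing 1-3 scans (~366 in total) between 8.5 and 14.5 years, one
#' cohort with two waves about 2.76 years apart and one with up to three
#' waves about 1.43 years apart, and a scanner upgrade that only affects the
#' final wave of the second cohort.
#'
#' The generative model for thickness of region r at age a in scan t of
#' subject s is
#' \deqn{y = \mu_r + d_s + \beta_{sex} sex + \beta_{coh} cohort +
#'   \beta_{scan} scanner + slope_r (a - a_0) + \lambda^g_r(a) F_t +
#'   \lambda^m(a) G_{m(r),t} + \epsilon}
#' where \eqn{F_t} and \eqn{G_{m,t}} are independent standard-normal common
#' factors (one global, one per module, redrawn per scan), and the loadings
#' carry a Gaussian bump in age centred at \code{factor_loading_peak_age}.
#' The bump induces a peak in between-region covariance at that age. Regions
#' in \code{hub_modules} get a larger baseline global loading (hence higher
#' degree at all ages) and, through \code{thinning_degree_coupling < 0},
#' steeper (more negative) thinning slopes — planting a negative association
#' between thinning rate and late-age degree.
#'
#' @param n_participants number of participants.
#' @param target_scans expected total number of scans; wave retention is
#'   solved so that the expected scan count matches this.
#' @param age_range two ages (years) bounding all generated scans.
#' @param cohort_fractions proportions of participants in the two cohorts
#'   (cohort 0: two waves, long gap; cohort 1: three waves, short gap).
#' @param interwave_gap_means,interwave_gap_sds mean and SD (years) of the
#'   interval between consecutive waves, one per cohort.
#' @param waves_per_cohort maximum waves per cohort.
#' @param baseline_age_ranges list of two age ranges from which baseline
#'   (wave-1) ages are drawn uniformly, one per cohort.
#' @param n_regions,n_modules parcellation size passed through to ground
#'   truth checks; must match the parcellation given to [generate_dataset()].
#' @param baseline_thickness_mean,baseline_thickness_sd mm; region means
#'   \eqn{\mu_r} are drawn Normal around the baseline mean.
#' @param thinning_slopes optional explicit vector of per-region slopes
#'   (mm/year, negative); when NULL slopes are drawn from the coupling model.
#' @param thinning_slope_mean,thinning_slope_sd mm/year; centre and noise of
#'   drawn slopes.
#' @param thinning_degree_coupling unitless, < 0 for the planted negative
#'   coupling; 0 disables it. Acts on the standardized baseline global
#'   loading, scaled by \code{slope_coupling_scale} (mm/year per SD).
#' @param slope_coupling_scale mm/year change in slope per SD of baseline
#'   loading.
#' @param factor_loading_peak_age,factor_loading_width centre and SD (years)
#'   of the Gaussian loading bump.
#' @param global_loading_base,global_loading_bump baseline and bump
#'   amplitude (mm) of the global-factor loading.
#' @param hub_modules module labels whose regions get the loading boost.
#' @param hub_loading_boost mm added to the baseline global loading of hub
#'   module regions.
#' @param module_loading_base,module_loading_bump baseline and bump
#'   amplitude (mm) of the module-factor loadings.
#' @param beta_sex,beta_cohort,beta_scanner mm; additive covariate effects.
#' @param subject_sd mm; SD of the per-subject random intercept.
#' @param noise_sd mm; SD of scan-level residual noise.
#' @param sex_specific_peaks optional numeric vector of two peak ages
#'   (female, male); when given, the loading bump is centred per sex,
#'   injecting a sex-by-age interaction in covariance.
#' @param scanner_upgrade_wave wave index at which the scanner flag switches
#'   on for the multi-wave cohort.
#' @param seed integer seed; regenerating with the same seed reproduces the
#'   dataset bit-for-bit.
#' @return A list of class \code{"scn_sim_config"}.
#' @export
scn_sim_config <- function(n_participants = 192L,
                           target_scans = 366L,
                           age_range = c(8.5, 14.5),
                           cohort_fractions = c(102, 90) / 192,
                           interwave_gap_means = c(2.763, 1.432),
                           interwave_gap_sds = c(0.243, 0.222),
                           waves_per_cohort = c(2L, 3L),
                           baseline_age_ranges = list(c(8.5, 10.6), c(9.5, 11.6)),
                           n_regions = 60L,
                           n_modules = 7L,
                           baseline_thickness_mean = 2.7,
                           baseline_thickness_sd = 0.15,
                           thinning_slopes = NULL,
                           thinning_slope_mean = -0.03,
                           thinning_slope_sd = 0.003,
                           thinning_degree_coupling = -1,
                           slope_coupling_scale = 0.01,
                           factor_loading_peak_age = 11.5,
                           factor_loading_width = 1.0,
                           global_loading_base = 0.015,
                           global_loading_bump = 0.08,
                           hub_modules = c(1L, 2L),
                           hub_loading_boost = 0.035,
                           module_loading_base = 0.02,
                           module_loading_bump = 0.03,
                           beta_sex = 0.04,
                           beta_cohort = 0.03,
                           beta_scanner = 0.02,
                           subject_sd = 0.02,
                           noise_sd = 0.12,
                           sex_specific_peaks = NULL,
                           scanner_upgrade_wave = 3L,
                           seed = 1L) {
  cfg <- as.list(environment())
  if (noise_sd < 0 || subject_sd < 0 || baseline_thickness_sd < 0 ||
      thinning_slope_sd < 0 || any(interwave_gap_sds < 0)) {
    stop_invalid("standard deviations must be non-negative")
  }
  if (n_participants < 1L) stop_invalid("n_participants must be positive")
  if (length(age_range) != 2L || diff(age_range) <= 0) {
    stop_invalid("age_range must be an increasing pair of ages")
  }
  if (abs(sum(cohort_fractions) - 1) > 1e-8 || any(cohort_fractions < 0)) {
    stop_invalid("cohort_fractions must be non-negative and sum to 1")
  }
  n_coh <- round(n_participants * cohort_fractions)
  n_coh[2] <- n_participants - n_coh[1]
  max_scans <- sum(n_coh * waves_per_cohort)
  if (target_scans > max_scans) {
    stop_invalid("target_scans (", target_scans, ") exceeds the maximum ",
                 max_scans, " achievable with ", n_participants,
                 " participants and the configured waves per cohort")
  }
  if (target_scans < n_participants) {
    stop_invalid("target_scans must be at least n_participants ",
                 "(every participant contributes one scan)")
  }
  if (!is.null(thinning_slopes) && length(thinning_slopes) != n_regions) {
    stop_invalid("thinning_slopes must have one value per region")
  }
  cfg$n_cohort <- n_coh
  class(cfg) <- "scn_sim_config"
  cfg
}

#' Generate a synthetic spherical parcellation
#'
#' Places \code{n_regions/2} regions uniformly on a unit sphere per
#' hemisphere, assigns each region to the nearest of \code{n_modules}
#' random module centroids within its hemisphere (yielding spatially
#' contiguous modules, redrawing centroids until every module is non-empty
#' in both hemispheres), and returns great-circle distance matrices per
#' hemisphere.
#'
#' @param n_regions even total number of regions (split across hemispheres).
#' @param n_modules number of module labels (1..n_modules).
#' @param seed integer seed.
#' @return A list of class \code{"scn_parcellation"} with elements
#'   \code{region_ids}, \code{hemisphere} ("L"/"R" per region),
#'   \code{coords} (region x 3 matrix), \code{modules} (integer per region)
#'   and \code{distance} (list of per-hemisphere matrices).
#' @export
generate_parcellation <- function(n_regions, n_modules = 7L, seed = 1L) {
  if (n_regions %% 2L != 0L) stop_invalid("n_regions must be even")
  if (n_regions < 2L * n_modules) {
    stop_invalid("n_regions must be at least 2 * n_modules")
  }
  set.seed(seed)
  per_hemi <- n_regions %/% 2L
  hemis <- c("L", "R")
  coords <- matrix(NA_real_, n_regions, 3)
  modules <- integer(n_regions)
  distance <- list()
  for (h in 1:2) {
    idx <- (h - 1L) * per_hemi + seq_len(per_hemi)
    xyz <- random_sphere_points(per_hemi)
    # redraw centroids until each module captures at least one region
    for (attempt in 1:200) {
      cent <- random_sphere_points(n_modules)
      lab <- max.col(xyz %*% t(cent), ties.method = "first")
      if (length(unique(lab)) == n_modules) break
    }
    if (length(unique(lab)) != n_modules) {
      stop_invalid("could not place ", n_modules, " non-empty modules on ",
                   per_hemi, " regions")
    }
    coords[idx, ] <- xyz
    modules[idx] <- lab
    gram <- xyz %*% t(xyz)
    d <- acos(pmin(pmax(gram, -1), 1))
    diag(d) <- 0
    dimnames(d) <- NULL
    distance[[hemis[h]]] <- d
  }
  region_ids <- sprintf("%s_%03d", rep(hemis, each = per_hemi),
                        rep(seq_len(per_hemi), 2))
  structure(list(region_ids = region_ids,
                 hemisphere = rep(hemis, each = per_hemi),
                 coords = coords,
                 modules = modules,
                 n_modules = as.integer(n_modules),
                 distance = distance),
            class = "scn_parcellation")
}

random_sphere_points <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a synthetic longitudinal scan table with known ground truth
#'
#' Draws participants, waves and regional thickness values from the
#' generative model described in [scn_sim_config()]. Wave retention is
#' solved so the expected number of scans equals \code{target_scans};
#' attendance is monotone (a participant who misses a wave contributes no
#' later scans), which reproduces the mix of one-, two- and three-scan
#' participants typical of accelerated longitudinal cohorts.
#'
#' @param config an [scn_sim_config()] object.
#' @param parcellation an [generate_parcellation()] object with
#'   \code{config$n_regions} regions.
#' @return A list with elements \code{scans} (the scan table: one row per
#'   scan, thickness columns named by region id) and \code{truth} (list of
#'   ground-truth parameters: region means, slopes, loadings, hub modules,
#'   module labels, peak age).
#' @export
generate_dataset <- function(config, parcellation) {
  stopifnot(inherits(config, "scn_sim_config"),
            inherits(parcellation, "scn_parcellation"))
  P <- length(parcellation$region_ids)
  if (P != config$n_regions) {
    stop_invalid("parcellation has ", P, " regions but config expects ",
                 config$n_regions)
  }
  set.seed(config$seed)
  n <- config$n_participants
  n_coh <- config$n_cohort
  cohort <- rep(0:1, times = n_coh)
  sex <- sample(rep(0:1, length.out = n))
  rho <- solve_retention(n_coh, config$waves_per_cohort, config$target_scans)

  age_min <- config$age_range[1]
  age_max <- config$age_range[2]

  # --- region-level ground truth -------------------------------------------
  mu <- config$baseline_thickness_mean +
    stats::rnorm(P, 0, config$baseline_thickness_sd)
  is_hub_region <- parcellation$modules %in% config$hub_modules
  g0 <- config$global_loading_base + config$hub_loading_boost * is_hub_region
  if (is.null(config$thinning_slopes)) {
    g0_z <- if (stats::sd(g0) > 0) (g0 - mean(g0)) / stats::sd(g0) else rep(0, P)
    slope <- config$thinning_slope_mean +
      config$thinning_degree_coupling * config$slope_coupling_scale * g0_z +
      stats::rnorm(P, 0, config$thinning_slope_sd)
  } else {
    slope <- config$thinning_slopes
  }

  # --- participant-level structure -----------------------------------------
  d_s <- stats::rnorm(n, 0, config$subject_sd)
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    coh <- cohort[s] + 1L             # 1-based cohort index
    W <- config$waves_per_cohort[coh]
    attended <- 1L
    while (attended < W && stats::runif(1) < rho) attended <- attended + 1L
    gaps <- if (W > 1L) {
      abs(stats::rnorm(W - 1L, config$interwave_gap_means[coh],
                       config$interwave_gap_sds[coh]))
    } else numeric(0)
    gaps_used <- gaps[seq_len(max(0L, attended - 1L))]
    lo <- config$baseline_age_ranges[[coh]][1]
    hi <- min(config$baseline_age_ranges[[coh]][2],
              age_max - sum(gaps_used) - 1e-6)
    if (hi < lo) {               # shrink gaps to fit the age range
      gaps_used <- gaps_used * (age_max - lo - 1e-6) / sum(gaps_used)
      hi <- lo
    }
    baseline <- stats::runif(1, lo, hi)
    ages <- baseline + cumsum(c(0, gaps_used))
    rows[[s]] <- data.frame(
      participant_id = sprintf("P%03d", s),
      scan_id = sprintf("P%03d_w%d", s, seq_len(attended)),
      wave = seq_len(attended),
      age = ages,
      sex = sex[s], cohort = cohort[s],
      scanner = as.integer(cohort[s] == 1L &
                           seq_len(attended) >= config$scanner_upgrade_wave),
      stringsAsFactors = FALSE)
  }
  scans <- do.call(rbind, rows)
  n_scans <- nrow(scans)

  # --- thickness values -----------------------------------------------------
  peak <- rep(config$factor_loading_peak_age, n_scans)
  if (!is.null(config$sex_specific_peaks)) {
    peak <- ifelse(scans$sex == 0, config$sex_specific_peaks[1],
                   config$sex_specific_peaks[2])
  }
  bump <- exp(-((scans$age - peak)^2) / (2 * config$factor_loading_width^2))
  f_global <- stats::rnorm(n_scans)
  f_module <- matrix(stats::rnorm(n_scans * config$n_modules),
                     n_scans, config$n_modules)
  subj_idx <- match(scans$participant_id, sprintf("P%03d", seq_len(n)))

  fixed <- config$beta_sex * scans$sex + config$beta_cohort * scans$cohort +
    config$beta_scanner * scans$scanner + d_s[subj_idx]
  th <- matrix(NA_real_, n_scans, P)
  for (r in seq_len(P)) {
    lam_g <- g0[r] + config$global_loading_bump * bump
    lam_m <- config$module_loading_base + config$module_loading_bump * bump
    th[, r] <- mu[r] + fixed + slope[r] * (scans$age - age_min) +
      lam_g * f_global + lam_m * f_module[, parcellation$modules[r]] +
      stats::rnorm(n_scans, 0, config$noise_sd)
  }
  if (any(th <= 0)) {
    stop_invalid("generated non-positive thickness values; ",
                 "the configured effect/noise sizes are too large")
  }
  colnames(th) <- parcellation$region_ids
  scan_table <- cbind(scans[, c("participant_id", "scan_id", "age",
                                "sex", "cohort", "scanner")], th)
  rownames(scan_table) <- NULL

  truth <- list(mu = mu, slope = slope, g0 = g0,
                global_loading_bump = config$global_loading_bump,
                module_loading_base = config$module_loading_base,
                module_loading_bump = config$module_loading_bump,
                hub_modules = config$hub_modules,
                modules = parcellation$modules,
                peak_age = config$factor_loading_peak_age,
                loading_width = config$factor_loading_width,
                retention = rho)
  list(scans = scan_table, truth = truth)
}

# Retention probability rho such that, with monotone attendance
# (wave w reached with probability rho^(w-1)), the expected total scan count
# equals the target.
solve_retention <- function(n_cohort, waves_per_cohort, target) {
  expected <- function(rho) {
    sum(vapply(seq_along(n_cohort), function(c) {
      n_cohort[c] * sum(rho^(0:(waves_per_cohort[c] - 1L)))
    }, numeric(1)))
  }
  if (expected(1) <= target) return(1)
  stats::uniroot(function(r) expected(r) - target, c(0, 1), tol = 1e-10)$root
}
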