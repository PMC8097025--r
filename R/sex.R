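#' Run the network pipeline within one sex
#'
#' Applies the core machinery to the subset of scans of one sex:
#' residualization on cohort and scanner only (sex is constant within the
#' stratum), age-bin construction, bootstrap thresholding, and global /
#' modular metrics. Modular densities are normalized by the stratum's own
#' global density. When the stratum holds fewer scans than the bin size the
#' configuration is skipped and an empty, flagged result is returned.
#'
#' @param scan_table full scan table.
#' @param sex value of the \code{sex} column defining the stratum.
#' @param bin_size,step_fraction window configuration.
#' @param B,alpha bootstrap thresholding parameters.
#' @param modules optional module labels (for modular densities).
#' @param covariates covariates removed within the stratum.
#' @param seed integer seed.
#' @return A list of class \code{"scn_sex_run"} with \code{sex},
#'   \code{skipped} flag, and when run: \code{bins}, \code{networks},
#'   \code{median_age}, \code{global_density}, \code{mean_correlation},
#'   \code{z_degree} (regions x bins) and \code{modular} (list per bin,
#'   when modules are given).
#' @export
stratified_pipeline <- function(scan_table, sex, bin_size, step_fraction,
                                B = 1000L, alpha = 0.05, modules = NULL,
                                covariates = c("cohort", "scanner"),
                                seed = 1L) {
  stratum <- scan_table[scan_table$sex == sex, , drop = FALSE]
  if (nrow(stratum) < bin_size) {
    warning("stratum sex=", sex, " has ", nrow(stratum),
            " scans < bin_size ", bin_size, "; configuration skipped",
            call. = FALSE)
    return(structure(list(sex = sex, skipped = TRUE), class = "scn_sex_run"))
  }
  resid <- residualize(stratum, covariates)
  bins <- build_bins(resid, bin_size, step_fraction)
  networks <- vector("list", length(bins))
  gd <- mc <- med <- numeric(length(bins))
  z <- matrix(NA_real_, length(region_columns(scan_table)), length(bins))
  modular <- if (!is.null(modules)) vector("list", length(bins))
  for (i in seq_along(bins)) {
    net <- bootstrap_threshold(resid, bins[[i]], B = B, alpha = alpha,
                               seed = derive_seed(seed, "sexboot", sex, i))
    networks[[i]] <- net
    med[i] <- bins[[i]]$median_age
    gd[i] <- global_density(net)
    mc[i] <- mean_correlation(net)
    z[, i] <- suppressWarnings(standardized_degree(net))
    if (!is.null(modules)) modular[[i]] <- modular_density(net, modules)
  }
  structure(list(sex = sex, skipped = FALSE, bins = bins, networks = networks,
                 median_age = med, global_density = gd, mean_correlation = mc,
                 z_degree = z, modular = modular),
            class = "scn_sex_run")
}

#' Compare age trajectories between sexes with an interaction model
#'
#' Pools the two per-bin metric series and fits, by Gaussian maximum
#' likelihood, (i) a shared model — one natural-cubic-spline smooth of age
#' (two basis functions, pooled knots) plus a sex offset — and (ii) a
#' by-sex model with a separate smooth per sex plus the offset. The by-sex
#' model is selected only if its AIC is at least \code{delta} lower than
#' the shared model's.
#'
#' @param age_female,value_female female series (bin median ages, values).
#' @param age_male,value_male male series.
#' @param delta AIC margin (default 3).
#' @return A list with \code{aic_shared}, \code{aic_by_sex},
#'   \code{selected} ("shared" or "by_sex") and \code{logLik} for both.
#' @export
sex_interaction_fit <- function(age_female, value_female,
                                age_male, value_male, delta = 3) {
  if (length(age_female) == 0L || length(age_male) == 0L) {
    stop_invalid("both strata must provide a non-empty series")
  }
  age <- c(age_female, age_male)
  value <- c(value_female, value_male)
  sex <- factor(rep(c("F", "M"), c(length(age_female), length(age_male))))
  B <- smooth_basis(age)           # pooled knots
  dat <- data.frame(value = value, sex = sex, b1 = B[, 1], b2 = B[, 2])
  shared <- stats::lm(value ~ sex + b1 + b2, data = dat)
  by_sex <- stats::lm(value ~ sex + (b1 + b2) * sex, data = dat)
  # saturated fits cannot estimate the error variance: treat as unfittable
  aic_of <- function(f) if (stats::nobs(f) <= f$rank) Inf else stats::AIC(f)
  aic_shared <- aic_of(shared)
  aic_by_sex <- aic_of(by_sex)
  list(aic_shared = aic_shared, aic_by_sex = aic_by_sex,
       selected = if (aic_by_sex <= aic_shared - delta) "by_sex" else "shared",
       logLik = c(shared = as.numeric(stats::logLik(shared)),
                  by_sex = as.numeric(stats::logLik(by_sex))))
}
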