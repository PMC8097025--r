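#' Per-region linear thinning rates from random-intercept mixed models
#'
#' For each region, fits the Gaussian linear mixed model
#' \deqn{Y = Intercept + d_i + \beta_1 sex + \beta_2 cohort +
#'   \beta_3 scanner + \beta_4 age + e_i}
#' with a participant random intercept \eqn{d_i}, by restricted maximum
#' likelihood (\pkg{lme4}). The age coefficient is the region's thinning
#' rate (mm/year; negative means thinning). Regions whose mixed model fails
#' or does not converge fall back to ordinary least squares and are flagged.
#' Constant covariates are dropped (with a warning) before fitting.
#'
#' @param scan_table a scan table (raw thickness, not residualized).
#' @param covariates fixed-effect covariates besides age.
#' @return Data frame with one row per region: \code{region}, \code{beta_age}
#'   (mm/year), \code{intercept}, \code{random_intercept_sd},
#'   \code{residual_sd}, \code{ols_fallback} (logical).
#' @export
fit_thinning_rates <- function(scan_table,
                               covariates = c("sex", "cohort", "scanner")) {
  check_scan_table(scan_table)
  keep <- vapply(covariates, function(v) length(unique(scan_table[[v]])) > 1L,
                 logical(1))
  if (any(!keep)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "), call. = FALSE)
  }
  covariates <- covariates[keep]
  regions <- region_columns(scan_table)
  rhs <- paste(c(covariates, "age"), collapse = " + ")
  lmm_formula <- stats::as.formula(paste("y ~", rhs, "+ (1 | participant_id)"))
  ols_formula <- stats::as.formula(paste("y ~", rhs))
  dat <- scan_table[, c("participant_id", covariates, "age")]

  out <- data.frame(region = regions, beta_age = NA_real_,
                    intercept = NA_real_, random_intercept_sd = NA_real_,
                    residual_sd = NA_real_, ols_fallback = FALSE,
                    stringsAsFactors = FALSE)
  base_fit <- NULL
  for (i in seq_along(regions)) {
    dat$y <- scan_table[[regions[i]]]
    fit <- tryCatch({
      f <- if (is.null(base_fit)) {
        lme4::lmer(lmm_formula, data = dat, REML = TRUE)
      } else {
        lme4::refit(base_fit, newresp = dat$y)
      }
      conv <- f@optinfo$conv$lme4
      if (!is.null(conv$code) && conv$code < 0) stop("did not converge")
      f
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      if (is.null(base_fit)) base_fit <- fit
      fe <- lme4::fixef(fit)
      vc <- as.data.frame(lme4::VarCorr(fit))
      out$beta_age[i] <- fe[["age"]]
      out$intercept[i] <- fe[["(Intercept)"]]
      out$random_intercept_sd[i] <- vc$sdcor[vc$grp == "participant_id"]
      out$residual_sd[i] <- vc$sdcor[vc$grp == "Residual"]
    } else {
      ols <- stats::lm(ols_formula, data = dat)
      cf <- stats::coef(ols)
      out$beta_age[i] <- cf[["age"]]
      out$intercept[i] <- cf[["(Intercept)"]]
      out$random_intercept_sd[i] <- 0
      out$residual_sd[i] <- summary(ols)$sigma
      out$ols_fallback[i] <- TRUE
    }
  }
  out
}

#' Spatial-autocorrelation-preserving surrogate maps
#'
#' Generates randomized versions of a regional map that keep both its value
#' distribution (exactly, by rank-remapping) and, approximately, its
#' spatial autocorrelation (by variogram matching). Each surrogate is built
#' by (1) randomly permuting the map values, (2) smoothing the permuted map
#' by inverse-distance-weighted averaging over the k nearest neighbours for
#' each candidate k in \code{kernel_grid} (k = 0 means no smoothing),
#' (3) keeping the k whose smoothed map (rescaled to the source mean/SD)
#' has the smallest squared error between its binned variogram and the
#' source map's, and (4) rank-remapping the chosen smoothed map onto the
#' source value multiset.
#'
#' @param map numeric regional map (one hemisphere).
#' @param distance symmetric distance matrix for the same regions.
#' @param n_surr number of surrogates (default 1000).
#' @param kernel_grid candidate neighbourhood sizes; defaults to
#'   \code{c(0, 2, 4, 8, 16)} truncated below the number of regions.
#' @param n_bins number of equal-count distance bins for the variogram
#'   (default 10).
#' @param seed integer seed.
#' @return A list of class \code{"scn_surrogates"}: \code{maps}
#'   (n_surr x regions matrix; every row has exactly the source value
#'   multiset), \code{kernel} (chosen k per surrogate), \code{variogram}
#'   (binned empirical variogram of the source map), \code{bin_centers}.
#' @export
build_surrogates <- function(map, distance, n_surr = 1000L,
                             kernel_grid = NULL, n_bins = 10L, seed = 1L) {
  n <- length(map)
  if (!is.matrix(distance) || nrow(distance) != n || ncol(distance) != n) {
    stop_invalid("distance matrix dimensions do not match the map")
  }
  if (n_surr < 1L) stop_invalid("n_surr must be >= 1")
  if (is.null(kernel_grid)) kernel_grid <- c(0L, 2L, 4L, 8L, 16L)
  kernel_grid <- sort(unique(pmin(kernel_grid, n - 1L)))
  sorted_vals <- sort(map)
  if (stats::sd(map) < 1e-12) {
    warning("map is constant; surrogates equal the map", call. = FALSE)
    return(structure(list(maps = matrix(map, n_surr, n, byrow = TRUE),
                          kernel = rep(NA_integer_, n_surr),
                          variogram = NULL, bin_centers = NULL, seed = seed),
                     class = "scn_surrogates"))
  }

  vg <- variogram_setup(distance, n_bins)
  emp <- binned_variogram(map, vg)

  # precompute kNN smoothing operators (rows: weights over neighbours)
  ops <- lapply(kernel_grid, function(k) {
    if (k == 0L) return(diag(n))
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(distance[i, ])[-1][seq_len(k)]   # exclude self
      w <- 1 / pmax(distance[i, nb], 1e-12)
      W[i, nb] <- w / sum(w)
    }
    W
  })

  set.seed(seed)
  maps <- matrix(NA_real_, n_surr, n)
  kern <- integer(n_surr)
  mu0 <- mean(map); sd0 <- stats::sd(map)
  for (s in seq_len(n_surr)) {
    perm <- sample(map)
    best_sse <- Inf; best <- perm; best_k <- 0L
    for (j in seq_along(kernel_grid)) {
      sm <- as.vector(ops[[j]] %*% perm)
      sm_std <- (sm - mean(sm)) / max(stats::sd(sm), 1e-12) * sd0 + mu0
      sse <- sum((binned_variogram(sm_std, vg) - emp)^2)
      if (sse < best_sse) {
        best_sse <- sse; best <- sm_std; best_k <- kernel_grid[j]
      }
    }
    maps[s, ] <- sorted_vals[rank(best, ties.method = "first")]
    kern[s] <- best_k
  }
  structure(list(maps = maps, kernel = kern, variogram = emp,
                 bin_centers = vg$centers, seed = seed),
            class = "scn_surrogates")
}

# Pair indices and equal-count distance bins for variogram computation.
variogram_setup <- function(distance, n_bins) {
  pr <- upper_pairs(nrow(distance))
  d <- distance[pr]
  edges <- stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1L))
  bin <- cut(d, breaks = unique(edges), include.lowest = TRUE, labels = FALSE)
  centers <- as.vector(tapply(d, bin, mean))
  list(i = pr[, 1], j = pr[, 2], bin = bin, centers = centers,
       counts = tabulate(bin), n_bins = max(bin))
}

# Binned semivariance: half the mean squared value difference per bin.
binned_variogram <- function(x, vg) {
  sq <- 0.5 * (x[vg$i] - x[vg$j])^2
  as.vector(rowsum(sq, vg$bin, reorder = TRUE)) / vg$counts
}

#' Surrogate-map correlation test
#'
#' Pearson correlation between two regional maps, with a non-parametric
#' p-value from an ensemble of autocorrelation-preserving surrogates of the
#' first map: the proportion of surrogates whose correlation with the
#' second map is at least as large as the empirical value, by default
#' compared in absolute magnitude (the sign of the empirical correlation is
#' recorded separately). The add-one convention keeps p strictly positive.
#'
#' @param map_a,map_b regional maps on the same regions.
#' @param surrogates an [build_surrogates()] ensemble built on \code{map_a}.
#' @param alternative \code{"magnitude"} (default; two-sided in |r|) or
#'   \code{"signed"} (one-sided in the direction of the empirical r).
#' @return A list with \code{r_empirical}, \code{p}, \code{direction}
#'   (sign of the empirical correlation), \code{alternative} and
#'   \code{n_surr}. If either map has zero variance, \code{r_empirical}
#'   and \code{p} are NA and \code{degenerate} is TRUE.
#' @export
surrogate_correlation_test <- function(map_a, map_b, surrogates,
                                       alternative = c("magnitude", "signed")) {
  alternative <- match.arg(alternative)
  if (length(map_a) != length(map_b)) stop_invalid("maps differ in length")
  if (ncol(surrogates$maps) != length(map_a)) {
    stop_invalid("surrogate ensemble was built for ", ncol(surrogates$maps),
                 " regions, not ", length(map_a))
  }
  n_surr <- nrow(surrogates$maps)
  if (stats::sd(map_a) < 1e-12 || stats::sd(map_b) < 1e-12) {
    return(list(r_empirical = NA_real_, p = NA_real_, direction = NA_real_,
                alternative = alternative, n_surr = n_surr, degenerate = TRUE))
  }
  r_emp <- stats::cor(map_a, map_b)
  r_surr <- as.vector(stats::cor(t(surrogates$maps), map_b))
  exceed <- if (alternative == "magnitude") {
    abs(r_surr) >= abs(r_emp)
  } else if (r_emp >= 0) r_surr >= r_emp else r_surr <= r_emp
  list(r_empirical = r_emp, p = (sum(exceed) + 1) / (n_surr + 1),
       direction = sign(r_emp), alternative = alternative,
       n_surr = n_surr, degenerate = FALSE)
}

#' Test the association between thinning rates and nodal degree
#'
#' Correlates per-region thinning rates (age slopes from
#' [fit_thinning_rates()]) with standardized degree in a designated bin,
#' separately per hemisphere, with significance from variogram-matched
#' surrogates of the thinning map.
#'
#' @param thinning data frame from [fit_thinning_rates()] (rows aligned
#'   with the parcellation's regions).
#' @param z_degree standardized degree per region for the designated bin.
#' @param parcellation the parcellation (for hemispheres and distances).
#' @param n_surr surrogates per hemisphere (default 1000).
#' @param seed integer seed.
#' @param surrogates optional pre-built list of ensembles (named "L","R")
#'   on the hemisphere thinning maps, to reuse across bins.
#' @return A list with one element per hemisphere, each the result of
#'   [surrogate_correlation_test()].
#' @export
thinning_degree_association <- function(thinning, z_degree, parcellation,
                                        n_surr = 1000L, seed = 1L,
                                        surrogates = NULL) {
  if (length(z_degree) != length(parcellation$region_ids)) {
    stop_invalid("z_degree length does not match the parcellation")
  }
  out <- list()
  for (h in unique(parcellation$hemisphere)) {
    idx <- which(parcellation$hemisphere == h)
    beta <- thinning$beta_age[idx]
    ens <- if (!is.null(surrogates)) surrogates[[h]] else {
      build_surrogates(beta, parcellation$distance[[h]], n_surr = n_surr,
                       seed = derive_seed(seed, "surr", h))
    }
    res <- surrogate_correlation_test(beta, z_degree[idx], ens)
    res$hemisphere <- h
    out[[h]] <- res
  }
  out
}
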