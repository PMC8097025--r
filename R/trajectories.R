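#' Natural cubic spline basis used by the smooth age model
#'
#' Two basis functions beyond the intercept (the maximum flexibility of a
#' rank-3 smooth), with the interior knot at the median age and boundary
#' knots at the age range.
#' @param age ages at which to evaluate the basis.
#' @param knots_from ages defining knot placement (defaults to \code{age}).
#' @return Basis matrix with two columns.
#' @keywords internal
smooth_basis <- function(age, knots_from = age) {
  splines::ns(age, knots = stats::median(knots_from),
              Boundary.knots = range(knots_from))
}

#' Fit null, linear and smooth age models to a per-bin metric series
#'
#' Fits three Gaussian models of a metric against bin median age by maximum
#' likelihood: a null (intercept-only) model, a linear model, and a smooth
#' model using a natural cubic spline of age with two basis functions
#' beyond the intercept (knots at the minimum, median and maximum age).
#' AIC counts the error variance as an estimated parameter in all three
#' models. A model is selected only if its AIC is at least \code{delta}
#' lower than every lower-order model; otherwise the simpler model wins.
#'
#' @param age bin median ages (non-decreasing).
#' @param value metric values, one per bin.
#' @param delta AIC margin for selecting a more complex model (default 3).
#' @return A list of class \code{"scn_trajectory"} with \code{aic} (named
#'   null/linear/smooth, +Inf when a model could not be fit), \code{selected},
#'   \code{smooth_p} (F-test of the spline terms against the null model),
#'   \code{fitted} (fitted values of the selected model), \code{peak_age}
#'   (age of the maximum of the smooth fit on a dense grid, reported when
#'   smooth is selected; NA otherwise), \code{peak_interior} (whether that
#'   maximum is away from the range edges) and \code{net_change} (fitted
#'   last minus fitted first value of the selected model).
#' @export
fit_trajectory <- function(age, value, delta = 3) {
  if (length(age) != length(value)) stop_invalid("age and value lengths differ")
  ok <- is.finite(age) & is.finite(value)
  age <- age[ok]; value <- value[ok]
  n <- length(age)
  if (n < 2L) stop_invalid("need at least 2 points")
  if (stats::sd(age) < 1e-12) stop_invalid("ages are constant")
  dat <- data.frame(age = age, value = value)
  kn <- stats::median(age)
  bk <- range(age)

  fits <- list(null = stats::lm(value ~ 1, data = dat),
               linear = if (n >= 3L) stats::lm(value ~ age, data = dat))
  fits$smooth <- if (n >= 4L && length(unique(age)) >= 3L) {
    # knots fixed outside the formula so predict() reuses them on new data
    stats::lm(value ~ splines::ns(age, knots = kn, Boundary.knots = bk),
              data = dat)
  }
  aic <- vapply(c("null", "linear", "smooth"), function(m) {
    f <- fits[[m]]
    if (is.null(f)) return(Inf)
    p_mean <- f$rank
    if (n <= p_mean) return(Inf)       # saturated: cannot estimate variance
    stats::AIC(f)
  }, numeric(1))

  selected <- select_by_aic(aic["null"], aic["linear"], aic["smooth"], delta)
  smooth_p <- NA_real_
  if (!is.null(fits$smooth) && is.finite(aic["smooth"])) {
    smooth_p <- stats::anova(fits$null, fits$smooth)[["Pr(>F)"]][2]
  }
  peak_age <- NA_real_
  peak_interior <- NA
  if (selected == "smooth") {
    grid <- seq(min(age), max(age), length.out = 401L)
    pred <- stats::predict(fits$smooth, newdata = data.frame(age = grid))
    k <- which.max(pred)
    peak_age <- grid[k]
    peak_interior <- k > 1L && k < length(grid)
  }
  fitted_sel <- stats::fitted(fits[[selected]])
  structure(list(aic = aic, selected = selected, smooth_p = smooth_p,
                 fitted = fitted_sel,
                 peak_age = peak_age, peak_interior = peak_interior,
                 net_change = unname(fitted_sel[n] - fitted_sel[1]),
                 logLik = vapply(fits, function(f) {
                   if (is.null(f)) -Inf else as.numeric(stats::logLik(f))
                 }, numeric(1)),
                 n = n, delta = delta),
            class = "scn_trajectory")
}

#' Step-up model selection by an AIC margin
#'
#' The smooth model is selected only if its AIC is at least \code{delta}
#' below both the linear and the null model; otherwise the linear model is
#' selected if its AIC is at least \code{delta} below the null model;
#' otherwise the null model is selected.
#'
#' @param aic_null,aic_linear,aic_smooth AIC values (may be +Inf for models
#'   that could not be fit).
#' @param delta required AIC gain (default 3).
#' @return One of \code{"null"}, \code{"linear"}, \code{"smooth"}.
#' @export
select_by_aic <- function(aic_null, aic_linear, aic_smooth, delta = 3) {
  if (is.finite(aic_smooth) &&
      aic_smooth <= aic_linear - delta && aic_smooth <= aic_null - delta) {
    return("smooth")
  }
  if (is.finite(aic_linear) && aic_linear <= aic_null - delta) {
    return("linear")
  }
  "null"
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' @param p p-values in [0, 1] (NAs allowed and passed through).
#' @param alpha FDR level (default 0.05).
#' @return A list with \code{adjusted} (monotone BH-adjusted p-values) and
#'   \code{reject} (logical flags at level \code{alpha}).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= alpha)
}

#' Consensus of findings across window configurations
#'
#' A finding (a metric together with its selected model and direction of
#' net change) is reported only when it is detected in strictly more than
#' \code{fraction} of the window configurations.
#'
#' @param findings data frame with columns \code{config_id},
#'   \code{metric_id}, \code{selected} and optionally \code{direction}.
#' @param n_configs total number of configurations evaluated (defaults to
#'   the number of distinct \code{config_id}s in \code{findings}).
#' @param fraction consensus threshold (default 0.5, i.e. "more than half").
#' @return Data frame with one row per distinct finding and columns
#'   \code{metric_id}, \code{selected}, \code{direction} (if supplied),
#'   \code{n_configs_detected}, \code{n_configs_total}, \code{reported}.
#' @export
consensus_report <- function(findings, n_configs = NULL, fraction = 0.5) {
  if (is.null(n_configs)) n_configs <- length(unique(findings$config_id))
  if (n_configs < 1L) stop_invalid("need at least one configuration")
  keys <- intersect(c("metric_id", "selected", "direction"), names(findings))
  counts <- stats::aggregate(
    list(n_configs_detected = findings$config_id),
    by = findings[, keys, drop = FALSE],
    FUN = function(x) length(unique(x)))
  counts$n_configs_total <- n_configs
  counts$reported <- counts$n_configs_detected / n_configs > fraction
  counts[order(counts$metric_id), , drop = FALSE]
}
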