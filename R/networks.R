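#' Residualize regional thickness for covariates
#'
#' Fits, per region, an ordinary least-squares regression of thickness on
#' the named covariates across the full sample, and replaces thickness by
#' internally studentized (standardized) residuals
#' \eqn{e_i / (\hat\sigma \sqrt{1 - h_{ii}})}, with
#' \eqn{\hat\sigma^2 = RSS/(n - p)} and \eqn{h_{ii}} the leverage of scan i
#' (the convention of \code{stats::rstandard}). Covariates that are constant
#' in the table are dropped with a warning; a perfectly fitted region
#' (\eqn{\hat\sigma = 0}) yields zero residuals.
#'
#' @param scan_table a scan table.
#' @param covariates character vector of covariate column names (default
#'   sex, cohort, scanner).
#' @return The scan table with region columns replaced by standardized
#'   residuals (unitless, mean ~ 0 per region).
#' @export
residualize <- function(scan_table, covariates = c("sex", "cohort", "scanner")) {
  check_scan_table(scan_table)
  missing <- setdiff(covariates, names(scan_table))
  if (length(missing) > 0L) {
    stop_invalid("covariate(s) not in scan table: ", paste(missing, collapse = ", "))
  }
  keep <- vapply(covariates, function(v) {
    length(unique(scan_table[[v]])) > 1L
  }, logical(1))
  if (any(!keep)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "), call. = FALSE)
  }
  covariates <- covariates[keep]
  n <- nrow(scan_table)
  X <- if (length(covariates) > 0L) {
    stats::model.matrix(~ ., data = scan_table[, covariates, drop = FALSE])
  } else {
    matrix(1, n, 1)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("rank-deficient design; dropping aliased column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  p <- ncol(X)
  if (n <= p) stop_invalid("need more scans (", n, ") than parameters (", p, ")")
  Y <- thickness_matrix(scan_table)
  res <- Y - X %*% qr.coef(qrX, Y)
  h <- rowSums(qr.Q(qrX)^2)
  sigma <- sqrt(colSums(res^2) / (n - p))
  denom <- outer(sqrt(pmax(0, 1 - h)), sigma)
  std <- res / denom
  std[, sigma < 1e-12] <- 0          # perfect fit: residuals defined as zero
  out <- scan_table
  out[region_columns(scan_table)] <- as.data.frame(std)
  out
}

#' Pearson correlation network for one age bin
#'
#' Correlates residualized thickness across regions over the scans retained
#' in a bin. Regions with zero variance within the bin get correlation 0
#' with all partners and are flagged in the diagnostics.
#'
#' @param residual_table a residualized scan table (see [residualize()]).
#' @param bin one bin from [build_bins()].
#' @return A list of class \code{"scn_network"} with elements \code{r}
#'   (region x region correlation matrix, unit diagonal), \code{retained}
#'   (NULL until thresholded), \code{median_age}, \code{n} (scans in bin)
#'   and \code{diagnostics}.
#' @export
bin_correlation <- function(residual_table, bin) {
  rows <- match(bin$scan_id, residual_table$scan_id)
  if (anyNA(rows)) stop_invalid("bin refers to scan ids absent from the table")
  if (length(rows) < 3L) stop_invalid("bin must contain at least 3 participants")
  X <- thickness_matrix(residual_table)[rows, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  degenerate <- which(sds < 1e-12)
  r <- suppressWarnings(stats::cor(X))
  if (length(degenerate) > 0L) {
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  diag(r) <- 1
  structure(list(r = r, retained = NULL,
                 median_age = bin$median_age, n = length(rows),
                 diagnostics = list(zero_variance_regions = degenerate)),
            class = "scn_network")
}

#' Mean off-diagonal correlation of an unthresholded network
#'
#' @param network an \code{"scn_network"} (or bare correlation matrix).
#' @param mode \code{"positive"} (default): mean of strictly positive
#'   upper-triangle entries; \code{"all"}: mean of all upper-triangle
#'   entries.
#' @return Scalar mean correlation; 0 with a warning if no positive entries
#'   exist in \code{"positive"} mode.
#' @export
mean_correlation <- function(network, mode = c("positive", "all")) {
  mode <- match.arg(mode)
  r <- if (inherits(network, "scn_network")) network$r else network
  vals <- r[upper.tri(r)]
  if (mode == "all") return(mean(vals))
  pos <- vals[vals > 0]
  if (length(pos) == 0L) {
    warning("no positive off-diagonal correlations; returning 0", call. = FALSE)
    return(0)
  }
  mean(pos)
}

#' Bootstrap-threshold and binarize a bin's correlation network
#'
#' Resamples the bin's participants with replacement \code{B} times,
#' re-estimating the correlation matrix each time. For every region pair
#' the bootstrap p-value is \eqn{p = (\#\{b: r_b \le 0\} + 1)/(B + 1)}
#' (add-one convention, so p is never exactly zero); Benjamini-Hochberg
#' correction is applied across all pairs at level \code{alpha}, and edges
#' that survive with a positive point-estimate correlation are set to 1,
#' all others to 0. A bootstrap replicate in which a region is degenerate
#' (zero variance) contributes \eqn{r_b = 0} for its pairs, i.e. counts
#' against retention.
#'
#' @param residual_table a residualized scan table.
#' @param bin one bin from [build_bins()].
#' @param B number of bootstrap resamples (default 1000).
#' @param alpha FDR level (default 0.05).
#' @param seed integer seed for the resampling.
#' @return An \code{"scn_network"} whose \code{retained} element is the
#'   binary adjacency matrix; \code{diagnostics$negative_edge_fraction}
#'   records the fraction of BH-surviving edges whose point-estimate
#'   correlation was negative (removed by the positivity guard).
#' @export
bootstrap_threshold <- function(residual_table, bin, B = 1000L, alpha = 0.05,
                                seed = 1L) {
  if (B < 1L) stop_invalid("B must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  net <- bin_correlation(residual_table, bin)
  rows <- match(bin$scan_id, residual_table$scan_id)
  X <- thickness_matrix(residual_table)[rows, , drop = FALSE]
  n <- nrow(X)
  P <- ncol(X)
  ut <- upper.tri(net$r)
  set.seed(seed)
  nonpos <- matrix(0L, P, P)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rb <- suppressWarnings(stats::cor(X[idx, , drop = FALSE]))
    rb[is.na(rb)] <- 0                 # degenerate resample: treat as r = 0
    nonpos <- nonpos + (rb <= 0)
  }
  pvals <- (nonpos[ut] + 1) / (B + 1)
  adj <- stats::p.adjust(pvals, method = "BH")
  survive <- adj <= alpha
  neg_frac <- if (any(survive)) mean(net$r[ut][survive] < 0) else 0
  retained_ut <- survive & net$r[ut] > 0
  retained <- matrix(0L, P, P)
  retained[ut] <- as.integer(retained_ut)
  retained <- retained + t(retained)
  dimnames(retained) <- dimnames(net$r)
  net$retained <- retained
  net$diagnostics$negative_edge_fraction <- neg_frac
  net$diagnostics$B <- B
  net$diagnostics$alpha <- alpha
  net
}
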