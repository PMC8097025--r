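#' Global density of a binarized network
#'
#' Fraction of all possible region pairs that are connected.
#'
#' @param network an \code{"scn_network"} with a \code{retained} mask, or a
#'   binary symmetric adjacency matrix.
#' @return Proportion in [0, 1].
#' @export
global_density <- function(network) {
  A <- adjacency_of(network)
  P <- nrow(A)
  if (P < 2L) stop_invalid("network must have at least 2 nodes")
  sum(A[upper.tri(A)]) / choose(P, 2)
}

#' Node degree of a binarized network
#' @inheritParams global_density
#' @return Integer vector of connection counts per region.
#' @export
node_degree <- function(network) {
  A <- adjacency_of(network)
  rowSums(A)
}

#' Standardized degree (z-degree)
#'
#' Degree expressed in standard-deviation units relative to all regions of
#' the same network, using the sample (n-1) standard deviation. When all
#' degrees are equal the z-degrees are defined as all zero (no region can
#' stand out), with a warning.
#'
#' @inheritParams global_density
#' @return Numeric vector with mean 0 and (when degrees vary) SD 1.
#' @export
standardized_degree <- function(network) {
  deg <- node_degree(network)
  if (length(deg) < 2L) stop_invalid("network must have at least 2 nodes")
  s <- stats::sd(deg)
  if (s < 1e-12) {
    warning("all degrees equal; standardized degree set to 0", call. = FALSE)
    return(rep(0, length(deg)))
  }
  (deg - mean(deg)) / s
}

#' Identify hub regions across bins
#'
#' A region is a hub when its standardized degree exceeds \code{threshold}
#' (strictly) in at least \code{min_bins} bins of a window configuration.
#'
#' @param z_by_bin regions x bins matrix of standardized degrees.
#' @param threshold z-degree cutoff (default 1, i.e. one SD above the mean).
#' @param min_bins minimum number of bins above threshold (default 2).
#' @return A list with \code{hub} (logical per region), \code{n_bins_as_hub}
#'   (count per region), \code{threshold} and \code{min_bins}.
#' @export
identify_hubs <- function(z_by_bin, threshold = 1, min_bins = 2L) {
  z_by_bin <- as.matrix(z_by_bin)
  if (min_bins > ncol(z_by_bin)) {
    stop_invalid("min_bins (", min_bins, ") exceeds the number of bins (",
                 ncol(z_by_bin), ")")
  }
  n_as_hub <- rowSums(z_by_bin > threshold)
  list(hub = n_as_hub >= min_bins, n_bins_as_hub = n_as_hub,
       threshold = threshold, min_bins = as.integer(min_bins))
}

#' Intra- and inter-modular density
#'
#' Density of connections within each module (edges among its regions over
#' all possible such pairs) and between each unordered pair of modules
#' (edges between the two sets over the product of their sizes), optionally
#' normalized by (divided by) the network's global density.
#'
#' @inheritParams global_density
#' @param modules integer module label per region.
#' @param normalize divide by global density (default TRUE)?
#' @return A list with data frames \code{intra} (module, n_regions, raw,
#'   value) and \code{inter} (module_a, module_b, raw, value), plus
#'   \code{global_density}. Singleton modules yield NA intra density; when
#'   the global density is 0 normalized values are NA.
#' @export
modular_density <- function(network, modules, normalize = TRUE) {
  A <- adjacency_of(network)
  P <- nrow(A)
  if (length(modules) != P) stop_invalid("one module label per region required")
  gd <- global_density(A)
  labs <- sort(unique(modules))
  intra <- data.frame(module = labs, n_regions = NA_integer_,
                      raw = NA_real_)
  for (i in seq_along(labs)) {
    idx <- which(modules == labs[i])
    intra$n_regions[i] <- length(idx)
    if (length(idx) >= 2L) {
      sub <- A[idx, idx, drop = FALSE]
      intra$raw[i] <- sum(sub[upper.tri(sub)]) / choose(length(idx), 2)
    }
  }
  pairs <- utils::combn(labs, 2)
  inter <- data.frame(module_a = pairs[1, ], module_b = pairs[2, ],
                      raw = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    ia <- which(modules == pairs[1, k])
    ib <- which(modules == pairs[2, k])
    inter$raw[k] <- sum(A[ia, ib, drop = FALSE]) / (length(ia) * length(ib))
  }
  denom <- if (normalize) { if (gd > 0) gd else NA_real_ } else 1
  intra$value <- intra$raw / denom
  inter$value <- inter$raw / denom
  list(intra = intra, inter = inter, global_density = gd,
       normalized = normalize)
}

adjacency_of <- function(network) {
  A <- if (inherits(network, "scn_network")) {
    if (is.null(network$retained)) {
      stop_invalid("network has not been thresholded; no adjacency available")
    }
    network$retained
  } else {
    as.matrix(network)
  }
  if (nrow(A) != ncol(A)) stop_invalid("adjacency matrix must be square")
  A
}
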