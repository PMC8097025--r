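#' Enumerate sliding-window configurations
#'
#' Cartesian product of bin sizes and step fractions, ordered by
#' (bin_size, step_fraction). With the defaults this yields the nine
#' configurations \{70, 80, 90\} x \{20\%, 25\%, 30\%\}.
#'
#' @param bin_sizes integer vector of window sizes (scans per window).
#' @param step_fractions fractions of the bin size by which consecutive
#'   windows advance; the step in scans is the fraction times the bin size,
#'   rounded half-up, and must be at least 1.
#' @return Data frame with columns \code{config_id}, \code{bin_size},
#'   \code{step_fraction}, \code{step}.
#' @export
window_configs <- function(bin_sizes = c(70L, 80L, 90L),
                           step_fractions = c(0.20, 0.25, 0.30)) {
  if (length(bin_sizes) == 0L || length(step_fractions) == 0L) {
    stop_invalid("bin_sizes and step_fractions must be non-empty")
  }
  if (any(bin_sizes < 2L)) stop_invalid("bin sizes must be >= 2")
  if (any(step_fractions <= 0) || any(step_fractions >= 1)) {
    stop_invalid("step fractions must lie in (0, 1)")
  }
  grid <- expand.grid(step_fraction = sort(step_fractions),
                      bin_size = sort(bin_sizes))[, 2:1]
  grid$step <- pmax(1L, as.integer(round_half_up(grid$bin_size * grid$step_fraction)))
  grid$config_id <- sprintf("b%d_s%02.0f", grid$bin_size,
                            100 * grid$step_fraction)
  rownames(grid) <- NULL
  grid[, c("config_id", "bin_size", "step_fraction", "step")]
}

#' Build overlapping age bins from a scan table
#'
#' Scans are pooled and sorted by age (ties broken by scan id); windows of
#' \code{bin_size} consecutive scans are placed at offsets 0, step, 2*step,
#' ... while they fit, and when the last regular window does not reach the
#' oldest scan one terminal window anchored at the end of the pool is
#' appended. Each window is then reduced to one scan per participant by
#' [dedup_bin()], and the bin's median age is computed over retained scans.
#'
#' @param scan_table a scan table (see [generate_dataset()]); only
#'   \code{participant_id}, \code{scan_id} and \code{age} are used.
#' @param bin_size number of scans per window (pre-deduplication).
#' @param step_fraction fraction of \code{bin_size} by which windows slide;
#'   the step in scans is rounded half-up.
#' @return A list of class \code{"scn_bins"}: one element per bin, each a
#'   list with \code{index}, \code{scan_id}, \code{participant_id},
#'   \code{age} (retained scans, age order) and \code{median_age}.
#' @export
build_bins <- function(scan_table, bin_size, step_fraction) {
  if (bin_size < 2L) stop_invalid("bin_size must be >= 2")
  if (step_fraction <= 0 || step_fraction >= 1) {
    stop_invalid("step_fraction must lie in (0, 1)")
  }
  pool <- scan_table[order(scan_table$age, scan_table$scan_id),
                     intersect(c("participant_id", "scan_id", "age"),
                               names(scan_table))]
  M <- nrow(pool)
  if (M < bin_size) {
    stop_invalid("scan pool (", M, ") is smaller than bin_size (", bin_size, ")")
  }
  step <- max(1L, as.integer(round_half_up(bin_size * step_fraction)))
  offsets <- seq(0L, M - bin_size, by = step)
  if (offsets[length(offsets)] != M - bin_size) {
    offsets <- c(offsets, M - bin_size)   # terminal window anchored at the end
  }
  bins <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    window <- pool[offsets[i] + seq_len(bin_size), , drop = FALSE]
    bins[[i]] <- dedup_bin(window)
    bins[[i]]$index <- i
  }
  structure(bins, class = "scn_bins",
            bin_size = bin_size, step_fraction = step_fraction, step = step)
}

#' Reduce a window of scans to one scan per participant
#'
#' For each participant with more than one scan in the window, the scan
#' whose age is closest to the window's median age (computed over all
#' window scans, before deduplication) is kept; exact distance ties keep
#' the lexicographically smaller scan id. The bin's median age is then
#' recomputed over the retained scans.
#'
#' @param window data frame with columns \code{participant_id},
#'   \code{scan_id}, \code{age} (the scans falling in one window).
#' @return A list with \code{scan_id}, \code{participant_id}, \code{age}
#'   (in age order, ties by scan id) and \code{median_age}.
#' @export
dedup_bin <- function(window) {
  if (nrow(window) == 0L) stop_invalid("empty window")
  med <- stats::median(window$age)
  ord <- order(abs(window$age - med), window$scan_id)
  ranked <- window[ord, , drop = FALSE]
  keep <- ranked[!duplicated(ranked$participant_id), , drop = FALSE]
  keep <- keep[order(keep$age, keep$scan_id), , drop = FALSE]
  list(scan_id = keep$scan_id,
       participant_id = keep$participant_id,
       age = keep$age,
       median_age = stats::median(keep$age))
}

#' Median ages of a bin list
#' @param bins an \code{"scn_bins"} object.
#' @return Numeric vector of bin median ages.
#' @export
bin_median_ages <- function(bins) {
  vapply(bins, function(b) b$median_age, numeric(1))
}
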