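# Internal helpers shared across modules.

# Columns of a ScanTable that are not thickness values.
.meta_cols <- c("participant_id", "scan_id", "age", "sex", "cohort", "scanner")

#' Region (thickness) columns of a scan table
#'
#' @param scan_table data frame in scan-table layout.
#' @return Character vector of region column names, in table order.
#' @export
region_columns <- function(scan_table) {
  setdiff(names(scan_table), .meta_cols)
}

# Round half away from zero (R's round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

# Deterministic seed for a pipeline stage: root seed plus a polynomial hash
# of the stage tag, kept inside 32-bit integer range.
derive_seed <- function(root_seed, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(root_seed) + h) %% 2147483647)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Upper-triangle indices (i < j) of a P x P matrix, as a 2-column matrix.
upper_pairs <- function(p) {
  which(upper.tri(diag(p)), arr.ind = TRUE)
}

check_scan_table <- function(scan_table) {
  missing <- setdiff(.meta_cols, names(scan_table))
  if (length(missing) > 0L) {
    stop_invalid("scan table is missing required column(s): ",
                 paste(missing, collapse = ", "))
  }
  key <- paste(scan_table$participant_id, scan_table$scan_id)
  if (anyDuplicated(key)) {
    stop_invalid("duplicate (participant_id, scan_id) pairs in scan table")
  }
  regions <- region_columns(scan_table)
  if (length(regions) == 0L) stop_invalid("scan table has no region columns")
  for (rc in regions) {
    if (!is.numeric(scan_table[[rc]])) {
      stop_invalid("non-numeric thickness column: ", rc)
    }
    if (anyNA(scan_table[[rc]])) {
      stop_invalid("missing thickness values in column ", rc,
                   " (rows ", paste(which(is.na(scan_table[[rc]]))[1], collapse = ","), ")")
    }
  }
  invisible(scan_table)
}

# Thickness values as a numeric matrix (scans x regions).
thickness_matrix <- function(scan_table) {
  as.matrix(scan_table[, region_columns(scan_table), drop = FALSE])
}
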