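#' Read and validate a scan table from CSV
#'
#' Expects one row per scan with columns \code{participant_id},
#' \code{scan_id}, \code{age}, \code{sex}, \code{cohort}, \code{scanner}
#' and one numeric thickness column per region.
#'
#' @param path CSV path.
#' @param parcellation optional parcellation; when given, the region
#'   columns must match its region ids exactly.
#' @return Validated scan table data frame.
#' @export
read_scan_table <- function(path, parcellation = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_scan_table(tab)
  if (!is.null(parcellation)) {
    if (!identical(region_columns(tab), parcellation$region_ids)) {
      stop_invalid("scan table region columns do not match the parcellation (",
                   length(region_columns(tab)), " vs ",
                   length(parcellation$region_ids), " regions)")
    }
  }
  tab
}

#' Write a scan table to CSV
#' @param scan_table scan table.
#' @param path output CSV path.
#' @export
write_scan_table <- function(scan_table, path) {
  check_scan_table(scan_table)
  utils::write.csv(scan_table, path, row.names = FALSE)
  invisible(path)
}

#' Write a parcellation to a directory
#'
#' Writes \code{parcellation.json} (region ids, hemispheres, coordinates,
#' modules) plus one distance-matrix CSV per hemisphere.
#'
#' @param parcellation an \code{"scn_parcellation"}.
#' @param dir output directory (created if missing).
#' @export
write_parcellation <- function(parcellation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(region_ids = parcellation$region_ids,
               hemisphere = parcellation$hemisphere,
               coords = unname(apply(parcellation$coords, 1, c, simplify = FALSE)),
               modules = parcellation$modules,
               n_modules = parcellation$n_modules)
  jsonlite::write_json(meta, file.path(dir, "parcellation.json"),
                       auto_unbox = TRUE, digits = NA)
  for (h in names(parcellation$distance)) {
    utils::write.csv(parcellation$distance[[h]],
                     file.path(dir, paste0("distance_", h, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a parcellation written by [write_parcellation()]
#' @param dir directory containing \code{parcellation.json}.
#' @return An \code{"scn_parcellation"}.
#' @export
read_parcellation <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "parcellation.json"),
                              simplifyVector = TRUE)
  distance <- list()
  for (h in unique(meta$hemisphere)) {
    distance[[h]] <- unname(as.matrix(utils::read.csv(
      file.path(dir, paste0("distance_", h, ".csv")))))
  }
  coords <- meta$coords
  if (!is.matrix(coords)) coords <- do.call(rbind, coords)
  structure(list(region_ids = meta$region_ids,
                 hemisphere = meta$hemisphere,
                 coords = unname(coords),
                 modules = as.integer(meta$modules),
                 n_modules = as.integer(meta$n_modules),
                 distance = distance),
            class = "scn_parcellation")
}
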