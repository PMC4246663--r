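## Deterministic serialization of result artifacts. All numeric output is
## written with 12 significant digits and keyed by reaction id, never by
## column index, so re-running a configuration gives byte-identical files
## and model reordering cannot corrupt comparisons.

fmt12 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

#' Write a scan's flux table as TSV
#'
#' Rows are reactions, columns the photon-flux grid of one r slice;
#' infeasible cells are NA.
#'
#' @param scan a `scan_result`.
#' @param path output file.
#' @param r slice to write.
#' @export
write_flux_table <- function(scan, path, r = scan$r_values[1]) {
  tab <- flux_table(scan, r)
  out <- data.frame(reaction = rownames(tab),
                    apply(tab, 2, fmt12),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region partition as JSON
#' @param regions a `region_partition`.
#' @param path output file.
#' @export
write_regions_json <- function(regions, path) {
  jsonlite::write_json(
    list(r = regions$r,
         breakpoints = regions$breakpoints,
         labels = regions$labels,
         change_sizes = regions$change_sizes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a relative-difference grid as TSV
#'
#' Rows are photon fluxes, columns r values; undefined cells are NA.
#' @param grid a `relative_difference_grid`.
#' @param path output file.
#' @export
write_relative_difference <- function(grid, path) {
  out <- data.frame(photon_flux = fmt12(grid$photon_values),
                    apply(grid$D, 2, fmt12),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("r=", fmt12(grid$r_values))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
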