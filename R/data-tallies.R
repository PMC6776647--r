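#' Per-site cell tallies from a published ten-hotspot whale survey
#'
#' Grid-cell tallies from a global whale-watching hotspot survey of ten
#' coastal sites: per site, the number of 71 x 71 m cells in which human
#' photo-interpretation found whales, the number flagged by the survey's
#' presence model, and the total number of evaluated cells. One site's
#' photo-interpretation is NA (imagery too coarse to annotate with
#' confidence). Useful as input to [aggregateSites()]: the columns sum to
#' 68 photo-interpreted whale cells and 13,348 evaluated cells.
#'
#' @return data.frame: site, whale_cells_photo, whale_cells_model,
#'   total_cells
#' @examples
#' tail(aggregateSites(hotspotCellTallies()), 1)
#' @export
hotspotCellTallies <- function() {
  utils::read.csv(system.file("extdata", "hotspot_cell_tallies.csv",
                              package = "whalescan"),
                  stringsAsFactors = FALSE)
}
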