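#' Classify one grid-cell patch into whale / ship / water + submerged rocks
#'
#' @param classifier a trained [PresenceClassifier-class], or any function
#'   taking a patch and returning a named probability vector (the contract
#'   is backbone-agnostic)
#' @param patch RGB array (height x width x 3); resized internally to the
#'   classifier's input size
#' @return named numeric vector (whale, ship, water_rock) summing to 1
#' @export
setGeneric("classifyCell", function(classifier, patch)
  standardGeneric("classifyCell"))

#' Detect whales in one patch
#'
#' @param detector a trained [WhaleDetector-class], or any function taking
#'   a patch and returning a scored box data.frame
#' @param patch RGB array
#' @param score_threshold minimum score for a detection to be kept
#' @param nms_iou IoU above which overlapping detections are suppressed
#' @return data.frame of detections: x_min, y_min, x_max, y_max, class
#'   ("whale"), score; all scores >= `score_threshold`, no two boxes with
#'   IoU > `nms_iou`
#' @export
setGeneric("detectWhales",
  function(detector, patch, score_threshold = 0.5, nms_iou = 0.5)
    standardGeneric("detectWhales"))

#' Aggregate per-site survey results into a multi-site summary
#'
#' @param reports a list of [SurveyReport-class] objects sharing a config
#'   hash, or a per-site data.frame of cell tallies
#' @param ... further arguments (`force = TRUE` to aggregate reports with
#'   mixed config hashes)
#' @return for reports: a list with per-site rows and totals; for a tally
#'   data.frame: the same frame with a "Total" row appended
#' @export
setGeneric("aggregateSites", function(reports, ...)
  standardGeneric("aggregateSites"))
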