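## Central S4 classes. Images are plain numeric arrays (height x width x 3,
## values in [0, 1]); grid cells, boxes and per-cell results are data.frames
## so they compose with ordinary R tooling.

WHALE_CLASSES <- c("whale", "ship", "water_rock")
WHALE_POSTURES <- c("logging", "breaching", "spyhopping", "blowing",
                    "peduncle", "submerged")

#' Scene: one survey raster with its pixel size
#'
#' The survey unit: an RGB raster together with the ground sampling
#' distance in metres per pixel and an optional planar origin for the
#' top-left pixel corner.
#'
#' @slot image numeric array, height x width x 3, values in `[0, 1]`
#' @slot pixelSize metres per pixel (> 0)
#' @slot origin numeric(2) planar coordinate of the top-left corner, or
#'   numeric(0) when the scene is not georeferenced
#' @slot siteId free-text site identifier
#' @exportClass Scene
setClass("Scene",
  representation(image = "array", pixelSize = "numeric",
                 origin = "numeric", siteId = "character"),
  validity = function(object) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L)
      return("image must be a height x width x 3 array")
    if (d[1] < 1L || d[2] < 1L) return("image must be non-empty")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    if (!length(object@origin) %in% c(0L, 2L))
      return("origin must be numeric(0) or numeric(2)")
    TRUE
  })

#' Construct a Scene
#'
#' @param image height x width x 3 numeric array in `[0, 1]`
#' @param pixelSize metres per pixel, > 0
#' @param origin optional numeric(2) planar coordinate of the top-left corner
#' @param siteId site identifier
#' @return a [Scene-class] object
#' @examples
#' sc <- Scene(array(0.2, c(10, 12, 3)), pixelSize = 1)
#' dim(sceneImage(sc))
#' @export
Scene <- function(image, pixelSize, origin = numeric(0), siteId = "scene") {
  assertImage(image, "Scene image")
  methods::new("Scene", image = image, pixelSize = as.numeric(pixelSize),
               origin = as.numeric(origin), siteId = as.character(siteId))
}

#' SceneAnnotation: ground-truth boxes in scene coordinates
#'
#' Boxes use half-open pixel coordinates with origin at the top-left.
#' Whale boxes may carry a posture tag; ships may be annotated too.
#'
#' @slot sceneRef identifier of the annotated scene
#' @slot boxes data.frame with columns x_min, y_min, x_max, y_max, class
#'   (whale/ship/water_rock) and optional posture
#' @exportClass SceneAnnotation
setClass("SceneAnnotation",
  representation(sceneRef = "character", boxes = "data.frame"),
  validity = function(object) {
    b <- object@boxes
    need <- c("x_min", "y_min", "x_max", "y_max", "class")
    if (!all(need %in% names(b)))
      return(paste("boxes must have columns", paste(need, collapse = ", ")))
    if (nrow(b) && any(b$x_max <= b$x_min | b$y_max <= b$y_min))
      return("all boxes must have positive extent")
    if (nrow(b) && !all(b$class %in% WHALE_CLASSES))
      return("box classes must be whale, ship or water_rock")
    if ("posture" %in% names(b)) {
      p <- b$posture[!is.na(b$posture) & b$posture != ""]
      if (!all(p %in% WHALE_POSTURES)) return("unknown posture tag")
    }
    TRUE
  })

#' Construct a SceneAnnotation
#' @param boxes data.frame of ground-truth boxes (scene pixel coordinates)
#' @param sceneRef scene/site identifier
#' @return a [SceneAnnotation-class] object
#' @export
SceneAnnotation <- function(boxes, sceneRef = "scene") {
  if (!"posture" %in% names(boxes) && nrow(boxes))
    boxes$posture <- NA_character_
  methods::new("SceneAnnotation", sceneRef = as.character(sceneRef),
               boxes = as.data.frame(boxes))
}

#' PresenceClassifier: stage-1 three-class cell classifier
#'
#' A fixed seeded convolutional filter bank (the backbone) feeding a
#' trainable fully connected stack; see [trainPresenceClassifier()].
#'
#' @slot backbone list with the filter bank and pooling geometry
#' @slot head list of fully connected parameter groups
#' @slot classes class labels in output order
#' @slot inputSize side length (pixels) patches are resized to
#' @slot config the [trainingConfig()] used
#' @slot log per-epoch training log (epoch, lr, loss, val_accuracy)
#' @exportClass PresenceClassifier
setClass("PresenceClassifier",
  representation(backbone = "list", head = "list", classes = "character",
                 inputSize = "integer", config = "list", log = "data.frame"))

#' WhaleDetector: stage-2 proposal + verification detector
#'
#' Region proposals from a local-contrast anomaly map are scored by a
#' small CNN verifier (whale vs background); see [trainDetector()].
#'
#' @slot proposal list of proposal-stage parameters
#' @slot backbone verifier filter bank
#' @slot head verifier fully connected parameter groups
#' @slot inputSize verifier input side length in pixels
#' @slot config the [trainingConfig()] used
#' @slot log per-epoch training log
#' @exportClass WhaleDetector
setClass("WhaleDetector",
  representation(proposal = "list", backbone = "list", head = "list",
                 inputSize = "integer", config = "list", log = "data.frame"))

#' SurveyReport: per-cell and aggregate results of one survey run
#'
#' @slot siteId surveyed site identifier
#' @slot mode "cascade" or "baseline"
#' @slot cells per-cell results: grid geometry, stage-1 probabilities and
#'   predicted class, pass flag, whale count
#' @slot detections merged whale detections in scene pixel coordinates
#' @slot totalCells number of evaluated cells
#' @slot cellsPassed cells forwarded to the detector
#' @slot detectorCalls number of detector invocations
#' @slot totalWhaleCount whales counted after cross-cell merging
#' @slot timings named numeric, seconds per stage
#' @slot provenance list: config hash, seed, model identifiers
#' @exportClass SurveyReport
setClass("SurveyReport",
  representation(siteId = "character", mode = "character",
                 cells = "data.frame", detections = "data.frame",
                 totalCells = "integer", cellsPassed = "integer",
                 detectorCalls = "integer", totalWhaleCount = "integer",
                 timings = "numeric", provenance = "list"),
  validity = function(object) {
    if (!object@mode %in% c("cascade", "baseline"))
      return("mode must be cascade or baseline")
    if (object@cellsPassed > object@totalCells)
      return("cellsPassed cannot exceed totalCells")
    TRUE
  })

## ---- accessors and show methods --------------------------------------

#' @describeIn Scene raster accessor
#' @param x,object a Scene
#' @export
sceneImage <- function(x) x@image

#' @describeIn Scene metres per pixel
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn Scene site identifier
#' @export
siteId <- function(x) x@siteId

#' @describeIn Scene scene extent: height/width in pixels and metres
#' @export
sceneDim <- function(x) {
  d <- dim(x@image)
  c(height_px = d[1], width_px = d[2],
    height_m = d[1] * x@pixelSize, width_m = d[2] * x@pixelSize)
}

#' @describeIn SceneAnnotation ground-truth boxes
#' @param x a SceneAnnotation
#' @export
annotationBoxes <- function(x) x@boxes

#' @describeIn SurveyReport per-cell results
#' @param x a SurveyReport
#' @export
reportCells <- function(x) x@cells

#' @describeIn SurveyReport merged scene-coordinate detections
#' @export
reportDetections <- function(x) x@detections

#' @describeIn SurveyReport total whales counted
#' @export
totalWhaleCount <- function(x) x@totalWhaleCount

setMethod("show", "Scene", function(object) {
  d <- dim(object@image)
  cat(sprintf("Scene '%s': %d x %d px at %.3g m/px (%.0f x %.0f m)%s\n",
              object@siteId, d[2], d[1], object@pixelSize,
              d[2] * object@pixelSize, d[1] * object@pixelSize,
              if (length(object@origin)) " [georeferenced]" else ""))
})

setMethod("show", "SceneAnnotation", function(object) {
  tab <- table(factor(object@boxes$class, levels = WHALE_CLASSES))
  cat(sprintf("SceneAnnotation '%s': %d boxes (%s)\n", object@sceneRef,
              nrow(object@boxes),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
})

setMethod("show", "PresenceClassifier", function(object) {
  cat(sprintf(
    "PresenceClassifier: %d-px input, classes [%s], %d epochs trained\n",
    object@inputSize, paste(object@classes, collapse = ", "),
    nrow(object@log)))
})

setMethod("show", "WhaleDetector", function(object) {
  cat(sprintf(
    "WhaleDetector: contrast-proposal + %d-px CNN verifier, %d epochs trained\n",
    object@inputSize, nrow(object@log)))
})

setMethod("show", "SurveyReport", function(object) {
  sid <- object@siteId
  parts <- strsplit(sid, "+", fixed = TRUE)[[1]]
  if (length(parts) > 3L)
    sid <- paste0(parts[1], " (+", length(parts) - 1L, " more scenes)")
  cat(sprintf(
    "SurveyReport '%s' (%s): %d cells, %d passed, %d detector calls, %d whales\n",
    sid, object@mode, object@totalCells, object@cellsPassed,
    object@detectorCalls, object@totalWhaleCount))
})
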