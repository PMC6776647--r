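## Two-step survey orchestration: tile -> classify every cell -> detect in
## passed cells -> merge detections across cell borders -> count. The
## baseline mode runs the detector on every cell with no stage-1 filter.

#' Cascade configuration
#'
#' @param cell_size_m grid-cell side in metres (default 71: twice a blue
#'   whale's length)
#' @param stride_m stride between cells (default 71: non-overlapping grid)
#' @param pad_policy edge-cell padding, see [tileScene()]
#' @param presence_rule how stage-1 passes a cell: `"argmax"` (predicted
#'   class is whale) or `"threshold"` (`p_whale >= presence_threshold`)
#' @param presence_threshold minimum whale probability under the
#'   `"threshold"` rule
#' @param score_threshold,nms_iou stage-2 detector thresholds
#' @param cross_cell_merge_iou IoU above which detections of the same whale
#'   in adjacent cells are merged (global NMS in scene coordinates)
#' @param seed seed recorded in the report provenance
#' @return validated list of class "cascadeConfig"
#' @export
cascadeConfig <- function(cell_size_m = 71, stride_m = 71,
                          pad_policy = "pad-reflect",
                          presence_rule = c("argmax", "threshold"),
                          presence_threshold = 0.5,
                          score_threshold = 0.5, nms_iou = 0.5,
                          cross_cell_merge_iou = 0.5, seed = 1L) {
  presence_rule <- match.arg(presence_rule)
  if (cell_size_m <= 0 || stride_m <= 0)
    stop("cell and stride sizes must be positive", call. = FALSE)
  for (v in c(presence_threshold, score_threshold, nms_iou,
              cross_cell_merge_iou))
    if (v < 0 || v > 1) stop("thresholds must lie in [0, 1]", call. = FALSE)
  structure(list(cell_size_m = cell_size_m, stride_m = stride_m,
                 pad_policy = pad_policy, presence_rule = presence_rule,
                 presence_threshold = presence_threshold,
                 score_threshold = score_threshold, nms_iou = nms_iou,
                 cross_cell_merge_iou = cross_cell_merge_iou,
                 seed = as.integer(seed)),
            class = "cascadeConfig")
}

.modelId <- function(model) {
  if (methods::is(model, "PresenceClassifier") ||
      methods::is(model, "WhaleDetector")) configHash(model@head)
  else if (is.function(model)) "plugin-function"
  else NA_character_
}

## shared survey loop; classifier = NULL disables stage-1 (baseline mode)
.runSurvey <- function(scenes, classifier, detector, config, mode) {
  stopifnot(inherits(config, "cascadeConfig"))
  if (methods::is(scenes, "Scene")) scenes <- list(scenes)
  cellRows <- list(); detRows <- list()
  t_stage1 <- 0; t_stage2 <- 0
  detector_calls <- 0L
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    stopifnot(methods::is(sc, "Scene"))
    cells <- tileScene(sc, config$cell_size_m, config$stride_m,
                       config$pad_policy)
    n <- nrow(cells)
    if (n == 0L) next
    probs <- matrix(NA_real_, n, 3L,
                    dimnames = list(NULL, WHALE_CLASSES))
    passed <- rep(TRUE, n)
    pred <- rep(NA_character_, n)
    imgs <- lapply(seq_len(n), function(i)
      extractCellImage(sc, cells[i, , drop = FALSE],
                       pad_policy = config$pad_policy))
    if (!is.null(classifier)) {
      t0 <- proc.time()[["elapsed"]]
      for (i in seq_len(n)) {
        p <- classifyCell(classifier, imgs[[i]])
        probs[i, ] <- p[WHALE_CLASSES]
        pred[i] <- WHALE_CLASSES[which.max(probs[i, ])]
        passed[i] <- if (config$presence_rule == "argmax")
          pred[i] == "whale"
        else probs[i, "whale"] >= config$presence_threshold
      }
      t_stage1 <- t_stage1 + proc.time()[["elapsed"]] - t0
    }
    t0 <- proc.time()[["elapsed"]]
    scene_dets <- emptyBoxes(score = TRUE)
    scene_dets$cell_index <- integer(0)
    for (i in which(passed)) {
      d <- detectWhales(detector, imgs[[i]],
                        score_threshold = config$score_threshold,
                        nms_iou = config$nms_iou)
      detector_calls <- detector_calls + 1L
      if (nrow(d)) {
        d$x_min <- d$x_min + cells$x0[i]; d$x_max <- d$x_max + cells$x0[i]
        d$y_min <- d$y_min + cells$y0[i]; d$y_max <- d$y_max + cells$y0[i]
        d$cell_index <- i
        d <- d[, c("x_min", "y_min", "x_max", "y_max", "class", "score",
                   "cell_index")]
        scene_dets <- rbind(scene_dets, d)
      }
    }
    ## merge duplicates of the same whale seen from adjacent cells:
    ## global NMS in scene coordinates; each kept box retains the cell it
    ## was detected in, so no whale is counted twice
    if (nrow(scene_dets))
      scene_dets <- nmsBoxes(scene_dets, config$cross_cell_merge_iou)
    t_stage2 <- t_stage2 + proc.time()[["elapsed"]] - t0
    counts <- integer(n)
    if (nrow(scene_dets)) {
      tab <- table(scene_dets$cell_index)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
    cells$scene <- siteId(sc)
    cells$p_whale <- probs[, "whale"]
    cells$p_ship <- probs[, "ship"]
    cells$p_water_rock <- probs[, "water_rock"]
    cells$pred_class <- pred
    cells$passed <- passed
    cells$whale_count <- counts
    cellRows[[length(cellRows) + 1L]] <- cells
    if (nrow(scene_dets)) {
      scene_dets$scene <- siteId(sc)
      detRows[[length(detRows) + 1L]] <- scene_dets
    }
  }
  allCells <- if (length(cellRows)) do.call(rbind, cellRows) else
    data.frame()
  allDets <- if (length(detRows)) do.call(rbind, detRows) else {
    d <- emptyBoxes(score = TRUE); d$cell_index <- integer(0)
    d$scene <- character(0); d
  }
  rownames(allCells) <- NULL; rownames(allDets) <- NULL
  sites <- unique(vapply(scenes, siteId, character(1)))
  methods::new("SurveyReport",
    siteId = paste(sites, collapse = "+"),
    mode = mode,
    cells = allCells, detections = allDets,
    totalCells = nrow(allCells),
    cellsPassed = as.integer(sum(allCells$passed %||% logical(0))),
    detectorCalls = detector_calls,
    totalWhaleCount = nrow(allDets),
    timings = c(stage1 = t_stage1, stage2 = t_stage2),
    provenance = list(config_hash = configHash(config), seed = config$seed,
                      classifier_id = .modelId(classifier),
                      detector_id = .modelId(detector)))
}

#' Run the two-step cascade survey
#'
#' Tiles each scene, classifies every grid cell with the stage-1 presence
#' model, runs the stage-2 detector only on cells that pass, merges
#' detections of the same whale across adjacent cells (global NMS in scene
#' coordinates) and counts. The detector invocation count is recorded and
#' never exceeds the number of cells — the mechanism that makes the
#' cascade an order of magnitude cheaper than detection everywhere.
#'
#' @param scenes a [Scene-class] or list of scenes
#' @param classifier stage-1 model (see [classifyCell()])
#' @param detector stage-2 model (see [detectWhales()])
#' @param config a [cascadeConfig()]
#' @return a [SurveyReport-class]
#' @export
runCascade <- function(scenes, classifier, detector,
                       config = cascadeConfig()) {
  if (is.null(classifier))
    stop("cascade mode requires a classifier; use runBaseline otherwise",
         call. = FALSE)
  .runSurvey(scenes, classifier, detector, config, mode = "cascade")
}

#' Run the detector-alone baseline survey
#'
#' Identical to [runCascade()] with the stage-1 filter disabled: the
#' detector analyses every grid cell.
#'
#' @inheritParams runCascade
#' @return a [SurveyReport-class] with mode "baseline"
#' @export
runBaseline <- function(scenes, detector, config = cascadeConfig()) {
  .runSurvey(scenes, classifier = NULL, detector, config, mode = "baseline")
}

#' @describeIn aggregateSites combine per-site survey reports (refuses
#'   mixed config hashes unless `force = TRUE`)
#' @export
setMethod("aggregateSites", "list", function(reports, force = FALSE) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, methods::is, logical(1), "SurveyReport")))
  hashes <- vapply(reports, function(r)
    r@provenance$config_hash %||% NA_character_, character(1))
  if (length(unique(hashes)) > 1L && !force)
    stop("reports have mixed config hashes; pass force = TRUE to aggregate",
         call. = FALSE)
  per_site <- do.call(rbind, lapply(reports, function(r)
    data.frame(site = r@siteId, mode = r@mode,
               total_cells = r@totalCells,
               cells_passed = r@cellsPassed,
               cells_with_whales_predicted =
                 sum(r@cells$whale_count > 0),
               whale_count = r@totalWhaleCount,
               detector_calls = r@detectorCalls)))
  totals <- data.frame(site = "Total", mode = per_site$mode[1],
                       t(colSums(per_site[, -(1:2), drop = FALSE])))
  list(per_site = per_site, totals = totals)
})

#' @describeIn aggregateSites sum the numeric columns of a per-site tally
#'   table (e.g. photo-interpreted and model whale-cell counts per site)
#'   and append a "Total" row; NA entries (uncertain sites) are ignored
#' @export
setMethod("aggregateSites", "data.frame", function(reports) {
  df <- reports
  num <- vapply(df, is.numeric, logical(1))
  tot <- lapply(names(df), function(nm)
    if (num[[nm]]) sum(df[[nm]], na.rm = TRUE) else "Total")
  names(tot) <- names(df)
  rbind(df, as.data.frame(tot, stringsAsFactors = FALSE))
})
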