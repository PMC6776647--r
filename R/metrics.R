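## Evaluation: confusion matrices, precision/recall/F1, IoU-based
## detection matching, posture-stratified detectability, k-fold CV and
## cascade-vs-baseline comparison.
##
## Percentages are reported truncated (not rounded) at two decimals, the
## convention used in published survey tables (14/68 prints as 20.58).

#' Precision, sensitivity and F1 from detection counts
#'
#' positive predictive value = tp / (tp + fp); sensitivity = tp /
#' (tp + fn); F1 = harmonic mean of the two. Degenerate 0/0 ratios are
#' defined as 0 so empty classes yield zero metrics rather than NaN.
#'
#' @param tp,fp,fn non-negative counts
#' @return list of class "classMetrics": the counts, `precision`,
#'   `recall`, `f1` as fractions in `[0, 1]`, and `precision_pct`,
#'   `recall_pct`, `f1_pct` truncated at two decimals
#' @examples
#' m <- precisionRecallF1(54, 13, 14)
#' c(m$precision_pct, m$recall_pct, m$f1_pct)
#' @export
precisionRecallF1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = prec, recall = rec, f1 = f1,
                 precision_pct = truncPct(prec), recall_pct = truncPct(rec),
                 f1_pct = truncPct(f1)),
            class = "classMetrics")
}

#' Three-class confusion matrix
#'
#' Rows are the photo-interpreted (true) class, columns the predicted
#' class, in the fixed order whale, ship, water_rock.
#'
#' @param true,pred character vectors of class labels
#' @return 3 x 3 integer matrix
#' @export
confusionMatrix3 <- function(true, pred) {
  stopifnot(length(true) == length(pred))
  m <- table(factor(true, levels = WHALE_CLASSES),
             factor(pred, levels = WHALE_CLASSES))
  matrix(as.integer(m), 3L, 3L, dimnames = list(true = WHALE_CLASSES,
                                                pred = WHALE_CLASSES))
}

#' Misclassification rates for one true class
#'
#' Each rate is the off-diagonal count divided by the row total, as a
#' percentage truncated at two decimals; the total is the truncation of
#' the summed off-diagonal fraction.
#'
#' @param confusion 3 x 3 confusion matrix from [confusionMatrix3()]
#' @param true_class the row to analyse
#' @return list: `rates` (named percentage per wrong class), `total`
#' @examples
#' cm <- matrix(c(54, 9, 4, 1, 391, 0, 13, 0, 396), 3, 3,
#'              dimnames = list(c("whale", "ship", "water_rock"),
#'                              c("whale", "ship", "water_rock")))
#' misclassificationRates(cm, "whale")  # 1.47% ship, 19.11% water, 20.58%
#' @export
misclassificationRates <- function(confusion, true_class) {
  stopifnot(true_class %in% rownames(confusion))
  row <- confusion[true_class, ]
  n <- sum(row)
  if (n == 0) stop("undefined rate: empty row for ", true_class,
                   call. = FALSE)
  wrong <- setdiff(colnames(confusion), true_class)
  rates <- vapply(wrong, function(cl) truncPct(row[[cl]] / n), numeric(1))
  list(rates = rates, total = truncPct(sum(row[wrong]) / n))
}

#' Match predicted detections to ground-truth boxes by IoU
#'
#' Greedy matching (the default, standard detection practice): predictions
#' are visited in descending score order and each takes the highest-IoU
#' not-yet-matched ground-truth box with IoU at or above the threshold.
#' `method = "optimal"` instead maximises the number of matched pairs
#' (maximum bipartite matching over admissible pairs).
#'
#' @param predictions data.frame of scored boxes (a score column is
#'   optional; row order is used when absent)
#' @param ground_truth data.frame of ground-truth boxes
#' @param iou_threshold matching threshold in (0, 1]
#' @param method "greedy" or "optimal"
#' @return list of class "matchResult": `pairs` (pred, gt, iou),
#'   `fp` (unmatched prediction indices), `fn` (unmatched ground-truth
#'   indices), and the `tp`/`fp_count`/`fn_count` tallies
#' @export
matchDetections <- function(predictions, ground_truth, iou_threshold = 0.5,
                            method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  for (b in list(predictions, ground_truth))
    if (nrow(b) && any(b$x_max <= b$x_min | b$y_max <= b$y_min))
      stop("malformed boxes", call. = FALSE)
  np <- nrow(predictions); ng <- nrow(ground_truth)
  iou <- boxIoUMatrix(predictions, ground_truth)
  pairs <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  if (np && ng) {
    if (method == "greedy") {
      ord <- if ("score" %in% names(predictions))
        order(-predictions$score) else seq_len(np)
      taken <- logical(ng)
      for (i in ord) {
        cand <- which(!taken & iou[i, ] >= iou_threshold)
        if (!length(cand)) next
        j <- cand[which.max(iou[i, cand])]
        taken[j] <- TRUE
        pairs <- rbind(pairs, data.frame(pred = i, gt = j, iou = iou[i, j]))
      }
    } else {
      ## maximum bipartite matching via augmenting paths
      adj <- lapply(seq_len(np), function(i)
        which(iou[i, ] >= iou_threshold))
      matchG <- rep(NA_integer_, ng)
      seen <- logical(ng)
      tryAugment <- function(i) {
        for (j in adj[[i]]) {
          if (seen[j]) next
          seen[j] <<- TRUE
          if (is.na(matchG[j]) || tryAugment(matchG[j])) {
            matchG[j] <<- i
            return(TRUE)
          }
        }
        FALSE
      }
      for (i in seq_len(np)) {
        seen[] <- FALSE
        tryAugment(i)
      }
      for (j in which(!is.na(matchG)))
        pairs <- rbind(pairs, data.frame(pred = matchG[j], gt = j,
                                         iou = iou[matchG[j], j]))
    }
  }
  fp <- setdiff(seq_len(np), pairs$pred)
  fn <- setdiff(seq_len(ng), pairs$gt)
  structure(list(pairs = pairs, fp = fp, fn = fn,
                 tp = nrow(pairs), fp_count = length(fp),
                 fn_count = length(fn)),
            class = "matchResult")
}

#' Posture-stratified detectability
#'
#' Tallies true positives and false negatives per whale posture and sorts
#' by detectability. Whales without a posture tag are excluded with a
#' warning and listed in the `missing` attribute.
#'
#' @param whales data.frame with columns `posture` and `detected` (logical)
#' @return data.frame: posture, tp, fn, n, detectability_pct (truncated),
#'   sorted by decreasing detectability
#' @export
postureDetectability <- function(whales) {
  stopifnot(all(c("posture", "detected") %in% names(whales)))
  miss <- is.na(whales$posture) | whales$posture == ""
  if (any(miss))
    warning(sum(miss), " whale(s) without posture tag excluded",
            call. = FALSE)
  w <- whales[!miss, , drop = FALSE]
  out <- do.call(rbind, lapply(split(w, w$posture), function(d)
    data.frame(posture = d$posture[1], tp = sum(d$detected),
               fn = sum(!d$detected), n = nrow(d),
               detectability_pct = truncPct(mean(d$detected)))))
  out <- out[order(-out$detectability_pct, out$posture), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- which(miss)
  out
}

#' Stratified fold assignment for k-fold cross-validation
#'
#' Folds are stratified by class, pairwise disjoint and exhaustive, and
#' deterministic given the seed. Classes with fewer members than folds
#' trigger a fall back to non-stratified assignment with a warning.
#'
#' @param labels class label per observation
#' @param k number of folds (>= 2)
#' @param seed RNG seed
#' @return integer vector of fold ids in 1..k
#' @export
kfoldFolds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("dataset smaller than k", call. = FALSE)
  folds <- integer(n)
  tab <- table(labels)
  withSeed(seed, {
    if (any(tab < k)) {
      warning("class with fewer than k members; falling back to ",
              "non-stratified folds", call. = FALSE)
      folds <- sample(rep_len(seq_len(k), n))
    } else {
      for (cl in names(tab)) {
        idx <- which(labels == cl)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
  })
  folds
}

#' k-fold cross-validated evaluation of a classification pipeline
#'
#' Splits the dataset into stratified folds, trains a fresh pipeline on
#' each training portion and evaluates macro-F1 on the held-out fold.
#'
#' @param dataset list with `patches` and `labels` (see
#'   [generateClassificationDataset()])
#' @param k number of folds
#' @param pipeline_factory function(train_dataset) returning a predict
#'   function: `function(patches) -> character labels`
#' @param seed RNG seed controlling fold assignment
#' @return list: `per_fold` (data.frame fold, macro_f1), `mean_f1`,
#'   `sd_f1`, `folds`
#' @export
kfoldEvaluate <- function(dataset, k, pipeline_factory, seed = 1L) {
  labels <- as.character(dataset$labels)
  folds <- kfoldFolds(labels, k, seed)
  per <- data.frame(fold = integer(0), macro_f1 = numeric(0))
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    train <- dataset
    train$patches <- dataset$patches[tr]
    train$labels <- labels[tr]
    train$split <- NULL
    predictFun <- pipeline_factory(train)
    pred <- predictFun(dataset$patches[te])
    f1s <- vapply(unique(labels), function(cl) {
      tp <- sum(pred == cl & labels[te] == cl)
      fp <- sum(pred == cl & labels[te] != cl)
      fn <- sum(pred != cl & labels[te] == cl)
      precisionRecallF1(tp, fp, fn)$f1
    }, numeric(1))
    per <- rbind(per, data.frame(fold = f, macro_f1 = mean(f1s)))
  }
  list(per_fold = per, mean_f1 = mean(per$macro_f1),
       sd_f1 = stats::sd(per$macro_f1), folds = folds)
}

#' Evaluate a survey report against ground truth
#'
#' End-to-end whale-level evaluation: the report's merged detections are
#' matched to ground-truth whale boxes per scene by IoU, giving counting
#' TP/FP/FN and precision/recall/F1. When stage-1 predictions are present
#' the cell-level confusion matrix against the annotated cell labels is
#' computed as well. Matched/missed ground-truth whales keep their posture
#' tags for [postureDetectability()].
#'
#' @param report a [SurveyReport-class]
#' @param annotations named list of [SceneAnnotation-class] keyed by scene
#'   id (as in the report's cells)
#' @param iou_threshold detection matching threshold
#' @return list of class "surveyEval": counts, `whale_metrics`
#'   (classMetrics), `overall_f1_pct`, `whales` (per-GT-whale data.frame
#'   with posture and detected flag), `cell_confusion` (or NULL),
#'   `cell_metrics` (stage-1 whale-class metrics, or NULL), `gt_hash`,
#'   `mode`
#' @export
evaluateReport <- function(report, annotations, iou_threshold = 0.5) {
  stopifnot(methods::is(report, "SurveyReport"))
  tp <- 0L; fp <- 0L; fn <- 0L
  whales <- data.frame(scene = character(0), posture = character(0),
                       detected = logical(0))
  cellsByScene <- split(report@cells, report@cells$scene)
  for (scn in names(annotations)) {
    ann <- annotations[[scn]]
    gt <- annotationBoxes(ann)
    gt <- gt[gt$class == "whale", , drop = FALSE]
    det <- report@detections
    det <- det[det$scene == scn, , drop = FALSE]
    mr <- matchDetections(det, gt, iou_threshold)
    tp <- tp + mr$tp; fp <- fp + mr$fp_count; fn <- fn + mr$fn_count
    if (nrow(gt))
      whales <- rbind(whales, data.frame(
        scene = scn,
        posture = if ("posture" %in% names(gt)) gt$posture
                  else NA_character_,
        detected = seq_len(nrow(gt)) %in% mr$pairs$gt))
  }
  wm <- precisionRecallF1(tp, fp, fn)
  ## stage-1 cell-level confusion where predictions exist
  cellConf <- NULL; cellMetrics <- NULL
  cells <- report@cells
  if (nrow(cells) && any(!is.na(cells$pred_class))) {
    truth <- character(nrow(cells)); truth[] <- NA_character_
    for (scn in names(annotations)) {
      sel <- which(cells$scene == scn)
      if (!length(sel)) next
      ga <- assignGroundTruth(annotations[[scn]],
                              cells[sel, , drop = FALSE],
                              warn_unassigned = FALSE)
      truth[sel] <- ga$label
    }
    ok <- !is.na(truth) & !is.na(cells$pred_class)
    if (any(ok)) {
      cellConf <- confusionMatrix3(truth[ok], cells$pred_class[ok])
      cellMetrics <- precisionRecallF1(
        tp = cellConf["whale", "whale"],
        fp = sum(cellConf[, "whale"]) - cellConf["whale", "whale"],
        fn = sum(cellConf["whale", ]) - cellConf["whale", "whale"])
    }
  }
  structure(list(tp = tp, fp = fp, fn = fn, whale_metrics = wm,
                 overall_f1_pct = wm$f1_pct, whales = whales,
                 cell_confusion = cellConf, cell_metrics = cellMetrics,
                 iou_threshold = iou_threshold,
                 gt_hash = configHash(lapply(annotations, annotationBoxes)),
                 mode = report@mode),
            class = "surveyEval")
}

#' Compare a two-step evaluation against a baseline evaluation
#'
#' Reports the F1 difference in percentage points (two-step minus
#' baseline). Inputs are either "surveyEval" objects from
#' [evaluateReport()] (which must share identical ground truth) or plain
#' lists carrying `overall_f1_pct`.
#'
#' @param two_step,baseline evaluations to compare
#' @return list: `two_step_f1_pct`, `baseline_f1_pct`,
#'   `improvement_points`, and FP/FN count differences when available
#' @examples
#' compareReports(list(overall_f1_pct = 78),
#'                list(overall_f1_pct = 42))$improvement_points  # 36
#' @export
compareReports <- function(two_step, baseline) {
  g1 <- two_step$gt_hash; g2 <- baseline$gt_hash
  if (!is.null(g1) && !is.null(g2) && !identical(g1, g2))
    stop("evaluations were not computed on identical ground truth",
         call. = FALSE)
  out <- list(two_step_f1_pct = two_step$overall_f1_pct,
              baseline_f1_pct = baseline$overall_f1_pct,
              improvement_points =
                two_step$overall_f1_pct - baseline$overall_f1_pct)
  if (!is.null(two_step$fp) && !is.null(baseline$fp)) {
    out$fp_difference <- baseline$fp - two_step$fp
    out$fn_difference <- baseline$fn - two_step$fn
  }
  out
}
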