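test_that("precision/recall/F1 match an independent brute-force oracle", {
  ## oracle: recompute the ratios directly from counts, independently
  set.seed(99)
  for (rep in 1:1000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    m <- precisionRecallF1(tp, fp, fn)
    p_o <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r_o <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f_o <- if (p_o + r_o == 0) 0 else 2 * p_o * r_o / (p_o + r_o)
    expect_identical(m$precision, p_o)
    expect_identical(m$recall, r_o)
    expect_equal(m$f1, f_o)
  }
})

test_that("degenerate and symmetric count cases follow the conventions", {
  z <- precisionRecallF1(0, 0, 0)
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  s <- precisionRecallF1(7, 7, 7)
  expect_equal(c(s$precision, s$recall, s$f1), c(0.5, 0.5, 0.5))
  expect_error(precisionRecallF1(-1, 0, 0), ">= 0")
})

test_that("the published whale-cell counts yield the printed metrics", {
  ## 68 annotated whale cells: 13 confused with water, 1 with a ship;
  ## 9 ship cells and 4 water cells predicted whale
  m <- precisionRecallF1(tp = 54, fp = 13, fn = 14)
  expect_equal(m$precision_pct, 80.59)
  expect_equal(m$recall_pct, 79.41)
  expect_equal(m$f1_pct, 80.00)
})

test_that("percentage truncation reproduces printed survey values", {
  expect_equal(truncPct(14 / 68), 20.58)   # truncation, not rounding
  expect_equal(truncPct(13 / 68), 19.11)
  expect_equal(truncPct(1 / 68), 1.47)
  expect_equal(truncPct(4 / 400), 1.00)
  expect_equal(truncPct(9 / 400), 2.25)
  expect_equal(truncPct(0.5), 50)
})

test_that("misclassification rates reproduce the published whale row", {
  cm <- matrix(c(54, 9, 4,   1, 390, 0,   13, 1, 396), 3, 3,
               dimnames = list(true = c("whale", "ship", "water_rock"),
                               pred = c("whale", "ship", "water_rock")))
  wr <- misclassificationRates(cm, "whale")
  expect_equal(unname(wr$rates["water_rock"]), 19.11)
  expect_equal(unname(wr$rates["ship"]), 1.47)
  expect_equal(wr$total, 20.58)
  ## confuser-to-whale rates: 9/400 ships, 4/400 water cells
  expect_equal(unname(misclassificationRates(cm, "ship")$rates["whale"]), 2.25)
  expect_equal(unname(misclassificationRates(cm, "water_rock")$rates["whale"]),
               1.00)
  ## diagonal-only matrix has zero rates
  d <- diag(c(5L, 5L, 5L)); dimnames(d) <- dimnames(cm)
  expect_equal(misclassificationRates(d, "whale")$total, 0)
  empty <- cm; empty["whale", ] <- 0L
  expect_error(misclassificationRates(empty, "whale"), "undefined rate")
})

test_that("confusion matrices conserve the number of evaluated cells", {
  set.seed(5)
  true <- sample(c("whale", "ship", "water_rock"), 200, replace = TRUE)
  pred <- sample(c("whale", "ship", "water_rock"), 200, replace = TRUE)
  cm <- confusionMatrix3(true, pred)
  expect_equal(sum(cm), 200L)
  expect_equal(unname(rowSums(cm)),
               unname(as.integer(table(factor(true,
                 levels = c("whale", "ship", "water_rock"))))))
})

test_that("greedy matching resolves the worked three-prediction example", {
  ## p1 overlaps g1 strongly, p2 overlaps g1 weakly, p3 overlaps g2
  gt <- data.frame(x_min = c(0, 100), y_min = c(0, 0),
                   x_max = c(10, 110), y_max = c(10, 10), class = "whale")
  pred <- data.frame(
    x_min = c(1, 4, 101), y_min = c(0, 0, 0),
    x_max = c(11, 14, 111), y_max = c(10, 10, 10),
    class = "whale", score = c(0.9, 0.8, 0.7))
  mr <- matchDetections(pred, gt, iou_threshold = 0.5)
  expect_equal(mr$tp, 2L)
  expect_equal(mr$fp, 2L)          # p2 left unmatched
  expect_equal(mr$fn_count, 0L)
  expect_equal(sort(mr$pairs$pred), c(1L, 3L))
})

test_that("matching degenerates correctly with missing predictions or truth", {
  gt <- data.frame(x_min = c(0, 20, 40), y_min = 0,
                   x_max = c(10, 30, 50), y_max = 10, class = "whale")
  none <- gt[0, ]; none$score <- numeric(0)
  mr <- matchDetections(none, gt, 0.5)
  expect_equal(c(mr$tp, mr$fp_count, mr$fn_count), c(0L, 0L, 3L))
  ## identical boxes match at IoU 1
  same <- gt; same$score <- c(0.9, 0.8, 0.7)
  mr2 <- matchDetections(same, gt, 0.5)
  expect_equal(mr2$tp, 3L)
  expect_true(all(mr2$pairs$iou == 1))
  expect_error(matchDetections(same, gt, 0), "0, 1")
  bad <- same; bad$x_max[1] <- bad$x_min[1]
  expect_error(matchDetections(bad, gt, 0.5), "malformed")
})

test_that("greedy matching never beats optimal matching (exhaustive check)", {
  ## oracle: enumerate every injective prediction-to-truth assignment on
  ## problems up to 5 x 5 and take the best admissible pair count
  bestByEnumeration <- function(iou, thr) {
    np <- nrow(iou); ng <- ncol(iou)
    best <- 0L
    idx <- c(seq_len(ng), rep(NA, max(0, np - ng)))
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (k in seq_along(v))
        for (rest in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
      out
    }
    for (assign in perms(idx)) {
      cnt <- 0L
      for (i in seq_len(np))
        if (!is.na(assign[i]) && iou[i, assign[i]] >= thr) cnt <- cnt + 1L
      best <- max(best, cnt)
    }
    best
  }
  set.seed(77)
  for (rep in 1:40) {
    np <- sample(1:4, 1); ng <- sample(1:4, 1)
    x0p <- runif(np, 0, 50); x0g <- runif(ng, 0, 50)
    pred <- data.frame(x_min = x0p, y_min = 0, x_max = x0p + 10, y_max = 10,
                       class = "whale", score = runif(np))
    gt <- data.frame(x_min = x0g, y_min = 0, x_max = x0g + 10, y_max = 10,
                     class = "whale")
    iou <- whalescan:::boxIoUMatrix(pred, gt)
    g <- matchDetections(pred, gt, 0.3, method = "greedy")$tp
    o <- matchDetections(pred, gt, 0.3, method = "optimal")$tp
    expect_lte(g, o)
    expect_equal(o, bestByEnumeration(iou, 0.3))
  }
})

test_that("posture detectability tables sort and exclude untagged whales", {
  whales <- data.frame(
    posture = c("blowing", "blowing", "submerged", "submerged", "logging",
                NA),
    detected = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_warning(tab <- postureDetectability(whales), "without posture")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$posture[1], "blowing")       # 100% first
  expect_equal(tab$detectability_pct[tab$posture == "submerged"], 50)
  expect_equal(sum(tab$n), 5L)
  ## single posture, all detected
  one <- postureDetectability(data.frame(posture = "logging",
                                         detected = TRUE))
  expect_equal(one$detectability_pct, 100)
})

test_that("stratified folds partition the data deterministically", {
  labels <- rep(c("whale", "ship", "water_rock"), times = c(40, 30, 30))
  f <- kfoldFolds(labels, 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.integer(table(f)), rep(20L, 5))       # n = 100, k = 5
  ## stratification: each fold holds 8 whales
  expect_true(all(table(f[labels == "whale"]) == 8))
  expect_identical(f, kfoldFolds(labels, 5, seed = 2))
  expect_false(identical(f, kfoldFolds(labels, 5, seed = 3)))
  expect_error(kfoldFolds(labels, 1), ">= 2")
  expect_error(kfoldFolds(labels[1:3], 5), "smaller than k")
  expect_warning(kfoldFolds(c("a", "a", "a", "b",
                              rep("c", 10)), 5, seed = 1),
                 "non-stratified")
})

test_that("k-fold evaluation reports per-fold and summary F1", {
  ## a deterministic nearest-mean pipeline over tiny feature patches keeps
  ## this test about the CV bookkeeping, not model quality
  set.seed(4)
  n <- 30
  labels <- rep(c("whale", "ship", "water_rock"), each = 10)
  patches <- lapply(seq_len(n), function(i) {
    lvl <- match(labels[i], c("whale", "ship", "water_rock"))
    array(lvl / 4 + rnorm(48, sd = 0.01), c(4, 4, 3))
  })
  factory <- function(train) {
    mus <- vapply(split(seq_along(train$labels), train$labels),
                  function(ix) mean(vapply(train$patches[ix], mean,
                                           numeric(1))), numeric(1))
    function(test_patches) {
      names(mus)[vapply(test_patches, function(p)
        which.min(abs(mus - mean(p))), integer(1))]
    }
  }
  res <- kfoldEvaluate(list(patches = patches, labels = labels), 5, factory,
                       seed = 6)
  expect_equal(nrow(res$per_fold), 5L)
  expect_equal(res$mean_f1, 1)          # perfectly separable by construction
  expect_equal(res$sd_f1, 0)
  ## folds partition the dataset
  expect_equal(sort(unique(res$folds)), 1:5)
  expect_equal(length(res$folds), n)
})

test_that("report comparison returns signed F1 point differences", {
  cmp <- compareReports(list(overall_f1_pct = 78),
                        list(overall_f1_pct = 42))
  expect_equal(cmp$improvement_points, 36)
  ## identical reports differ by zero; swapping negates
  expect_equal(compareReports(list(overall_f1_pct = 50),
                              list(overall_f1_pct = 50))$improvement_points,
               0)
  a <- list(overall_f1_pct = 61.2); b <- list(overall_f1_pct = 47.9)
  expect_equal(compareReports(a, b)$improvement_points,
               -compareReports(b, a)$improvement_points)
  ## mismatched ground truth refuses
  expect_error(compareReports(list(overall_f1_pct = 1, gt_hash = "x"),
                              list(overall_f1_pct = 2, gt_hash = "y")),
               "identical ground truth")
})
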