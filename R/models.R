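## Stage-1 presence classifier and stage-2 detector.
##
## Both models share the same machinery: a fixed, seeded convolutional
## filter bank (the "pretrained" backbone — it is never updated, mirroring
## transfer learning from frozen features) feeding a fully connected stack
## trained with RMSProp under a stepped learning-rate schedule. The
## detector combines region proposals from a local-contrast anomaly map
## with a CNN verifier scoring each candidate crop; its contract is
## architecture-agnostic: boxes and scores out.

#' Training configuration
#'
#' Defaults follow the transfer-learning recipe used for whale survey
#' models: initial learning rate 0.001 divided by a decay factor of 16
#' every 30 epochs, RMSProp with momentum 0.9, squared-gradient decay 0.9
#' and epsilon 0.1, retraining only the last two fully connected parameter
#' groups (`head_only`). The large epsilon is deliberate and kept as a
#' configurable override.
#'
#' @param learning_rate initial step size (> 0)
#' @param decay_factor multiplicative LR divisor (>= 1)
#' @param decay_every_epochs epochs between LR drops
#' @param momentum RMSProp momentum
#' @param rms_decay RMSProp squared-gradient decay
#' @param epsilon RMSProp denominator stabiliser
#' @param epochs training epochs (>= 1)
#' @param batch_size minibatch size (class-balanced sampling)
#' @param head_only freeze all but the final two FC parameter groups
#' @param val_fraction held-out fraction when the dataset has no split
#' @param seed RNG seed; training is deterministic given the seed under
#'   single-threaded execution
#' @return validated list of class "trainingConfig"
#' @export
trainingConfig <- function(learning_rate = 0.001, decay_factor = 16,
                           decay_every_epochs = 30, momentum = 0.9,
                           rms_decay = 0.9, epsilon = 0.1,
                           epochs = 30, batch_size = 16, head_only = TRUE,
                           val_fraction = 0.2, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (decay_factor < 1) stop("decay_factor must be >= 1", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, decay_factor = decay_factor,
                 decay_every_epochs = as.integer(decay_every_epochs),
                 momentum = momentum, rms_decay = rms_decay,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 head_only = isTRUE(head_only),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "trainingConfig")
}

#' Stepped learning-rate schedule
#'
#' Closed form: `lr * decay_factor^(-floor((epoch - 1) / decay_every))`
#' for 1-based epochs, i.e. epochs 1–30 run at 0.001 and epochs 31–60 at
#' 0.0000625 under the defaults.
#'
#' @param config a [trainingConfig()]
#' @param n_epochs schedule length (defaults to the configured epochs)
#' @return numeric vector of per-epoch learning rates
#' @export
lrSchedule <- function(config, n_epochs = config$epochs) {
  e <- seq_len(n_epochs)
  config$learning_rate *
    config$decay_factor^(-floor((e - 1) / config$decay_every_epochs))
}

## ---- backbone ---------------------------------------------------------

## Fixed seeded filter bank + pooled-intensity features. input 32x32x3.
.makeBackbone <- function(input_size = 32L, n_filters = 8L, kernel = 5L,
                          pool = 4L, seed = 1234L) {
  conv_out <- input_size - kernel + 1L           # valid convolution
  stopifnot(conv_out %% pool == 0L)
  W <- withSeed(seed, {
    w <- matrix(stats::rnorm(kernel * kernel * 3L * n_filters), ncol = n_filters)
    w <- sweep(w, 2L, colMeans(w))               # zero-mean (edge/texture)
    sweep(w, 2L, sqrt(colSums(w^2)), "/")
  })
  ## im2col index table: rows = conv positions, cols = kernel taps
  pos <- expand.grid(y = seq_len(conv_out), x = seq_len(conv_out))
  tap <- expand.grid(dy = seq_len(kernel) - 1L, dx = seq_len(kernel) - 1L,
                     ch = seq_len(3L) - 1L)
  idx <- outer(seq_len(nrow(pos)), seq_len(nrow(tap)), function(i, j) {
    (tap$ch[j]) * input_size * input_size +
      (pos$x[i] + tap$dx[j] - 1L) * input_size + (pos$y[i] + tap$dy[j])
  })
  ## mean-pool map: conv grid -> (conv_out/pool)^2 blocks
  blk <- (pos$y - 1L) %/% pool + ((pos$x - 1L) %/% pool) * (conv_out %/% pool)
  ## 8x8 pooled-intensity grid per channel
  int_pool <- input_size %/% 8L
  nblk <- (conv_out %/% pool)^2
  list(input_size = input_size, n_filters = n_filters, kernel = kernel,
       pool = pool, conv_out = conv_out, W = W, idx = idx, blk = blk,
       int_pool = int_pool, seed = seed,
       n_features = 2L * nblk * n_filters + 8L * 8L * 3L + 16L + 10L)
}

## global luminance-anomaly statistics: scale, spread and shape of the
## departure from the local sea background at two blur scales — sensitive
## to faint elongated bodies, hard bright hulls and dark rock cores
.anomalyStats <- function(p) {
  L <- luminance(p)
  stats_at <- function(sigma) {
    A <- L - blurMatrix(L, sigma)
    q <- stats::quantile(A, c(0.01, 0.5, 0.99), names = FALSE)
    c(max(A), -min(A), stats::sd(A), q,
      mean(A > 0.04), mean(A < -0.04))
  }
  c(stats_at(2), stats_at(5), .blobShape(L))
}

## shape of the dominant bright and dark anomaly blobs: area fraction,
## elongation (principal-axis ratio), mean contrast, bounding-box fill.
## Whales are elongated bright blobs; rocks are round dark cores inside
## bright foam rings; pure sea has neither.
.blobShape <- function(L) {
  A <- L - blurMatrix(L, 5)
  one <- function(mask, vals) {
    if (sum(mask) < 4L) return(c(0, 0, 0, 0, 0))
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    k <- which.max(sizes)
    sel <- which(lab == k, arr.ind = TRUE)
    n <- nrow(sel)
    if (n < 3L) return(c(n / length(mask), 1, mean(vals[lab == k]), 1, sqrt(n)))
    cv <- stats::cov(sel) + diag(1e-6, 2)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    bbox_fill <- n / ((diff(range(sel[, 1])) + 1) * (diff(range(sel[, 2])) + 1))
    c(n / length(mask), sqrt(ev[1] / ev[2]), mean(vals[lab == k]),
      bbox_fill, sqrt(n))
  }
  c(one(A > 0.03, A), one(A < -0.03, -A))
}

## per-feature standardisation fitted on the training features; stored in
## the backbone so inference applies the same transform
.standardizeFit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  list(mu = mu, sd = sdv)
}

.standardizeApply <- function(X, st) {
  if (is.null(st)) return(X)
  sweep(sweep(X, 2L, st$mu), 2L, st$sd, "/")
}

## feature vector(s) for a list of RGB patches
.featurize <- function(backbone, patches) {
  b <- backbone
  t(vapply(patches, function(p0) {
    p <- resizeImage(p0, b$input_size, b$input_size)
    v <- as.numeric(p)
    X <- matrix(v[b$idx], nrow = nrow(b$idx))     # positions x taps
    A <- pmax(X %*% b$W, 0)                       # ReLU feature maps
    pooled <- rowsum(A, b$blk) / (b$pool^2)       # mean-pool blocks
    ord <- order(b$blk)
    gmax <- apply(A, 2L, function(col)            # max-pool blocks
      vapply(split(col[ord], b$blk[ord]), max, numeric(1)))
    ## pooled raw intensities, 8x8 per channel
    ip <- b$int_pool
    g <- vapply(1:3, function(ch) {
      m <- p[, , ch]
      as.numeric(rowsum(t(rowsum(m, (seq_len(nrow(m)) - 1L) %/% ip)),
                        (seq_len(ncol(m)) - 1L) %/% ip)) / ip^2
    }, numeric(64L))
    ## anomaly statistics at the patch's native resolution
    c(as.numeric(pooled), as.numeric(gmax), as.numeric(g), .anomalyStats(p0))
  }, numeric(b$n_features)))
}

## ---- fully connected head + RMSProp -----------------------------------

.initHead <- function(n_in, hidden = c(64L, 32L), n_out, seed) {
  withSeed(seed, {
    sizes <- c(n_in, hidden, n_out)
    lapply(seq_len(length(sizes) - 1L), function(i) {
      list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                   sd = sqrt(2 / sizes[i])),
                      sizes[i], sizes[i + 1L]),
           b = rep(0, sizes[i + 1L]))
    })
  })
}

.headForward <- function(head, X) {
  acts <- vector("list", length(head))
  A <- X
  for (i in seq_along(head)) {
    Z <- sweep(A %*% head[[i]]$W, 2L, head[[i]]$b, "+")
    A <- if (i < length(head)) pmax(Z, 0) else Z
    acts[[i]] <- A
  }
  list(acts = acts, logits = A)
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## one RMSProp-with-momentum step on the trainable groups
.rmspropStep <- function(head, grads, state, lr, cfg, trainable) {
  for (i in trainable) {
    for (nm in c("W", "b")) {
      g <- grads[[i]][[nm]]
      state[[i]][[nm]]$r <- cfg$rms_decay * state[[i]][[nm]]$r +
        (1 - cfg$rms_decay) * g^2
      state[[i]][[nm]]$m <- cfg$momentum * state[[i]][[nm]]$m +
        lr * g / sqrt(state[[i]][[nm]]$r + cfg$epsilon)
      head[[i]][[nm]] <- head[[i]][[nm]] - state[[i]][[nm]]$m
    }
  }
  list(head = head, state = state)
}

## train an FC head on features X (rows) and integer labels y in 1..C
.trainHead <- function(X, y, n_classes, cfg, hidden = 32L,
                       val_idx = integer(0)) {
  n <- nrow(X)
  head <- .initHead(ncol(X), hidden, n_classes, seed = cfg$seed)
  state <- lapply(head, function(l)
    list(W = list(r = l$W * 0, m = l$W * 0),
         b = list(r = l$b * 0, m = l$b * 0)))
  ## head_only retrains the final two FC parameter groups only
  trainable <- if (cfg$head_only)
    seq.int(max(1L, length(head) - 1L), length(head)) else seq_along(head)
  tr <- setdiff(seq_len(n), val_idx)
  lrs <- lrSchedule(cfg)
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                    val_accuracy = numeric(0))
  byclass <- split(tr, y[tr])
  withSeed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- lrs[ep]
      ord <- sample(tr)
      nb <- max(1L, ceiling(length(tr) / cfg$batch_size))
      eploss <- 0
      for (bi in seq_len(nb)) {
        ## class-balanced batch
        per <- max(1L, ceiling(cfg$batch_size / n_classes))
        take <- unlist(lapply(byclass, function(ix)
          ix[sample.int(length(ix), min(per, cfg$batch_size), replace = TRUE)]))
        Xb <- X[take, , drop = FALSE]
        yb <- y[take]
        fw <- .headForward(head, Xb)
        P <- .softmax(fw$logits)
        m <- nrow(Xb)
        eploss <- eploss +
          -mean(log(pmax(P[cbind(seq_len(m), yb)], 1e-12)))
        ## backprop
        D <- P
        D[cbind(seq_len(m), yb)] <- D[cbind(seq_len(m), yb)] - 1
        D <- D / m
        grads <- vector("list", length(head))
        delta <- D
        for (i in rev(seq_along(head))) {
          Ain <- if (i == 1L) Xb else fw$acts[[i - 1L]]
          grads[[i]] <- list(W = crossprod(Ain, delta),
                             b = colSums(delta))
          if (i > 1L) {
            delta <- delta %*% t(head[[i]]$W)
            delta <- delta * (fw$acts[[i - 1L]] > 0)
          }
        }
        up <- .rmspropStep(head, grads, state, lr, cfg, trainable)
        head <- up$head; state <- up$state
      }
      val_acc <- if (length(val_idx)) {
        P <- .softmax(.headForward(head, X[val_idx, , drop = FALSE])$logits)
        mean(max.col(P) == y[val_idx])
      } else NA_real_
      log <- rbind(log, data.frame(epoch = ep, lr = lr, loss = eploss / nb,
                                   val_accuracy = val_acc))
    }
  })
  list(head = head, log = log)
}

.predictHead <- function(backbone, head, patch) {
  X <- .standardizeApply(.featurize(backbone, list(patch)),
                         backbone$standardize)
  as.numeric(.softmax(.headForward(head, X)$logits))
}

## resolve a dataset's patches into in-memory arrays
.resolvePatches <- function(patches, dir = NULL) {
  lapply(patches, function(p) {
    if (is.character(p)) {
      path <- if (!is.null(dir)) file.path(dir, p) else p
      img <- png::readPNG(path)
      if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
      img[, , 1:3, drop = FALSE]
    } else p
  })
}

## ---- stage 1: presence classifier -------------------------------------

#' Train the stage-1 whale-presence classifier
#'
#' Three-class image classification (whale / ship / water + submerged
#' rocks) over grid-cell patches. Features come from the fixed seeded
#' convolutional backbone; the fully connected stack is trained with
#' RMSProp under the stepped LR schedule. With `head_only` (default) only
#' the last two FC parameter groups are updated.
#'
#' @param dataset a patch set from [generateClassificationDataset()], or a
#'   list with `patches` (RGB arrays or PNG paths), `labels`, optional
#'   `split` ("train"/"val") and `dir`
#' @param config a [trainingConfig()]
#' @param backbone optional backbone created by the package's internal
#'   builder; the default is a small filter bank trainable head in minutes
#'   on one CPU
#' @param augment optional [augmentConfig()]; when given, each training
#'   patch additionally contributes `augment_repeats` augmented copies
#' @param augment_repeats augmented copies per training patch
#' @return a [PresenceClassifier-class]
#' @export
trainPresenceClassifier <- function(dataset, config = trainingConfig(),
                                    backbone = NULL, augment = NULL,
                                    augment_repeats = 1L) {
  patches <- .resolvePatches(dataset$patches, dataset$dir)
  labels <- as.character(dataset$labels)
  missing <- setdiff(WHALE_CLASSES, unique(labels))
  if (length(missing))
    stop("invalid dataset: class(es) missing from training data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(backbone)) backbone <- .makeBackbone()
  split <- dataset$split
  if (is.null(split)) {
    split <- rep("train", length(labels))
    withSeed(config$seed + 17L, for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nv <- floor(length(idx) * config$val_fraction)
      if (nv > 0) split[sample(idx, nv)] <- "val"
    })
  }
  if (!is.null(augment)) {
    tr <- which(split == "train")
    withSeed(config$seed + 29L, {
      for (r in seq_len(augment_repeats)) {
        for (i in tr) {
          patches[[length(patches) + 1L]] <-
            augmentPatch(patches[[i]], config = augment)$image
          labels <- c(labels, labels[i])
          split <- c(split, "train")
        }
      }
    })
  }
  y <- match(labels, WHALE_CLASSES)
  X <- .featurize(backbone, patches)
  backbone$standardize <- .standardizeFit(X[split == "train", , drop = FALSE])
  X <- .standardizeApply(X, backbone$standardize)
  fit <- .trainHead(X, y, n_classes = 3L, cfg = config,
                    val_idx = which(split == "val"))
  methods::new("PresenceClassifier", backbone = backbone, head = fit$head,
               classes = WHALE_CLASSES, inputSize = backbone$input_size,
               config = unclass(config), log = fit$log)
}

#' @describeIn classifyCell trained stage-1 model: resize, featurise,
#'   softmax over the three classes
#' @export
setMethod("classifyCell", "PresenceClassifier", function(classifier, patch) {
  assertImage(patch, "patch")
  p <- .predictHead(classifier@backbone, classifier@head, patch)
  stats::setNames(p, classifier@classes)
})

#' @describeIn classifyCell plug-in classifier: any function
#'   `patch -> named probabilities`
#' @export
setMethod("classifyCell", "function", function(classifier, patch) {
  p <- classifier(patch)
  if (abs(sum(p) - 1) > 1e-6)
    stop("plug-in classifier must return probabilities summing to 1",
         call. = FALSE)
  p
})

## ---- stage 2: detector ------------------------------------------------

#' Train the stage-2 whale detector
#'
#' Candidate regions are proposed from a local-contrast anomaly map
#' (luminance minus its large-scale blur); a small CNN verifier is trained
#' to score candidate crops as whale vs background. Positives are the
#' annotated whale boxes; negatives are random background crops plus
#' proposal-stage false alarms (hard negatives). Images without boxes are
#' allowed and contribute negatives only.
#'
#' @param dataset a set from [generateDetectionDataset()], or a list with
#'   `patches` and `boxes`
#' @param config a [trainingConfig()]
#' @param backbone optional backbone override
#' @param proposal named list of proposal parameters: `sigma_bg`
#'   (background blur, px), `min_contrast` (anomaly threshold),
#'   `min_area_px`, `margin` (crop enlargement fraction)
#' @return a [WhaleDetector-class]
#' @export
trainDetector <- function(dataset, config = trainingConfig(),
                          backbone = NULL, proposal = list()) {
  patches <- .resolvePatches(dataset$patches, dataset$dir)
  boxes <- dataset$boxes
  if (length(patches) == 0L)
    stop("invalid dataset: no images", call. = FALSE)
  if (is.null(boxes) || length(boxes) != length(patches))
    stop("invalid dataset: boxes must parallel patches", call. = FALSE)
  if (is.null(backbone)) backbone <- .makeBackbone()
  prop <- utils::modifyList(list(sigma_bg = 6, min_contrast = 0.05,
                                 min_area_px = 6, margin = 0.2), proposal)
  crops <- list(); lab <- integer(0)   # 1 = whale, 2 = background
  withSeed(config$seed + 43L, {
    for (i in seq_along(patches)) {
      img <- patches[[i]]
      h <- dim(img)[1]; w <- dim(img)[2]
      b <- boxes[[i]]
      b <- if (!is.null(b) && nrow(b)) b[b$class == "whale", , drop = FALSE]
           else emptyBoxes()
      if (nrow(b)) for (j in seq_len(nrow(b))) {
        crops[[length(crops) + 1L]] <-
          .cropBox(img, b[j, , drop = FALSE], prop$margin)
        lab <- c(lab, 1L)
      }
      ## random background crops
      for (k in seq_len(2L)) {
        side <- stats::runif(1, 8, max(10, min(h, w) / 3))
        x0 <- stats::runif(1, 0, w - side); y0 <- stats::runif(1, 0, h - side)
        cand <- data.frame(x_min = x0, y_min = y0,
                           x_max = x0 + side, y_max = y0 + side)
        if (!nrow(b) || all(boxIoU(cand, b) < 0.1)) {
          crops[[length(crops) + 1L]] <- .cropBox(img, cand, 0)
          lab <- c(lab, 2L)
        }
      }
      ## hard negatives: proposals that miss every ground-truth box
      pr <- .proposeRegions(img, prop)
      if (nrow(pr)) for (j in seq_len(min(nrow(pr), 3L))) {
        cand <- pr[j, , drop = FALSE]
        if (!nrow(b) || all(boxIoU(cand, b) < 0.1)) {
          crops[[length(crops) + 1L]] <- .cropBox(img, cand, prop$margin)
          lab <- c(lab, 2L)
        }
      }
    }
  })
  if (!any(lab == 1L))
    stop("invalid dataset: no whale boxes to learn from", call. = FALSE)
  X <- .featurize(backbone, crops)
  nv <- max(1L, floor(length(lab) * config$val_fraction))
  val_idx <- withSeed(config$seed + 51L, sample(length(lab), nv))
  backbone$standardize <- .standardizeFit(X[-val_idx, , drop = FALSE])
  X <- .standardizeApply(X, backbone$standardize)
  fit <- .trainHead(X, lab, n_classes = 2L, cfg = config, val_idx = val_idx)
  methods::new("WhaleDetector", proposal = prop, backbone = backbone,
               head = fit$head, inputSize = backbone$input_size,
               config = unclass(config), log = fit$log)
}

## crop a (possibly fractional) box with relative margin, edge-clamped
.cropBox <- function(img, b, margin) {
  h <- dim(img)[1]; w <- dim(img)[2]
  mw <- (b$x_max - b$x_min) * margin; mh <- (b$y_max - b$y_min) * margin
  x0 <- max(0, floor(b$x_min - mw)); x1 <- min(w, ceiling(b$x_max + mw))
  y0 <- max(0, floor(b$y_min - mh)); y1 <- min(h, ceiling(b$y_max + mh))
  if (x1 - x0 < 2) x1 <- min(w, x0 + 2)
  if (y1 - y0 < 2) y1 <- min(h, y0 + 2)
  img[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
}

## connected components of the thresholded anomaly map -> candidate boxes
.proposeRegions <- function(img, prop) {
  L <- luminance(img)
  A <- abs(L - blurMatrix(L, prop$sigma_bg))
  mask <- A > prop$min_contrast
  if (!any(mask)) return(emptyBoxes())
  labm <- EBImage::bwlabel(mask * 1)
  n <- max(labm)
  out <- emptyBoxes()
  h <- nrow(labm); w <- ncol(labm)
  for (k in seq_len(n)) {
    sel <- which(labm == k, arr.ind = TRUE)
    if (nrow(sel) < prop$min_area_px) next
    bx <- data.frame(x_min = min(sel[, 2]) - 1, y_min = min(sel[, 1]) - 1,
                     x_max = max(sel[, 2]), y_max = max(sel[, 1]),
                     class = "whale")
    if ((bx$x_max - bx$x_min) >= 0.95 * w && (bx$y_max - bx$y_min) >= 0.95 * h)
      next                                     # degenerate whole-image blob
    out <- rbind(out, bx)
  }
  out
}

#' Non-maximum suppression of scored boxes
#'
#' Greedy: keep the highest-scoring box, discard boxes overlapping it with
#' IoU > `nms_iou`, repeat. Idempotent.
#'
#' @param boxes data.frame with x_min, y_min, x_max, y_max, score
#' @param nms_iou suppression threshold in `[0, 1]`
#' @return the retained rows of `boxes`, ordered by decreasing score
#' @export
nmsBoxes <- function(boxes, nms_iou = 0.5) {
  if (nms_iou < 0 || nms_iou > 1)
    stop("nms_iou must lie in [0, 1]", call. = FALSE)
  if (nrow(boxes) == 0L) return(boxes)
  boxes <- boxes[order(-boxes$score), , drop = FALSE]
  keep <- logical(nrow(boxes))
  alive <- rep(TRUE, nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(boxes)) {
      rest <- which(alive & seq_len(nrow(boxes)) > i)
      if (length(rest)) {
        ious <- boxIoU(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])
        alive[rest[ious > nms_iou]] <- FALSE
      }
    }
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn detectWhales trained detector: propose candidate regions,
#'   score each crop with the CNN verifier, threshold and apply NMS
#' @export
setMethod("detectWhales", "WhaleDetector",
  function(detector, patch, score_threshold = 0.5, nms_iou = 0.5) {
    if (score_threshold < 0 || score_threshold > 1 ||
        nms_iou < 0 || nms_iou > 1)
      stop("thresholds must lie in [0, 1]", call. = FALSE)
    assertImage(patch, "patch")
    cand <- .proposeRegions(patch, detector@proposal)
    if (!nrow(cand)) { out <- emptyBoxes(score = TRUE); return(out) }
    scores <- vapply(seq_len(nrow(cand)), function(j) {
      crop <- .cropBox(patch, cand[j, , drop = FALSE],
                       detector@proposal$margin)
      .predictHead(detector@backbone, detector@head, crop)[1L]
    }, numeric(1))
    cand$score <- scores
    cand <- cand[cand$score >= score_threshold, , drop = FALSE]
    nmsBoxes(cand, nms_iou)
  })

#' @describeIn detectWhales plug-in detector: any function
#'   `patch -> scored box data.frame`; thresholding and NMS still apply
#' @export
setMethod("detectWhales", "function",
  function(detector, patch, score_threshold = 0.5, nms_iou = 0.5) {
    if (score_threshold < 0 || score_threshold > 1 ||
        nms_iou < 0 || nms_iou > 1)
      stop("thresholds must lie in [0, 1]", call. = FALSE)
    out <- detector(patch)
    if (!nrow(out)) return(out)
    out <- out[out$score >= score_threshold, , drop = FALSE]
    nmsBoxes(out, nms_iou)
  })

## ---- checkpoints -------------------------------------------------------

#' Save a trained model as a single-file checkpoint
#'
#' The checkpoint archives the model type, package version, configuration,
#' class map, seed and weights.
#' @param model a [PresenceClassifier-class] or [WhaleDetector-class]
#' @param path output file
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(format = "whalescan-checkpoint", version = "1",
              package_version = as.character(utils::packageVersion("whalescan")),
              type = class(model)[1])
  for (sl in methods::slotNames(class(model)))
    obj[[sl]] <- methods::slot(model, sl)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint written by [saveCheckpoint()]
#' @param path checkpoint file
#' @return the restored model object
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "whalescan-checkpoint"))
    stop("not a whalescan checkpoint: ", path, call. = FALSE)
  slots <- setdiff(names(obj), c("format", "version", "package_version", "type"))
  do.call(methods::new, c(list(Class = obj$type), obj[slots]))
}
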