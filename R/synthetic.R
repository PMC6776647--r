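## Seeded generator of annotated synthetic VHR ocean scenes.
##
## A scene is composed as  clean object layer + water base + wave texture +
## sun glint.  The clean layer (whale bodies, blow plumes, ship hulls and
## wakes, submerged rocks with foam rings) is returned alongside the final
## image so that tests can use it as an oracle: connected components of the
## pre-noise layer recover exactly the objects that were placed.

#' Default posture rendering parameters
#'
#' Controls how each of the six whale postures is rendered: the relative
#' luminance contrast between body and water, the fraction of the body
#' length rendered (spyhopping shows only the head), whether a bright
#' blow/splash plume is added, and the body aspect ratio range.
#' Submerged bodies sit at near-zero contrast and blowing/breaching carry a
#' plume of contrast >= 0.5, so detectability increases with surface
#' activity — the ordering observed in real surveys.
#'
#' @return data.frame with one row per posture: contrast_min, contrast_max,
#'   surface_fraction, plume, aspect_min, aspect_max
#' @export
posturePresets <- function() {
  data.frame(
    posture = c("logging", "breaching", "spyhopping", "blowing",
                "peduncle", "submerged"),
    contrast_min     = c(0.10, 0.20, 0.08, 0.15, 0.12, 0.02),
    contrast_max     = c(0.25, 0.35, 0.16, 0.30, 0.25, 0.10),
    surface_fraction = c(1.00, 0.80, 0.25, 1.00, 0.60, 0.00),
    plume            = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    aspect_min       = c(0.18, 0.25, 0.45, 0.18, 0.22, 0.18),
    aspect_max       = c(0.28, 0.40, 0.70, 0.28, 0.35, 0.28),
    stringsAsFactors = FALSE)
}

#' Specification of one synthetic ocean scene
#'
#' @param width_m,height_m scene extent in metres
#' @param pixel_size metres per pixel (VHR satellite/aerial range is about
#'   0.15–1.5 m)
#' @param n_whales,n_ships,n_rocks object counts
#' @param posture_mix named probability vector over the six postures; must
#'   sum to 1. The default is weighted towards the passive logging and
#'   submerged postures that dominate real surveys.
#' @param sea_state wave-texture amplitude in `[0, 1]`
#' @param glint specular sun-glint intensity in `[0, 1]`
#' @param whale_length_m sampling range of body length; whales never exceed
#'   30 m (blue whale)
#' @param seed integer RNG seed
#' @param max_attempts placement retries before generation fails
#' @return validated list of class "sceneSpec"
#' @export
sceneSpec <- function(width_m = 213, height_m = 213, pixel_size = 1,
                      n_whales = 0, n_ships = 0, n_rocks = 0,
                      posture_mix = c(logging = 0.40, submerged = 0.34,
                                      peduncle = 0.08, blowing = 0.07,
                                      spyhopping = 0.06, breaching = 0.05),
                      sea_state = 0.3, glint = 0.1,
                      whale_length_m = c(5, 30), seed = 1L,
                      max_attempts = 200L) {
  if (width_m <= 0 || height_m <= 0 || pixel_size <= 0)
    stop("scene extent and pixel_size must be positive", call. = FALSE)
  if (any(c(n_whales, n_ships, n_rocks) < 0))
    stop("object counts must be non-negative", call. = FALSE)
  if (!all(names(posture_mix) %in% WHALE_POSTURES) ||
      abs(sum(posture_mix) - 1) > 1e-8)
    stop("posture_mix must be a probability vector over the six postures",
         call. = FALSE)
  if (length(whale_length_m) != 2L || any(whale_length_m <= 0) ||
      whale_length_m[2] > 30)
    stop("whale_length_m must be positive and at most 30 m", call. = FALSE)
  if (sea_state < 0 || sea_state > 1 || glint < 0 || glint > 1)
    stop("sea_state and glint must lie in [0, 1]", call. = FALSE)
  structure(list(width_m = width_m, height_m = height_m,
                 pixel_size = pixel_size, n_whales = as.integer(n_whales),
                 n_ships = as.integer(n_ships), n_rocks = as.integer(n_rocks),
                 posture_mix = posture_mix, sea_state = sea_state,
                 glint = glint, whale_length_m = whale_length_m,
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "sceneSpec")
}

## soft-edged rotated ellipse written into a region of accumulator matrices
## acc: list(delta = h x w matrix, mask = integer matrix); returns acc
.paintEllipse <- function(acc, cx, cy, a, b, theta, value, object_id,
                          soft = 0.35) {
  h <- nrow(acc$delta); w <- ncol(acc$delta)
  r <- ceiling(max(a, b)) + 1L
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(acc)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  r2 <- u^2 + v^2
  inside <- r2 <= 1
  if (!any(inside)) return(acc)
  fall <- pmin(1, pmax(0, (1 - r2) / soft))     # soft edge
  add <- value * fall * inside
  acc$delta[ys, xs] <- acc$delta[ys, xs] + add
  m <- acc$mask[ys, xs]
  m[inside & m == 0L] <- object_id
  acc$mask[ys, xs] <- m
  .trackExtent(acc, object_id, xs, ys, inside)
}

## merge the painted region's bounding box into the object's extent record
.trackExtent <- function(acc, object_id, xs, ys, inside) {
  if (any(inside)) {
    cols <- xs[apply(inside, 2L, any)]
    rows <- ys[apply(inside, 1L, any)]
    bb <- c(min(cols) - 1, min(rows) - 1, max(cols), max(rows))
    old <- acc$extent[[as.character(object_id)]]
    if (!is.null(old))
      bb <- c(pmin(bb[1:2], old[1:2]), pmax(bb[3:4], old[3:4]))
    acc$extent[[as.character(object_id)]] <- bb
  }
  acc
}

## soft-edged rotated rectangle (ship hulls); same contract as .paintEllipse
.paintRect <- function(acc, cx, cy, a, b, theta, value, object_id,
                       soft = 0.15) {
  h <- nrow(acc$delta); w <- ncol(acc$delta)
  r <- ceiling(sqrt(a^2 + b^2)) + 1L
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(acc)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- abs(dx * cos(theta) + dy * sin(theta)) / a
  v <- abs(-dx * sin(theta) + dy * cos(theta)) / b
  m <- pmax(u, v)
  inside <- m <= 1
  if (!any(inside)) return(acc)
  fall <- pmin(1, pmax(0, (1 - m) / soft))
  acc$delta[ys, xs] <- acc$delta[ys, xs] + value * fall * inside
  mm <- acc$mask[ys, xs]
  mm[inside & mm == 0L] <- object_id
  acc$mask[ys, xs] <- mm
  .trackExtent(acc, object_id, xs, ys, inside)
}

## axis extent (half-width along x and y) of a rotated ellipse
.ellipseExtent <- function(a, b, theta) {
  c(x = sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    y = sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

#' Generate one annotated synthetic ocean scene
#'
#' Deterministic given the spec's seed: the same spec yields bit-identical
#' images and annotations. Whales are rendered as elongated soft-edged
#' blobs whose contrast, visible fraction and plume follow
#' [posturePresets()]; ships as bright sharp rectangles with a wake; rocks
#' as dark blobs ringed by foam. Annotation boxes tightly enclose the
#' rendered object masks.
#'
#' @param spec a [sceneSpec()]
#' @param site_id identifier stamped on the scene
#' @return list: `scene` ([Scene-class]), `annotation`
#'   ([SceneAnnotation-class] with class and posture per box), `layers`
#'   (clean object delta array and integer object mask, for oracle checks),
#'   `objects` (data.frame of placed objects with posture and contrast)
#' @examples
#' g <- generateScene(sceneSpec(n_whales = 2, seed = 7))
#' nrow(annotationBoxes(g$annotation))
#' @export
generateScene <- function(spec, site_id = "synthetic") {
  stopifnot(inherits(spec, "sceneSpec"))
  withSeed(spec$seed, {
    px <- spec$pixel_size
    h <- max(2L, as.integer(round(spec$height_m / px)))
    w <- max(2L, as.integer(round(spec$width_m / px)))
    presets <- posturePresets()

    acc <- list(delta = matrix(0, h, w), mask = matrix(0L, h, w),
                extent = list())
    placed <- emptyBoxes(); placed$posture <- character(0)
    objects <- data.frame(class = character(0), posture = character(0),
                          contrast = numeric(0), stringsAsFactors = FALSE)
    object_id <- 0L

    tryPlace <- function(ext_x, ext_y) {
      ## returns centre (cx, cy) whose box does not overlap placed boxes
      for (att in seq_len(spec$max_attempts)) {
        cx <- stats::runif(1, ext_x + 1, w - ext_x - 1)
        cy <- stats::runif(1, ext_y + 1, h - ext_y - 1)
        cand <- data.frame(x_min = cx - ext_x, y_min = cy - ext_y,
                           x_max = cx + ext_x, y_max = cy + ext_y)
        if (!nrow(placed) || all(boxIoU(cand, placed) <= 0.05))
          return(c(cx, cy))
      }
      stop("could not place object without exceeding the overlap budget",
           call. = FALSE)
    }

    paintWhale <- function() {
      posture <- sample(names(spec$posture_mix), 1L,
                        prob = as.numeric(spec$posture_mix))
      p <- presets[presets$posture == posture, ]
      L <- stats::runif(1, spec$whale_length_m[1], spec$whale_length_m[2])
      L_px <- max(2.5, L / px)
      aspect <- stats::runif(1, p$aspect_min, p$aspect_max)
      a <- L_px / 2; b <- max(1, a * aspect)
      theta <- stats::runif(1, 0, pi)
      contrast <- stats::runif(1, p$contrast_min, p$contrast_max)
      a_vis <- max(1.2, a * ifelse(p$surface_fraction > 0,
                                   p$surface_fraction, 1))
      ext <- .ellipseExtent(a_vis, b, theta)
      ext[1] <- max(ext[1], a * 0.9); ext[2] <- max(ext[2], a * 0.9 * abs(sin(theta)) + b)
      cen <- tryPlace(ext[1] + 2, ext[2] + 2)
      object_id <<- object_id + 1L
      acc <<- .paintEllipse(acc, cen[1], cen[2], a_vis, b, theta,
                            contrast, object_id)
      if (p$plume) {
        ## bright blow/splash blob near the head
        hx <- cen[1] + cos(theta) * a_vis * 0.9
        hy <- cen[2] + sin(theta) * a_vis * 0.9
        pr <- max(1.5, L_px * 0.15)
        acc <<- .paintEllipse(acc, hx, hy, pr, pr * 0.8,
                              stats::runif(1, 0, pi),
                              stats::runif(1, 0.5, 0.7), object_id)
      }
      objects <<- rbind(objects, data.frame(class = "whale",
                                            posture = posture,
                                            contrast = contrast))
      posture
    }

    paintShip <- function() {
      L <- stats::runif(1, 12, 45) / px      # hull length in px
      L <- max(3, min(L, 0.8 * min(h, w)))   # hull must fit the scene
      a <- L / 2; b <- max(1, a * stats::runif(1, 0.22, 0.32))
      theta <- stats::runif(1, 0, pi)
      ext <- .ellipseExtent(a, b, theta)
      cen <- tryPlace(ext[1] + 2, ext[2] + 2)
      object_id <<- object_id + 1L
      ## hull: bright rectangle, hard-edged
      acc <<- .paintRect(acc, cen[1], cen[2], a, b, theta,
                         stats::runif(1, 0.45, 0.65), object_id)
      ## wake: faint elongated streak astern
      wx <- cen[1] - cos(theta) * a * 1.8
      wy <- cen[2] - sin(theta) * a * 1.8
      if (wx > 1 && wx < w - 1 && wy > 1 && wy < h - 1)
        acc <<- .paintEllipse(acc, wx, wy, a * 1.4, b * 1.6, theta,
                              stats::runif(1, 0.08, 0.15), object_id)
      objects <<- rbind(objects, data.frame(class = "ship",
                                            posture = NA_character_,
                                            contrast = NA_real_))
    }

    paintRock <- function() {
      R <- max(2, stats::runif(1, 2.5, 8) / px)
      R <- min(R, (min(h, w) / 2 - 6) / 1.7)  # foam ring must fit the scene
      e <- stats::runif(1, 0.6, 1)
      theta <- stats::runif(1, 0, pi)
      ext <- .ellipseExtent(R * 1.6, R * 1.6 * e, theta)
      cen <- tryPlace(ext[1] + 2, ext[2] + 2)
      object_id <<- object_id + 1L
      ## foam ring: bright annulus = large bright blob minus core
      acc <<- .paintEllipse(acc, cen[1], cen[2], R * 1.5, R * 1.5 * e, theta,
                            stats::runif(1, 0.20, 0.35), object_id)
      acc <<- .paintEllipse(acc, cen[1], cen[2], R, R * e, theta,
                            -stats::runif(1, 0.35, 0.55), object_id)
      objects <<- rbind(objects, data.frame(class = "rock",
                                            posture = NA_character_,
                                            contrast = NA_real_))
    }

    kinds <- c(rep("whale", spec$n_whales), rep("ship", spec$n_ships),
               rep("rock", spec$n_rocks))
    postures <- character(0)
    for (kind in kinds) {
      before <- object_id
      if (kind == "whale") postures <- c(postures, paintWhale())
      else if (kind == "ship") paintShip()
      else paintRock()
      ## tight box over the object's painted extent (union of its parts)
      ids <- as.character(seq.int(before + 1L, object_id))
      ebbs <- acc$extent[ids]
      ebbs <- ebbs[!vapply(ebbs, is.null, logical(1))]
      stopifnot(length(ebbs) > 0L)
      bb <- Reduce(function(a, b) c(pmin(a[1:2], b[1:2]), pmax(a[3:4], b[3:4])),
                   ebbs)
      placed <- rbind(placed, data.frame(
        x_min = bb[1], y_min = bb[2], x_max = bb[3], y_max = bb[4],
        class = if (kind == "rock") "water_rock" else kind,
        posture = if (kind == "whale") postures[length(postures)]
                  else NA_character_))
    }

    ## water base + wave texture + glint
    base <- c(0.10, 0.20, 0.30) + stats::runif(3, -0.02, 0.02)
    tex <- blurMatrix(matrix(stats::runif(h * w, -1, 1), h, w), sigma = 1.5)
    tex <- tex / max(1e-9, stats::sd(tex)) * 0.035 * spec$sea_state
    glintLayer <- matrix(0, h, w)
    if (spec$glint > 0) {
      nspark <- stats::rbinom(1, h * w, 0.0015 * spec$glint)
      if (nspark > 0) {
        idx <- sample.int(h * w, nspark)
        glintLayer[idx] <- stats::runif(nspark, 0.3, 0.6)
        glintLayer <- blurMatrix(glintLayer, 0.6)
      }
    }
    img <- array(0, c(h, w, 3L))
    chw <- c(1.0, 0.99, 0.92)   # objects are slightly warm against blue water
    for (ch in 1:3)
      img[, , ch] <- clampRange(base[ch] + tex + glintLayer +
                                acc$delta * chw[ch])

    gtBoxes <- placed[placed$class %in% c("whale", "ship"), , drop = FALSE]
    rownames(gtBoxes) <- NULL
    list(scene = Scene(img, px, siteId = site_id),
         annotation = SceneAnnotation(gtBoxes, sceneRef = site_id),
         layers = list(objects = acc$delta, mask = acc$mask),
         objects = objects)
  })
}

## pixel sizes of the satellite/aerial sensors the generator emulates
.sensorPixelSizes <- c(0.15, 0.31, 0.46, 0.61, 1.5)

## build a patch-sized spec derived from a template
.patchSpec <- function(template, patch_size, pixel_size, n_whales, n_ships,
                       n_rocks, seed) {
  extent_m <- patch_size * pixel_size
  len <- template$whale_length_m
  len[2] <- min(len[2], extent_m * 0.35)   # whales must fit the patch
  len[1] <- min(len[1], len[2] * 0.9)
  sceneSpec(width_m = extent_m, height_m = extent_m, pixel_size = pixel_size,
            n_whales = n_whales, n_ships = n_ships, n_rocks = n_rocks,
            posture_mix = template$posture_mix,
            sea_state = template$sea_state, glint = template$glint,
            whale_length_m = len, seed = seed,
            max_attempts = template$max_attempts)
}

## render one curated classification patch: the labelling object fully
## visible, as in training sets built from photo libraries
.curatedPatch <- function(cls, patch_size, pixel_size, template, si, i) {
  spec <- .patchSpec(template, patch_size, pixel_size,
                     n_whales = as.integer(cls == "whale"),
                     n_ships = as.integer(cls == "ship"),
                     n_rocks = if (cls == "water_rock")
                       withSeed(si + 1L, stats::rbinom(1, 1, 0.5)) else 0L,
                     seed = si)
  g <- generateScene(spec, site_id = sprintf("patch_%05d", i))
  list(img = g$scene@image,
       posture = if (cls == "whale") g$objects$posture[1] else NA_character_)
}

## render one labelled classification patch as a window cropped from a
## larger mini-scene, so patches exhibit what deployed grid cells see:
## the labelling object (its centre inside the window, label priority
## whale > ship > water_rock) plus partial neighbours overhanging the
## window border — foam arcs, hull edges, whale flukes from next cells.
.classPatch <- function(cls, patch_size, pixel_size, template, si, i) {
  canvas <- 2L * patch_size
  counts <- withSeed(si + 1L, switch(cls,
    whale = c(1L, stats::rbinom(1, 1, 0.15), stats::rbinom(1, 1, 0.30)),
    ship = c(0L, 1L, stats::rbinom(1, 1, 0.30)),
    water_rock = c(stats::rbinom(1, 1, 0.25), stats::rbinom(1, 1, 0.25),
                   stats::rbinom(1, 1, 0.50))))
  ## crowded draws on a small canvas may defeat placement; degrade by
  ## dropping the extra confusers, then the canvas stays labelled by the
  ## remaining object
  need <- switch(cls, whale = c(1L, 0L, 0L), ship = c(0L, 1L, 0L),
                 water_rock = c(0L, 0L, counts[3]))
  g <- NULL
  for (att in 0:2) {
    trial <- if (att < 2) pmax(counts - att * (counts - need), need) else need
    spec <- .patchSpec(template, canvas, pixel_size,
                       n_whales = trial[1], n_ships = trial[2],
                       n_rocks = trial[3], seed = si + att)
    g <- tryCatch(generateScene(spec, site_id = sprintf("patch_%05d", i)),
                  error = function(e) NULL)
    if (!is.null(g)) break
  }
  if (is.null(g)) stop("could not render classification patch ", i,
                       call. = FALSE)
  full <- g$scene@image
  H <- dim(full)[1]; W <- dim(full)[2]
  S <- min(patch_size, H, W)
  b <- annotationBoxes(g$annotation)
  cx <- (b$x_min + b$x_max) / 2; cy <- (b$y_min + b$y_max) / 2
  withSeed(si + 2L, {
    pickWindow <- function() {
      target <- if (cls == "whale") which(b$class == "whale")[1]
                else if (cls == "ship") which(b$class == "ship")[1]
                else NA_integer_
      for (att in 1:40) {
        if (!is.na(target)) {
          ## window must contain the labelling object's centre
          x0 <- round(stats::runif(1, max(0, cx[target] - S + 2),
                                   min(W - S, cx[target] - 2)))
          y0 <- round(stats::runif(1, max(0, cy[target] - S + 2),
                                   min(H - S, cy[target] - 2)))
        } else {
          x0 <- sample.int(W - S + 1L, 1L) - 1L
          y0 <- sample.int(H - S + 1L, 1L) - 1L
        }
        inwin <- cx >= x0 & cx < x0 + S & cy >= y0 & cy < y0 + S
        lab <- if (any(inwin & b$class == "whale")) "whale"
               else if (any(inwin & b$class == "ship")) "ship"
               else "water_rock"
        if (lab == cls) return(c(x0, y0))
      }
      NULL
    }
    win <- pickWindow()
    if (is.null(win)) {
      ## fall back: a clean window exists in an object-free rendering
      spec2 <- .patchSpec(template, patch_size, pixel_size, 0L, 0L,
                          if (cls == "water_rock") counts[3] else 0L,
                          seed = si + 3L)
      g2 <- generateScene(spec2, site_id = sprintf("patch_%05d", i))
      return(list(img = g2$scene@image,
                  posture = NA_character_))
    }
    img <- full[win[2] + seq_len(S), win[1] + seq_len(S), , drop = FALSE]
    posture <- NA_character_
    if (cls == "whale") {
      inwin <- cx >= win[1] & cx < win[1] + S & cy >= win[2] & cy < win[2] + S
      wi <- which(inwin & b$class == "whale")[1]
      if ("posture" %in% names(b)) posture <- b$posture[wi]
    }
    list(img = img, posture = posture)
  })
}

#' Generate a labelled three-class classification patch set
#'
#' Emits exactly `3 * n_per_class` patches over the classes whale, ship and
#' water + submerged rocks (exact class balance), with a stratified
#' train/validation split manifest. Each patch is a window cropped from a
#' larger rendered mini-scene and labelled by the centre rule used for
#' survey cells (whale > ship > water_rock priority), so patches include
#' partial neighbouring objects overhanging the border, as deployed grid
#' cells do. Whale patches carry a posture tag; water_rock patches are
#' pure sea, foam-ringed rocks, or sea crossed by partial confusers whose
#' centres lie outside. Pixel size per patch is drawn from a grid of VHR
#' sensor resolutions (0.15–1.5 m).
#'
#' @param n_per_class patches per class (>= 1)
#' @param patch_size patch side length in pixels
#' @param template a [sceneSpec()] supplying sea state, glint, posture mix
#' @param seed master seed; per-patch streams are derived from it
#' @param val_fraction fraction per class assigned to the validation split
#' @param pixel_sizes grid of metres-per-pixel values patches are sampled
#'   from (one draw per patch)
#' @param style `"cells"` (default) emulates survey grid cells: each patch
#'   is a window cropped from a larger mini-scene, labelled by the centre
#'   rule, with partial neighbours overhanging the border; `"curated"`
#'   emulates photo-library training images with the labelling object
#'   fully visible
#' @param dir when given, patches are written as PNG under `dir` together
#'   with a JSON manifest, and file names are returned instead of arrays
#' @return list of class "whalePatchSet": `patches` (arrays or file names),
#'   `labels`, `postures`, `pixel_sizes`, `split` ("train"/"val"),
#'   `manifest` (data.frame), `seed`
#' @export
generateClassificationDataset <- function(n_per_class, patch_size = 224,
                                          template = sceneSpec(),
                                          seed = 1L, val_fraction = 0.2,
                                          pixel_sizes = .sensorPixelSizes,
                                          style = c("cells", "curated"),
                                          dir = NULL) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (patch_size < 8L) stop("patch_size too small", call. = FALSE)
  style <- match.arg(style)
  classes <- rep(WHALE_CLASSES, each = n_per_class)
  n <- length(classes)
  patches <- vector("list", n)
  postures <- rep(NA_character_, n)
  psizes <- numeric(n)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (i in seq_len(n)) {
    si <- deriveSeed(seed, i)
    ps <- withSeed(si, sample(pixel_sizes, 1L))
    cls <- classes[i]
    pc <- if (style == "cells")
      .classPatch(cls, patch_size, ps, template, si, i)
    else .curatedPatch(cls, patch_size, ps, template, si, i)
    img <- pc$img
    if (any(dim(img)[1:2] != patch_size))
      img <- resizeImage(img, patch_size, patch_size)
    postures[i] <- pc$posture
    psizes[i] <- ps
    if (is.null(dir)) patches[[i]] <- img
    else {
      fn <- sprintf("%s_%05d.png", cls, i)
      png::writePNG(clampRange(img), file.path(dir, fn))
      patches[[i]] <- fn
    }
  }
  ## stratified split: deterministic per class
  split <- rep("train", n)
  for (cls in WHALE_CLASSES) {
    idx <- which(classes == cls)
    nval <- floor(length(idx) * val_fraction)
    if (nval > 0) {
      vi <- withSeed(deriveSeed(seed, match(cls, WHALE_CLASSES) * 1000003L),
                     sample(idx, nval))
      split[vi] <- "val"
    }
  }
  manifest <- data.frame(id = seq_len(n),
                         file = if (is.null(dir)) NA_character_
                                else unlist(patches),
                         class = classes, posture = postures,
                         pixel_size = psizes, split = split, seed = seed,
                         stringsAsFactors = FALSE)
  if (!is.null(dir))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  structure(list(patches = patches, labels = classes, postures = postures,
                 pixel_sizes = psizes, split = split, manifest = manifest,
                 seed = seed),
            class = "whalePatchSet")
}

#' Generate a whale-detection patch set with bounding boxes
#'
#' Images contain whales and sea background only; the number of whales per
#' image is Poisson with the configured mean density, so some images are
#' pure background (usable as negatives). The default density of 1.35
#' boxes/image matches the composition of published detection training
#' sets of this kind (945 boxes over 700 images).
#'
#' @param n_images number of patches (>= 1)
#' @param patch_size side length in pixels
#' @param boxes_per_image mean whales per image (Poisson)
#' @param template a [sceneSpec()] template
#' @param seed master seed
#' @param pixel_sizes grid of metres-per-pixel values images are sampled from
#' @param dir optional output directory (PNG + COCO JSON + manifest)
#' @return list of class "whaleDetectionSet": `patches`, `boxes` (list of
#'   data.frames with posture tags), `total_boxes`, `manifest`, `seed`
#' @export
generateDetectionDataset <- function(n_images, patch_size = 224,
                                     boxes_per_image = 1.35,
                                     template = sceneSpec(), seed = 1L,
                                     pixel_sizes = .sensorPixelSizes,
                                     dir = NULL) {
  if (n_images < 1L) stop("n_images must be >= 1", call. = FALSE)
  if (boxes_per_image < 0) stop("box density must be >= 0", call. = FALSE)
  patches <- vector("list", n_images)
  boxes <- vector("list", n_images)
  psizes <- numeric(n_images)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  anns <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- deriveSeed(seed, 7000000L + i)
    draw <- withSeed(si, list(k = stats::rpois(1, boxes_per_image),
                              ps = sample(pixel_sizes, 1L)))
    spec <- .patchSpec(template, patch_size, draw$ps,
                       n_whales = draw$k, n_ships = 0L, n_rocks = 0L,
                       seed = si)
    g <- generateScene(spec, site_id = sprintf("det_%05d", i))
    img <- g$scene@image
    sy <- patch_size / dim(img)[1]; sx <- patch_size / dim(img)[2]
    if (any(dim(img)[1:2] != patch_size))
      img <- resizeImage(img, patch_size, patch_size)
    b <- annotationBoxes(g$annotation)
    if (nrow(b)) {
      b$x_min <- b$x_min * sx; b$x_max <- b$x_max * sx
      b$y_min <- b$y_min * sy; b$y_max <- b$y_max * sy
    }
    boxes[[i]] <- b
    psizes[i] <- draw$ps
    anns[[i]] <- SceneAnnotation(b, sceneRef = sprintf("det_%05d.png", i))
    if (is.null(dir)) patches[[i]] <- img
    else {
      fn <- sprintf("det_%05d.png", i)
      png::writePNG(clampRange(img), file.path(dir, fn))
      patches[[i]] <- fn
    }
  }
  total <- sum(vapply(boxes, nrow, integer(1)))
  manifest <- data.frame(id = seq_len(n_images),
                         file = if (is.null(dir)) NA_character_
                                else unlist(patches),
                         n_boxes = vapply(boxes, nrow, integer(1)),
                         pixel_size = psizes, seed = seed,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    writeCOCO(anns, file.path(dir, "annotations.json"),
              image_sizes = stats::setNames(
                rep(list(c(patch_size, patch_size)), n_images),
                vapply(anns, function(a) a@sceneRef, character(1))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  structure(list(patches = patches, boxes = boxes, total_boxes = total,
                 manifest = manifest, seed = seed),
            class = "whaleDetectionSet")
}
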