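## Training-time augmentation for classification and detection patches.
## Geometric ops transform bounding boxes consistently with the image;
## photometric augmentation is limited to brightness.

#' Augmentation configuration
#'
#' The recipe applied to every training patch: random rotation in
#' `[0, rotation_range_deg]`, horizontal flip of half the images, random
#' crop retaining at least `crop_min_fraction` of the area (then resized
#' back), isotropic rescale within `scale_range`, and a brightness
#' multiplier drawn from `[1 - f, 1 + f]` with `f = brightness_max_factor`
#' (up to 50% by default).
#'
#' @param rotation_range_deg maximum rotation angle, within `[0, 360]`
#' @param flip_probability probability of a horizontal flip, in `[0, 1]`
#' @param crop enable random cropping
#' @param crop_min_fraction minimum retained area fraction when cropping
#' @param scale_range multiplicative rescale bounds
#' @param brightness_max_factor maximum brightness deviation, in `[0, 1]`
#' @param min_box_area_fraction boxes whose visible area falls below this
#'   fraction of their original area are dropped (degenerate targets)
#' @param out_size optional output side length in pixels (model input size)
#' @return validated list of class "augmentConfig"
#' @export
augmentConfig <- function(rotation_range_deg = 360, flip_probability = 0.5,
                          crop = TRUE, crop_min_fraction = 0.7,
                          scale_range = c(0.75, 1.25),
                          brightness_max_factor = 0.5,
                          min_box_area_fraction = 0.25, out_size = NULL) {
  if (rotation_range_deg < 0 || rotation_range_deg > 360)
    stop("rotation_range_deg must lie in [0, 360]", call. = FALSE)
  if (flip_probability < 0 || flip_probability > 1)
    stop("flip_probability must lie in [0, 1]", call. = FALSE)
  if (brightness_max_factor < 0 || brightness_max_factor > 1)
    stop("brightness_max_factor must lie in [0, 1]", call. = FALSE)
  if (crop_min_fraction <= 0 || crop_min_fraction > 1)
    stop("crop_min_fraction must lie in (0, 1]", call. = FALSE)
  if (length(scale_range) != 2L || any(scale_range <= 0) ||
      scale_range[1] > scale_range[2])
    stop("scale_range must be positive increasing bounds", call. = FALSE)
  structure(list(rotation_range_deg = rotation_range_deg,
                 flip_probability = flip_probability, crop = crop,
                 crop_min_fraction = crop_min_fraction,
                 scale_range = scale_range,
                 brightness_max_factor = brightness_max_factor,
                 min_box_area_fraction = min_box_area_fraction,
                 out_size = out_size),
            class = "augmentConfig")
}

## rotate an image by angle (degrees, clockwise) about its centre;
## exposed corners are filled by reflection, consistent with tiling padding
.rotateImage <- function(img, angle_deg) {
  h <- dim(img)[1]; w <- dim(img)[2]
  th <- angle_deg * pi / 180
  cx <- w / 2; cy <- h / 2
  xo <- rep(seq_len(w) - 0.5, each = h)
  yo <- rep(seq_len(h) - 0.5, times = w)
  ## inverse map: source = centre + R(-theta) (dest - centre)
  dx <- xo - cx; dy <- yo - cy
  sx <- cx + cos(th) * dx + sin(th) * dy
  sy <- cy - sin(th) * dx + cos(th) * dy
  x0 <- floor(sx - 0.5); y0 <- floor(sy - 0.5)
  fx <- sx - 0.5 - x0;   fy <- sy - 0.5 - y0
  ix0 <- reflectIndex(x0 + 1L, w); ix1 <- reflectIndex(x0 + 2L, w)
  iy0 <- reflectIndex(y0 + 1L, h); iy1 <- reflectIndex(y0 + 2L, h)
  out <- array(0, dim(img))
  for (ch in 1:3) {
    m <- img[, , ch]
    v <- (m[cbind(iy0, ix0)] * (1 - fx) + m[cbind(iy0, ix1)] * fx) * (1 - fy) +
         (m[cbind(iy1, ix0)] * (1 - fx) + m[cbind(iy1, ix1)] * fx) * fy
    out[, , ch] <- matrix(v, h, w)
  }
  out
}

## forward-map boxes through the same clockwise rotation (corners -> AABB)
.rotateBoxes <- function(boxes, angle_deg, w, h) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(boxes)
  th <- angle_deg * pi / 180
  cx <- w / 2; cy <- h / 2
  for (i in seq_len(nrow(boxes))) {
    xs <- c(boxes$x_min[i], boxes$x_max[i], boxes$x_min[i], boxes$x_max[i])
    ys <- c(boxes$y_min[i], boxes$y_min[i], boxes$y_max[i], boxes$y_max[i])
    dx <- xs - cx; dy <- ys - cy
    nx <- cx + cos(th) * dx - sin(th) * dy
    ny <- cy + sin(th) * dx + cos(th) * dy
    boxes$x_min[i] <- min(nx); boxes$x_max[i] <- max(nx)
    boxes$y_min[i] <- min(ny); boxes$y_max[i] <- max(ny)
  }
  boxes
}

#' Augment one training patch (and its boxes)
#'
#' Applies, in order: rotation, horizontal flip, random crop + resize,
#' isotropic rescale, brightness. Draws come from the current RNG stream,
#' so seed once per dataset pass. Boxes are transformed with the geometry,
#' clipped to the output, and dropped (with a warning) when their visible
#' area falls below the configured fraction of their original area. With
#' the identity configuration (rotation 0, flip off, crop off, scale
#' `c(1, 1)`, brightness factor 0) the output is pixel-identical to the
#' input.
#'
#' @param image RGB array (height x width x 3)
#' @param boxes optional data.frame of boxes within the image
#' @param config an [augmentConfig()]
#' @return list with `image` (side length `out_size` if configured, else
#'   unchanged) and `boxes`
#' @export
augmentPatch <- function(image, boxes = NULL, config = augmentConfig()) {
  stopifnot(inherits(config, "augmentConfig"))
  assertImage(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  orig_area <- if (!is.null(boxes) && nrow(boxes)) boxArea(boxes) else numeric(0)

  ## rotation
  if (config$rotation_range_deg > 0) {
    ang <- stats::runif(1, 0, config$rotation_range_deg)
    image <- .rotateImage(image, ang)
    boxes <- .rotateBoxes(boxes, ang, w, h)
  }
  ## horizontal flip
  if (config$flip_probability > 0 &&
      stats::runif(1) < config$flip_probability) {
    image <- image[, rev(seq_len(w)), , drop = FALSE]
    if (!is.null(boxes) && nrow(boxes)) {
      x0 <- boxes$x_min
      boxes$x_min <- w - boxes$x_max
      boxes$x_max <- w - x0
    }
  }
  ## random crop, resized back
  if (isTRUE(config$crop)) {
    f <- stats::runif(1, config$crop_min_fraction, 1)
    s <- sqrt(f)
    ch_ <- max(2L, round(h * s)); cw_ <- max(2L, round(w * s))
    oy <- sample.int(h - ch_ + 1L, 1L) - 1L
    ox <- sample.int(w - cw_ + 1L, 1L) - 1L
    image <- image[oy + seq_len(ch_), ox + seq_len(cw_), , drop = FALSE]
    image <- resizeImage(image, h, w)
    if (!is.null(boxes) && nrow(boxes)) {
      boxes$x_min <- (boxes$x_min - ox) * w / cw_
      boxes$x_max <- (boxes$x_max - ox) * w / cw_
      boxes$y_min <- (boxes$y_min - oy) * h / ch_
      boxes$y_max <- (boxes$y_max - oy) * h / ch_
    }
  }
  ## isotropic rescale back onto the same canvas
  if (!(config$scale_range[1] == 1 && config$scale_range[2] == 1)) {
    s <- stats::runif(1, config$scale_range[1], config$scale_range[2])
    nh <- max(2L, round(h * s)); nw <- max(2L, round(w * s))
    scaled <- resizeImage(image, nh, nw)
    offy <- floor((nh - h) / 2); offx <- floor((nw - w) / 2)
    ## centre-crop when larger, reflect-pad when smaller
    iy <- reflectIndex(offy + seq_len(h), nh)
    ix <- reflectIndex(offx + seq_len(w), nw)
    image <- scaled[iy, ix, , drop = FALSE]
    if (!is.null(boxes) && nrow(boxes)) {
      boxes$x_min <- boxes$x_min * nw / w - offx
      boxes$x_max <- boxes$x_max * nw / w - offx
      boxes$y_min <- boxes$y_min * nh / h - offy
      boxes$y_max <- boxes$y_max * nh / h - offy
    }
  }
  ## brightness: multiplier in [1 - f, 1 + f], clamped to valid range
  if (config$brightness_max_factor > 0) {
    m <- stats::runif(1, 1 - config$brightness_max_factor,
                      1 + config$brightness_max_factor)
    image <- clampRange(image * m)
  }
  ## clip boxes; drop degenerate targets
  if (!is.null(boxes) && nrow(boxes)) {
    boxes$x_min <- clampRange(boxes$x_min, 0, w)
    boxes$x_max <- clampRange(boxes$x_max, 0, w)
    boxes$y_min <- clampRange(boxes$y_min, 0, h)
    boxes$y_max <- clampRange(boxes$y_max, 0, h)
    keep <- boxArea(boxes) >= config$min_box_area_fraction * orig_area
    if (any(!keep))
      warning(sum(!keep), " box(es) dropped below minimum visible area",
              call. = FALSE)
    boxes <- boxes[keep, , drop = FALSE]
  }
  ## model input size
  if (!is.null(config$out_size) &&
      any(dim(image)[1:2] != config$out_size)) {
    sy <- config$out_size / h; sx <- config$out_size / w
    image <- resizeImage(image, config$out_size, config$out_size)
    if (!is.null(boxes) && nrow(boxes)) {
      boxes$x_min <- boxes$x_min * sx; boxes$x_max <- boxes$x_max * sx
      boxes$y_min <- boxes$y_min * sy; boxes$y_max <- boxes$y_max * sy
    }
  }
  list(image = image, boxes = boxes)
}
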