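## Internal utilities: seeded evaluation, box geometry, raster helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded helpers do not
#' perturb the global stream.
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive an independent child seed from a master seed and an index
#'
#' Linear-congruential mixing keeps scene-level streams stable under
#' parallel or out-of-order generation. Result is a valid 32-bit seed.
#' @noRd
deriveSeed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  for (k in seq_len(2L)) s <- (s * 48271 + as.double(index) * 8191 + 1) %% 2147483647
  as.integer(s)
}

#' Clamp numeric values into [lo, hi]
#' @noRd
clampRange <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

## ---- bounding boxes ---------------------------------------------------
## Boxes are data.frames with half-open pixel coordinates
## (x_min, y_min, x_max, y_max), origin at the top-left corner, x rightward,
## y downward.

emptyBoxes <- function(score = FALSE) {
  df <- data.frame(x_min = numeric(0), y_min = numeric(0),
                   x_max = numeric(0), y_max = numeric(0),
                   class = character(0), stringsAsFactors = FALSE)
  if (score) df$score <- numeric(0)
  df
}

boxArea <- function(b) pmax(0, b$x_max - b$x_min) * pmax(0, b$y_max - b$y_min)

#' Intersection-over-union between one box and a set of boxes
#' @noRd
boxIoU <- function(a, b) {
  if (nrow(b) == 0L) return(numeric(0))
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  u <- boxArea(a) + boxArea(b) - inter
  ifelse(u > 0, inter / u, 0)
}

#' Pairwise IoU matrix between two box sets
#' @noRd
boxIoUMatrix <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(0, nrow(a), nrow(b)))
  m <- vapply(seq_len(nrow(a)),
              function(i) boxIoU(a[i, , drop = FALSE], b),
              numeric(nrow(b)))
  matrix(m, nrow = nrow(a), ncol = nrow(b), byrow = TRUE)
}

clipBoxes <- function(boxes, width, height) {
  if (nrow(boxes) == 0L) return(boxes)
  boxes$x_min <- clampRange(boxes$x_min, 0, width)
  boxes$x_max <- clampRange(boxes$x_max, 0, width)
  boxes$y_min <- clampRange(boxes$y_min, 0, height)
  boxes$y_max <- clampRange(boxes$y_max, 0, height)
  boxes[boxes$x_max > boxes$x_min & boxes$y_max > boxes$y_min, , drop = FALSE]
}

## ---- rasters ----------------------------------------------------------
## Images are numeric arrays height x width x 3 with values in [0, 1]
## (8-bit quantised on disk). Row index = y, column index = x.

assertImage <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be a height x width x 3 array", call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(what, " must have positive height and width", call. = FALSE)
  invisible(img)
}

#' Luminance (Rec. 601 weights) of an RGB array
#' @noRd
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Bilinear resize of an RGB array to out_h x out_w
#'
#' Edge-clamped sampling at pixel centres; deterministic and dependency-free
#' so model inputs are identical across platforms.
#' @noRd
resizeImage <- function(img, out_h, out_w) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h == out_h && w == out_w) return(img)
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- clampRange(floor(ys), 0, h - 1); x0 <- clampRange(floor(xs), 0, w - 1)
  y1 <- pmin(y0 + 1, h - 1);            x1 <- pmin(x0 + 1, w - 1)
  fy <- clampRange(ys - y0, 0, 1);      fx <- clampRange(xs - x0, 0, 1)
  out <- array(0, c(out_h, out_w, 3L))
  for (ch in 1:3) {
    m <- img[, , ch]
    a <- m[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
    b <- m[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
    cc <- m[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
    d <- m[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
    fya <- rep(fy, out_w); fxa <- rep(fx, each = out_h)
    v <- (a * (1 - fxa) + b * fxa) * (1 - fya) +
         (cc * (1 - fxa) + d * fxa) * fya
    out[, , ch] <- matrix(v, out_h, out_w)
  }
  out
}

#' Separable box-Gaussian blur of a matrix via band-matrix products
#' @noRd
blurMatrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(2.5 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  bandMat <- function(n) {
    B <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      idx <- seq_len(n)
      src <- clampRange(idx + j, 1, n)   # edge clamp
      B[cbind(idx, src)] <- B[cbind(idx, src)] + k[j + r + 1]
    }
    B
  }
  bandMat(nrow(m)) %*% m %*% t(bandMat(ncol(m)))
}

#' Reflect out-of-range indices back into [1, n]
#' @noRd
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

#' Truncate (not round) a fraction to a percentage with two decimals
#'
#' Printed survey percentages in this field are truncations: 14/68 prints
#' as 20.58, not 20.59. A half-ulp guard keeps exact ratios stable.
#' @param x fraction in [0, 1]
#' @return percentage truncated at two decimal places
#' @export
truncPct <- function(x) {
  stopifnot(is.numeric(x))
  trunc(x * 10000 + 1e-9) / 100
}

#' Hash a configuration object for provenance stamps
#' @noRd
configHash <- function(x) rlang::hash(x)
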