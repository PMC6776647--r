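## Tiling of survey scenes into grid cells and assignment of ground truth.
##
## Coordinate convention used throughout: pixel coordinates, origin at the
## top-left corner, x rightward, y downward, half-open intervals
## [x0, x1) x [y0, y1). Metric bounds are pixel bounds times pixelSize.

#' Tile a scene into grid cells
#'
#' Slides a square window of `cell_size_m` metres over the scene with a
#' stride of `stride_m` metres and returns the resulting grid cells in
#' row-major order. With stride equal to cell size the cells partition the
#' scene: every pixel belongs to exactly one cell. Cells extending past the
#' right/bottom edge are flagged `padded` (policies `pad-reflect` and
#' `pad-zero`) or omitted (`drop`).
#'
#' The default 71 m window is twice the length of the largest whales
#' (blue whales reach 30 m), so any whale fits entirely in at least one cell.
#'
#' @param scene a [Scene-class]
#' @param cell_size_m cell side length in metres (> 0)
#' @param stride_m stride between cell origins in metres (> 0)
#' @param pad_policy how to handle cells that extend past the scene edge:
#'   `"pad-reflect"` (default; mirrored content, avoids artificial dark
#'   borders), `"pad-zero"`, or `"drop"`
#' @return data.frame of cells: row, col (0-based), x0, y0, x1, y1 (pixel
#'   bounds, half-open; clipped to the scene), size_px (nominal side in
#'   pixels), padded (logical)
#' @examples
#' sc <- Scene(array(0.2, c(213, 213, 3)), pixelSize = 1)
#' nrow(tileScene(sc, 71, 71))  # 3 x 3 grid
#' @export
tileScene <- function(scene, cell_size_m = 71, stride_m = 71,
                      pad_policy = c("pad-reflect", "pad-zero", "drop")) {
  stopifnot(methods::is(scene, "Scene"))
  pad_policy <- match.arg(pad_policy)
  if (!is.finite(cell_size_m) || cell_size_m <= 0)
    stop("cell_size_m must be positive", call. = FALSE)
  if (!is.finite(stride_m) || stride_m <= 0)
    stop("stride_m must be positive", call. = FALSE)
  px <- scene@pixelSize
  size_px <- round(cell_size_m / px)
  stride_px <- round(stride_m / px)
  if (size_px < 1L) stop("cell smaller than one pixel", call. = FALSE)
  if (stride_px < 1L) stop("stride smaller than one pixel", call. = FALSE)
  d <- dim(scene@image); h <- d[1]; w <- d[2]

  x0s <- seq(0L, max(0L, w - 1L), by = stride_px)
  y0s <- seq(0L, max(0L, h - 1L), by = stride_px)
  grid <- expand.grid(col = seq_along(x0s) - 1L, row = seq_along(y0s) - 1L)
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]  # row-major
  x0 <- x0s[grid$col + 1L]; y0 <- y0s[grid$row + 1L]
  x1n <- x0 + size_px; y1n <- y0 + size_px  # nominal, may overrun
  padded <- x1n > w | y1n > h
  cells <- data.frame(row = grid$row, col = grid$col,
                      x0 = x0, y0 = y0,
                      x1 = pmin(x1n, w), y1 = pmin(y1n, h),
                      size_px = size_px, padded = padded)
  if (pad_policy == "drop") cells <- cells[!cells$padded, , drop = FALSE]
  attr(cells, "pad_policy") <- pad_policy
  attr(cells, "pixel_size") <- px
  attr(cells, "cell_size_m") <- cell_size_m
  rownames(cells) <- NULL
  cells
}

#' Extract the raster of one grid cell
#'
#' Returns the cell's sub-raster at its nominal size. For padded edge
#' cells the out-of-scene region is filled according to the tiling's pad
#' policy (mirror-reflected scene content or zeros).
#'
#' @param scene the parent [Scene-class]
#' @param cell one row of the data.frame produced by [tileScene()], or a
#'   list with the same fields
#' @param pad_policy override of the policy recorded at tiling time
#' @return RGB array of side `cell$size_px`
#' @export
extractCellImage <- function(scene, cell, pad_policy = NULL) {
  stopifnot(methods::is(scene, "Scene"))
  if (is.data.frame(cell)) {
    stopifnot(nrow(cell) == 1L)
    if (is.null(pad_policy)) pad_policy <- attr(cell, "pad_policy")
    cell <- as.list(cell)
  }
  if (is.null(pad_policy)) pad_policy <- "pad-reflect"
  d <- dim(scene@image); h <- d[1]; w <- d[2]
  size <- cell$size_px
  xs <- cell$x0 + seq_len(size)        # 1-based column indices, may overrun
  ys <- cell$y0 + seq_len(size)
  if (cell$x0 < 0 || cell$y0 < 0 || cell$x0 >= w || cell$y0 >= h)
    stop("cell does not originate inside the scene", call. = FALSE)
  if (pad_policy == "drop" && (max(xs) > w || max(ys) > h))
    stop("cell extends past the scene and pad policy is 'drop'",
         call. = FALSE)
  if (pad_policy == "pad-zero") {
    out <- array(0, c(size, size, 3L))
    inY <- ys <= h; inX <- xs <= w
    out[inY, inX, ] <- scene@image[ys[inY], xs[inX], , drop = FALSE]
    out
  } else {                             # pad-reflect
    scene@image[reflectIndex(ys, h), reflectIndex(xs, w), , drop = FALSE]
  }
}

#' Assign ground-truth boxes to grid cells
#'
#' Each ground-truth box is assigned to exactly one cell: the cell whose
#' half-open bounds contain the box centre. This prevents a whale lying on
#' a cell border from being counted twice. Cell labels follow the priority
#' whale > ship > water_rock; a cell with no assigned object is
#' water + submerged rocks.
#'
#' @param annotation a [SceneAnnotation-class] in scene pixel coordinates
#' @param cells data.frame from [tileScene()]
#' @param warn_unassigned warn when a box centre falls in no cell (possible
#'   under the `drop` pad policy)
#' @return data.frame: one row per cell with label, whale_count, posture
#'   (most frequent whale posture in the cell, NA otherwise) and a `boxes`
#'   list-column of cell-local whale boxes. Unassigned boxes are returned
#'   in attribute `"unassigned"`.
#' @export
assignGroundTruth <- function(annotation, cells, warn_unassigned = TRUE) {
  stopifnot(methods::is(annotation, "SceneAnnotation"))
  b <- annotation@boxes
  n <- nrow(cells)
  label <- rep("water_rock", n)
  count <- integer(n)
  posture <- rep(NA_character_, n)
  boxlist <- rep(list(emptyBoxes()), n)
  unassigned <- integer(0)
  if (nrow(b)) {
    cx <- (b$x_min + b$x_max) / 2
    cy <- (b$y_min + b$y_max) / 2
    for (i in seq_len(nrow(b))) {
      ## clipped bounds: a centre past the scene edge belongs to no cell
      hit <- which(cells$x0 <= cx[i] & cx[i] < cells$x1 &
                   cells$y0 <= cy[i] & cy[i] < cells$y1)
      ## with overlapping strides a centre can fall in several cells;
      ## the first (row-major) cell owns it
      if (!length(hit)) { unassigned <- c(unassigned, i); next }
      j <- hit[1L]
      if (b$class[i] == "whale") {
        label[j] <- "whale"
        count[j] <- count[j] + 1L
        loc <- b[i, c("x_min", "y_min", "x_max", "y_max", "class"),
                 drop = FALSE]
        loc$x_min <- loc$x_min - cells$x0[j]; loc$x_max <- loc$x_max - cells$x0[j]
        loc$y_min <- loc$y_min - cells$y0[j]; loc$y_max <- loc$y_max - cells$y0[j]
        if ("posture" %in% names(b)) loc$posture <- b$posture[i]
        rownames(loc) <- NULL
        boxlist[[j]] <- if (nrow(boxlist[[j]])) rbind(boxlist[[j]], loc)
                        else loc
        if ("posture" %in% names(b) && !is.na(b$posture[i]) &&
            is.na(posture[j])) posture[j] <- b$posture[i]
      } else if (b$class[i] == "ship" && label[j] != "whale") {
        label[j] <- "ship"
      }
    }
  }
  if (length(unassigned) && warn_unassigned)
    warning(length(unassigned), " ground-truth box(es) fall in no cell",
            call. = FALSE)
  out <- cells
  out$label <- label
  out$whale_count <- count
  out$posture <- posture
  out$boxes <- boxlist
  attr(out, "unassigned") <- if (length(unassigned))
    b[unassigned, , drop = FALSE] else emptyBoxes()
  out
}
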