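## Raster and annotation I/O.
##
## Rasters: PNG (and TIFF when the tiff package is installed) with the
## pixel size supplied either as an argument or in a JSON sidecar
## ("<image>.meta.json" with fields pixel_size, optional origin, site_id).
## Annotations: COCO-style detection JSON (categories whale=1, ship=2,
## boxes as [x, y, width, height]) and a flat CSV dialect
## (scene_id,x_min,y_min,x_max,y_max,class,posture).

#' Read a scene raster from disk
#'
#' @param path PNG or TIFF file
#' @param pixel_size metres per pixel; when NULL, read from the
#'   `<image>.meta.json` sidecar
#' @param site_id optional site identifier (defaults to sidecar value or
#'   file name)
#' @return a [Scene-class]
#' @export
readScene <- function(path, pixel_size = NULL, site_id = NULL) {
  meta <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size
  if (is.null(pixel_size))
    stop("pixel_size not given and no sidecar found for ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  Scene(img, pixel_size,
        origin = if (!is.null(meta$origin)) as.numeric(meta$origin) else numeric(0),
        siteId = site_id %||% meta$site_id %||%
          tools::file_path_sans_ext(basename(path)))
}

#' Write a scene raster (PNG) plus its JSON metadata sidecar
#'
#' @param scene a [Scene-class]
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
writeScene <- function(scene, path) {
  stopifnot(methods::is(scene, "Scene"))
  png::writePNG(clampRange(scene@image), path)
  meta <- list(pixel_size = scene@pixelSize, site_id = scene@siteId)
  if (length(scene@origin)) meta$origin <- scene@origin
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write annotations as flat CSV
#'
#' One row per box: scene_id,x_min,y_min,x_max,y_max,class,posture.
#' @param annotations a [SceneAnnotation-class] or list of them
#' @param path output CSV path
#' @export
writeBoxesCSV <- function(annotations, path) {
  if (methods::is(annotations, "SceneAnnotation"))
    annotations <- list(annotations)
  rows <- lapply(annotations, function(a) {
    b <- a@boxes
    if (!nrow(b)) return(NULL)
    if (!"posture" %in% names(b)) b$posture <- NA_character_
    data.frame(scene_id = a@sceneRef,
               b[, c("x_min", "y_min", "x_max", "y_max", "class", "posture")])
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(scene_id = character(0), x_min = numeric(0),
                     y_min = numeric(0), x_max = numeric(0),
                     y_max = numeric(0), class = character(0),
                     posture = character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read annotations from flat CSV
#' @param path CSV written by [writeBoxesCSV()]
#' @return named list of [SceneAnnotation-class], one per scene_id
#' @export
readBoxesCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$scene_id), function(d)
    SceneAnnotation(d[, setdiff(names(d), "scene_id"), drop = FALSE],
                    sceneRef = d$scene_id[1]))
  out[unique(df$scene_id)]
}

#' Write annotations as COCO-style detection JSON
#'
#' Categories: whale = 1, ship = 2. Boxes are stored as
#' `[x_min, y_min, width, height]`; whale boxes keep their posture tag.
#' @param annotations list of [SceneAnnotation-class]
#' @param path output JSON path
#' @param image_sizes optional named list of c(width, height) per sceneRef
#' @export
writeCOCO <- function(annotations, path, image_sizes = NULL) {
  if (methods::is(annotations, "SceneAnnotation"))
    annotations <- list(annotations)
  images <- list(); anns <- list(); aid <- 0L
  catmap <- c(whale = 1L, ship = 2L)
  for (i in seq_along(annotations)) {
    a <- annotations[[i]]
    sz <- image_sizes[[a@sceneRef]] %||% c(NA_real_, NA_real_)
    images[[i]] <- list(id = i, file_name = a@sceneRef,
                        width = sz[1], height = sz[2])
    b <- a@boxes
    for (j in seq_len(nrow(b))) {
      if (!b$class[j] %in% names(catmap)) next  # water_rock has no boxes
      aid <- aid + 1L
      ann <- list(id = aid, image_id = i,
                  category_id = unname(catmap[b$class[j]]),
                  bbox = c(b$x_min[j], b$y_min[j],
                           b$x_max[j] - b$x_min[j], b$y_max[j] - b$y_min[j]),
                  area = (b$x_max[j] - b$x_min[j]) * (b$y_max[j] - b$y_min[j]),
                  iscrowd = 0L)
      if ("posture" %in% names(b) && !is.na(b$posture[j]))
        ann$posture <- b$posture[j]
      anns[[aid]] <- ann
    }
  }
  obj <- list(images = images, annotations = anns,
              categories = list(list(id = 1L, name = "whale"),
                                list(id = 2L, name = "ship")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read COCO-style detection JSON
#' @param path JSON written by [writeCOCO()] or compatible
#' @return named list of [SceneAnnotation-class], one per image
#' @export
readCOCO <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cats <- stats::setNames(
    vapply(obj$categories, function(c) c$name, character(1)),
    vapply(obj$categories, function(c) as.character(c$id), character(1)))
  imgs <- stats::setNames(
    vapply(obj$images, function(im) im$file_name, character(1)),
    vapply(obj$images, function(im) as.character(im$id), character(1)))
  rows <- lapply(obj$annotations, function(a) {
    bb <- as.numeric(a$bbox)
    data.frame(image_id = as.character(a$image_id),
               x_min = bb[1], y_min = bb[2],
               x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
               class = unname(cats[as.character(a$category_id)]),
               posture = if (!is.null(a$posture)) a$posture else NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0))
  out <- lapply(names(imgs), function(id) {
    d <- df[df$image_id == id, setdiff(names(df), "image_id"), drop = FALSE]
    if (!nrow(d)) d <- emptyBoxes()
    SceneAnnotation(d, sceneRef = imgs[[id]])
  })
  stats::setNames(out, unname(imgs))
}

#' Write a per-cell table as CSV
#'
#' Columns: site_id,row,col,x0,y0,x1,y1,label,whale_count,posture.
#' @param cells data.frame from [assignGroundTruth()] or a SurveyReport's
#'   cells
#' @param path output CSV path
#' @param site_id site identifier stamped on every row
#' @export
writeCellTable <- function(cells, path, site_id = "site") {
  keep <- intersect(c("row", "col", "x0", "y0", "x1", "y1", "label",
                      "whale_count", "posture"), names(cells))
  df <- cbind(site_id = site_id, as.data.frame(cells)[, keep, drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell table written by [writeCellTable()]
#' @param path CSV path
#' @return data.frame
#' @export
readCellTable <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
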