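test_that("tiling divides exact multiples into unpadded row-major grids", {
  sc <- Scene(array(0.2, c(213, 213, 3)), pixelSize = 1)
  cells <- tileScene(sc, 71, 71)
  expect_equal(nrow(cells), 9L)
  expect_false(any(cells$padded))
  ## row-major ordering
  expect_equal(cells$row, rep(0:2, each = 3))
  expect_equal(cells$col, rep(0:2, times = 3))
  expect_equal(cells$x1 - cells$x0, rep(71L, 9))
})

test_that("tiling pads or drops edge cells as configured", {
  sc <- Scene(array(0.2, c(100, 150, 3)), pixelSize = 1)
  ## ceil(150/71) x ceil(100/71) = 3 x 2, right/bottom cells padded
  cells <- tileScene(sc, 71, 71, "pad-reflect")
  expect_equal(nrow(cells), 6L)
  expect_equal(sum(cells$padded), 4L)
  expect_true(all(cells$padded[cells$col == 2 | cells$row == 1]))

  tiny <- Scene(array(0.2, c(40, 40, 3)), pixelSize = 1)
  expect_equal(nrow(tileScene(tiny, 71, 71, "drop")), 0L)
  expect_equal(nrow(tileScene(tiny, 71, 71, "pad-zero")), 1L)
})

test_that("tiling respects pixel size and rejects invalid arguments", {
  sc <- Scene(array(0.2, c(100, 100, 3)), pixelSize = 0.5)  # 50 x 50 m
  cells <- tileScene(sc, 25, 25)   # 50 px cells
  expect_equal(nrow(cells), 4L)
  expect_equal(unique(cells$x1 - cells$x0), 50)
  ## metric invariant within one pixel
  expect_true(all((cells$x1 - cells$x0) * 0.5 <= 25 + 0.5))

  expect_error(tileScene(sc, -1, 25), "positive")
  expect_error(tileScene(sc, 25, 0), "positive")
  expect_error(tileScene(sc, 0.1, 0.1), "smaller than one pixel")
})

test_that("with stride = cell size the grid partitions every scene pixel", {
  for (dims in list(c(213, 213), c(100, 150), c(97, 211))) {
    sc <- Scene(array(0.2, c(dims, 3)), pixelSize = 1)
    cells <- tileScene(sc, 71, 71, "pad-zero")
    covered <- matrix(0L, dims[1], dims[2])
    for (i in seq_len(nrow(cells)))
      covered[(cells$y0[i] + 1):cells$y1[i], (cells$x0[i] + 1):cells$x1[i]] <-
        covered[(cells$y0[i] + 1):cells$y1[i], (cells$x0[i] + 1):cells$x1[i]] + 1L
    expect_true(all(covered == 1L), info = paste(dims, collapse = "x"))
  }
})

test_that("cell extraction crops interior cells pixel-identically", {
  set.seed(42)
  img <- array(runif(120 * 150 * 3), c(120, 150, 3))
  sc <- Scene(img, pixelSize = 1)
  cells <- tileScene(sc, 40, 40)
  interior <- cells[!cells$padded, ][1, , drop = FALSE]
  patch <- extractCellImage(sc, interior)
  expect_identical(patch,
                   img[(interior$y0 + 1):(interior$y0 + 40),
                       (interior$x0 + 1):(interior$x0 + 40), , drop = FALSE])
  ## fully in-bounds cells are identical under every pad policy
  expect_identical(extractCellImage(sc, interior, "pad-zero"), patch)
  expect_identical(extractCellImage(sc, interior, "drop"), patch)
})

test_that("edge-cell padding fills out-of-scene pixels as configured", {
  img <- array(0.7, c(50, 50, 3))
  sc <- Scene(img, pixelSize = 1)
  cells <- tileScene(sc, 40, 40, "pad-zero")
  edge <- cells[cells$padded, ][1, , drop = FALSE]
  pz <- extractCellImage(sc, edge, "pad-zero")
  expect_equal(dim(pz), c(40, 40, 3))
  expect_true(all(pz[, 11:40, ] == 0))    # beyond x = 50
  pr <- extractCellImage(sc, edge, "pad-reflect")
  expect_true(all(pr == 0.7))             # reflection of constant scene
  expect_error(extractCellImage(sc, edge, "drop"), "drop")
})

test_that("ground truth assignment follows the centre rule and priority", {
  sc <- Scene(array(0.2, c(142, 142, 3)), pixelSize = 1)
  cells <- tileScene(sc, 71, 71)
  ## one whale centred in cell (0,0); one ship and one whale share cell (1,1)
  boxes <- data.frame(
    x_min = c(10, 80, 90), y_min = c(10, 80, 100),
    x_max = c(30, 100, 120), y_max = c(20, 95, 115),
    class = c("whale", "whale", "ship"),
    posture = c("logging", "submerged", NA))
  ga <- assignGroundTruth(SceneAnnotation(boxes), cells)
  expect_equal(ga$label, c("whale", "water_rock", "water_rock", "whale"))
  expect_equal(ga$whale_count, c(1L, 0L, 0L, 1L))
  expect_equal(ga$posture[1], "logging")
  ## cell-local coordinates of the assigned box
  expect_equal(ga$boxes[[4]]$x_min, 80 - 71)
  ## ship present but whale wins the label
  expect_equal(ga$label[4], "whale")
})

test_that("a straddling whale is counted once, in its centre cell", {
  sc <- Scene(array(0.2, c(142, 142, 3)), pixelSize = 1)
  cells <- tileScene(sc, 71, 71)
  ## box spans the vertical border at x = 71; centre at x = 65 -> left cell
  boxes <- data.frame(x_min = 50, y_min = 30, x_max = 80, y_max = 40,
                      class = "whale")
  ga <- assignGroundTruth(SceneAnnotation(boxes), cells)
  expect_equal(sum(ga$whale_count), 1L)
  expect_equal(ga$whale_count[1], 1L)
})

test_that("whale counts are conserved across random scenes and grids", {
  set.seed(2024)
  for (rep in 1:100) {
    W <- sample(80:400, 1); H <- sample(80:400, 1)
    n <- sample(0:12, 1)
    cellm <- sample(c(40, 71, 100), 1)
    boxes <- if (n > 0) {
      x0 <- runif(n, 0, W - 10); y0 <- runif(n, 0, H - 10)
      data.frame(x_min = x0, y_min = y0,
                 x_max = x0 + runif(n, 2, 30), y_max = y0 + runif(n, 2, 30),
                 class = sample(c("whale", "ship"), n, replace = TRUE))
    } else data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      class = character(0))
    sc <- Scene(array(0.2, c(H, W, 3)), pixelSize = 1)
    cells <- tileScene(sc, cellm, cellm, "pad-zero")
    ga <- suppressWarnings(
      assignGroundTruth(SceneAnnotation(boxes, "s"), cells))
    in_scene <- sum(boxes$class == "whale" &
                    (boxes$x_min + boxes$x_max) / 2 < W &
                    (boxes$y_min + boxes$y_max) / 2 < H)
    expect_equal(sum(ga$whale_count), in_scene)
    expect_equal(sum(attr(ga, "unassigned")$class == "whale"),
                 sum(boxes$class == "whale") - in_scene)
  }
})

test_that("scene and annotation constructors validate their invariants", {
  expect_error(Scene(array(0.2, c(10, 10, 4)), 1), "height x width x 3")
  expect_error(Scene(array(0.2, c(10, 10, 3)), -1), "pixelSize")
  expect_error(methods::validObject(
    SceneAnnotation(data.frame(x_min = 5, y_min = 5, x_max = 4, y_max = 9,
                               class = "whale"))), "positive extent")
  expect_error(methods::validObject(
    SceneAnnotation(data.frame(x_min = 1, y_min = 1, x_max = 4, y_max = 9,
                               class = "kraken"))), "class")
})
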