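test_that("scene generation is bit-identical under a fixed seed", {
  spec <- sceneSpec(n_whales = 3, n_ships = 1, n_rocks = 2, seed = 17)
  g1 <- generateScene(spec)
  g2 <- generateScene(spec)
  expect_identical(sceneImage(g1$scene), sceneImage(g2$scene))
  expect_identical(annotationBoxes(g1$annotation),
                   annotationBoxes(g2$annotation))
  expect_identical(g1$layers$mask, g2$layers$mask)
  ## a different seed changes the image
  g3 <- generateScene(sceneSpec(n_whales = 3, n_ships = 1, n_rocks = 2,
                                seed = 18))
  expect_false(identical(sceneImage(g1$scene), sceneImage(g3$scene)))
})

test_that("an empty spec renders pure sea with no boxes", {
  g <- generateScene(sceneSpec(seed = 4))
  expect_equal(nrow(annotationBoxes(g$annotation)), 0L)
  expect_true(all(g$layers$objects == 0))
  expect_true(all(g$layers$mask == 0L))
})

test_that("object counts and classes match the spec exactly", {
  g <- generateScene(sceneSpec(n_whales = 5, n_ships = 2, n_rocks = 3,
                               seed = 11))
  b <- annotationBoxes(g$annotation)
  expect_equal(sum(b$class == "whale"), 5L)
  expect_equal(sum(b$class == "ship"), 2L)
  ## rocks belong to the background class: no annotation boxes
  expect_equal(nrow(b), 7L)
  expect_equal(nrow(g$objects), 10L)
})

test_that("connected components of the clean layer recover the objects", {
  ## oracle: label the noise-free object layer; each placed object is one
  ## component (body + plume/wake/foam are contiguous)
  g <- generateScene(sceneSpec(n_whales = 5, seed = 11, width_m = 400,
                               height_m = 400))
  comps <- EBImage::bwlabel((abs(g$layers$objects) > 1e-9) * 1)
  expect_equal(max(comps), 5L)
  g2 <- generateScene(sceneSpec(n_whales = 2, n_ships = 2, n_rocks = 2,
                                seed = 23, width_m = 400, height_m = 400))
  comps2 <- EBImage::bwlabel((abs(g2$layers$objects) > 1e-9) * 1)
  expect_equal(max(comps2), 6L)
})

test_that("annotation boxes tightly contain the rendered whale masks", {
  g <- generateScene(sceneSpec(n_whales = 6, seed = 31, width_m = 300,
                               height_m = 300))
  b <- annotationBoxes(g$annotation)
  mask <- g$layers$mask
  for (i in seq_len(nrow(b))) {
    sel <- which(mask == i, arr.ind = TRUE)
    inside <- sel[, 2] - 1 >= b$x_min[i] & sel[, 2] <= b$x_max[i] &
              sel[, 1] - 1 >= b$y_min[i] & sel[, 1] <= b$y_max[i]
    expect_gte(mean(inside), 0.9)
  }
})

test_that("placement fails cleanly when the overlap budget is exceeded", {
  expect_error(
    generateScene(sceneSpec(width_m = 40, height_m = 40, n_ships = 30,
                            seed = 1, max_attempts = 20L)),
    "overlap budget")
})

test_that("posture contrast ordering matches surface activity", {
  ## generator invariant behind the detectability gradient: blowing and
  ## breaching whales carry more contrast than submerged ones
  mixes <- list(blowing = c(blowing = 1), breaching = c(breaching = 1),
                submerged = c(submerged = 1))
  mc <- vapply(names(mixes), function(m) {
    g <- generateScene(sceneSpec(n_whales = 6, posture_mix = mixes[[m]],
                                 seed = 7, width_m = 400, height_m = 400))
    mean(g$objects$contrast)
  }, numeric(1))
  expect_gt(mc[["blowing"]], mc[["submerged"]])
  expect_gt(mc[["breaching"]], mc[["submerged"]])
  ## presets themselves respect the documented bands
  pp <- posturePresets()
  expect_true(all(pp$contrast_min >= 0 & pp$contrast_max <= 1))
  expect_equal(pp$surface_fraction[pp$posture == "submerged"], 0)
  expect_true(all(pp$plume[pp$posture %in% c("blowing", "breaching")]))
})

test_that("classification patch sets are exactly balanced and reproducible", {
  ds <- generateClassificationDataset(4, patch_size = 48, seed = 10,
                                      pixel_sizes = 1.0)
  expect_length(ds$patches, 12L)
  expect_equal(as.integer(table(ds$labels)), rep(4L, 3))
  expect_true(all(!is.na(ds$postures[ds$labels == "whale"])))
  expect_true(all(is.na(ds$postures[ds$labels == "ship"])))
  expect_true(all(vapply(ds$patches, function(p)
    identical(dim(p), c(48L, 48L, 3L)), logical(1))))
  expect_true(all(ds$split %in% c("train", "val")))
  ds2 <- generateClassificationDataset(4, patch_size = 48, seed = 10,
                                       pixel_sizes = 1.0)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$patches, ds2$patches)
  expect_equal(nrow(ds$manifest), 12L)
  ## one patch per class at the minimum size
  d1 <- generateClassificationDataset(1, patch_size = 48, seed = 2)
  expect_equal(sort(d1$labels), sort(c("whale", "ship", "water_rock")))
})

test_that("detection sets report box totals and honour zero density", {
  dd <- generateDetectionDataset(25, patch_size = 48, seed = 13,
                                 pixel_sizes = 1.0)
  expect_length(dd$patches, 25L)
  expect_equal(dd$total_boxes, sum(vapply(dd$boxes, nrow, integer(1))))
  expect_equal(dd$manifest$n_boxes, vapply(dd$boxes, nrow, integer(1)))
  ## all boxes lie within the patch
  for (b in dd$boxes) if (nrow(b))
    expect_true(all(b$x_min >= 0 & b$x_max <= 48 &
                    b$y_min >= 0 & b$y_max <= 48))
  zero <- generateDetectionDataset(1, patch_size = 48, boxes_per_image = 0,
                                   seed = 5)
  expect_equal(zero$total_boxes, 0L)
  dd2 <- generateDetectionDataset(25, patch_size = 48, seed = 13,
                                  pixel_sizes = 1.0)
  expect_identical(dd$manifest, dd2$manifest)
})

test_that("on-disk datasets mirror the in-memory ones and reload", {
  dir <- withr::local_tempdir()
  ds <- generateClassificationDataset(2, patch_size = 48, seed = 8,
                                      pixel_sizes = 1.0, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "\\.png$"), 6L)
  re <- loadClassificationDataset(dir)
  expect_equal(re$labels, ds$labels)

  ddir <- withr::local_tempdir()
  dd <- generateDetectionDataset(4, patch_size = 48, seed = 8,
                                 pixel_sizes = 1.0, dir = ddir)
  expect_true(file.exists(file.path(ddir, "annotations.json")))
  rd <- loadDetectionDataset(ddir)
  expect_equal(vapply(rd$boxes, nrow, integer(1)),
               vapply(dd$boxes, nrow, integer(1)))
})

test_that("scene specs reject invalid parameters", {
  expect_error(sceneSpec(pixel_size = 0), "positive")
  expect_error(sceneSpec(n_whales = -1), "non-negative")
  expect_error(sceneSpec(posture_mix = c(logging = 0.5)), "probability")
  expect_error(sceneSpec(whale_length_m = c(5, 40)), "30 m")
  expect_error(sceneSpec(sea_state = 2), "0, 1")
  expect_error(generateClassificationDataset(0), ">= 1")
  expect_error(generateDetectionDataset(0), ">= 1")
})
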