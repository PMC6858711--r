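test_that("image dimensions follow ceil(field / um_per_pixel)", {
  sc <- manual_scene(as_cells <- data.frame(x_um = numeric(0),
                                            y_um = numeric(0),
                                            marker = character(0)),
                     field = 1000)
  img <- render_ihc_image(sc, um_per_pixel = 0.5)
  expect_equal(dim(img$img)[1:2], c(2000, 2000))
  # empty scene is pure background (+ nothing else)
  bg <- img$palette$background
  expect_true(all(img$img[, , 1] == bg[1]))
  expect_error(render_ihc_image(sc, um_per_pixel = 10, nucleus_radius_um = 4),
               "coarse")
})

test_that("pixel classification is exact on noise-free renders", {
  cells <- grid_cells(30, field = 400, seed = 2)
  cells$marker[1:10] <- "NEG"
  img <- render_ihc_image(manual_scene(cells, 400), um_per_pixel = 0.5)
  mask <- classify_pixels(img)
  # red pixels = rendered fast-red disks exactly (IoU 1 against the palette)
  red_truth <- img$img[, , 1] == img$palette$fast_red[1] &
    img$img[, , 3] == img$palette$fast_red[3]
  expect_identical(unclass(mask) == 1L, red_truth)
  blue_truth <- img$img[, , 3] == img$palette$nucleus[3] &
    img$img[, , 1] == img$palette$nucleus[1]
  expect_identical(unclass(mask) == 2L, blue_truth)
  expect_error(classify_pixels(img$img[, , 1], 0.5), "3-channel")
})

test_that("pixel classification stays accurate under noise", {
  cells <- grid_cells(30, field = 400, seed = 3)
  clean <- render_ihc_image(manual_scene(cells, 400), um_per_pixel = 0.5)
  noisy <- render_ihc_image(manual_scene(cells, 400), um_per_pixel = 0.5,
                            noise_sd = 10, seed = 4)
  m0 <- unclass(classify_pixels(clean))
  m1 <- unclass(classify_pixels(noisy))
  expect_gte(mean(m0 == m1), 0.98)
})

test_that("detection recovers non-overlapping positives with exact centroids", {
  cells <- grid_cells(50, field = 500, seed = 1)
  img <- render_ihc_image(manual_scene(cells, 500), um_per_pixel = 0.5)
  det <- detect_cells(classify_pixels(img), marker = "CD8")
  pos <- det[det$marker == "CD8", ]
  expect_equal(nrow(pos), 50)
  m <- match_cells(pos, cells)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_lt(m$max_err, 2)
  # blank mask -> no cells
  blank <- structure(matrix(0L, 10, 10), um_per_pixel = 0.5,
                     class = "pixel_mask")
  expect_identical(nrow(detect_cells(blank, marker = "CD8")), 0L)
})

test_that("components outside the area filter are rejected", {
  # a red blob far below min area: one pixel (0.25 um^2 at 0.5 um/px)
  mask <- matrix(0L, 100, 100)
  mask[50, 50] <- 1L
  mask <- structure(mask, um_per_pixel = 0.5, class = "pixel_mask")
  expect_identical(nrow(detect_cells(mask, marker = "CD8")), 0L)
  # a huge blob above max area is rejected too
  mask2 <- matrix(0L, 100, 100)
  mask2[10:80, 10:80] <- 1L  # 71^2 px * 0.25 um^2 > 400 um^2
  mask2 <- structure(mask2, um_per_pixel = 0.5, class = "pixel_mask")
  expect_identical(nrow(detect_cells(mask2, marker = "CD8")), 0L)
})

test_that("detected centroids are stable across rendering scales", {
  cells <- grid_cells(20, field = 300, seed = 5)
  sc <- manual_scene(cells, 300)
  d1 <- detect_cells(classify_pixels(render_ihc_image(sc, 0.5)), marker = "CD8")
  d2 <- detect_cells(classify_pixels(render_ihc_image(sc, 0.25)), marker = "CD8")
  d1 <- d1[d1$marker == "CD8", ]; d2 <- d2[d2$marker == "CD8", ]
  expect_equal(nrow(d1), nrow(d2))
  o1 <- order(round(d1$x_um), round(d1$y_um))
  o2 <- order(round(d2$x_um), round(d2$y_um))
  shift <- sqrt((d1$x_um[o1] - d2$x_um[o2])^2 + (d1$y_um[o1] - d2$y_um[o2])^2)
  expect_lt(max(shift), 1)
})

test_that("field densitometry follows the mean-of-fields definition", {
  # counts 10,10,10,10,10 at 1e-3 mm^2 -> 10/0.001 = 10000 cells/mm^2
  spec <- field_spec(n_fields = 5, placement = "grid")
  # build a region and cells giving exactly 10 per chosen field is brittle;
  # check the arithmetic directly on the returned counts instead
  set.seed(8)
  cells <- data.frame(x_um = runif(3000, 0, 1000),
                      y_um = runif(3000, 0, 1000), marker = "CD8")
  fd <- field_density(cells, c(0, 0, 1000, 1000), spec)
  expect_equal(fd$density_per_mm2, mean(fd$counts) / 1e-3)
  # zero positives -> density 0
  neg <- data.frame(x_um = runif(50, 0, 1000), y_um = runif(50, 0, 1000),
                    marker = "NEG")
  expect_equal(field_density(neg, c(0, 0, 1000, 1000), spec)$density_per_mm2, 0)
  # region too small for a single 31.6 um field
  expect_error(field_density(cells, c(0, 0, 20, 20), spec), "too small")
})

test_that("hotspot placement never undercounts random placement", {
  for (s in 1:5) {
    sc <- generate_tissue_scene(scene_config(1200, 1200, "circle", 400,
                                             lambda_in = c(CD8 = 1200,
                                                           NEG = 500),
                                             lambda_out = c(CD8 = 100),
                                             seed = s))
    hot <- field_density(sc$cells, sc$geometry,
                         field_spec(placement = "hotspot"))
    rnd <- field_density(sc$cells, sc$geometry,
                         field_spec(placement = "random", seed = s))
    expect_gte(hot$density_per_mm2, rnd$density_per_mm2)
  }
})

test_that("random-field densities track a uniform intensity", {
  lam <- 2000
  dens <- vapply(1:50, function(s) {
    sc <- generate_tissue_scene(scene_config(900, 900, "circle", 400,
                                             lambda_in = c(CD8 = lam),
                                             lambda_out = c(CD8 = lam),
                                             seed = 200 + s))
    field_density(sc$cells, sc$geometry,
                  field_spec(placement = "random", seed = s))$density_per_mm2
  }, 0)
  # mean of 250 Poisson(2) fields: SE = sqrt(lam / (0.001 * 250)) / 1000
  se <- sqrt(lam / 1e-3 / 250)
  expect_lt(abs(mean(dens) - lam), 4 * se)
})

test_that("images round-trip through PNG/TIFF with their scale sidecar", {
  cells <- grid_cells(5, field = 100, spacing = 30, seed = 6)
  img <- render_ihc_image(manual_scene(cells, 100), um_per_pixel = 1)
  for (ext in c("png", "tif")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_image(img, p)
    back <- read_image(p)
    expect_equal(back$um_per_pixel, 1)
    expect_equal(dim(back$img), dim(img$img))
    expect_lt(max(abs(back$img - img$img)), 0.51)  # 8-bit quantisation
    unlink(c(p, paste0(p, ".json")))
  }
})
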