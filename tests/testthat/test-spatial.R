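test_that("signed distance has the expected sign and trivial values", {
  g <- circle_geom(radius = 500, field = 2000)
  # centre of a circle of radius 500 -> -500 (up to polygon discretisation)
  expect_equal(signed_distance(matrix(c(1000, 1000), 1), g), -500,
               tolerance = 1e-4)
  # a polygon vertex lies exactly on the boundary -> 0
  v <- g$rings[[1]][1, , drop = FALSE]
  expect_equal(signed_distance(v, g), 0)
  # outside point: distance to the circle
  expect_equal(signed_distance(matrix(c(1700, 1000), 1), g), 200,
               tolerance = 1e-3)
  expect_warning(signed_distance(matrix(c(-50, 50), 1), g), "field of view")
})

test_that("signed distance matches brute-force boundary sampling", {
  set.seed(42)
  for (s in 1:3) {
    g <- blob_geom(seed = s)
    pts <- cbind(runif(100, 0, 2000), runif(100, 0, 2000))
    d_fast <- signed_distance(pts, g)
    d_brute <- brute_force_distance(pts, g$rings[[1]], n_boundary = 2e4)
    expect_lt(max(abs(abs(d_fast) - d_brute)), 0.1)
  }
})

test_that("holes in multi-ring geometry count as host tissue", {
  outer_ring <- circle_margin(c(1000, 1000), 600)
  hole <- circle_margin(c(1000, 1000), 200)
  g <- tumor_geometry(list(outer_ring, hole), c(0, 0, 2000, 2000),
                      validate = FALSE)
  # centre sits in the hole: outside tumor, 200 um from the hole boundary
  expect_equal(signed_distance(matrix(c(1000, 1000), 1), g), 200,
               tolerance = 1e-3)
  # in the annulus of tumor tissue: negative
  expect_lt(signed_distance(matrix(c(1000, 1400), 1), g), 0)
})

test_that("compartment assignment follows the 500 um threshold rules", {
  g <- circle_geom(radius = 500, field = 3000)
  # signed distances -30, +499, +501 um via points on the x axis
  pts <- data.frame(x_um = 1500 + c(470, 999, 1001, -200),
                    y_um = rep(1500, 4), marker = "CD8")
  comp <- assign_compartment(pts, g)
  expect_equal(as.character(comp),
               c("intratumoral", "peritumoral", "outside", "intratumoral"))
  # boundary cell (d = 0) is intratumoral
  v <- g$rings[[1]][1, ]
  comp0 <- assign_compartment(data.frame(x_um = v[1], y_um = v[2],
                                         marker = "CD8"), g)
  expect_equal(as.character(comp0), "intratumoral")
})

test_that("peritumoral/intratumoral count ratio matches the area ratio", {
  # circle r = 1000, uniform intensity: E ratio = pi(1.5^2 - 1)/pi = 1.25
  ratios <- vapply(1:40, function(s) {
    sc <- generate_tissue_scene(scene_config(3200, 3200, "circle", 1000,
                                             lambda_in = c(CD8 = 800),
                                             lambda_out = c(CD8 = 800),
                                             seed = s))
    comp <- assign_compartment(sc$cells, sc$geometry, 500)
    sum(comp == "peritumoral") / sum(comp == "intratumoral")
  }, 0)
  expect_equal(mean(ratios), 1.25, tolerance = 0.02)
})

test_that("band areas of a circular margin match closed-form annulus areas", {
  g <- circle_geom(radius = 500, field = 2000)
  ann <- function(r1, r2) pi * (r2^2 - r1^2) / 1e6  # mm^2, radii in um
  expect_equal(as.numeric(band_area(g, 0, 20)), ann(500, 520),
               tolerance = 1e-4 / ann(500, 520))
  expect_equal(as.numeric(band_area(g, -20, 0)), ann(480, 500),
               tolerance = 1e-4 / ann(480, 500))
  expect_equal(as.numeric(band_area(g, -Inf, 0)), pi * 0.25, tolerance = 1e-3)
})

test_that("area is additive over contiguous bands", {
  g <- blob_geom(seed = 9)
  a <- as.numeric(band_area(g, 0, 20)) + as.numeric(band_area(g, 20, 40))
  expect_equal(a, as.numeric(band_area(g, 0, 40)), tolerance = 1e-6)
})

test_that("erosion beyond the inscribed radius collapses to a degenerate band", {
  g <- circle_geom(radius = 100, field = 1000)
  a <- band_area(g, -160, -140)
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "degenerate"))
})

test_that("outside band areas are non-decreasing with distance (convex margin)", {
  g <- circle_geom(radius = 400, field = 3000)
  areas <- vapply(seq(0, 80, by = 20), function(lo)
    as.numeric(band_area(g, lo, lo + 20)), 0)
  expect_true(all(diff(areas) > 0))
})

test_that("band histogram bins single cells correctly and conserves counts", {
  g <- circle_geom(radius = 500, field = 2000)
  # one cell 30 um inside the margin -> band (-40, -20]
  one <- data.frame(x_um = 1000, y_um = 1000 - 470, marker = "CD8")
  h <- band_histogram(one, g)
  expect_equal(sum(h$count), 1L)
  hit <- h[h$count == 1L, ]
  expect_equal(c(hit$band_lo_um, hit$band_hi_um), c(-40, -20))
  expect_identical(attr(h, "excluded"), 0L)
  # conservation on a populated scene
  sc <- generate_tissue_scene(scene_config(2000, 2000, "circle", 500,
                                           lambda_in = c(CD8 = 600,
                                                         CD163 = 400),
                                           seed = 3))
  d <- signed_distance(sc$cells, sc$geometry)
  h2 <- band_histogram(sc$cells, sc$geometry)
  in_range <- abs(d) <= 100 & d > -100 & sc$cells$marker != "NEG"
  n_in <- sum(d > -100 & d <= 100 & sc$cells$marker %in% c("CD8", "CD163"))
  expect_identical(sum(h2$count), n_in)
  expect_identical(attr(h2, "excluded"), nrow(sc$cells) - sum(d > -100 & d <= 100))
  # densities times areas reproduce counts
  expect_equal(h2$density_per_mm2 * h2$area_mm2, as.numeric(h2$count))
})

test_that("uniform scenes give band densities near the generating intensity", {
  lam <- 1500
  devs <- vapply(1:20, function(s) {
    sc <- generate_tissue_scene(scene_config(2000, 2000, "circle", 500,
                                             lambda_in = c(CD8 = lam),
                                             lambda_out = c(CD8 = lam),
                                             seed = 100 + s))
    h <- band_histogram(sc$cells, sc$geometry, min_cell_um = 2)
    h <- h[h$marker == "CD8", ]
    max(abs(h$count - lam * h$area_mm2) / sqrt(lam * h$area_mm2))
  }, 0)
  # every band count within 4 SD of its Poisson mean in nearly all seeds
  expect_gte(mean(devs < 4), 0.95)
})

test_that("compartment densities and fractions are consistent", {
  g <- circle_geom(radius = 500, field = 3000)
  # 100 CD8 cells placed intratumorally: density = 100 / area
  set.seed(1)
  th <- runif(100, 0, 2 * pi); r <- sqrt(runif(100)) * 450
  cells <- data.frame(x_um = 1500 + r * cos(th), y_um = 1500 + r * sin(th),
                      marker = "CD8")
  cd <- compartment_densities(cells, g)
  it <- cd[cd$marker == "CD8" & cd$compartment == "intratumoral", ]
  expect_equal(it$count, 100)
  expect_equal(it$density_per_mm2, 100 / it$area_mm2)
  expect_equal(it$positive_fraction_pct, 100)  # CD8-only slide
  # empty compartment: zero density and fraction
  pt <- cd[cd$marker == "CD163" & cd$compartment == "peritumoral", ]
  expect_equal(pt$density_per_mm2, 0)
  expect_equal(pt$positive_fraction_pct, 0)
})
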