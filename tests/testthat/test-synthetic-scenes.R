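test_that("an empty noiseless scene renders as a constant background", {
  spec <- scene_spec(image_size_px = c(64, 64), background_level = 40,
                     noise_std = 0, seed = 1)
  sc <- render_scene(spec)
  expect_true(all(unclass(sc$image) == 40))
  expect_equal(nrow(sc$truth$circles), 0)
  expect_false(sc$truth$is_aggregate)
})

test_that("rendering is bit-identical for a fixed seed", {
  spec <- scene_spec(image_size_px = c(300, 300),
                     carriers = data.frame(center_row = 150, center_col = 150,
                                           radius_px = 100,
                                           texture_fraction = 0.4),
                     cells = data.frame(row = 150, col = 150, sigma_px = 6,
                                        amplitude = 100, carrier = 1),
                     noise_std = 4, seed = 99)
  a <- render_scene(spec); b <- render_scene(spec)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$truth, b$truth)

  m1 <- render_monolayer(0.4, seed = 5); m2 <- render_monolayer(0.4, seed = 5)
  expect_identical(unclass(m1$image), unclass(m2$image))

  s1 <- render_suite("aggregate", 3, seed = 42)
  s2 <- render_suite("aggregate", 3, seed = 42)
  expect_identical(lapply(s1, `[[`, "truth"), lapply(s2, `[[`, "truth"))
  expect_identical(unclass(s1[[2]]$image), unclass(s2[[2]]$image))

  # rendering does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(render_scene(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("scene truth reflects the specification exactly", {
  sc <- render_suite("single-carrier", 1, seed = 8, n_cells = 15)[[1]]
  expect_equal(nrow(sc$truth$cell_centroids), 15)
  expect_equal(nrow(sc$truth$circles), 1)
  expect_length(sc$truth$cell_footprint_px2, 15)

  agg <- render_suite("aggregate", 3, seed = 12)
  for (sc in agg) {
    expect_gte(nrow(sc$truth$circles), 3)
    expect_true(sc$truth$is_aggregate)
  }
  pair <- render_suite("pair", 2, seed = 13)
  for (sc in pair) {
    expect_equal(nrow(sc$truth$circles), 2)
    expect_false(sc$truth$is_aggregate)
  }
  expect_error(render_suite("spiral", 2, seed = 1), "arg")
})

test_that("invalid geometry is rejected with the offending element named", {
  expect_error(
    scene_spec(image_size_px = c(200, 200),
               carriers = data.frame(center_row = 100, center_col = 190,
                                     radius_px = 50)),
    "carrier 1")
  expect_error(
    scene_spec(image_size_px = c(400, 400),
               carriers = data.frame(center_row = 200, center_col = 200,
                                     radius_px = 100),
               cells = data.frame(row = 295, col = 200, sigma_px = 6,
                                  amplitude = 100, carrier = 1)),
    "cell 1")
  expect_error(
    scene_spec(image_size_px = c(400, 400),
               carriers = data.frame(center_row = 200, center_col = 200,
                                     radius_px = 100),
               cells = data.frame(row = 200, col = 200, sigma_px = 6,
                                  amplitude = 100, carrier = 3)),
    "carrier that does not exist")
})

test_that("monolayers hit their target foreground fraction", {
  m0 <- render_monolayer(0, seed = 3)
  expect_equal(m0$truth$true_foreground_fraction, 0)
  expect_false(any(m0$truth$region_mask))

  m1 <- render_monolayer(1, seed = 3)
  expect_equal(m1$truth$true_foreground_fraction, 1)

  for (s in 1:3) {
    m <- render_monolayer(0.5, seed = s)
    expect_gte(m$truth$true_foreground_fraction, 0.49)
    expect_lte(m$truth$true_foreground_fraction, 0.51)
    # recorded fraction is the realized mask fraction, exactly
    expect_identical(m$truth$true_foreground_fraction,
                     mean(m$truth$region_mask))
  }
  expect_error(render_monolayer(1.5), "\\[0, 1\\]")
})

test_that("rendered cell footprints match the analytic Gaussian iso-contour", {
  for (sig in c(4, 8)) {
    spec <- scene_spec(image_size_px = c(400, 400),
                       carriers = data.frame(center_row = 200, center_col = 200,
                                             radius_px = 150,
                                             body_brightness = 100,
                                             rim_brightness = 140),
                       cells = data.frame(row = 200, col = 200, sigma_px = sig,
                                          amplitude = 120, carrier = 1),
                       noise_std = 0, seed = 1)
    sc <- render_scene(spec)
    x <- unclass(sc$image)
    # pixels at or above half amplitude over the carrier body
    foot <- sum(x >= 100 + 60)
    expect_equal(foot, sc$truth$cell_footprint_px2[1], tolerance = 0.1)
  }
})

test_that("in-carrier texture covers the requested fraction of the disk", {
  spec <- scene_spec(image_size_px = c(400, 400),
                     carriers = data.frame(center_row = 200, center_col = 200,
                                           radius_px = 150,
                                           texture_fraction = 0.5),
                     noise_std = 0, seed = 6)
  sc <- render_scene(spec)
  expect_equal(sc$truth$texture_fraction_realized[1], 0.5, tolerance = 0.02)
})
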