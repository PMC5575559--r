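test_that("local_std_map matches the exhaustive per-window oracle", {
  for (seed in 1:3) {
    x <- random_image(64, 64, seed)
    for (k in c(7L, 15L)) {
      got <- local_std_map(x, kernel_px = k, overlap_fraction = 0.93)
      want <- oracle_std_map(x, k, stride = 1L)
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
  # a window split between 0s and 255s agrees with the direct computation
  x <- matrix(0, 32, 32); x[, 17:32] <- 255
  got <- local_std_map(x, 15L, 0.93)
  expect_lt(max(abs(got - oracle_std_map(x, 15L, 1L))), 1e-9)
})

test_that("the 93% overlap default gives stride one; coarser overlaps stride > 1", {
  # stride = max(1, round(15 * 0.07)) = 1
  x <- random_image(48, 40, 11)
  expect_lt(max(abs(local_std_map(x, 15L, 0.93) - oracle_std_map(x, 15L, 1L))), 1e-9)
  # overlap 0.5 -> stride round(7.5) = 8, uncovered border inherits nearest value
  expect_lt(max(abs(local_std_map(x, 15L, 0.5) - oracle_std_map(x, 15L, 8L))), 1e-9)
  expect_error(local_std_map(matrix(1, 20, 20), 21L), "larger than the image")
  expect_error(local_std_map(x, 8L), "odd")
})

test_that("confluence is 0% on featureless images and 100% on pure texture", {
  flat <- gray_image(matrix(128, 64, 64))
  expect_true(all(local_std_map(flat) == 0))
  expect_warning(res <- segment_confluence(flat), "featureless")
  expect_equal(res$confluence_pct, 0)

  # constant mode on a flat image: nothing exceeds the fixed threshold
  res_c <- segment_confluence(flat, mode = "constant")
  expect_equal(res_c$confluence_pct, 0)
  expect_equal(res_c$threshold_used, 0.4 * 21.1)

  noisy <- random_image(64, 64, 5)   # sd ~73 everywhere, far above 0.35*sigma
  res_n <- segment_confluence(gray_image(noisy))
  expect_equal(res_n$confluence_pct, 100)
  expect_equal(res_n$sigma_image, o_pop_sd(as.vector(noisy)))
  expect_equal(res_n$threshold_used, 0.35 * res_n$sigma_image)
})

test_that("adaptive confluence is invariant to affine intensity rescaling", {
  set.seed(21)
  base <- matrix(runif(64 * 64, 40, 200), 64, 64)
  base[1:32, ] <- 120   # half flat, half textured
  r1 <- segment_confluence(gray_image(base))
  r2 <- segment_confluence(gray_image(0.5 * base + 20))
  expect_equal(r1$confluence_pct, r2$confluence_pct)
  expect_equal(r1$mask, r2$mask)
})

test_that("confluence is monotone in the threshold factor and bounded", {
  x <- gray_image(random_image(64, 64, 31))
  factors <- c(0.2, 0.35, 0.5, 0.8, 1.5)
  pcts <- vapply(factors, function(f)
    segment_confluence(x, analysis_config(confluence_threshold_factor = f))$confluence_pct,
    numeric(1))
  expect_true(all(diff(pcts) <= 0))
  expect_true(all(pcts >= 0 & pcts <= 100))
})

test_that("per-carrier confluence uses in-circle pixels only", {
  # uniform disk on uniform background: nothing to segment inside the circle
  H <- 160
  x <- matrix(40, H, H)
  d2 <- outer((1:H - 80)^2, (1:H - 80)^2, "+")
  x[d2 <= 60^2] <- 120
  circ <- list(center_row = 80, center_col = 80, radius_px = 60)
  expect_warning(res <- confluence_on_carrier(gray_image(x), circ), "featureless")
  expect_equal(res$confluence_pct, 0)

  # fully textured interior -> 100%
  set.seed(7)
  x2 <- matrix(40, H, H)
  inside <- d2 <= 60^2
  x2[inside] <- runif(sum(inside), 0, 255)
  res2 <- confluence_on_carrier(gray_image(x2), circ)
  expect_equal(res2$confluence_pct, 100)
  expect_equal(res2$region_px, sum(inside))
  expect_equal(res2$sigma_image, o_pop_sd(x2[inside]))

  # half textured, half flat: the in-circle classification agrees with the
  # masked-window oracle pixel for pixel
  set.seed(8)
  x3 <- matrix(40, H, H)
  x3[inside] <- 120
  top <- inside & row(x3) <= 80
  x3[top] <- runif(sum(top), 0, 255)
  res3 <- confluence_on_carrier(gray_image(x3), circ)
  want <- oracle_masked_classify(unclass(crop_to_circle(gray_image(x3), circ)$image),
                                 crop_to_circle(gray_image(x3), circ)$mask,
                                 15L, res3$threshold_used)
  expect_equal(res3$mask == 1, want)
  expect_equal(res3$confluence_pct, 100 * sum(want) / sum(inside))
})

test_that("a half-covered large carrier measures close to 50% confluence", {
  # carrier big enough that the ~14 px kernel-edge band stays within 5 pp
  H <- 420
  x <- matrix(40, H, H)
  d2 <- outer((1:H - 210)^2, (1:H - 210)^2, "+")
  inside <- d2 <= 200^2
  x[inside] <- 120
  set.seed(12)
  top <- inside & row(x) <= 210
  x[top] <- runif(sum(top), 0, 255)
  res <- confluence_on_carrier(gray_image(x),
                               list(center_row = 210, center_col = 210,
                                    radius_px = 200))
  expect_lt(abs(res$confluence_pct - 100 * sum(top) / sum(inside)), 5)
})

test_that("carriers outside or mostly outside the image are rejected", {
  img <- gray_image(matrix(100, 100, 100))
  expect_error(confluence_on_carrier(img, list(center_row = 500, center_col = 500,
                                               radius_px = 30)),
               "outside")
  expect_error(confluence_on_carrier(img, list(center_row = -20, center_col = 50,
                                               radius_px = 40)),
               "half inside")
})
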