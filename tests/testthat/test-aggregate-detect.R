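test_that("binarization and disk dilation behave as defined", {
  dark <- matrix(50, 40, 40)
  expect_true(all(!binarize_and_dilate(dark, threshold = 100,
                                       dilation_radius_px = 3)))

  # single bright pixel dilated by r = 3: exactly the discrete disk
  x <- matrix(0, 41, 41); x[21, 21] <- 255
  bin <- binarize_and_dilate(x, threshold = 128, dilation_radius_px = 3)
  expect_equal(sum(bin), 29)
  # against the distance-map oracle
  d2 <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+")
  expect_equal(unname(which(bin)), which(d2 <= 9))

  # radius 0 is a plain threshold
  expect_equal(sum(binarize_and_dilate(x, 128, 0)), 1)

  # two foreground disks closer than twice the dilation radius merge
  y <- matrix(0, 60, 60)
  dd <- outer((1:60 - 30)^2, (1:60 - 20)^2, "+"); y[dd <= 5^2] <- 255
  dd <- outer((1:60 - 30)^2, (1:60 - 37)^2, "+"); y[dd <= 5^2] <- 255
  before <- binarize_and_dilate(y, 128, 0)
  after <- binarize_and_dilate(y, 128, 4)   # gap 7 < 2 * 4
  expect_equal(max(oracle_label(before)), 2)
  expect_equal(max(oracle_label(after)), 1)
})

test_that("dilation is extensive and monotone in the radius", {
  set.seed(42)
  x <- matrix(0, 50, 50)
  x[sample(2500, 40)] <- 255
  prev <- binarize_and_dilate(x, 128, 0)
  for (r in c(1, 2, 4)) {
    cur <- binarize_and_dilate(x, 128, r)
    expect_true(all(cur[prev]))   # superset of smaller radius (and input)
    prev <- cur
  }
})

test_that("label_and_filter matches the flood-fill oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    bin <- matrix(runif(64 * 64) < 0.35, 64, 64)
    got <- label_and_filter(bin, carrier_area_range_px2 = c(1, 1e9),
                            eccentricity_max = 1)
    want <- oracle_label(bin, 8L)
    expect_equal(nrow(got), max(want))
    # same partition: areas and centroids agree object-by-object
    st <- lapply(seq_len(max(want)), function(id) {
      px <- which(want == id, arr.ind = TRUE)
      c(area = nrow(px), r = mean(px[, 1]), c = mean(px[, 2]))
    })
    st <- do.call(rbind, st)
    ord <- order(-st[, "area"], seq_len(nrow(st)))
    st <- st[ord, , drop = FALSE]
    expect_equal(got$area_px2, unname(st[, "area"]))
    expect_equal(got$centroid_row, unname(st[, "r"]))
    expect_equal(got$centroid_col, unname(st[, "c"]))
  }
})

test_that("shape filtering keeps disks and rejects bars", {
  H <- 200
  mk_disk <- function(cr, cc, r) outer((1:H - cr)^2, (1:H - cc)^2, "+") <= r^2
  one <- mk_disk(100, 100, 40)
  obj <- label_and_filter(one, c(100, 1e9), 0.8)
  expect_equal(nrow(obj), 1)
  expect_lt(obj$eccentricity, 0.3)

  # eccentricity agrees with the moment oracle
  px <- which(one, arr.ind = TRUE)
  expect_equal(obj$eccentricity, oracle_eccentricity(px[, 1], px[, 2]),
               tolerance = 1e-6)

  # a 100 x 4 bar has in-range area but extreme eccentricity
  bar <- matrix(FALSE, H, H); bar[50:53, 40:139] <- TRUE
  expect_equal(nrow(label_and_filter(bar, c(100, 1e9), 0.8)), 0)
  kept <- label_and_filter(bar, c(100, 1e9), 0.9999)
  expect_equal(nrow(kept), 1)
  expect_gt(kept$eccentricity, 0.99)

  three <- mk_disk(50, 50, 25) | mk_disk(50, 150, 25) | mk_disk(150, 100, 25)
  expect_equal(nrow(label_and_filter(three, c(100, 1e9), 0.8)), 3)
})

test_that("the aggregate flag fires strictly above two carrier objects", {
  obj <- function(n) data.frame(area_px2 = rep(5e4, n))
  expect_false(flag_aggregate(obj(0)))
  expect_false(flag_aggregate(obj(1)))
  expect_false(flag_aggregate(obj(2)))
  expect_true(flag_aggregate(obj(3)))
  expect_true(flag_aggregate(obj(5)))
  # optional merged-component extension
  big <- data.frame(area_px2 = 3e5)
  expect_false(flag_aggregate(big))
  expect_true(flag_aggregate(big, merged_area_px2 = 1.8 * 150000))
})

test_that("aggregate rates are per 50 images, overall and per group", {
  expect_equal(aggregate_rate(c(rep(FALSE, 49), TRUE)), 1)
  expect_equal(aggregate_rate(c(rep(TRUE, 8), rep(FALSE, 92))), 4)
  flags <- c(rep(c(TRUE, FALSE), c(1, 49)), rep(c(TRUE, FALSE), c(2, 48)),
             rep(c(TRUE, FALSE), c(3, 47)), rep(c(TRUE, FALSE), c(4, 46)))
  days <- rep(c(2, 4, 6, 8), each = 50)
  expect_equal(aggregate_rate(flags, days),
               c(`2` = 1, `4` = 2, `6` = 3, `8` = 4))
  expect_error(aggregate_rate(logical(0)), "non-empty")
  # empty factor level: rate undefined, reported missing
  f <- factor(rep("a", 4), levels = c("a", "b"))
  r <- aggregate_rate(c(TRUE, FALSE, FALSE, FALSE), f)
  expect_true(is.na(r[["b"]]))
  expect_equal(r[["a"]], 12.5)
})

test_that("rendered carrier clumps are flagged with full precision and recall", {
  flags <- logical(0); truth <- logical(0)
  for (kind in c("single-carrier", "pair", "aggregate")) {
    for (sc in render_suite(kind, 3, seed = 77)) {
      bin <- binarize_and_dilate(sc$image)
      obj <- label_and_filter(bin)
      flags <- c(flags, flag_aggregate(obj))
      truth <- c(truth, sc$truth$is_aggregate)
    }
  }
  expect_equal(flags, truth)
})
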