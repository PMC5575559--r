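#' Local standard-deviation map
#'
#' Slides a square analysis window across the image and assigns each
#' window's population standard deviation to every pixel the window
#' covers; where several windows cover a pixel the maximum is kept, so a
#' pixel is credited with the most variable neighborhood it belongs to.
#' This windowed-variability map is the texture statistic behind the
#' confluence measurement: cell-covered regions show high local intensity
#' variability while the background is nearly flat.
#'
#' The window stride is `max(1, round(kernel_px * (1 - overlap_fraction)))`;
#' the defaults (15 px, 93% overlap) give a stride of one pixel. Windows
#' are fully interior (no padding). With a stride above one, pixels beyond
#' the last full window inherit the value of the nearest covered pixel.
#'
#' @param image a [gray_image] or numeric matrix.
#' @param kernel_px odd window side, >= 3; must fit inside the image.
#' @param overlap_fraction fractional window overlap in (0, 1).
#' @return numeric matrix of the image's shape.
#' @export
#' @examples
#' m <- local_std_map(gray_image(matrix(rep(c(0, 255), each = 240), 16, 30)))
#' range(m)
local_std_map <- function(image, kernel_px = 15L, overlap_fraction = 0.93) {
  x <- as_pixel_matrix(image)
  std_map_impl(x, kernel_px, overlap_fraction, mask = NULL)
}

std_map_impl <- function(x, kernel_px, overlap_fraction, mask = NULL) {
  k <- as.integer(kernel_px)
  if (k < 3L || k %% 2L == 0L)
    stop("kernel_px must be an odd integer >= 3")
  if (!is.numeric(overlap_fraction) || overlap_fraction <= 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie strictly between 0 and 1")
  H <- nrow(x); W <- ncol(x)
  if (k > H || k > W)
    stop("kernel is larger than the image")
  stride <- max(1L, as.integer(round(k * (1 - overlap_fraction))))

  if (is.null(mask)) {
    s1 <- box_sum(x, k)
    s2 <- box_sum(x * x, k)
    n <- k * k
    v <- (s2 - s1 * s1 / n) / n
  } else {
    m <- mask
    storage.mode(m) <- "double"
    s1 <- box_sum(x * m, k)
    s2 <- box_sum(x * x * m, k)
    n <- box_sum(m, k)
    nn <- pmax(n, 1)
    v <- (s2 - s1 * s1 / nn) / nn
    v[n < 1] <- NA_real_
  }
  sd_grid <- sqrt(pmax(v, 0))

  rows <- seq.int(1L, H - k + 1L, by = stride)
  cols <- seq.int(1L, W - k + 1L, by = stride)
  P <- matrix(-Inf, H, W)
  sd_fill <- sd_grid
  sd_fill[is.na(sd_fill)] <- -Inf
  P[rows, cols] <- sd_fill[rows, cols]

  ## max over covering windows = left-looking running max of width k,
  ## separable over rows then columns
  out <- P
  for (off in seq_len(k - 1L))
    out[(1L + off):H, ] <- pmax(out[(1L + off):H, , drop = FALSE],
                                P[seq_len(H - off), , drop = FALSE])
  P2 <- out
  for (off in seq_len(k - 1L))
    out[, (1L + off):W] <- pmax(out[, (1L + off):W, drop = FALSE],
                                P2[, seq_len(W - off), drop = FALSE])

  if (is.null(mask)) {
    ## pixels beyond the last full window (stride > 1) inherit the value of
    ## the nearest covered pixel
    last_r <- rows[length(rows)] + k - 1L
    if (last_r < H) out[(last_r + 1L):H, ] <- out[rep(last_r, H - last_r), , drop = FALSE]
    last_c <- cols[length(cols)] + k - 1L
    if (last_c < W) out[, (last_c + 1L):W] <- out[, rep(last_c, W - last_c), drop = FALSE]
  } else {
    out[!is.finite(out)] <- NA_real_
  }
  out
}

confluence_result <- function(mask, confluence_pct, sigma_image,
                              threshold_used, mode, region_px = length(mask)) {
  structure(list(mask = mask, confluence_pct = confluence_pct,
                 sigma_image = sigma_image, threshold_used = threshold_used,
                 mode = mode, region_px = region_px),
            class = "confluence_result")
}

#' @export
print.confluence_result <- function(x, ...) {
  cat(sprintf("<confluence_result> %.2f%% confluent (%s mode, sigma = %.3f, threshold = %.3f, %d px analyzed)\n",
              x$confluence_pct, x$mode, x$sigma_image, x$threshold_used,
              x$region_px))
  invisible(x)
}

#' Segment cell-covered area and measure confluence
#'
#' Classifies each pixel as cell or background by comparing the local
#' standard-deviation map against a threshold, and reports the percentage
#' of pixels classified as cells. In `adaptive` mode the threshold is
#' `confluence_threshold_factor` (default 35%) of the grayscale standard
#' deviation of the analyzed image, so the segmentation adapts to image
#' brightness and contrast; `constant` mode applies the configured fixed
#' threshold instead (retained for comparison with the adaptive rule).
#'
#' @param image a [gray_image] or numeric matrix.
#' @param config an [analysis_config()].
#' @param mode `"adaptive"` or `"constant"`.
#' @return a `confluence_result`: binary `mask` (1 = cell), scalar
#'   `confluence_pct`, `sigma_image`, and `threshold_used`.
#' @export
#' @examples
#' img <- gray_image(matrix(pmin(255, pmax(0, 128 + rnorm(4096, sd = 30))), 64, 64))
#' segment_confluence(img)$confluence_pct
segment_confluence <- function(image, config = analysis_config(),
                               mode = c("adaptive", "constant")) {
  mode <- match.arg(mode)
  x <- as_pixel_matrix(image)
  sigma <- pop_sd(as.vector(x))
  if (mode == "adaptive") {
    if (sigma == 0) {
      warning("featureless image (zero grayscale standard deviation); confluence set to 0%")
      return(confluence_result(matrix(0L, nrow(x), ncol(x)), 0, 0, 0, mode))
    }
    thr <- config$confluence_threshold_factor * sigma
  } else {
    if (is.null(config$constant_threshold))
      stop("constant mode requires config$constant_threshold")
    thr <- config$constant_threshold
  }
  sm <- std_map_impl(x, config$confluence_kernel_px,
                     config$confluence_overlap_fraction)
  mask <- matrix(as.integer(sm >= thr), nrow(x), ncol(x))
  confluence_result(mask, 100 * mean(mask), sigma, thr, mode)
}

#' Confluence restricted to one microcarrier
#'
#' Measures confluence over the interior of a detected carrier circle
#' only: the image standard deviation, the window statistics and the
#' percentage all use in-circle pixels exclusively, so the dark background
#' surrounding the carrier cannot dilute the measurement. Window standard
#' deviations are computed from the in-circle pixels each window covers
#' (masked statistics).
#'
#' @param image a [gray_image] or numeric matrix.
#' @param circle a detected circle (one row of [detect_circles()] output,
#'   or a list with `center_row`, `center_col`, `radius_px`). At least half
#'   of its area must lie inside the image.
#' @param config an [analysis_config()].
#' @param mode `"adaptive"` or `"constant"`.
#' @return a `confluence_result` whose `mask` covers the carrier's
#'   bounding box (out-of-circle pixels 0) and whose `confluence_pct` is
#'   the percentage of in-circle pixels classified as cells; carries the
#'   crop offset as attribute `offset`.
#' @export
confluence_on_carrier <- function(image, circle, config = analysis_config(),
                                  mode = c("adaptive", "constant")) {
  mode <- match.arg(mode)
  circle <- as_circle(circle)
  crop <- crop_to_circle(image, circle, margin_px = 0)
  sub <- as_pixel_matrix(crop$image)
  msk <- crop$mask
  vals <- sub[msk]
  sigma <- pop_sd(vals)
  if (mode == "adaptive") {
    if (sigma == 0) {
      warning("featureless carrier (zero grayscale standard deviation); confluence set to 0%")
      res <- confluence_result(matrix(0L, nrow(sub), ncol(sub)), 0, 0, 0,
                               mode, region_px = sum(msk))
      attr(res, "offset") <- c(row = crop$offset_row, col = crop$offset_col)
      return(res)
    }
    thr <- config$confluence_threshold_factor * sigma
  } else {
    if (is.null(config$constant_threshold))
      stop("constant mode requires config$constant_threshold")
    thr <- config$constant_threshold
  }
  k <- config$confluence_kernel_px
  if (k > min(dim(sub)))
    stop("carrier crop is smaller than the analysis kernel")
  sm <- std_map_impl(sub, k, config$confluence_overlap_fraction, mask = msk)
  cls <- !is.na(sm) & sm >= thr & msk
  mask_out <- matrix(as.integer(cls), nrow(sub), ncol(sub))
  res <- confluence_result(mask_out, 100 * sum(cls) / sum(msk), sigma, thr,
                           mode, region_px = sum(msk))
  attr(res, "offset") <- c(row = crop$offset_row, col = crop$offset_col)
  res
}
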