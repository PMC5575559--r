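## Sobel derivative kernels; row kernel differentiates along rows (dim 1)
sobel_row <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE) / 8
sobel_col <- t(sobel_row)

## 3x3 correlation with mirror padding (kernels here are tiny; direct shifts)
conv3 <- function(x, k) {
  xp <- pad_reflect(x, 1L)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (dr in -1:1)
    for (dc in -1:1) {
      w <- k[dr + 2L, dc + 2L]
      if (w != 0)
        out <- out + w * xp[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc)]
    }
  out
}

empty_circles <- function() {
  data.frame(center_row = numeric(), center_col = numeric(),
             radius_px = numeric(), score = numeric())
}

## accumulate gradient-direction Hough votes for one radius
vote_radius <- function(er, ec, ur, uc, r, H, W) {
  acc <- numeric(H * W)
  for (s in c(1, -1)) {
    vr <- as.integer(round(er + s * r * ur))
    vc <- as.integer(round(ec + s * r * uc))
    ok <- vr >= 1L & vr <= H & vc >= 1L & vc <= W
    if (any(ok))
      acc <- acc + tabulate(vr[ok] + (vc[ok] - 1L) * H, nbins = H * W)
  }
  matrix(acc, H, W)
}

#' Detect microcarriers by circular Hough transform
#'
#' Finds circular carriers via a gradient-direction circular Hough
#' transform: pixels whose gradient magnitude exceeds a percentile
#' threshold vote, for every candidate radius, at the two points lying
#' that radius away along their gradient direction; accumulator peaks are
#' circle hypotheses. Peaks are non-maximum suppressed so that returned
#' centers are at least `min_separation_px` apart, and center/radius are
#' refined from the supporting edge pixels. The procedure is fully
#' deterministic: ties in score are broken by smaller row, then column,
#' then radius.
#'
#' @param image a [gray_image] or numeric matrix.
#' @param radius_range_px `c(min, max)` radii searched; requires
#'   `0 < min < max <= floor(min(dim(image)) / 2)`.
#' @param max_circles maximum number of circles returned.
#' @param min_separation_px minimum distance between returned centers;
#'   `NULL` uses `1.2 * min(radius_range_px)`.
#' @param config an [analysis_config()] supplying the edge percentile,
#'   edge-pixel cap, radius step and minimum score.
#' @return data.frame with one row per detection, score-descending:
#'   `center_row`, `center_col`, `radius_px` (fractional), `score`
#'   (accumulator votes per unit circumference). Zero rows when no
#'   candidate reaches the minimum score.
#' @export
detect_circles <- function(image,
                           radius_range_px = config$hough_radius_range_px,
                           max_circles = config$hough_max_circles,
                           min_separation_px = NULL,
                           config = analysis_config()) {
  x <- as_pixel_matrix(image)
  H <- nrow(x); W <- ncol(x)
  rmin <- radius_range_px[1L]; rmax <- radius_range_px[2L]
  if (!(rmin > 0 && rmin < rmax && rmax <= floor(min(H, W) / 2)))
    stop("radius_range_px must satisfy 0 < min < max <= half the smaller image dimension")
  if (is.null(min_separation_px)) min_separation_px <- 1.2 * rmin

  gr <- conv3(x, sobel_row)
  gc <- conv3(x, sobel_col)
  g <- sqrt(gr * gr + gc * gc)
  nz <- which(g > 1e-9)
  if (length(nz) == 0L) return(empty_circles())
  thr <- stats::quantile(g[nz], probs = config$hough_edge_percentile,
                         names = FALSE, type = 7)
  sel <- nz[g[nz] >= thr]
  if (length(sel) > config$hough_max_edge_px) {
    ord <- order(-g[sel], sel, method = "radix")
    sel <- sel[ord[seq_len(config$hough_max_edge_px)]]
  }
  er <- (sel - 1L) %% H + 1L
  ec <- (sel - 1L) %/% H + 1L
  gm <- g[sel]
  ur <- gr[sel] / gm
  uc <- gc[sel] / gm

  radii <- unique(c(seq(rmin, rmax, by = config$hough_radius_step_px), rmax))
  cand <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    am <- vote_radius(er, ec, ur, uc, r, H, W)
    sc <- box3(am) / (2 * pi * r)
    hits <- which(sc >= config$hough_min_score)
    if (length(hits)) {
      mx <- max3(sc)
      hits <- hits[sc[hits] >= mx[hits]]    # local maxima only
      if (length(hits))
        cand[[i]] <- data.frame(
          center_row = (hits - 1L) %% H + 1L,
          center_col = (hits - 1L) %/% H + 1L,
          radius_px = r, score = sc[hits])
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(empty_circles())

  ## greedy non-maximum suppression, score-descending with deterministic ties
  ord <- order(-cand$score, cand$center_row, cand$center_col, cand$radius_px,
               method = "radix")
  cand <- cand[ord, , drop = FALSE]
  kept <- cand[0, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) >= max_circles) break
    if (nrow(kept)) {
      d2 <- (kept$center_row - cand$center_row[i])^2 +
            (kept$center_col - cand$center_col[i])^2
      if (any(d2 < min_separation_px^2)) next
    }
    kept <- rbind(kept, cand[i, , drop = FALSE])
  }
  if (nrow(kept) == 0L) return(empty_circles())

  ## refine each detection from its supporting votes and edge pixels
  for (i in seq_len(nrow(kept))) {
    r0 <- kept$radius_px[i]
    am <- vote_radius(er, ec, ur, uc, r0, H, W)
    pr <- as.integer(kept$center_row[i]); pc <- as.integer(kept$center_col[i])
    rr <- max(1L, pr - 2L):min(H, pr + 2L)
    cc <- max(1L, pc - 2L):min(W, pc + 2L)
    wts <- am[rr, cc, drop = FALSE]
    if (sum(wts) > 0) {
      kept$center_row[i] <- sum(outer(rr, rep(1, length(cc))) * wts) / sum(wts)
      kept$center_col[i] <- sum(outer(rep(1, length(rr)), cc) * wts) / sum(wts)
    }
    dr <- er - kept$center_row[i]
    dc <- ec - kept$center_col[i]
    rho <- sqrt(dr * dr + dc * dc)
    align <- abs(dr * ur + dc * uc) / pmax(rho, 1e-9)
    selr <- rho >= r0 - 4 & rho <= r0 + 4 & align >= 0.85
    if (any(selr))
      kept$radius_px[i] <- sum(rho[selr] * gm[selr]) / sum(gm[selr])
  }
  ord <- order(-kept$score, kept$center_row, kept$center_col, kept$radius_px,
               method = "radix")
  kept <- kept[ord, , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Crop an image to a carrier's bounding box
#'
#' Extracts the axis-aligned bounding box of a circle, expanded by
#' `margin_px` and clipped to the image bounds, together with the
#' in-circle membership mask (pixels whose center lies within `radius_px`
#' of the circle center). At least half of the circle's area must lie
#' inside the image.
#'
#' @param image a [gray_image] or numeric matrix.
#' @param circle circle as for [confluence_on_carrier()].
#' @param margin_px margin added on every side before clipping.
#' @return list with `image` (the [gray_image] subimage), logical `mask`
#'   of the same shape, `offset_row`/`offset_col` (pixels cropped away
#'   above/left, so subimage row 1 is original row `offset_row + 1`), and
#'   the `circle`.
#' @export
crop_to_circle <- function(image, circle, margin_px = 0) {
  circle <- as_circle(circle)
  x <- as_pixel_matrix(image)
  H <- nrow(x); W <- ncol(x)
  cr <- circle$center_row; cc <- circle$center_col; r <- circle$radius_px

  r0 <- max(1L, as.integer(floor(cr - r - margin_px)))
  r1 <- min(H, as.integer(ceiling(cr + r + margin_px)))
  c0 <- max(1L, as.integer(floor(cc - r - margin_px)))
  c1 <- min(W, as.integer(ceiling(cc + r + margin_px)))
  if (r1 < r0 || c1 < c0)
    stop("circle lies entirely outside the image")

  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
  mask <- d2 <= r^2
  inside <- sum(mask)
  if (inside == 0L)
    stop("circle lies entirely outside the image")
  if (inside < 0.5 * pi * r^2)
    stop("circle must lie at least half inside the image")

  sub <- gray_image(x[rows, cols, drop = FALSE],
                    pixel_scale_um = attr(image, "pixel_scale_um"))
  list(image = sub, mask = mask,
       offset_row = r0 - 1L, offset_col = c0 - 1L, circle = circle)
}
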