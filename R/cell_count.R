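#' Laplacian-of-Gaussian kernel
#'
#' Discrete LoG kernel with the sign convention that bright blobs on a
#' dark background produce positive response peaks (i.e. the negated
#' Laplacian of a Gaussian), mean-corrected so the kernel sums to zero and
#' flat regions give zero response.
#'
#' @param sigma_px Gaussian sigma in pixels (> 0).
#' @param kernel_px odd kernel side; the recommended minimum is
#'   `2 * ceiling(3 * sigma_px) + 1`.
#' @return `kernel_px` x `kernel_px` numeric matrix summing to zero.
#' @export
log_kernel <- function(sigma_px, kernel_px = 2L * ceiling(3 * sigma_px) + 1L) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || sigma_px <= 0)
    stop("sigma_px must be a single positive number")
  k <- as.integer(kernel_px)
  if (k < 3L || k %% 2L == 0L)
    stop("kernel_px must be an odd integer >= 3")
  h <- (k - 1L) / 2L
  d <- seq(-h, h)
  r2 <- outer(d^2, d^2, "+")
  s2 <- sigma_px^2
  ker <- (2 * s2 - r2) / s2^2 * exp(-r2 / (2 * s2))   # -laplacian(gaussian)
  ker - mean(ker)
}

#' Filter an image with a Laplacian-of-Gaussian kernel
#'
#' Convolves the image with [log_kernel()] under mirror (reflective)
#' border padding, returning a same-shape response raster in which bright
#' blob centers appear as positive peaks.
#'
#' @inheritParams log_kernel
#' @param image a [gray_image] or numeric matrix.
#' @return numeric response matrix of the image's shape.
#' @export
log_filter <- function(image, sigma_px,
                       kernel_px = 2L * ceiling(3 * sigma_px) + 1L) {
  x <- as_pixel_matrix(image)
  ker <- log_kernel(sigma_px, kernel_px)
  k <- nrow(ker)
  if (k > nrow(x) || k > ncol(x))
    stop("kernel is larger than the image")
  p <- (k - 1L) %/% 2L
  xp <- pad_reflect(x, p)
  r <- EBImage::filter2(xp, ker, boundary = 0)
  if (inherits(r, "Image")) r <- EBImage::imageData(r)
  r[(p + 1L):(p + nrow(x)), (p + 1L):(p + ncol(x)), drop = FALSE]
}

#' Detect cells on an isolated microcarrier
#'
#' Runs the cell-detection sequence on a carrier subimage: (1) LoG
#' filtering at the configured scale; (2) a grayscale high-pass gate that
#' zeroes the response wherever the raw intensity is below
#' `cell_intensity_threshold` (under epi-illumination, cells are the
#' brightest structures); (3) binarization of the remaining response
#' above `cell_response_fraction` of its maximum; (4) 8-connected
#' component labeling; (5) retention of components whose pixel area lies
#' in `cell_area_range_px2` and whose centroid falls inside the carrier
#' mask. Overlapping cells that fuse into one component are counted once.
#'
#' @param subimage carrier subimage ([gray_image] or matrix), e.g. from
#'   [crop_to_circle()].
#' @param mask logical in-circle mask of the same shape (non-empty).
#' @param config an [analysis_config()].
#' @return data.frame of detections sorted by (row, col): `centroid_row`,
#'   `centroid_col`, `area_px2`, `peak_response`. Zero rows when nothing
#'   is detected.
#' @export
detect_cells <- function(subimage, mask, config = analysis_config()) {
  x <- as_pixel_matrix(subimage)
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), dim(x)))
    stop("mask must match the subimage shape")
  if (!any(mask)) stop("mask is empty")

  sig <- config$log_sigma_px
  k <- config$log_kernel_px
  kmax <- min(dim(x))
  if (kmax %% 2L == 0L) kmax <- kmax - 1L
  k <- min(k, kmax)            # keep the kernel inside small crops
  resp <- log_filter(x, sig, k)
  resp[x < config$cell_intensity_threshold] <- 0

  mx <- max(resp)
  if (!is.finite(mx) || mx <= 1e-9) return(empty_cells())
  bin <- resp >= config$cell_response_fraction * mx

  lab <- label8(bin)
  st <- component_stats(lab, aux = resp)
  if (nrow(st) == 0L) return(empty_cells())

  ar <- config$cell_area_range_px2
  ri <- pmin(nrow(x), pmax(1L, as.integer(round(st$centroid_row))))
  ci <- pmin(ncol(x), pmax(1L, as.integer(round(st$centroid_col))))
  keep <- st$area_px2 >= ar[1L] & st$area_px2 <= ar[2L] &
    mask[cbind(ri, ci)]
  st <- st[keep, , drop = FALSE]
  if (nrow(st) == 0L) return(empty_cells())

  st <- st[order(st$centroid_row, st$centroid_col), , drop = FALSE]
  out <- data.frame(centroid_row = st$centroid_row,
                    centroid_col = st$centroid_col,
                    area_px2 = st$area_px2,
                    peak_response = st$peak)
  rownames(out) <- NULL
  out
}

empty_cells <- function() {
  data.frame(centroid_row = numeric(), centroid_col = numeric(),
             area_px2 = numeric(), peak_response = numeric())
}

#' Hemisphere-corrected cell count
#'
#' Doubles the visible-cell count under the assumption that only cells on
#' the carrier's illuminated upper hemisphere are imaged and the lower
#' hemisphere carries as many again.
#'
#' @param cells_visible non-negative integer count(s) of detected cells.
#' @return `2 * cells_visible`, an even non-negative integer (vectorized).
#' @export
#' @examples
#' hemisphere_corrected_count(7)   # 14
hemisphere_corrected_count <- function(cells_visible) {
  if (!is.numeric(cells_visible) || any(cells_visible < 0) ||
      any(cells_visible != as.integer(cells_visible)))
    stop("cells_visible must be non-negative integer(s)")
  2L * as.integer(cells_visible)
}

#' Convert mean cells per carrier to culture density
#'
#' @param mean_cells_per_carrier average (hemisphere-corrected) cells per
#'   microcarrier, >= 0.
#' @param carriers_per_ml microcarrier concentration, >= 0.
#' @return cells per mL (the product; vectorized).
#' @export
#' @examples
#' cell_density(50, 1000)   # 5e4 cells/mL
cell_density <- function(mean_cells_per_carrier, carriers_per_ml) {
  if (!is.numeric(mean_cells_per_carrier) || any(mean_cells_per_carrier < 0))
    stop("mean_cells_per_carrier must be >= 0")
  if (!is.numeric(carriers_per_ml) || any(carriers_per_ml < 0))
    stop("carriers_per_ml must be >= 0")
  mean_cells_per_carrier * carriers_per_ml
}
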