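#' Binarize an image and dilate the foreground
#'
#' First step of aggregate detection: thresholding highlights the
#' illuminated carrier bodies, and a disk dilation agglomerates each
#' carrier's bright regions into one solid object.
#'
#' @param image a [gray_image] or numeric matrix.
#' @param threshold intensity threshold in `[0, 255]`; `NULL` selects it
#'   from the image histogram by Otsu's method.
#' @param dilation_radius_px radius of the disk structuring element
#'   (pixels with `dr^2 + dc^2 <= r^2`); 0 means no dilation.
#' @return logical foreground raster of the image's shape, with the
#'   threshold actually applied as attribute `threshold`.
#' @export
binarize_and_dilate <- function(image, threshold = NULL,
                                dilation_radius_px = 5L) {
  x <- as_pixel_matrix(image)
  if (is.null(threshold)) {
    threshold <- 255 * EBImage::otsu(EBImage::Image(x / 255), range = c(0, 1))
  } else {
    if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
      stop("threshold must lie in [0, 255]")
  }
  r <- as.integer(dilation_radius_px)
  if (r < 0L) stop("dilation_radius_px must be >= 0")
  bin <- x >= threshold
  if (r > 0L && any(bin)) {
    b <- bin
    storage.mode(b) <- "double"
    d <- EBImage::dilate(b, disc_kernel(r))
    if (inherits(d, "Image")) d <- EBImage::imageData(d)
    bin <- d > 0
  }
  attr(bin, "threshold") <- threshold
  bin
}

#' Label foreground objects and keep carrier-shaped ones
#'
#' Labels 8-connected foreground components, measures each component's
#' pixel area and equivalent-ellipse eccentricity (from second-order
#' central moments), and keeps components that are both carrier-sized
#' (area within `carrier_area_range_px2`) and near-circular (eccentricity
#' at most `eccentricity_max`).
#'
#' @param binary logical or 0/1 raster, e.g. from [binarize_and_dilate()].
#' @param carrier_area_range_px2 `c(min, max)` accepted pixel area.
#' @param eccentricity_max maximum accepted eccentricity in `[0, 1)`.
#' @return data.frame sorted by area descending: `label_id`, `area_px2`,
#'   `eccentricity`, `centroid_row`, `centroid_col`.
#' @export
label_and_filter <- function(binary, carrier_area_range_px2 = c(30000, 150000),
                             eccentricity_max = 0.8) {
  if (!is.matrix(binary)) stop("binary must be a matrix")
  lab <- label8(binary)
  st <- component_stats(lab)
  if (nrow(st) == 0L)
    return(data.frame(label_id = integer(), area_px2 = numeric(),
                      eccentricity = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  mom <- EBImage::computeFeatures.moment(lab)
  ecc <- mom[, "m.eccentricity"]
  ecc[!is.finite(ecc)] <- 0
  st$eccentricity <- as.numeric(ecc)

  keep <- st$area_px2 >= carrier_area_range_px2[1L] &
    st$area_px2 <= carrier_area_range_px2[2L] &
    st$eccentricity <= eccentricity_max
  st <- st[keep, , drop = FALSE]
  st <- st[order(-st$area_px2, st$label_id), , drop = FALSE]
  rownames(st) <- NULL
  st[, c("label_id", "area_px2", "eccentricity",
         "centroid_row", "centroid_col")]
}

#' Flag an image as containing a microcarrier aggregate
#'
#' An image is flagged when more than two carrier-shaped objects are
#' present (strictly more than two, i.e. at least three). Optionally a
#' single over-sized component — carriers fused into one object — can
#' also raise the flag.
#'
#' @param objects data.frame from [label_and_filter()].
#' @param merged_area_px2 if a number, additionally flag when any
#'   component area exceeds it; `NULL` (default) disables the extension.
#' @return logical.
#' @export
#' @examples
#' flag_aggregate(data.frame(area_px2 = c(5e4, 5e4)))        # FALSE
#' flag_aggregate(data.frame(area_px2 = c(5e4, 5e4, 5e4)))   # TRUE
flag_aggregate <- function(objects, merged_area_px2 = NULL) {
  n <- if (is.data.frame(objects)) nrow(objects) else length(objects)
  if (n > 2L) return(TRUE)
  if (!is.null(merged_area_px2) && n > 0L &&
      any(objects$area_px2 > merged_area_px2)) return(TRUE)
  FALSE
}

#' Aggregation frequency per 50 images
#'
#' Converts per-image aggregate flags into the number of flagged images
#' per 50 images acquired, overall or per group (typically culture day).
#'
#' @param flags logical vector of per-image aggregate flags (non-empty).
#' @param group_labels optional grouping vector (same length as `flags`);
#'   a factor's empty levels are reported as `NA` (rate undefined).
#' @return a single rate, or a named vector of per-group rates.
#' @export
#' @examples
#' aggregate_rate(c(rep(FALSE, 49), TRUE))   # 1 per 50 images
aggregate_rate <- function(flags, group_labels = NULL) {
  if (length(flags) == 0L) stop("flags must be non-empty")
  flags <- as.logical(flags)
  if (anyNA(flags)) stop("flags must not contain NA")
  if (is.null(group_labels)) return(50 * mean(flags))
  if (length(group_labels) != length(flags))
    stop("group_labels must match flags in length")
  f <- if (is.factor(group_labels)) group_labels else factor(group_labels)
  cnt <- tapply(flags, f, function(v) 50 * mean(v))
  out <- as.numeric(cnt)
  names(out) <- levels(f)
  out
}
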