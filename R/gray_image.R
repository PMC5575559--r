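#' Grayscale image container
#'
#' All analyses in carrierscope operate on `gray_image` objects: a numeric
#' matrix of intensities on the 8-bit `[0, 255]` scale (whatever the source
#' bit depth), indexed `[row, col]` with the origin at the top-left corner,
#' plus an optional physical pixel scale in micrometers per pixel.
#'
#' Intensities are kept on the 8-bit scale because the classical constant
#' segmentation threshold (0.4 x 21.1) and the default cell intensity
#' threshold are stated in 8-bit grayscale units.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`; at least
#'   15 x 15 so one confluence analysis kernel fits.
#' @param pixel_scale_um optional micrometers per pixel (single positive
#'   number). The package-wide default, 0.467 um/px, corresponds to a
#'   598 um field imaged across 1280 detector pixels.
#' @return an object of class `gray_image`.
#' @export
#' @examples
#' img <- gray_image(matrix(128, 32, 32))
#' dim(img)
gray_image <- function(pixels, pixel_scale_um = NULL) {
  if (is.array(pixels) && length(dim(pixels)) == 2L) pixels <- as.matrix(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("image intensities must lie in [0, 255]")
  if (nrow(pixels) < 15L || ncol(pixels) < 15L)
    stop("image must be at least 15 x 15 pixels (one analysis kernel)")
  if (!is.null(pixel_scale_um)) {
    if (!is.numeric(pixel_scale_um) || length(pixel_scale_um) != 1L ||
        !is.finite(pixel_scale_um) || pixel_scale_um <= 0)
      stop("'pixel_scale_um' must be a single positive number")
  }
  structure(pixels, class = c("gray_image", "matrix"),
            pixel_scale_um = pixel_scale_um)
}

#' @export
print.gray_image <- function(x, ...) {
  ps <- attr(x, "pixel_scale_um")
  cat(sprintf("<gray_image> %d x %d px, intensities [%.1f, %.1f]%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (is.null(ps)) "" else sprintf(", %.3f um/px", ps)))
  invisible(x)
}

#' Test for gray_image
#' @param x object
#' @return logical
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

## strip the class/attributes down to a plain double matrix
as_pixel_matrix <- function(image) {
  if (is_gray_image(image)) {
    m <- unclass(image)
    attr(m, "pixel_scale_um") <- NULL
    return(m)
  }
  if (is.matrix(image) && is.numeric(image)) {
    m <- image
    storage.mode(m) <- "double"
    return(m)
  }
  stop("expected a gray_image or numeric matrix")
}

#' Pixel scale of an image
#' @param image a [gray_image]
#' @param default value returned when the image carries no scale
#' @return micrometers per pixel
#' @export
pixel_scale <- function(image, default = 0.467) {
  ps <- attr(image, "pixel_scale_um")
  if (is.null(ps)) default else ps
}

luminance_weights <- c(0.2126, 0.7152, 0.0722)

## collapse an HxWx{3,4} array to luminance, keeping the native scale
to_luminance <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  nc <- dim(a)[3L]
  if (nc == 2L) return(a[, , 1L])          # gray + alpha
  w <- luminance_weights
  a[, , 1L] * w[1L] + a[, , 2L] * w[2L] + a[, , 3L] * w[3L]
}

read_one_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(p) > 255) 16L else 8L
    list(native = to_luminance(p), max_value = 2^bits - 1)
  })
}

read_one_png <- function(path) {
  p <- png::readPNG(path, info = TRUE)
  info <- attr(p, "info")
  bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  # readPNG returns values already divided by (2^bits - 1)
  list(list(native = to_luminance(p) * (2^bits - 1), max_value = 2^bits - 1))
}

#' Read microscopy images as gray_image objects
#'
#' Reads a single TIFF/PNG file, a multi-page TIFF, or every TIFF/PNG in a
#' directory (lexicographic filename order, pages in file order). Color
#' images are converted to luminance (Rec. 709 weights) before intensity
#' scaling. 8-bit inputs pass through unchanged; deeper inputs are mapped
#' linearly from their native range onto `[0, 255]`.
#'
#' @param path file or directory path.
#' @param rescale if `TRUE`, additionally stretch each image so its observed
#'   minimum and maximum map to 0 and 255 (contrast normalization); the
#'   default `FALSE` applies only the fixed bit-depth scaling.
#' @param pixel_scale_um optional micrometers per pixel attached to every
#'   returned image.
#' @return named list of [gray_image]; multi-page TIFFs contribute one
#'   element per page, named `<file>#p<page>`.
#' @export
read_images <- function(path, rescale = FALSE, pixel_scale_um = NULL) {
  if (length(path) != 1L || !is.character(path))
    stop("'path' must be a single file or directory path")
  if (!file.exists(path)) stop(sprintf("path does not exist: '%s'", path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L)
      stop(sprintf("no images found in directory '%s'", path))
  } else {
    files <- path
  }
  out <- list()
  for (f in files) {
    ext <- tolower(tools::file_ext(f))
    pages <- tryCatch(
      switch(ext,
             tif = , tiff = read_one_tiff(f),
             png = read_one_png(f),
             stop("unsupported extension (expected TIFF or PNG)")),
      error = function(e)
        stop(sprintf("failed to read '%s': %s", f, conditionMessage(e)),
             call. = FALSE))
    for (i in seq_along(pages)) {
      x <- pages[[i]]$native
      mx <- pages[[i]]$max_value
      if (mx > 255) x <- x * (255 / mx)
      if (isTRUE(rescale)) {
        rng <- range(x)
        if (rng[2L] > rng[1L]) x <- (x - rng[1L]) * (255 / (rng[2L] - rng[1L]))
      }
      x <- pmin(pmax(x, 0), 255)
      nm <- if (length(pages) > 1L)
        sprintf("%s#p%d", basename(f), i) else basename(f)
      out[[nm]] <- gray_image(x, pixel_scale_um = pixel_scale_um)
    }
  }
  out
}
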