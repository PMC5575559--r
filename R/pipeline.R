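#' Per-image analysis record
#'
#' Container for the full analysis of one image: per-carrier rows
#' (circle, confluence, visible and hemisphere-corrected cell counts) and
#' the image-level aggregate flag. `cells_corrected` is always exactly
#' twice `cells_visible`.
#'
#' @param image_id identifier (typically the file name).
#' @param carriers data.frame with one row per analyzed carrier:
#'   `center_row`, `center_col`, `radius_px`, `score`, `confluence_pct`,
#'   `cells_visible`, `cells_corrected`; may have zero rows.
#' @param culture_day optional integer culture day.
#' @param is_aggregate image-level aggregate flag.
#' @param carrier_object_count number of carrier-shaped objects found by
#'   the aggregate detector.
#' @return object of class `report_record`.
#' @export
report_record <- function(image_id, carriers = NULL, culture_day = NA_integer_,
                          is_aggregate = NA, carrier_object_count = NA_integer_) {
  if (is.null(carriers)) carriers <- empty_carrier_rows()
  need <- c("center_row", "center_col", "radius_px", "score",
            "confluence_pct", "cells_visible", "cells_corrected")
  if (!all(need %in% names(carriers)))
    stop("carriers is missing required columns")
  if (nrow(carriers) &&
      any(carriers$cells_corrected != 2L * carriers$cells_visible))
    stop("cells_corrected must equal 2 * cells_visible in every row")
  structure(list(image_id = as.character(image_id),
                 culture_day = as.integer(culture_day),
                 carriers = carriers,
                 is_aggregate = as.logical(is_aggregate),
                 carrier_object_count = as.integer(carrier_object_count)),
            class = "report_record")
}

empty_carrier_rows <- function() {
  data.frame(center_row = numeric(), center_col = numeric(),
             radius_px = numeric(), score = numeric(),
             confluence_pct = numeric(), cells_visible = integer(),
             cells_corrected = integer())
}

#' @export
print.report_record <- function(x, ...) {
  cat(sprintf("<report_record> %s (day %s): %d carrier(s), aggregate = %s\n",
              x$image_id, ifelse(is.na(x$culture_day), "?", x$culture_day),
              nrow(x$carriers), x$is_aggregate))
  invisible(x)
}

#' Analyze one image end to end
#'
#' Runs the full static-image pipeline: carrier detection (circular
#' Hough), per-carrier confluence (adaptive by default) and LoG cell
#' counting with hemisphere correction, plus the image-level aggregate
#' check. The Hough radius search range is clipped to half the smaller
#' image dimension when necessary.
#'
#' @param image a [gray_image] or numeric matrix.
#' @param config an [analysis_config()].
#' @param image_id identifier stored in the record.
#' @param culture_day optional integer culture day.
#' @param mode confluence thresholding mode.
#' @return a [report_record()].
#' @export
analyze_image <- function(image, config = analysis_config(),
                          image_id = "image", culture_day = NA_integer_,
                          mode = c("adaptive", "constant")) {
  mode <- match.arg(mode)
  x <- as_pixel_matrix(image)
  half <- floor(min(dim(x)) / 2)
  rr <- config$hough_radius_range_px
  rr[2L] <- min(rr[2L], half)
  if (rr[1L] >= rr[2L])
    stop("image too small for the configured carrier radius range")
  circles <- detect_circles(image, radius_range_px = rr, config = config)

  rows <- empty_carrier_rows()
  for (i in seq_len(nrow(circles))) {
    circ <- circles[i, , drop = FALSE]
    conf <- confluence_on_carrier(image, circ, config, mode = mode)
    crop <- crop_to_circle(image, circ, margin_px = config$crop_margin_px)
    cells <- detect_cells(crop$image, crop$mask, config)
    visible <- nrow(cells)
    rows <- rbind(rows, data.frame(
      center_row = circ$center_row, center_col = circ$center_col,
      radius_px = circ$radius_px, score = circ$score,
      confluence_pct = conf$confluence_pct,
      cells_visible = visible,
      cells_corrected = hemisphere_corrected_count(visible)))
  }

  bin <- binarize_and_dilate(image, config$aggregate_binarize_threshold,
                             config$aggregate_dilation_radius_px)
  objects <- label_and_filter(bin, config$carrier_area_range_px2,
                              config$carrier_eccentricity_max)
  merged <- if (is.null(config$aggregate_merged_area_factor)) NULL else
    config$aggregate_merged_area_factor * config$carrier_area_range_px2[2L]
  report_record(image_id, rows, culture_day,
                is_aggregate = flag_aggregate(objects, merged),
                carrier_object_count = nrow(objects))
}
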