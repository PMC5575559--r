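#' Analysis configuration
#'
#' Bundles every tunable of the analysis pipeline with documented defaults,
#' so all entry points run with zero configuration. Lengths are in pixels
#' and intensities on the 8-bit `[0, 255]` scale throughout.
#'
#' @param confluence_kernel_px side of the square analysis window for the
#'   local-standard-deviation confluence filter (odd, >= 3). Default 15.
#' @param confluence_overlap_fraction fractional overlap between successive
#'   windows in both directions, in (0, 1). Default 0.93, which with a
#'   15 px kernel gives a stride of one pixel.
#' @param confluence_threshold_factor adaptive-mode threshold as a fraction
#'   of the whole-image grayscale standard deviation. Default 0.35.
#' @param constant_threshold fixed threshold (intensity-std units) used in
#'   constant mode. Default `0.4 * 21.1 = 8.44`, the classical reference
#'   value for monolayer flask images.
#' @param pixel_scale_um micrometers per pixel. Default 0.467 (a 598 um
#'   field across 1280 detector pixels).
#' @param hough_radius_range_px `c(min, max)` carrier radii searched by the
#'   circular Hough transform. Default `c(139, 268)`: Cytodex-class carrier
#'   diameters of roughly 130-250 um at the default pixel scale.
#' @param hough_radius_step_px radius sampling step of the Hough
#'   accumulator before refinement. Default 2.
#' @param hough_edge_percentile percentile (0-1) of nonzero gradient
#'   magnitudes above which pixels vote. Default 0.90.
#' @param hough_max_edge_px cap on the number of voting edge pixels
#'   (strongest gradients kept). Default 20000.
#' @param hough_min_score minimum normalized accumulator score (votes per
#'   unit circumference) for a detection. Default 0.25.
#' @param hough_max_circles maximum number of circles returned. Default 3.
#' @param hough_min_separation_px non-maximum-suppression distance between
#'   returned centers; `NULL` means `1.2 * min(radius range)`.
#' @param crop_margin_px margin added around a carrier's bounding box when
#'   cropping. Default 6.
#' @param log_sigma_px Gaussian sigma of the Laplacian-of-Gaussian cell
#'   detector; `NULL` derives it as `(10 / pixel_scale_um) / sqrt(2)`
#'   (blob-matched sizing for a ~10 um cell radius).
#' @param log_kernel_px LoG kernel side; `NULL` derives the standard
#'   `2 * ceiling(3 * sigma) + 1`.
#' @param cell_intensity_threshold raw grayscale value below which LoG
#'   responses are discarded (cells are the brightest structures under
#'   epi-illumination). Default 200.
#' @param cell_response_fraction fraction of the maximum positive (gated)
#'   LoG response used as the binarization threshold. Default 0.2.
#' @param cell_area_range_px2 `c(min, max)` pixel area accepted for a cell
#'   object. Default `c(40, 2000)`.
#' @param aggregate_binarize_threshold fixed intensity threshold for
#'   aggregate detection; `NULL` (default) selects it per image by Otsu's
#'   method.
#' @param aggregate_dilation_radius_px disk radius of the morphological
#'   dilation that agglomerates each carrier's bright regions. Default 5.
#' @param carrier_area_range_px2 `c(min, max)` pixel area accepted for a
#'   carrier-sized object. Default `c(30000, 150000)` (radii of roughly
#'   100-215 px after dilation).
#' @param carrier_eccentricity_max maximum equivalent-ellipse eccentricity
#'   of a carrier object. Default 0.8.
#' @param aggregate_merged_area_factor if a number, additionally flag an
#'   image when one component's area exceeds this multiple of
#'   `carrier_area_range_px2[2]` (catches carriers fused into one object).
#'   Default `NULL`: off, so the flag rule is exactly "more than two
#'   carrier objects".
#' @param carriers_per_ml microcarrier concentration used to convert mean
#'   cells per carrier into cells/mL; `NULL` leaves densities unreported.
#' @param convergence_tolerance fractional band around the final running
#'   mean that defines count convergence. Default 0.05.
#' @param histogram_bin_width bin width (cells per carrier) of the
#'   colonization histogram. Default 5.
#' @return an object of class `analysis_config` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config(confluence_threshold_factor = 0.4)
#' cfg$confluence_threshold_factor
analysis_config <- function(confluence_kernel_px = 15L,
                            confluence_overlap_fraction = 0.93,
                            confluence_threshold_factor = 0.35,
                            constant_threshold = 0.4 * 21.1,
                            pixel_scale_um = 0.467,
                            hough_radius_range_px = c(139, 268),
                            hough_radius_step_px = 2,
                            hough_edge_percentile = 0.90,
                            hough_max_edge_px = 20000L,
                            hough_min_score = 0.25,
                            hough_max_circles = 3L,
                            hough_min_separation_px = NULL,
                            crop_margin_px = 6,
                            log_sigma_px = NULL,
                            log_kernel_px = NULL,
                            cell_intensity_threshold = 200,
                            cell_response_fraction = 0.2,
                            cell_area_range_px2 = c(40, 2000),
                            aggregate_binarize_threshold = NULL,
                            aggregate_dilation_radius_px = 5L,
                            carrier_area_range_px2 = c(30000, 150000),
                            carrier_eccentricity_max = 0.8,
                            aggregate_merged_area_factor = NULL,
                            carriers_per_ml = NULL,
                            convergence_tolerance = 0.05,
                            histogram_bin_width = 5L) {
  cfg <- list(
    confluence_kernel_px = as.integer(confluence_kernel_px),
    confluence_overlap_fraction = confluence_overlap_fraction,
    confluence_threshold_factor = confluence_threshold_factor,
    constant_threshold = constant_threshold,
    pixel_scale_um = pixel_scale_um,
    hough_radius_range_px = as.numeric(hough_radius_range_px),
    hough_radius_step_px = hough_radius_step_px,
    hough_edge_percentile = hough_edge_percentile,
    hough_max_edge_px = as.integer(hough_max_edge_px),
    hough_min_score = hough_min_score,
    hough_max_circles = as.integer(hough_max_circles),
    hough_min_separation_px = hough_min_separation_px,
    crop_margin_px = crop_margin_px,
    log_sigma_px = log_sigma_px,
    log_kernel_px = log_kernel_px,
    cell_intensity_threshold = cell_intensity_threshold,
    cell_response_fraction = cell_response_fraction,
    cell_area_range_px2 = as.numeric(cell_area_range_px2),
    aggregate_binarize_threshold = aggregate_binarize_threshold,
    aggregate_dilation_radius_px = as.integer(aggregate_dilation_radius_px),
    carrier_area_range_px2 = as.numeric(carrier_area_range_px2),
    carrier_eccentricity_max = carrier_eccentricity_max,
    aggregate_merged_area_factor = aggregate_merged_area_factor,
    carriers_per_ml = carriers_per_ml,
    convergence_tolerance = convergence_tolerance,
    histogram_bin_width = as.integer(histogram_bin_width))
  validate_config(cfg)
  if (is.null(cfg$log_sigma_px))
    cfg$log_sigma_px <- (10 / cfg$pixel_scale_um) / sqrt(2)
  if (is.null(cfg$log_kernel_px))
    cfg$log_kernel_px <- 2L * as.integer(ceiling(3 * cfg$log_sigma_px)) + 1L
  if (is.null(cfg$hough_min_separation_px))
    cfg$hough_min_separation_px <- 1.2 * cfg$hough_radius_range_px[1L]
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  k <- cfg$confluence_kernel_px
  if (k < 3L || k %% 2L == 0L)
    stop("confluence_kernel_px must be an odd integer >= 3")
  ov <- cfg$confluence_overlap_fraction
  if (!is.numeric(ov) || ov <= 0 || ov >= 1)
    stop("confluence_overlap_fraction must lie strictly between 0 and 1")
  for (nm in c("confluence_threshold_factor", "cell_intensity_threshold",
               "cell_response_fraction", "hough_min_score"))
    if (cfg[[nm]] < 0) stop(sprintf("%s must be >= 0", nm))
  if (!is.null(cfg$constant_threshold) && cfg$constant_threshold < 0)
    stop("constant_threshold must be >= 0")
  rr <- cfg$hough_radius_range_px
  if (length(rr) != 2L || rr[1L] <= 0 || rr[1L] >= rr[2L])
    stop("hough_radius_range_px must be c(min, max) with 0 < min < max")
  for (nm in c("cell_area_range_px2", "carrier_area_range_px2")) {
    ar <- cfg[[nm]]
    if (length(ar) != 2L || ar[1L] < 0 || ar[1L] >= ar[2L])
      stop(sprintf("%s must be c(min, max) with 0 <= min < max", nm))
  }
  if (cfg$aggregate_dilation_radius_px < 0L)
    stop("aggregate_dilation_radius_px must be >= 0")
  if (cfg$carrier_eccentricity_max < 0 || cfg$carrier_eccentricity_max >= 1)
    stop("carrier_eccentricity_max must lie in [0, 1)")
  if (cfg$convergence_tolerance <= 0 || cfg$convergence_tolerance >= 1)
    stop("convergence_tolerance must lie strictly between 0 and 1")
  if (cfg$histogram_bin_width < 1L)
    stop("histogram_bin_width must be >= 1")
  if (!is.null(cfg$pixel_scale_um) && cfg$pixel_scale_um <= 0)
    stop("pixel_scale_um must be positive")
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-30s %s\n", nm,
                if (is.null(v)) "NULL" else paste(signif(unlist(v), 6), collapse = ", ")))
  }
  invisible(x)
}

#' Read an analysis configuration from a YAML file
#'
#' The file holds flat key/value pairs (two-element keys such as
#' `hough_radius_range_px` may be YAML lists); keys absent from the file
#' keep their [analysis_config()] defaults.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return an `analysis_config`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(analysis_config())
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(analysis_config())
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  do.call(analysis_config, vals)
}
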