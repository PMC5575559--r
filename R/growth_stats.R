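#' Running mean of per-carrier counts
#'
#' Element `k` is the mean of the first `k` counts in acquisition order;
#' plotting it against `k` shows how many carriers must be analyzed
#' before the culture's average cells-per-carrier stabilizes.
#'
#' @param counts non-empty numeric vector of per-carrier (corrected)
#'   counts in acquisition order.
#' @return numeric vector of partial means, same length.
#' @export
#' @examples
#' running_mean(c(10, 20, 30))   # 10 15 20
running_mean <- function(counts) {
  if (length(counts) == 0L) stop("counts must be non-empty")
  if (!is.numeric(counts)) stop("counts must be numeric")
  cumsum(counts) / seq_along(counts)
}

#' Index at which a running mean has converged
#'
#' Returns the smallest index `k` such that every partial mean from `k`
#' onward lies within `tolerance_fraction` of the final mean (relative
#' band). When the final mean is zero the band degenerates to an absolute
#' deviation of `tolerance_fraction`. If the band is first entered only
#' at the last element, the sequence length is returned.
#'
#' @param partial_means numeric vector of partial means (length >= 2),
#'   e.g. from [running_mean()].
#' @param tolerance_fraction relative half-width of the convergence band,
#'   in (0, 1).
#' @return integer index.
#' @export
convergence_index <- function(partial_means, tolerance_fraction = 0.05) {
  if (length(partial_means) < 2L) stop("partial_means must have length >= 2")
  if (!is.numeric(tolerance_fraction) || tolerance_fraction <= 0 ||
      tolerance_fraction >= 1)
    stop("tolerance_fraction must lie strictly between 0 and 1")
  n <- length(partial_means)
  final <- partial_means[n]
  band <- if (final != 0) tolerance_fraction * abs(final) else tolerance_fraction
  ok <- abs(partial_means - final) <= band
  bad <- which(!ok)
  if (length(bad) == 0L) return(1L)
  min(max(bad) + 1L, n)
}

#' Colonization histogram normalized to the day's maximum
#'
#' Bins per-carrier counts into intervals of `bin_width` cells covering
#' `[0, max(counts)]` and divides each bin frequency by the largest bin
#' frequency, so the best-populated colonization class is 1 and all other
#' classes are relative to it. This normalization makes the shape of the
#' cell-distribution comparable across culture days with very different
#' numbers of carriers analyzed.
#'
#' @param counts non-empty numeric vector of per-carrier counts (>= 0).
#' @param bin_width bin width in cells per carrier (integer >= 1).
#' @return object of class `colonization_histogram`: `bin_edges` (length
#'   `nbins + 1`, left-closed bins), `normalized_frequency` in `[0, 1]`
#'   with at least one bin equal to 1, and raw `counts` per bin.
#' @export
#' @examples
#' colonization_histogram(c(rep(0, 5), rep(12, 10), rep(25, 5)), 10)
colonization_histogram <- function(counts, bin_width = 5L) {
  if (length(counts) == 0L) stop("counts must be non-empty")
  if (!is.numeric(counts) || any(counts < 0)) stop("counts must be >= 0")
  bw <- as.integer(bin_width)
  if (bw < 1L) stop("bin_width must be >= 1")
  nbins <- floor(max(counts) / bw) + 1L
  edges <- seq(0L, nbins * bw, by = bw)
  bin <- pmin(floor(counts / bw) + 1L, nbins)
  freq <- tabulate(bin, nbins = nbins)
  structure(list(bin_edges = edges,
                 normalized_frequency = freq / max(freq),
                 counts = freq),
            class = "colonization_histogram")
}

#' @export
print.colonization_histogram <- function(x, ...) {
  cat("<colonization_histogram>\n")
  n <- length(x$counts)
  lab <- sprintf("[%g, %g)", x$bin_edges[-(n + 1L)], x$bin_edges[-1L])
  for (i in seq_len(n))
    cat(sprintf("  %-12s n = %4d  normalized = %.3f\n",
                lab[i], x$counts[i], x$normalized_frequency[i]))
  invisible(x)
}

#' Assemble a culture growth profile
#'
#' Collapses per-carrier analyses into one point per culture day: the
#' number of carriers analyzed, the mean hemisphere-corrected cells per
#' carrier, and (when the microcarrier concentration is known) the
#' implied culture density in cells/mL.
#'
#' @param per_day_analyses named list mapping culture day (names coercible
#'   to integer) to either a list of carrier analyses carrying
#'   `cells_corrected`, or a numeric vector of corrected counts. Days with
#'   no analyzable carriers are dropped with a message (reported as
#'   missing, not zero).
#' @param carriers_per_ml microcarrier concentration; `NULL` omits the
#'   density column (`NA`).
#' @return data.frame sorted by ascending day: `culture_day`,
#'   `n_carriers_analyzed`, `mean_cells_per_carrier`,
#'   `cell_density_per_ml`.
#' @export
#' @examples
#' build_growth_profile(list(`2` = c(10, 20)), carriers_per_ml = 1000)
build_growth_profile <- function(per_day_analyses, carriers_per_ml = NULL) {
  if (length(per_day_analyses) == 0L) stop("no per-day analyses supplied")
  if (is.null(names(per_day_analyses)))
    stop("per_day_analyses must be a named list (names = culture days)")
  days <- suppressWarnings(as.integer(names(per_day_analyses)))
  if (anyNA(days)) stop("culture-day names must be integers")

  rows <- lapply(seq_along(days), function(i) {
    el <- per_day_analyses[[i]]
    counts <- if (is.numeric(el)) el else
      vapply(el, function(a) as.numeric(a$cells_corrected), numeric(1L))
    if (length(counts) == 0L) {
      message(sprintf("day %d has no analyzable carriers; reported as missing",
                      days[i]))
      return(NULL)
    }
    data.frame(culture_day = days[i],
               n_carriers_analyzed = length(counts),
               mean_cells_per_carrier = mean(counts))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no day had any analyzable carriers")
  out <- out[order(out$culture_day), , drop = FALSE]
  out$cell_density_per_ml <- if (is.null(carriers_per_ml)) NA_real_ else
    cell_density(out$mean_cells_per_carrier, carriers_per_ml)
  rownames(out) <- NULL
  out
}
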