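#' Synthetic scene specification
#'
#' Describes a synthetic epi-illumination scene: spherical carriers drawn
#' as shaded disks with a brighter rim on a dark background, cells as
#' additive Gaussian blobs on a named carrier, optional in-carrier
#' confluent texture, and i.i.d. Gaussian sensor noise added last. The
#' renderer targets algorithm testability (known ground truth), not
#' photorealism; no optical physics is simulated.
#'
#' @param image_size_px `c(rows, cols)`. Default `c(1024, 1280)`, the
#'   detector geometry at the default pixel scale.
#' @param carriers data.frame with columns `center_row`, `center_col`,
#'   `radius_px`, and optionally `rim_brightness` (default 180),
#'   `body_brightness` (default 120), `texture_fraction` (default 0;
#'   fraction of the disk covered by high-variance cell texture, filled
#'   from the top as a chord).
#' @param cells data.frame with columns `row`, `col`, `sigma_px`,
#'   `amplitude` and `carrier` (index into `carriers`); may be empty.
#' @param background_level background intensity. Default 40.
#' @param noise_std Gaussian sensor-noise standard deviation (8-bit
#'   units). Default 0.
#' @param texture_std standard deviation of the in-carrier cell texture.
#'   Default 45.
#' @param seed integer RNG seed making the rendering reproducible.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size_px = c(1024L, 1280L),
                       carriers = NULL, cells = NULL,
                       background_level = 40, noise_std = 0,
                       texture_std = 45, seed = 1L) {
  H <- as.integer(image_size_px[1L]); W <- as.integer(image_size_px[2L])
  if (H < 15L || W < 15L) stop("image_size_px must be at least 15 x 15")
  if (is.null(carriers))
    carriers <- data.frame(center_row = numeric(), center_col = numeric(),
                           radius_px = numeric())
  if (!all(c("center_row", "center_col", "radius_px") %in% names(carriers)))
    stop("carriers needs columns center_row, center_col, radius_px")
  if (is.null(carriers$rim_brightness))
    carriers$rim_brightness <- rep(180, nrow(carriers))
  if (is.null(carriers$body_brightness))
    carriers$body_brightness <- rep(120, nrow(carriers))
  if (is.null(carriers$texture_fraction))
    carriers$texture_fraction <- rep(0, nrow(carriers))
  if (is.null(cells))
    cells <- data.frame(row = numeric(), col = numeric(),
                        sigma_px = numeric(), amplitude = numeric(),
                        carrier = integer())
  if (!all(c("row", "col", "sigma_px", "amplitude", "carrier") %in% names(cells)))
    stop("cells needs columns row, col, sigma_px, amplitude, carrier")

  edge_margin <- 6   # room for the soft edge profile
  for (i in seq_len(nrow(carriers))) {
    r <- carriers$radius_px[i]
    if (r <= 0) stop(sprintf("carrier %d has non-positive radius", i))
    if (carriers$center_row[i] - r - edge_margin < 1 ||
        carriers$center_row[i] + r + edge_margin > H ||
        carriers$center_col[i] - r - edge_margin < 1 ||
        carriers$center_col[i] + r + edge_margin > W)
      stop(sprintf("carrier %d extends outside the image bounds", i))
    tf <- carriers$texture_fraction[i]
    if (tf < 0 || tf > 1)
      stop(sprintf("carrier %d has texture_fraction outside [0, 1]", i))
  }
  for (j in seq_len(nrow(cells))) {
    ci <- cells$carrier[j]
    if (is.na(ci) || ci < 1L || ci > nrow(carriers))
      stop(sprintf("cell %d names a carrier that does not exist", j))
    d <- sqrt((cells$row[j] - carriers$center_row[ci])^2 +
              (cells$col[j] - carriers$center_col[ci])^2)
    if (d > carriers$radius_px[ci] - 3 * cells$sigma_px[j])
      stop(sprintf("cell %d lies outside carrier %d (must fit 3 sigma inside the rim)", j, ci))
    if (cells$sigma_px[j] <= 0 || cells$amplitude[j] <= 0)
      stop(sprintf("cell %d needs positive sigma and amplitude", j))
  }
  structure(list(image_size_px = c(H, W), carriers = carriers, cells = cells,
                 background_level = background_level, noise_std = noise_std,
                 texture_std = texture_std, seed = as.integer(seed)),
            class = "scene_spec")
}

## radial intensity profile of one carrier at distances rho
carrier_profile <- function(rho, R, bg, body, rim) {
  S <- 1 / (1 + exp(-(R - rho) / 1.5))           # soft disk edge
  bg + (body - bg) * S + (rim - body) * exp(-(rho - (R - 2))^2 / (2 * 1.5^2)) * S
}

#' Render a synthetic scene with ground truth
#'
#' Deterministically (for a fixed seed; Mersenne-Twister with inversion
#' normals) renders the scene described by a [scene_spec()]: carriers as
#' rim-shaded disks, optional in-carrier cell texture, cells as clamped
#' additive Gaussian blobs, and sensor noise added last, all clamped to
#' `[0, 255]`.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (a [gray_image]) and `truth` (class
#'   `scene_truth`): `circles` (the true carrier circles),
#'   `cell_centroids` (row/col/carrier per cell), `cell_footprint_px2`
#'   (analytic half-amplitude footprint area per cell),
#'   `texture_fraction_realized` per carrier,
#'   `true_foreground_fraction` (`NA` for carrier scenes), and
#'   `is_aggregate` (more than two carriers).
#' @export
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec")
  H <- spec$image_size_px[1L]; W <- spec$image_size_px[2L]
  bg <- spec$background_level
  img <- matrix(bg, H, W)
  carriers <- spec$carriers
  tex_real <- rep(0, nrow(carriers))

  with_seed(spec$seed, {
    for (i in seq_len(nrow(carriers))) {
      cr <- carriers$center_row[i]; cc <- carriers$center_col[i]
      R <- carriers$radius_px[i]
      ri <- max(1L, floor(cr - R - 6)):min(H, ceiling(cr + R + 6))
      ci <- max(1L, floor(cc - R - 6)):min(W, ceiling(cc + R + 6))
      rho <- sqrt(outer((ri - cr)^2, (ci - cc)^2, "+"))
      val <- carrier_profile(rho, R, bg, carriers$body_brightness[i],
                             carriers$rim_brightness[i])
      img[ri, ci] <- pmax(img[ri, ci], val)

      tf <- carriers$texture_fraction[i]
      if (tf > 0) {
        disk <- which(rho <= R - 4)
        rows_of <- outer(ri, rep(1L, length(ci)))[disk]
        if (tf >= 1) sel <- disk else {
          cutoff <- stats::quantile(rows_of, probs = tf, names = FALSE, type = 7)
          sel <- disk[rows_of <= cutoff]
        }
        tex_real[i] <- length(sel) / length(disk)
        sub <- img[ri, ci]
        sub[sel] <- sub[sel] + stats::rnorm(length(sel), 0, spec$texture_std)
        img[ri, ci] <- sub
      }
    }
    for (j in seq_len(nrow(spec$cells))) {
      rj <- spec$cells$row[j]; cj <- spec$cells$col[j]
      s <- spec$cells$sigma_px[j]; a <- spec$cells$amplitude[j]
      ext <- ceiling(4 * s)
      ri <- max(1L, floor(rj - ext)):min(H, ceiling(rj + ext))
      ci <- max(1L, floor(cj - ext)):min(W, ceiling(cj + ext))
      d2 <- outer((ri - rj)^2, (ci - cj)^2, "+")
      img[ri, ci] <- img[ri, ci] + a * exp(-d2 / (2 * s^2))
    }
    if (spec$noise_std > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_std)
  })
  img <- pmin(pmax(img, 0), 255)

  truth <- structure(list(
    circles = carriers[, c("center_row", "center_col", "radius_px")],
    cell_centroids = spec$cells[, c("row", "col", "carrier")],
    cell_footprint_px2 = pi * (spec$cells$sigma_px * sqrt(2 * log(2)))^2,
    texture_fraction_realized = tex_real,
    true_foreground_fraction = NA_real_,
    is_aggregate = nrow(carriers) > 2L), class = "scene_truth")
  list(image = gray_image(img), truth = truth)
}

#' Render a synthetic monolayer at a target confluence
#'
#' Emulates a flask monolayer image: a spatially correlated random region
#' (threshold of a bilinearly upsampled coarse Gaussian field, patch scale
#' `patch_scale_px`) is filled with zero-mean high-variance cell texture
#' whose amplitude ramps up over `taper_px` from the region border (colony
#' margins are sparser than colony cores); the remainder stays
#' near-constant, and mild sensor noise covers everything. The region is
#' thresholded at the empirical quantile of the field, so the realized
#' foreground fraction matches the target to well within one percent and
#' is recorded exactly.
#'
#' @param target_foreground_fraction fraction of pixels to cover, in
#'   `[0, 1]`.
#' @param image_size_px `c(rows, cols)`. Default `c(768, 768)`.
#' @param seed RNG seed.
#' @param background_level mean intensity everywhere. Default 110.
#' @param texture_std cell-texture standard deviation. Default 45.
#' @param noise_std sensor-noise standard deviation. Default 2.
#' @param patch_scale_px correlation scale of the colony field. Default
#'   320 (confluent colonies span hundreds of pixels, i.e. ~150 um
#'   patches at the default pixel scale).
#' @param taper_px width of the colony-margin amplitude ramp (the texture
#'   variance ramps up quadratically over this distance from the colony
#'   border, emulating the sparse fringe of edge cells). Default 16.
#' @return list with `image` and `truth` (`true_foreground_fraction` is
#'   the realized fraction, `region_mask` the true cell region).
#' @export
render_monolayer <- function(target_foreground_fraction,
                             image_size_px = c(768L, 768L), seed = 1L,
                             background_level = 110, texture_std = 45,
                             noise_std = 2, patch_scale_px = 320,
                             taper_px = 16) {
  f <- target_foreground_fraction
  if (!is.numeric(f) || f < 0 || f > 1)
    stop("target_foreground_fraction must lie in [0, 1]")
  H <- as.integer(image_size_px[1L]); W <- as.integer(image_size_px[2L])

  img <- matrix(0, H, W)
  mask <- matrix(FALSE, H, W)
  with_seed(seed, {
    if (f > 0 && f < 1) {
      gh <- floor((H - 1) / patch_scale_px) + 2L
      gw <- floor((W - 1) / patch_scale_px) + 2L
      g <- matrix(stats::rnorm(gh * gw), gh, gw)
      tr <- (seq_len(H) - 1) / patch_scale_px
      tc <- (seq_len(W) - 1) / patch_scale_px
      i0 <- floor(tr) + 1L; fr <- tr - floor(tr)
      j0 <- floor(tc) + 1L; fc <- tc - floor(tc)
      gi <- g[i0, , drop = FALSE] * (1 - fr) + g[i0 + 1L, , drop = FALSE] * fr
      field <- gi[, j0, drop = FALSE] * rep(1 - fc, each = H) +
        gi[, j0 + 1L, drop = FALSE] * rep(fc, each = H)
      cutoff <- stats::quantile(field, probs = 1 - f, names = FALSE, type = 7)
      mask <- field >= cutoff
    } else if (f >= 1) {
      mask[] <- TRUE
    }
    amp <- matrix(0, H, W)
    if (any(mask)) {
      m <- mask
      storage.mode(m) <- "double"
      d <- EBImage::distmap(m)
      if (inherits(d, "Image")) d <- EBImage::imageData(d)
      amp <- pmin(d / taper_px, 1)^2   # quadratic ramp: sparse colony fringe
    }
    img <- background_level + amp * stats::rnorm(H * W, 0, texture_std)
    if (noise_std > 0)
      img <- img + stats::rnorm(H * W, 0, noise_std)
  })
  img <- pmin(pmax(img, 0), 255)

  truth <- structure(list(
    circles = data.frame(center_row = numeric(), center_col = numeric(),
                         radius_px = numeric()),
    cell_centroids = data.frame(row = numeric(), col = numeric(),
                                carrier = integer()),
    cell_footprint_px2 = numeric(),
    texture_fraction_realized = numeric(),
    true_foreground_fraction = mean(mask),
    region_mask = mask,
    is_aggregate = FALSE), class = "scene_truth")
  list(image = gray_image(img), truth = truth)
}

## rejection-sample n points in a disk with a minimum pairwise separation
place_points_in_disk <- function(n, center_row, center_col, radius,
                                 min_sep, max_tries = 50000L) {
  pr <- numeric(0); pc <- numeric(0)
  tries <- 0L
  while (length(pr) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place the requested number of cells; reduce n or min_sep")
    a <- stats::runif(1, 0, 2 * pi)
    rr <- radius * sqrt(stats::runif(1))
    r <- center_row + rr * sin(a); c <- center_col + rr * cos(a)
    if (length(pr) == 0L || all((pr - r)^2 + (pc - c)^2 >= min_sep^2)) {
      pr <- c(pr, r); pc <- c(pc, c)
    }
  }
  data.frame(row = pr, col = pc)
}

## place n_carriers mutually separated carriers (gap range edge-to-edge)
place_carrier_cluster <- function(n_carriers, H, W, radius_range, gap_range,
                                  margin = 8, max_tries = 400L) {
  R <- stats::runif(n_carriers, radius_range[1L], radius_range[2L])
  cr <- numeric(n_carriers); cc <- numeric(n_carriers)
  cr[1L] <- H / 2 + stats::runif(1, -40, 40)
  cc[1L] <- W / 2 + stats::runif(1, -40, 40)
  for (i in seq_len(n_carriers)[-1L]) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      anchor <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
      ang <- stats::runif(1, 0, 2 * pi)
      gap <- stats::runif(1, gap_range[1L], gap_range[2L])
      d <- R[anchor] + R[i] + gap
      r <- cr[anchor] + d * sin(ang); c <- cc[anchor] + d * cos(ang)
      if (r - R[i] - margin < 1 || r + R[i] + margin > H ||
          c - R[i] - margin < 1 || c + R[i] + margin > W) next
      prev <- seq_len(i - 1L)
      if (all(sqrt((cr[prev] - r)^2 + (cc[prev] - c)^2) >=
              R[prev] + R[i] + gap_range[1L])) {
        cr[i] <- r; cc[i] <- c; placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place carrier cluster; image too small")
  }
  data.frame(center_row = cr, center_col = cc, radius_px = R)
}

#' Render a reproducible suite of synthetic scenes
#'
#' Generates `n_scenes` parameter-randomized scenes of one kind with
#' per-scene derived seeds (`seed + index - 1` for parameter sampling,
#' offset by 10^6 for rendering), so a suite is reproducible end to end.
#'
#' Kinds:
#' \describe{
#'   \item{`monolayer`}{flask monolayers; `fraction` fixes the target
#'     confluence, otherwise sampled uniformly in `[0.1, 0.9]`.}
#'   \item{`single-carrier`}{one carrier per scene (radius sampled in
#'     `radius_range`) bearing `n_cells` well-separated cells.}
#'   \item{`pair`}{two closely spaced carriers (not an aggregate under the
#'     "more than two" rule).}
#'   \item{`aggregate`}{a clump of 3-4 closely spaced carriers;
#'     `is_aggregate` is `TRUE` by construction.}
#' }
#'
#' @param kind scene kind (see above).
#' @param n_scenes number of scenes (>= 1).
#' @param seed base seed.
#' @param fraction (monolayer) target foreground fraction, or `NULL`.
#' @param n_cells (single-carrier) cells per carrier. Default 0.
#' @param noise_std sensor noise. Default 3 (carrier kinds), 2 (monolayer).
#' @param radius_range carrier radius range in px. Defaults: single
#'   carrier `c(150, 235)`, pair/aggregate `c(140, 180)`.
#' @param image_size_px scene size. Defaults: monolayer `c(768, 768)`,
#'   single carrier `c(520, 520)`, pair/aggregate `c(1024, 1280)`.
#' @param cell_sigma_px Gaussian sigma of rendered cells. Default 10.
#' @param cell_amplitude peak cell brightness above the carrier body.
#'   Default 110.
#' @return list of `list(image, truth)` of length `n_scenes`.
#' @export
render_suite <- function(kind = c("monolayer", "single-carrier", "pair",
                                  "aggregate"),
                         n_scenes, seed = 1L, fraction = NULL,
                         n_cells = 0L, noise_std = NULL,
                         radius_range = NULL, image_size_px = NULL,
                         cell_sigma_px = 10, cell_amplitude = 110) {
  kind <- match.arg(kind)
  if (n_scenes < 1L) stop("n_scenes must be >= 1")
  out <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    param_seed <- as.integer(seed) + i - 1L
    render_seed <- param_seed + 1000000L
    out[[i]] <- switch(
      kind,
      "monolayer" = {
        f <- if (is.null(fraction))
          with_seed(param_seed, stats::runif(1, 0.1, 0.9)) else fraction
        render_monolayer(f,
                         image_size_px = if (is.null(image_size_px))
                           c(768L, 768L) else image_size_px,
                         seed = render_seed,
                         noise_std = if (is.null(noise_std)) 2 else noise_std)
      },
      "single-carrier" = {
        rr <- if (is.null(radius_range)) c(150, 235) else radius_range
        sz <- if (is.null(image_size_px)) c(520L, 520L) else image_size_px
        ns <- if (is.null(noise_std)) 3 else noise_std
        spec <- with_seed(param_seed, {
          R <- stats::runif(1, rr[1L], rr[2L])
          jit <- min(15, (min(sz) / 2 - R - 8))
          cr <- sz[1L] / 2 + stats::runif(1, -jit, jit)
          cc <- sz[2L] / 2 + stats::runif(1, -jit, jit)
          cells <- NULL
          if (n_cells > 0L) {
            pts <- place_points_in_disk(n_cells, cr, cc,
                                        R - 3.2 * cell_sigma_px,
                                        min_sep = 3.2 * cell_sigma_px)
            cells <- data.frame(row = pts$row, col = pts$col,
                                sigma_px = cell_sigma_px,
                                amplitude = cell_amplitude, carrier = 1L)
          }
          scene_spec(image_size_px = sz,
                     carriers = data.frame(center_row = cr, center_col = cc,
                                           radius_px = R),
                     cells = cells, noise_std = ns, seed = render_seed)
        })
        render_scene(spec)
      },
      "pair" = ,
      "aggregate" = {
        rr <- if (is.null(radius_range)) c(140, 180) else radius_range
        sz <- if (is.null(image_size_px)) c(1024L, 1280L) else image_size_px
        ns <- if (is.null(noise_std)) 3 else noise_std
        spec <- with_seed(param_seed, {
          nc <- if (kind == "pair") 2L else sample(3:4, 1L)
          carriers <- place_carrier_cluster(nc, sz[1L], sz[2L], rr,
                                            gap_range = c(15, 30))
          scene_spec(image_size_px = sz, carriers = carriers,
                     noise_std = ns, seed = render_seed)
        })
        render_scene(spec)
      })
  }
  out
}
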