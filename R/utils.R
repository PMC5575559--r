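## Internal numeric helpers shared across modules.

## population standard deviation (divisor n, not n-1)
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

## mirror-pad a matrix by p pixels on every side (edge row not duplicated)
pad_reflect <- function(x, p) {
  if (p == 0L) return(x)
  H <- nrow(x); W <- ncol(x)
  if (p >= H || p >= W)
    stop("padding exceeds image size")
  ri <- c((p + 1L):2L, seq_len(H), (H - 1L):(H - p))
  ci <- c((p + 1L):2L, seq_len(W), (W - 1L):(W - p))
  x[ri, ci]
}

## sliding k x k window sums at every top-left position (shift-add, not
## integral images: keeps absolute rounding error at ~k additions per window)
box_sum <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  nr <- H - k + 1L
  s <- x[seq_len(nr), , drop = FALSE]
  if (k > 1L)
    for (off in seq_len(k - 1L))
      s <- s + x[seq_len(nr) + off, , drop = FALSE]
  nc <- W - k + 1L
  s2 <- s[, seq_len(nc), drop = FALSE]
  if (k > 1L)
    for (off in seq_len(k - 1L))
      s2 <- s2 + s[, seq_len(nc) + off, drop = FALSE]
  s2
}

## 3x3 box sum, zero-padded, same shape
box3 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  s <- x
  s[seq_len(H - 1L), ] <- s[seq_len(H - 1L), , drop = FALSE] + x[2L:H, , drop = FALSE]
  s[2L:H, ] <- s[2L:H, , drop = FALSE] + x[seq_len(H - 1L), , drop = FALSE]
  s2 <- s
  s2[, seq_len(W - 1L)] <- s2[, seq_len(W - 1L), drop = FALSE] + s[, 2L:W, drop = FALSE]
  s2[, 2L:W] <- s2[, 2L:W, drop = FALSE] + s[, seq_len(W - 1L), drop = FALSE]
  s2
}

## 3x3 max filter, same shape
max3 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  s <- x
  s[seq_len(H - 1L), ] <- pmax(s[seq_len(H - 1L), , drop = FALSE], x[2L:H, , drop = FALSE])
  s[2L:H, ] <- pmax(s[2L:H, , drop = FALSE], x[seq_len(H - 1L), , drop = FALSE])
  s2 <- s
  s2[, seq_len(W - 1L)] <- pmax(s2[, seq_len(W - 1L), drop = FALSE], s[, 2L:W, drop = FALSE])
  s2[, 2L:W] <- pmax(s2[, 2L:W, drop = FALSE], s[, seq_len(W - 1L), drop = FALSE])
  s2
}

## binary disk structuring element: offsets with dr^2 + dc^2 <= r^2
disc_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= r^2
  storage.mode(k) <- "double"
  k
}

## run code under a fixed Mersenne-Twister seed, restoring the caller's
## RNG state afterwards (keeps library calls free of global side effects)
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

## 8-connected component labeling: EBImage::bwlabel (4-connected) plus a
## union-find merge of diagonally adjacent labels; labels are renumbered
## 1..n in order of each component's first pixel (column-major)
label8 <- function(binary) {
  b <- binary
  storage.mode(b) <- "double"
  lab <- EBImage::bwlabel(b)
  if (inherits(lab, "Image")) lab <- EBImage::imageData(lab)
  lab <- matrix(as.integer(lab), nrow(b), ncol(b))
  n <- max(lab)
  if (n == 0L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  ## diagonal neighbor pairs (down-right and down-left shifts)
  a1 <- lab[-H, -W]; b1 <- lab[-1L, -1L]
  a2 <- lab[-H, -1L]; b2 <- lab[-1L, -W]
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1L))
  ## renumber roots by first-pixel order so labeling is deterministic
  first_px <- match(seq_len(n), as.vector(lab))
  root_first <- vapply(unique(root), function(r)
    min(first_px[root == r]), numeric(1L))
  ord <- unique(root)[order(root_first)]
  newid <- integer(n)
  newid[ord] <- seq_along(ord)
  out <- lab
  out[lab > 0L] <- newid[root[lab[lab > 0L]]]
  out
}

## per-label area, centroid and peak of an auxiliary raster
component_stats <- function(lab, aux = NULL) {
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label_id = integer(), area_px2 = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      peak = numeric()))
  idx <- which(lab > 0L)
  l <- lab[idx]
  H <- nrow(lab)
  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  area <- tabulate(l, nbins = n)
  crow <- as.vector(rowsum(as.numeric(rr), l)) / area
  ccol <- as.vector(rowsum(as.numeric(cc), l)) / area
  pk <- if (is.null(aux)) rep(NA_real_, n) else
    vapply(split(aux[idx], l), max, numeric(1L))
  data.frame(label_id = seq_len(n), area_px2 = as.numeric(area),
             centroid_row = crow, centroid_col = ccol, peak = pk)
}

## accept a one-row data.frame or a named list/vector as a circle
as_circle <- function(circle) {
  if (is.data.frame(circle)) {
    if (nrow(circle) != 1L) stop("expected a single circle (one row)")
    circle <- as.list(circle)
  }
  circle <- as.list(circle)
  need <- c("center_row", "center_col", "radius_px")
  if (!all(need %in% names(circle)))
    stop("a circle needs fields center_row, center_col, radius_px")
  if (circle$radius_px <= 0) stop("circle radius must be positive")
  circle
}
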