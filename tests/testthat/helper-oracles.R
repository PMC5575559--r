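# Independent brute-force oracles used to validate the fast implementations.

# population sd
o_pop_sd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / length(v))
}

# exhaustive windowed-std map: every pixel gets the max population sd over
# all stride-grid windows covering it; uncovered pixels inherit the value
# of the nearest covered pixel (index clamping)
oracle_std_map <- function(x, k, stride) {
  H <- nrow(x); W <- ncol(x)
  tops_r <- seq(1L, H - k + 1L, by = stride)
  tops_c <- seq(1L, W - k + 1L, by = stride)
  wsd <- matrix(NA_real_, length(tops_r), length(tops_c))
  for (a in seq_along(tops_r))
    for (b in seq_along(tops_c)) {
      w <- x[tops_r[a]:(tops_r[a] + k - 1L), tops_c[b]:(tops_c[b] + k - 1L)]
      wsd[a, b] <- o_pop_sd(as.vector(w))
    }
  out <- matrix(NA_real_, H, W)
  cov_r_max <- max(tops_r) + k - 1L
  cov_c_max <- max(tops_c) + k - 1L
  for (i in seq_len(H))
    for (j in seq_len(W)) {
      ii <- min(i, cov_r_max); jj <- min(j, cov_c_max)
      ra <- which(tops_r <= ii & tops_r + k - 1L >= ii)
      cb <- which(tops_c <= jj & tops_c + k - 1L >= jj)
      out[i, j] <- max(wsd[ra, cb])
    }
  out
}

# dense convolution with mirror border padding (edge pixel not duplicated)
oracle_conv_reflect <- function(x, ker) {
  H <- nrow(x); W <- ncol(x)
  k <- nrow(ker); h <- (k - 1L) %/% 2L
  refl <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H))
    for (j in seq_len(W)) {
      acc <- 0
      for (di in -h:h)
        for (dj in -h:h)
          acc <- acc + ker[di + h + 1L, dj + h + 1L] *
            x[refl(i + di, H), refl(j + dj, W)]
      out[i, j] <- acc
    }
  out
}

# flood-fill connected-component labeling (8- or 4-connectivity), labels
# numbered by first pixel in column-major order
oracle_label <- function(bin, connectivity = 8L) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  cur <- 0L
  for (j in seq_len(W))
    for (i in seq_len(H)) {
      if (!bin[i, j] || lab[i, j] != 0L) next
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (q in seq_len(nrow(nb))) {
          r <- p[1L] + nb[q, 1L]; c <- p[2L] + nb[q, 2L]
          if (r >= 1L && r <= H && c >= 1L && c <= W &&
              bin[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  lab
}

# masked windowed-std classification: an in-mask pixel is foreground when
# any covering full window has a population sd (over its in-mask pixels)
# at or above the threshold
oracle_masked_classify <- function(x, mask, k, thr) {
  H <- nrow(x); W <- ncol(x)
  cls <- matrix(FALSE, H, W)
  for (a in seq_len(H - k + 1L))
    for (b in seq_len(W - k + 1L)) {
      rows <- a:(a + k - 1L); cols <- b:(b + k - 1L)
      m <- mask[rows, cols]
      if (!any(m)) next
      if (o_pop_sd(x[rows, cols][m]) >= thr)
        cls[rows, cols] <- cls[rows, cols] | TRUE
    }
  cls & mask
}

# equivalent-ellipse eccentricity from second-order central moments
oracle_eccentricity <- function(rows, cols) {
  mr <- mean(rows); mc <- mean(cols)
  mrr <- mean((rows - mr)^2); mcc <- mean((cols - mc)^2)
  mrc <- mean((rows - mr) * (cols - mc))
  tr <- mrr + mcc
  det <- mrr * mcc - mrc^2
  l1 <- tr / 2 + sqrt(max(0, tr^2 / 4 - det))
  l2 <- tr / 2 - sqrt(max(0, tr^2 / 4 - det))
  if (l1 <= 0) return(0)
  sqrt(1 - l2 / l1)
}

# deterministic random test image on [0, 255]
random_image <- function(H, W, seed) {
  set.seed(seed)
  matrix(runif(H * W, 0, 255), H, W)
}
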