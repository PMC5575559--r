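test_that("running_mean returns the sequence of partial means", {
  expect_equal(running_mean(c(10, 20, 30)), c(10, 15, 20))
  expect_equal(running_mean(rep(7, 5)), rep(7, 5))
  set.seed(1)
  v <- rpois(40, 25)
  rm_ <- running_mean(v)
  expect_equal(rm_[length(v)], mean(v))
  expect_equal(rm_, cumsum(v) / seq_along(v))
  expect_error(running_mean(numeric(0)), "non-empty")
})

test_that("convergence_index finds the first index after the last excursion", {
  expect_equal(convergence_index(rep(5, 10), 0.05), 1L)
  expect_equal(convergence_index(c(0, 20, rep(10, 8)), 0.05), 3L)

  # direct-scan oracle on random partial-mean sequences
  oracle_k <- function(pm, tol) {
    final <- pm[length(pm)]
    band <- if (final != 0) tol * abs(final) else tol
    for (k in seq_along(pm))
      if (all(abs(pm[k:length(pm)] - final) <= band)) return(k)
    length(pm)
  }
  set.seed(9)
  for (i in 1:20) {
    pm <- running_mean(rpois(60, 20))
    for (tol in c(0.02, 0.05, 0.2))
      expect_equal(convergence_index(pm, tol), oracle_k(pm, tol))
  }

  # a sequence that only enters the band at its final element
  pm <- c(10, 9, 8, 7, 1)
  expect_equal(convergence_index(pm, 0.05), 5L)

  # zero final mean: absolute-deviation rule
  expect_equal(convergence_index(c(1, 0.04, 0, 0), 0.05), 2L)

  # widening the tolerance never delays convergence
  pm2 <- running_mean(c(0, 40, 20, 22, 19, 21, 20, 20, 20, 20))
  ks <- vapply(c(0.01, 0.05, 0.1, 0.3), function(t)
    convergence_index(pm2, t), integer(1))
  expect_true(all(diff(ks) <= 0))

  expect_error(convergence_index(5, 0.05), "length >= 2")
  expect_error(convergence_index(c(1, 2), 1.5), "between 0 and 1")
})

test_that("the convergence index behaves plausibly for Poisson-like cultures", {
  # i.i.d. counts around 30 cells/carrier: the running mean should settle
  # within a few dozen carriers, echoing the 20-40 carriers seen in practice
  set.seed(123)
  ks <- replicate(100, convergence_index(running_mean(rpois(120, 30)), 0.05))
  expect_gte(stats::median(ks), 5)
  expect_lte(stats::median(ks), 80)
  expect_gte(mean(ks <= 100), 0.9)
})

test_that("colonization histograms normalize to the day's maximum bin", {
  h <- colonization_histogram(c(rep(0, 5), rep(12, 10), rep(25, 5)), 10)
  expect_equal(h$normalized_frequency, c(0.5, 1, 0.5))
  expect_equal(h$bin_edges, c(0, 10, 20, 30))
  expect_equal(h$counts, c(5, 10, 5))

  # identical counts occupy a single bin at frequency 1
  h1 <- colonization_histogram(rep(14, 8), 5)
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(max(h1$normalized_frequency), 1)

  set.seed(4)
  for (i in 1:10) {
    counts <- rpois(50, 20)
    h2 <- colonization_histogram(counts, 5)
    expect_true(all(h2$normalized_frequency >= 0 & h2$normalized_frequency <= 1))
    expect_equal(max(h2$normalized_frequency), 1)
    expect_equal(sum(h2$counts), length(counts))
    expect_gte(h2$bin_edges[length(h2$bin_edges)], max(counts))
    # bin contents agree with a direct tally
    want <- tabulate(pmin(floor(counts / 5) + 1, length(h2$counts)),
                     nbins = length(h2$counts))
    expect_equal(h2$counts, want)
  }
  expect_error(colonization_histogram(numeric(0)), "non-empty")
  expect_error(colonization_histogram(c(1, 2), 0), ">= 1")
})

test_that("growth profiles aggregate per-day counts correctly", {
  prof <- build_growth_profile(list(`2` = c(10, 20)), carriers_per_ml = 1000)
  expect_equal(prof$mean_cells_per_carrier, 15)
  expect_equal(prof$cell_density_per_ml, 15000)
  expect_equal(prof$n_carriers_analyzed, 2L)

  # reverse day order in, ascending out; missing concentration -> NA density
  prof2 <- build_growth_profile(list(`6` = c(40, 50), `2` = c(10, 20)))
  expect_equal(prof2$culture_day, c(2L, 6L))
  expect_true(all(is.na(prof2$cell_density_per_ml)))

  # accepts carrier-analysis lists and matches brute-force recomputation
  set.seed(11)
  days <- list()
  for (d in c(2, 4, 6)) {
    counts <- 2L * rpois(5, 10)
    days[[as.character(d)]] <- lapply(counts, function(k)
      list(cells_corrected = k))
  }
  prof3 <- build_growth_profile(days, carriers_per_ml = 800)
  for (i in seq_len(nrow(prof3))) {
    raw <- vapply(days[[as.character(prof3$culture_day[i])]],
                  function(a) a$cells_corrected, numeric(1))
    expect_equal(prof3$mean_cells_per_carrier[i], mean(raw))
    expect_equal(prof3$cell_density_per_ml[i], mean(raw) * 800)
  }

  # a day with no analyzable carriers is reported missing, not zero
  expect_message(
    prof4 <- build_growth_profile(list(`2` = c(10), `4` = numeric(0))),
    "missing")
  expect_equal(prof4$culture_day, 2L)
  expect_error(build_growth_profile(list(`2` = numeric(0))), "no day")
})
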