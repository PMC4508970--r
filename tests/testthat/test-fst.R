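test_that("fixed differences give theta exactly 1", {
  comp <- wc_theta_site(10, 10, 1, 0, 0, 0)
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)
  # swapping which population is fixed changes nothing
  comp2 <- wc_theta_site(10, 10, 0, 1, 0, 0)
  expect_equal(comp2, comp)
})

test_that("identical population samples give theta <= 0", {
  set.seed(5)
  for (k in 1:10) {
    p <- runif(1, 0.1, 0.9)
    h <- 2 * p * (1 - p)
    comp <- wc_theta_site(12, 12, p, p, h, h)
    den <- comp$a + comp$b + comp$c
    if (den > 0) expect_lte(comp$a / den, 0)
  }
})

test_that("theta is invariant to allele-label swap", {
  set.seed(8)
  for (k in 1:10) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    p1 <- runif(1); p2 <- runif(1)
    h1 <- runif(1, 0, 2 * min(p1, 1 - p1))
    h2 <- runif(1, 0, 2 * min(p2, 1 - p2))
    a <- wc_theta_site(n1, n2, p1, p2, h1, h2)
    b <- wc_theta_site(n1, n2, 1 - p1, 1 - p2, h1, h2)
    expect_equal(a$a / (a$a + a$b + a$c), b$a / (b$a + b$b + b$c),
                 tolerance = 1e-12)
  }
})

test_that("variance components match the ANOVA-form oracle", {
  set.seed(21)
  for (k in 1:30) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    p1 <- runif(1); p2 <- runif(1)
    h1 <- runif(1, 0, 2 * min(p1, 1 - p1))
    h2 <- runif(1, 0, 2 * min(p2, 1 - p2))
    got <- wc_theta_site(n1, n2, p1, p2, h1, h2)
    want <- oracle_wc(c(n1, n2), c(p1, p2), c(h1, h2))
    expect_equal(got$a, unname(want["a"]), tolerance = 1e-12)
    expect_equal(got$b, unname(want["b"]), tolerance = 1e-12)
    expect_equal(got$c, unname(want["c"]), tolerance = 1e-12)
  }
})

make_two_pop_cohort <- function(geno, positions, layout,
                                pops = rep(c("p1", "p2"), each = 4)) {
  sites <- tibble::tibble(chrom = "1", pos = positions,
                          class = "synonymous")
  toy_cohort(layout, sites, geno, pops = pops)
}

test_that("binned Fst: monomorphic bins missing, fixed differences at 1", {
  layout <- genome_layout("1", 3e4)
  # 3 bins: bin0 fixed difference, bin1 monomorphic, bin2 polymorphic
  geno <- rbind(c(2, 2, 2, 2, 0, 0, 0, 0),    # fixed diff
                c(0, 0, 0, 0, 0, 0, 0, 0),    # monomorphic
                c(1, 0, 2, 1, 0, 1, 1, 2))    # shared polymorphism
  storage.mode(geno) <- "integer"
  colnames(geno) <- paste0("I", 1:8)
  co <- make_two_pop_cohort(geno, c(5e3, 15e3, 25e3), layout)
  tr <- fst_bins(co)
  expect_equal(tr$theta[tr$bin == 0], 1)
  expect_true(is.na(tr$theta[tr$bin == 1]))
  expect_equal(tr$n_sites, c(1L, 0L, 1L))
})

test_that("bin theta is a ratio of sums matching a per-site oracle", {
  set.seed(33)
  layout <- genome_layout("1", 2e4)
  n <- 40
  geno <- matrix(sample(0:2, n * 10, replace = TRUE), n, 10,
                 dimnames = list(NULL, paste0("I", 1:10)))
  storage.mode(geno) <- "integer"
  geno[sample(length(geno), 20)] <- NA  # missing genotypes reduce n
  co <- make_two_pop_cohort(geno, sort(sample(0:19999, n)), layout,
                            pops = rep(c("p1", "p2"), each = 5))
  tr <- fst_bins(co)
  # oracle: loop sites, accumulate components per bin
  sums <- matrix(0, 2, 2)  # rows bins, cols (num, den)
  nsit <- c(0L, 0L)
  for (i in seq_len(n)) {
    g1 <- geno[i, 1:5]; g2 <- geno[i, 6:10]
    n1 <- sum(!is.na(g1)); n2 <- sum(!is.na(g2))
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) next
    p1 <- sum(g1, na.rm = TRUE) / (2 * n1)
    p2 <- sum(g2, na.rm = TRUE) / (2 * n2)
    h1 <- sum(g1 == 1, na.rm = TRUE) / n1
    h2 <- sum(g2 == 1, na.rm = TRUE) / n2
    cmp <- oracle_wc(c(n1, n2), c(p1, p2), c(h1, h2))
    if (sum(cmp) == 0) next
    b <- co$sites$pos[i] %/% 10000 + 1
    sums[b, 1] <- sums[b, 1] + cmp["a"]
    sums[b, 2] <- sums[b, 2] + sum(cmp)
    nsit[b] <- nsit[b] + 1L
  }
  expect_equal(tr$theta, sums[, 1] / sums[, 2], tolerance = 1e-12)
  expect_equal(tr$n_sites, nsit)
})

test_that("planted frequency divergence raises bin Fst monotonically", {
  layout <- genome_layout("1", 1e5)
  thetas <- purrr::map_dbl(c(0, 0.2, 0.4), function(shift) {
    co <- simulate_cohort(layout, sim_params(
      n_pops = 2, n_per_pop = 10, tract_plan = NULL, seed = 9,
      sweep = list(chrom = "1", start = 0, end = 1e5, carrier_frac = 0,
                   freq_shift = shift)))
    mean(fst_bins(co)$theta, na.rm = TRUE)
  })
  expect_true(all(diff(thetas) > 0))
})

test_that("populations with fewer than two samples are skipped", {
  layout <- genome_layout("1", 2e4)
  geno <- matrix(sample(0:2, 30, replace = TRUE), 10, 3,
                 dimnames = list(NULL, paste0("I", 1:3)))
  storage.mode(geno) <- "integer"
  co <- make_two_pop_cohort(geno, sort(sample(0:19999, 10)), layout,
                            pops = c("p1", "p1", "p2"))
  expect_warning(tr <- fst_bins(co), "skipped")
  expect_equal(nrow(tr), 0)
})

test_that("aggregation averages windows missing-aware", {
  track <- tibble::tibble(chrom = "1", bin = 0:59,
                          bin_start = (0:59) * 1e4,
                          bin_end = (1:60) * 1e4,
                          theta = c(rep(0.1, 25), NA, rep(0.3, 24),
                                    rep(NA, 10)))
  agg <- aggregate_track(track, theta, agg_size = 5e5)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$value[1], mean(c(rep(0.1, 25), rep(0.3, 24))))
  expect_true(is.na(agg$value[2]))
  expect_equal(agg$n_bins, c(49L, 0L))
  agg2 <- aggregate_track(dplyr::mutate(track, theta = NA_real_), theta)
  expect_true(all(is.na(agg2$value)))
})

test_that("track correlation: identity, and failure below 3 windows", {
  t1 <- tibble::tibble(chrom = "1", bin_start = (0:9) * 5e5,
                       value = runif(10))
  expect_equal(correlate_tracks(t1, t1)$r, 1)
  expect_error(correlate_tracks(t1[1:2, ], t1[1:2, ]), "fewer than 3")
})

test_that("a co-located sweep couples Fst to ROH sharing", {
  lay <- genome_layout(c("1", "2"), c(5e6, 5e6))
  plan <- tibble::tibble(size_class = c("S", "M"), count = c(10, 3),
                         min_bp = c(2e4, 15e4), max_bp = c(9e4, 5e5))
  co <- simulate_cohort(lay, sim_params(
    n_pops = 2, n_per_pop = 8, tract_plan = plan, seed = 31,
    sweep = list(chrom = "1", start = 1e6, end = 2e6, carrier_frac = 0.9,
                 freq_shift = 0.35)))
  roh <- classify_roh(call_roh(bin_heterozygosity(co)))
  share <- sharing_track(roh, lay)
  fst <- fst_bins(co)
  agg_f <- aggregate_track(fst, theta)
  agg_s <- aggregate_track(share, sharing)
  ct <- correlate_tracks(agg_f, agg_s)
  expect_gt(ct$r, 0)
  expect_lt(ct$p.value, 0.05)
})
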