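#' Weir-Cockerham per-site variance components for two populations
#'
#' The genotypic (observed-heterozygosity-aware) two-level estimator:
#' per site, components a (among populations), b (among individuals within
#' populations) and c (within individuals), from per-population sample
#' sizes (diploid individuals with non-missing genotypes), alternate-allele
#' frequencies and observed heterozygote proportions. The per-site theta
#' is a / (a + b + c); sites monomorphic across both populations give all
#' zero components and are skipped in the ratio-of-sums.
#'
#' Vectorised over sites.
#'
#' @param n1,n2 Sample sizes (individuals) per population.
#' @param p1,p2 Alternate-allele frequencies per population.
#' @param h1,h2 Observed heterozygote proportions per population.
#' @return Tibble with columns `a`, `b`, `c`.
#' @examples
#' wc_theta_site(10, 10, 1, 0, 0, 0)  # fixed difference: a/(a+b+c) = 1
#' @export
wc_theta_site <- function(n1, n2, p1, p2, h1, h2) {
  stopifnot(all(n1 >= 1), all(n2 >= 1))
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  tibble::tibble(a = a, b = b, c = cc)
}

#' Binned pairwise Weir-Cockerham Fst
#'
#' For every pair of populations, computes per-site variance components and
#' combines them per fixed-width bin as a ratio of sums:
#' theta_bin = sum(a) / sum(a + b + c) over the bin's polymorphic sites.
#' Bins with a zero denominator (no informative site) are missing.
#' Missing genotypes reduce the per-population sample size site by site;
#' populations with fewer than 2 genotyped individuals are skipped with a
#' warning.
#'
#' @param cohort An `roh_cohort`.
#' @param bin_size Bin width in bp (default 10 kbp).
#' @param pairs Optional list of 2-vectors of population names; default all
#'   pairs.
#' @return Tibble: `pop_a`, `pop_b`, `chrom`, `bin`, `bin_start`,
#'   `bin_end`, `theta`, `n_sites` over the full bin grid.
#' @export
fst_bins <- function(cohort, bin_size = 10000, pairs = NULL) {
  samples <- cohort$samples
  pops <- unique(samples$pop)
  if (length(pops) < 2) stop("need at least 2 populations")
  sizes <- table(samples$pop)
  ok <- names(sizes)[sizes >= 2]
  if (length(ok) < length(pops))
    warning("populations with < 2 samples skipped: ",
            paste(setdiff(pops, ok), collapse = ", "))
  grid0 <- bin_grid(cohort$layout, bin_size)
  if (length(ok) < 2) {
    return(tibble::tibble(pop_a = character(), pop_b = character(),
                          chrom = character(), bin = integer(),
                          bin_start = numeric(), bin_end = numeric(),
                          theta = numeric(), n_sites = integer()))
  }
  if (is.null(pairs)) {
    pairs <- utils::combn(ok, 2, simplify = FALSE)
  }
  grid <- bin_grid(cohort$layout, bin_size)
  sites <- cohort$sites
  site_bin <- .pos_to_bin(sites$pos, bin_size)

  purrr::map_dfr(pairs, function(pr) {
    ga <- cohort$geno[, samples$sample[samples$pop == pr[1]], drop = FALSE]
    gb <- cohort$geno[, samples$sample[samples$pop == pr[2]], drop = FALSE]
    st_a <- .pop_site_stats(ga)
    st_b <- .pop_site_stats(gb)
    usable <- st_a$n >= 1 & st_b$n >= 1 & (st_a$n + st_b$n) >= 3
    comp <- wc_theta_site(st_a$n[usable], st_b$n[usable],
                          st_a$p[usable], st_b$p[usable],
                          st_a$h[usable], st_b$h[usable])
    poly <- (comp$a + comp$b + comp$c) != 0
    key <- paste(sites$chrom[usable], site_bin[usable])
    num <- tapply(ifelse(poly, comp$a, 0), key, sum)
    den <- tapply(ifelse(poly, comp$a + comp$b + comp$c, 0), key, sum)
    nst <- tapply(as.integer(poly), key, sum)
    g <- grid
    gk <- paste(g$chrom, g$bin)
    g$n_sites <- as.integer(nst[gk])
    g$n_sites[is.na(g$n_sites)] <- 0L
    d <- as.numeric(den[gk])
    n <- as.numeric(num[gk])
    g$theta <- ifelse(!is.na(d) & d > 0, n / d, NA_real_)
    g$pop_a <- pr[1]
    g$pop_b <- pr[2]
    g[, c("pop_a", "pop_b", "chrom", "bin", "bin_start", "bin_end",
          "theta", "n_sites")]
  })
}

# per-site n (genotyped individuals), alt frequency, observed het proportion
.pop_site_stats <- function(g) {
  n <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  het <- rowSums(g == 1L, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
       h = ifelse(n > 0, het / n, NA_real_))
}

#' Aggregate a binned track into larger windows
#'
#' Missing-aware mean of a fine-binned value (e.g. 10-kbp theta or
#' sharing) over coarser windows (default 500 kbp, i.e. 50 constituent
#' bins except at chromosome ends).
#'
#' @param track Tibble with `chrom`, `bin_start`, `bin_end` and the value
#'   column.
#' @param value Column to aggregate (tidy-eval).
#' @param agg_size Window size in bp (default 500 kbp).
#' @return Tibble: `chrom`, `bin_start`, `bin_end`, `value` (the mean),
#'   `n_bins` (non-missing constituent bins).
#' @export
aggregate_track <- function(track, value, agg_size = 5e5) {
  track |>
    dplyr::mutate(.w = (.data$bin_start %/% agg_size) * agg_size,
                  .v = dplyr::pull(track, {{ value }})) |>
    dplyr::group_by(.data$chrom, bin_start = .data$.w) |>
    dplyr::summarise(bin_end = max(.data$bin_end),
                     value = if (all(is.na(.data$.v))) NA_real_
                             else mean(.data$.v, na.rm = TRUE),
                     n_bins = sum(!is.na(.data$.v)),
                     .groups = "drop")
}

#' Correlate two aggregated genomic tracks
#'
#' Joins two tracks on their (chrom, window) grid and computes the Pearson
#' correlation with its two-tailed test over windows where both values are
#' non-missing — e.g. 500-kbp Fst against 500-kbp ROH sharing.
#'
#' @param track_a,track_b Tibbles from [aggregate_track()] (columns
#'   `chrom`, `bin_start`, `value`).
#' @return One-row tibble: `r`, `statistic`, `p.value`, `n`.
#' @export
correlate_tracks <- function(track_a, track_b) {
  j <- dplyr::inner_join(track_a, track_b, by = c("chrom", "bin_start"),
                         suffix = c("_a", "_b"))
  j <- j[is.finite(j$value_a) & is.finite(j$value_b), ]
  if (nrow(j) < 3) stop("fewer than 3 shared non-missing windows")
  pearson_with_test(j$value_a, j$value_b)
}
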