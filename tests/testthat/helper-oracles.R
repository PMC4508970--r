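# Independent brute-force oracles and hand-built fixtures. Every oracle is
# written from the defining formula, not by calling the package code.

# --- fixtures ---------------------------------------------------------------

# a minimal in-memory cohort with full uniform coverage
toy_cohort <- function(layout, sites, geno, bin_size = 10000,
                       pops = NULL, depth = NULL) {
  samples <- colnames(geno)
  if (is.null(pops)) pops <- rep("pop1", length(samples))
  grid <- rohscape::bin_grid(layout, bin_size)
  if (is.null(depth)) {
    depth <- purrr::map_dfr(samples, function(s) {
      dplyr::mutate(grid, sample = s, covered_bp = bin_bp)
    })
    depth <- depth[, c("sample", "chrom", "bin", "bin_start", "bin_end",
                       "covered_bp")]
  }
  sites$site_id <- seq_len(nrow(sites))
  if (!"ref" %in% names(sites)) sites$ref <- "A"
  if (!"alt" %in% names(sites)) sites$alt <- "T"
  structure(list(sites = sites, geno = geno,
                 samples = tibble::tibble(sample = samples, pop = pops),
                 freqs = NULL, depth = depth,
                 truth_tracts = tibble::tibble(sample = character(),
                                               chrom = character(),
                                               start = numeric(),
                                               end = numeric(),
                                               size_class = character()),
                 layout = layout, bin_size = bin_size, params = NULL),
            class = "roh_cohort")
}

# a hand-made binned-heterozygosity track for one individual
toy_bins <- function(corrected, usable = NULL, chrom = "1",
                     bin_size = 10000, sample = "S1") {
  n <- length(corrected)
  if (is.null(usable)) usable <- rep(TRUE, n)
  tibble::tibble(sample = sample, chrom = chrom, bin = seq_len(n) - 1L,
                 bin_start = (seq_len(n) - 1) * bin_size,
                 bin_end = seq_len(n) * bin_size, bin_bp = bin_size,
                 n_het = NA_integer_, covered_bp = bin_size,
                 corrected = ifelse(usable, corrected, NA_real_),
                 usable = usable)
}

# one default-conditions cohort, simulated once and shared across tests
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- rohscape::simulate_cohort(
        rohscape::demo_layout(),
        rohscape::sim_params(n_pops = 1, n_per_pop = 20, seed = 101))
    }
    cache
  }
})

# --- caller oracle ----------------------------------------------------------

# brute force: test every bin against the threshold, enumerate runs by
# explicit scanning (no rle), apply the minimum length last
oracle_call_roh <- function(bins, threshold_factor = 0.25,
                            min_length = 10000) {
  out <- NULL
  for (s in unique(bins$sample)) {
    b <- bins[bins$sample == s, ]
    thr <- threshold_factor * mean(b$corrected[b$usable])
    for (cn in unique(b$chrom)) {
      bc <- b[b$chrom == cn, ]
      bc <- bc[order(bc$bin), ]
      run_start <- NA
      for (k in seq_len(nrow(bc) + 1)) {
        ok <- k <= nrow(bc) && bc$usable[k] && !is.na(bc$corrected[k]) &&
          bc$corrected[k] <= thr
        if (ok && is.na(run_start)) run_start <- k
        if (!ok && !is.na(run_start)) {
          seg <- data.frame(sample = s, chrom = cn,
                            start = bc$bin_start[run_start],
                            end = bc$bin_end[k - 1])
          out <- rbind(out, seg)
          run_start <- NA
        }
      }
    }
  }
  if (is.null(out)) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          length = numeric(), n_bins = integer()))
  }
  out$length <- out$end - out$start
  out <- out[out$length >= min_length, ]
  tibble::as_tibble(out[order(out$sample, out$chrom, out$start),
                        c("sample", "chrom", "start", "end", "length")])
}

# random binned track for oracle-equivalence tests
random_track <- function(n_bins, sample = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  toy_bins(corrected = stats::rpois(n_bins, lambda = sample(c(0.2, 2, 8), n_bins,
                                                            replace = TRUE)),
           usable = stats::runif(n_bins) > 0.1,
           chrom = sample(c("1", "2"), 1), sample = sample)
}

# --- partition oracle -------------------------------------------------------

# per-site loop over every (individual, site): direct interval membership
oracle_partition <- function(cohort, roh) {
  rows <- list()
  for (s in colnames(cohort$geno)) {
    segs <- roh[roh$sample == s, ]
    for (i in seq_len(nrow(cohort$sites))) {
      g <- cohort$geno[i, s]
      if (is.na(g)) next
      cls <- "N"
      if (nrow(segs)) {
        for (r in seq_len(nrow(segs))) {
          if (segs$chrom[r] == cohort$sites$chrom[i] &&
              cohort$sites$pos[i] >= segs$start[r] &&
              cohort$sites$pos[i] < segs$end[r]) {
            cls <- segs$size_class[r]
            break
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, roh_class = cls, func_class = cohort$sites$class[i],
        k = g)
    }
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          df[, c("sample", "roh_class", "func_class", "k")],
                          FUN = sum)
  tibble::as_tibble(agg)
}

# random small partition fixture: sites + genotypes + disjoint labeled ROH
random_partition_fixture <- function(seed) {
  set.seed(seed)
  layout <- rohscape::genome_layout("1", 1e6)
  n <- 50
  sites <- tibble::tibble(
    chrom = "1", pos = sort(sample.int(1e6, n) - 1),
    class = sample(c("deleterious", "non_deleterious", "synonymous"), n,
                   replace = TRUE))
  geno <- matrix(sample(c(0:2, NA), n * 3, replace = TRUE,
                        prob = c(.4, .3, .25, .05)),
                 n, 3, dimnames = list(NULL, c("A", "B", "C")))
  roh <- purrr::map_dfr(c("A", "B", "C"), function(s) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    starts <- sort(sample(seq(0, 9e5, by = 1e5), k))
    tibble::tibble(sample = s, chrom = "1", start = starts,
                   end = starts + sample(c(2e4, 5e4, 9e4), k, replace = TRUE))
  })
  if (nrow(roh)) {
    roh$length <- roh$end - roh$start
    roh <- rohscape::classify_roh(roh, short_max = 5e4, long_min = 8e4)
  }
  list(cohort = toy_cohort(layout, sites, geno), roh = roh)
}

# --- regression / correlation / t-test oracles ------------------------------

# OLS by explicit normal equations, with classical SEs and t-tests
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(s2 * solve(XtX)))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)
  list(beta = as.numeric(beta), se = as.numeric(se),
       t = as.numeric(tstat), p = as.numeric(pval))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# --- Weir-Cockerham oracle --------------------------------------------------

# ANOVA-style formulation with explicit population loops (Weir 1996 ch. 5)
oracle_wc <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  n_tot <- sum(n_i)
  n_bar <- n_tot / r
  n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  p_bar <- sum(n_i * p_i) / n_tot
  h_bar <- sum(n_i * h_i) / n_tot
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  a <- (n_bar / n_c) * (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                                h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                                  (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

# --- sharing oracle ---------------------------------------------------------

# O(n_individuals x n_bins) interval stabbing
oracle_sharing <- function(roh, layout, bin_size = 10000) {
  grid <- rohscape::bin_grid(layout, bin_size)
  counts <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    for (s in unique(roh$sample)) {
      segs <- roh[roh$sample == s & roh$chrom == grid$chrom[g], ]
      hit <- FALSE
      for (r in seq_len(nrow(segs))) {
        if (segs$start[r] < grid$bin_end[g] &&
            grid$bin_start[g] < segs$end[r]) hit <- TRUE
      }
      if (hit) counts[g] <- counts[g] + 1L
    }
  }
  grid$sharing <- counts
  grid
}

# fraction of truth tracts (>= min_bins bins long) recovered by a called
# segment with both boundaries within tol_bp
tract_recall <- function(truth, called, min_bins = 2, bin_size = 10000,
                         tol_bp = 10000) {
  big <- truth[truth$end - truth$start >= min_bins * bin_size, ]
  if (!nrow(big)) return(NA_real_)
  hit <- purrr::map_lgl(seq_len(nrow(big)), function(i) {
    cand <- called[called$sample == big$sample[i] &
                     called$chrom == big$chrom[i], ]
    any(abs(cand$start - big$start[i]) <= tol_bp &
          abs(cand$end - big$end[i]) <= tol_bp)
  })
  mean(hit)
}
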