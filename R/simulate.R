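#' Draw diploid genotypes under the HWE / IBD-tract law
#'
#' Outside identity-by-descent (IBD) tracts a site follows Hardy-Weinberg
#' equilibrium: P(0) = (1-p)^2, P(1) = 2p(1-p), P(2) = p^2. Inside a tract
#' both haplotypes descend from one ancestral copy, so the site is
#' homozygous with the *allele* frequency governing which homozygote:
#' P(2) = p, P(0) = 1 - p, P(1) = 0. A heterozygote-error is applied last:
#' each truly homozygous call flips to heterozygous with probability
#' `het_error_rate`.
#'
#' @param p Numeric vector of alternate-allele frequencies in \[0, 1\].
#' @param in_tract Logical vector (recycled): is the site inside an IBD
#'   tract of this individual?
#' @param het_error_rate Probability a homozygous genotype is read as
#'   heterozygous.
#' @return Integer vector of alternate-allele counts in \{0, 1, 2\}.
#' @examples
#' set.seed(1)
#' table(draw_genotypes(rep(0.5, 1000), in_tract = TRUE))
#' @export
draw_genotypes <- function(p, in_tract = FALSE, het_error_rate = 0) {
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  n <- length(p)
  in_tract <- rep_len(as.logical(in_tract), n)
  u <- stats::runif(n)
  g <- integer(n)
  if (any(in_tract)) {
    g[in_tract] <- ifelse(u[in_tract] < p[in_tract], 2L, 0L)
  }
  if (any(!in_tract)) {
    ph <- p[!in_tract]
    uh <- u[!in_tract]
    q0 <- (1 - ph)^2
    q1 <- q0 + 2 * ph * (1 - ph)
    g[!in_tract] <- ifelse(uh < q0, 0L, ifelse(uh < q1, 1L, 2L))
  }
  if (het_error_rate > 0) {
    hom <- g != 1L
    flip <- hom & stats::runif(n) < het_error_rate
    g[flip] <- 1L
  }
  g
}

#' Simulate a multi-population diploid cohort with planted IBD tracts
#'
#' Generates everything the downstream ROH pipeline consumes: biallelic
#' sites with one functional class each, per-population allele frequencies,
#' diploid genotypes under the HWE/IBD law of [draw_genotypes()], planted
#' truth tracts in three size classes, and a per-bin depth track feeding
#' the caller's correction factor. Optionally plants a shared "sweep"
#' region (an IBD tract common to a fraction of individuals, with optional
#' allele-frequency divergence in population 1) as a positive control for
#' the sharing null and the Fst correlation.
#'
#' @param layout A [genome_layout()].
#' @param params A [sim_params()] object.
#' @param bin_size Bin width in bp for the depth track (default 10 kbp).
#' @return A list of class `roh_cohort` with elements `sites` (tibble:
#'   site_id, chrom, pos (0-based), ref, alt, class), `geno` (integer
#'   matrix, sites x samples, alt-allele counts), `samples` (tibble:
#'   sample, pop), `freqs` (matrix, sites x populations, truth
#'   frequencies), `depth` (tibble: sample, chrom, bin, bin_start,
#'   bin_end, covered_bp), `truth_tracts` (tibble: sample, chrom, start,
#'   end, size_class), plus `layout`, `bin_size` and the `params` echo.
#' @export
simulate_cohort <- function(layout, params = sim_params(), bin_size = 10000) {
  .check_layout(layout)
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)

  classes <- names(params$site_density)
  sites <- purrr::map_dfr(classes, function(cl) {
    dens <- params$site_density[[cl]]
    purrr::map2_dfr(layout$chrom, layout$length, function(cn, len) {
      n <- stats::rpois(1, dens * len)
      if (n == 0) return(NULL)
      tibble::tibble(chrom = cn, pos = sort(sample.int(len, n) - 1), class = cl)
    })
  })
  sites <- dplyr::arrange(sites, match(.data$chrom, layout$chrom), .data$pos)
  # one site per position: keep first class drawn at a collided position
  sites <- dplyr::distinct(sites, .data$chrom, .data$pos, .keep_all = TRUE)
  n_sites <- nrow(sites)
  if (n_sites == 0) stop("site densities produced an empty site set")
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, n_sites, replace = TRUE)
  sites$alt <- purrr::map_chr(sites$ref, function(r) sample(setdiff(bases, r), 1))
  sites$site_id <- seq_len(n_sites)
  sites <- sites[, c("site_id", "chrom", "pos", "ref", "alt", "class")]

  # Balding-Nichols frequencies: an ancestral frequency per site from the
  # class law, then one Beta draw per population dispersed around it with
  # target differentiation F = pop_divergence
  freqs <- matrix(NA_real_, n_sites, params$n_pops,
                  dimnames = list(NULL, paste0("pop", seq_len(params$n_pops))))
  p0 <- numeric(n_sites)
  for (cl in classes) {
    idx <- which(sites$class == cl)
    m <- params$freq_mean[[cl]]
    p0[idx] <- stats::rbeta(length(idx), m * params$freq_conc,
                            (1 - m) * params$freq_conc)
  }
  p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
  bn_k <- (1 - params$pop_divergence) / params$pop_divergence
  for (j in seq_len(params$n_pops)) {
    freqs[, j] <- if (params$n_pops == 1) p0 else {
      stats::rbeta(n_sites, p0 * bn_k, (1 - p0) * bn_k)
    }
  }
  sweep <- params$sweep
  if (!is.null(sweep)) {
    shift <- sweep$freq_shift %||% 0
    if (shift != 0) {
      in_sw <- sites$chrom == sweep$chrom & sites$pos >= sweep$start & sites$pos < sweep$end
      freqs[in_sw, 1] <- pmin(0.999, pmax(0.001, freqs[in_sw, 1] + shift))
    }
  }

  samples <- tibble::tibble(
    sample = paste0("P", rep(seq_len(params$n_pops), each = params$n_per_pop),
                    "_I", rep(seq_len(params$n_per_pop), params$n_pops)),
    pop = paste0("pop", rep(seq_len(params$n_pops), each = params$n_per_pop))
  )
  n_ind <- nrow(samples)

  # planted tracts: sweep carriers first, then the per-class random plan
  tracts <- vector("list", n_ind)
  carriers <- logical(n_ind)
  if (!is.null(sweep)) {
    frac <- sweep$carrier_frac %||% 1
    carriers <- stats::runif(n_ind) < frac
  }
  intensity <- stats::runif(n_ind, params$ind_intensity[1], params$ind_intensity[2])
  for (i in seq_len(n_ind)) {
    existing <- if (carriers[i]) {
      tibble::tibble(chrom = sweep$chrom, start = sweep$start, end = sweep$end,
                     size_class = .size_class_of(sweep$end - sweep$start))
    } else {
      tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                     size_class = character())
    }
    if (!is.null(params$tract_plan)) {
      plan <- purrr::map_dfr(seq_len(nrow(params$tract_plan)), function(r) {
        row <- params$tract_plan[r, ]
        k <- stats::rpois(1, row$count * intensity[i])
        if (k == 0) return(NULL)
        tibble::tibble(size_class = row$size_class,
                       len = round(stats::runif(k, row$min_bp, row$max_bp)))
      })
      if (nrow(plan)) {
        plan <- plan[order(-plan$len), ]  # big tracts first: fewer rejections
        for (r in seq_len(nrow(plan))) {
          existing <- .place_tracts(plan$len[r], plan$size_class[r], existing,
                                    layout, who = samples$sample[i])
        }
      }
    }
    if (nrow(existing)) existing$sample <- samples$sample[i]
    tracts[[i]] <- existing
  }
  truth <- dplyr::bind_rows(tracts)
  if (nrow(truth)) {
    truth <- dplyr::arrange(truth[, c("sample", "chrom", "start", "end", "size_class")],
                            .data$sample, match(.data$chrom, layout$chrom), .data$start)
  } else {
    truth <- tibble::tibble(sample = character(), chrom = character(),
                            start = numeric(), end = numeric(), size_class = character())
  }

  # genotypes
  geno <- matrix(NA_integer_, n_sites, n_ind, dimnames = list(NULL, samples$sample))
  pop_of <- match(samples$pop, colnames(freqs))
  mult <- params$tract_freq_mult
  for (i in seq_len(n_ind)) {
    tr <- truth[truth$sample == samples$sample[i], ]
    in_tract <- .sites_in_intervals(sites, tr)
    p <- freqs[, pop_of[i]]
    if (!is.null(mult)) {
      # class-specific enrichment: scale deleterious freqs inside tracts
      jcl <- .site_roh_class(sites, tr)
      for (sc in names(mult)) {
        sel <- sites$class == "deleterious" & jcl == sc
        p[sel] <- pmin(0.999, p[sel] * mult[[sc]])
      }
    }
    geno[, i] <- draw_genotypes(p, in_tract, params$het_error_rate)
  }

  # per-bin depth: covered bases = bin width x capped log-normal fraction
  grid <- bin_grid(layout, bin_size)
  depth <- purrr::map_dfr(samples$sample, function(s) {
    frac <- pmin(1, stats::rlnorm(nrow(grid), log(0.92), params$depth_sdlog))
    dplyr::mutate(grid, sample = s, covered_bp = round(.data$bin_bp * frac))
  })
  depth <- depth[, c("sample", "chrom", "bin", "bin_start", "bin_end", "covered_bp")]

  structure(list(sites = sites, geno = geno, samples = samples, freqs = freqs,
                 depth = depth, truth_tracts = truth,
                 layout = layout, bin_size = bin_size, params = params),
            class = "roh_cohort")
}

#' @export
print.roh_cohort <- function(x, ...) {
  cat("<roh_cohort> ", nrow(x$sites), " sites x ", nrow(x$samples),
      " individuals (", length(unique(x$samples$pop)), " populations)\n", sep = "")
  cat("  genome: ", nrow(x$layout), " chromosomes, ",
      format(genome_size(x$layout), big.mark = ","), " bp; bin size ",
      x$bin_size, "\n", sep = "")
  cat("  planted tracts: ", nrow(x$truth_tracts), "\n", sep = "")
  invisible(x)
}

#' Thin a cohort to SNP-array density
#'
#' Uniformly subsamples the site set, preserving genotypes at retained
#' sites — a stand-in for genotyping the same individuals on a lower-density
#' SNP chip, used to demonstrate that short ROH become undetectable at
#' array density.
#'
#' @param cohort An `roh_cohort`.
#' @param target_density Target sites per bp (must be below the current
#'   density, otherwise the cohort is returned unchanged with a warning).
#' @param seed Integer seed for the thinning draw.
#' @return A reduced `roh_cohort`.
#' @export
downsample_to_array <- function(cohort, target_density, seed = 1L) {
  stopifnot(inherits(cohort, "roh_cohort"))
  cur <- nrow(cohort$sites) / genome_size(cohort$layout)
  if (target_density >= cur) {
    warning("target density is not below current density; returning cohort unchanged")
    return(cohort)
  }
  set.seed(seed)
  n_keep <- max(1, round(target_density * genome_size(cohort$layout)))
  keep <- sort(sample.int(nrow(cohort$sites), n_keep))
  cohort$sites <- cohort$sites[keep, ]
  cohort$sites$site_id <- seq_len(nrow(cohort$sites))
  cohort$geno <- cohort$geno[keep, , drop = FALSE]
  cohort$freqs <- cohort$freqs[keep, , drop = FALSE]
  cohort
}

# uniform placement of tract lengths on a layout, avoiding overlap with
# `existing` tracts of the same individual; resamples up to a retry cap
.place_tracts <- function(lens, size_class, existing, layout, who, max_try = 1000) {
  for (L in lens) {
    ok_chrom <- layout[layout$length >= L, ]
    if (nrow(ok_chrom) == 0)
      stop("tract of ", L, " bp does not fit any chromosome (individual ", who, ")")
    placed <- FALSE
    for (try in seq_len(max_try)) {
      cn <- sample(ok_chrom$chrom, 1, prob = ok_chrom$length)
      len_c <- ok_chrom$length[ok_chrom$chrom == cn]
      start <- floor(stats::runif(1, 0, len_c - L + 1))
      end <- start + L
      same <- existing[existing$chrom == cn, ]
      if (!nrow(same) || all(end <= same$start | start >= same$end)) {
        existing <- dplyr::bind_rows(existing,
          tibble::tibble(chrom = cn, start = start, end = end,
                         size_class = size_class))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a ", L, " bp tract without overlap for individual ",
           who, " after ", max_try, " tries; tract plan infeasible")
  }
  existing
}

# logical: is each site inside any of the (disjoint) intervals?
.sites_in_intervals <- function(sites, intervals) {
  out <- logical(nrow(sites))
  if (!nrow(intervals)) return(out)
  for (cn in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == cn, ]
    iv <- iv[order(iv$start), ]
    on_c <- which(sites$chrom == cn)
    if (!length(on_c)) next
    idx <- findInterval(sites$pos[on_c], iv$start)
    hit <- idx > 0 & sites$pos[on_c] < iv$end[pmax(idx, 1)]
    out[on_c[hit]] <- TRUE
  }
  out
}

# default size-class labeller used for planted tracts (default thresholds)
.size_class_of <- function(len, short_max = 1e5, long_min = 3e6) {
  ifelse(len < short_max, "S", ifelse(len <= long_min, "M", "L"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
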