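#' Bin heterozygosity with depth correction
#'
#' Counts heterozygous genotypes per individual in fixed-width genomic bins
#' and applies the coverage correction: the corrected count is the raw
#' heterozygous-SNP count multiplied by `bin width / DP`, where DP is the
#' number of covered bases in the bin. Bins whose relative coverage
#' (DP / bin width) falls outside 0.5x-2x of the individual's mean relative
#' coverage, or that have no depth information, are flagged unusable: they
#' are too distorted for the correction to be trusted, and they interrupt
#' ROH runs downstream.
#'
#' @param cohort An `roh_cohort` (from [simulate_cohort()] or
#'   [read_cohort_vcf()]).
#' @param qual_threshold Optional minimum site QUAL; sites below it are
#'   ignored. Default `NULL` (off) — synthetic genotypes carry no QUAL.
#' @return Tibble with one row per individual x bin: `sample`, `chrom`,
#'   `bin`, `bin_start`, `bin_end`, `bin_bp`, `n_het` (raw count),
#'   `covered_bp`, `corrected`, `usable`.
#' @export
bin_heterozygosity <- function(cohort, qual_threshold = NULL) {
  stopifnot(inherits(cohort, "roh_cohort") || is.list(cohort))
  sites <- cohort$sites
  geno <- cohort$geno
  if (is.null(geno) || nrow(geno) == 0) stop("cohort has no genotypes")
  if (!is.null(qual_threshold) && "qual" %in% names(sites)) {
    keep <- !is.na(sites$qual) & sites$qual > qual_threshold
    sites <- sites[keep, ]
    geno <- geno[keep, , drop = FALSE]
  }
  bin_size <- cohort$bin_size
  site_bin <- .pos_to_bin(sites$pos, bin_size)
  key <- paste(sites$chrom, site_bin)

  depth <- cohort$depth
  out <- purrr::map_dfr(colnames(geno), function(s) {
    het <- geno[, s] == 1L
    het[is.na(het)] <- FALSE
    cnt <- tapply(het, key, sum)
    d <- depth[depth$sample == s, ]
    d$n_het <- as.integer(cnt[paste(d$chrom, d$bin)])
    d$n_het[is.na(d$n_het)] <- 0L
    rel <- d$covered_bp / (d$bin_end - d$bin_start)
    mean_rel <- mean(rel[!is.na(rel) & d$covered_bp > 0])
    d$usable <- !is.na(d$covered_bp) & d$covered_bp > 0 &
      rel >= 0.5 * mean_rel & rel <= 2 * mean_rel
    d$corrected <- ifelse(d$usable,
                          d$n_het * (d$bin_end - d$bin_start) / d$covered_bp,
                          NA_real_)
    d
  })
  out$bin_bp <- out$bin_end - out$bin_start
  out[, c("sample", "chrom", "bin", "bin_start", "bin_end", "bin_bp",
          "n_het", "covered_bp", "corrected", "usable")]
}

#' Call runs of homozygosity from a binned heterozygosity track
#'
#' A bin qualifies as homozygous when its corrected heterozygous-SNP count
#' is at most `threshold_factor` times the individual's genome-wide mean
#' corrected count per usable bin. Maximal runs of consecutive qualifying
#' usable bins on one chromosome become ROH segments; unusable bins
#' interrupt runs (a `bridge` allowance can let short unusable gaps be
#' crossed), and segments shorter than `min_length` are discarded.
#'
#' @param bins Output of [bin_heterozygosity()].
#' @param threshold_factor Fraction of the genome-wide mean corrected count
#'   below which a bin counts as homozygous (default 0.25).
#' @param min_length Minimum ROH length in bp (default 10 kbp, the minimum
#'   size considered).
#' @param bridge Number of consecutive unusable bins a run may cross
#'   (default 0: conservative, no calling through no-data regions).
#' @return Tibble of segments: `sample`, `chrom`, `start`, `end` (0-based
#'   half-open, bin-aligned), `length`, `n_bins`.
#' @export
call_roh <- function(bins, threshold_factor = 0.25, min_length = 10000,
                     bridge = 0) {
  stopifnot(threshold_factor > 0, min_length > 0)
  out <- purrr::map_dfr(unique(bins$sample), function(s) {
    b <- bins[bins$sample == s, ]
    if (!any(b$usable)) {
      warning("all bins unusable for individual ", s, "; no ROH called")
      return(NULL)
    }
    thr <- threshold_factor * mean(b$corrected[b$usable])
    segs <- purrr::map_dfr(unique(b$chrom), function(cn) {
      bc <- b[b$chrom == cn, ]
      bc <- bc[order(bc$bin), ]
      qual <- bc$usable & !is.na(bc$corrected) & bc$corrected <= thr
      sg <- .runs_to_segments(qual, bc$usable, bc$bin_start, bc$bin_end, bridge)
      if (!is.null(sg) && nrow(sg)) sg$chrom <- cn
      sg
    })
    if (nrow(segs)) segs$sample <- s
    segs
  })
  if (!nrow(out)) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          length = numeric(), n_bins = integer()))
  }
  out <- out[out$length >= min_length, ]
  out[, c("sample", "chrom", "start", "end", "length", "n_bins")]
}

# maximal runs of TRUE in `qual`; non-qualifying usable bins always break a
# run, unusable bins break it unless the unusable gap is <= bridge bins and
# qualifying bins flank it
.runs_to_segments <- function(qual, usable, bin_start, bin_end, bridge = 0) {
  n <- length(qual)
  if (n == 0) return(NULL)
  state <- ifelse(qual, 1L, ifelse(usable, 0L, 2L))
  if (bridge > 0) {
    # promote short unusable gaps flanked by qualifying bins
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] == 2L && r$lengths[k] <= bridge &&
          k > 1 && k < length(r$values) &&
          r$values[k - 1] == 1L && r$values[k + 1] == 1L) {
        state[starts[k]:ends[k]] <- 1L
      }
    }
  }
  in_run <- state == 1L
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep)) return(NULL)
  tibble::tibble(
    start = bin_start[starts[keep]],
    end = bin_end[ends[keep]],
    length = bin_end[ends[keep]] - bin_start[starts[keep]],
    n_bins = as.integer(r$lengths[keep])
  )
}

#' Nucleotide diversity genome-wide and outside ROH
#'
#' Computes pi as corrected heterozygous positions per kbp over usable
#' bins, and pi-out as the same restricted to usable bins that do not
#' overlap any ROH of the individual. Whenever ROH exist, pi-out >= pi,
#' because ROH bins are depleted of heterozygotes by construction.
#'
#' @param bins Output of [bin_heterozygosity()].
#' @param roh Segment tibble from [call_roh()] (may be empty).
#' @return Tibble per individual: `sample`, `pi`, `pi_out`,
#'   `n_usable_bins`, `n_bins_out`. `NA` where no usable bases exist.
#' @export
nucleotide_diversity <- function(bins, roh) {
  purrr::map_dfr(unique(bins$sample), function(s) {
    b <- bins[bins$sample == s & bins$usable, ]
    if (!nrow(b)) {
      return(tibble::tibble(sample = s, pi = NA_real_, pi_out = NA_real_,
                            n_usable_bins = 0L, n_bins_out = 0L))
    }
    pi <- sum(b$corrected) / sum(b$bin_bp) * 1000
    r <- roh[roh$sample == s, ]
    if (nrow(r)) {
      in_roh <- purrr::map_lgl(seq_len(nrow(b)), function(k) {
        rc <- r[r$chrom == b$chrom[k], ]
        any(rc$start < b$bin_end[k] & b$bin_start[k] < rc$end)
      })
    } else {
      in_roh <- rep(FALSE, nrow(b))
    }
    bo <- b[!in_roh, ]
    pi_out <- if (nrow(bo)) sum(bo$corrected) / sum(bo$bin_bp) * 1000 else NA_real_
    tibble::tibble(sample = s, pi = pi, pi_out = pi_out,
                   n_usable_bins = nrow(b), n_bins_out = nrow(bo))
  })
}
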