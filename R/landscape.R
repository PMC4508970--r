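#' Classify ROH segments into size classes
#'
#' Short (S) segments are smaller than `short_max`; medium (M) segments run
#' from `short_max` up to and including `long_min`; long (L) segments are
#' strictly larger than `long_min`. Defaults follow the standard 100 kbp /
#' 3 Mbp convention; the alternates 50 kbp / 2 Mbp and 150 kbp / 4 Mbp are
#' supported by changing the thresholds.
#'
#' @param roh Segment tibble from [call_roh()] (needs a `length` column).
#' @param short_max Upper bound (exclusive) of the short class, bp.
#' @param long_min Lower bound (exclusive) of the long class, bp.
#' @return The input tibble with a `size_class` column in \{"S","M","L"\}.
#' @export
classify_roh <- function(roh, short_max = 1e5, long_min = 3e6) {
  stopifnot(short_max < long_min)
  dplyr::mutate(roh, size_class = ifelse(.data$length < short_max, "S",
                                  ifelse(.data$length <= long_min, "M", "L")))
}

#' Genome coverage proportions by ROH size class
#'
#' For each individual, the fraction of total genome length covered by
#' short, medium, long, and any ROH (G_S, G_M, G_L, G_R). Additivity
#' G_S + G_M + G_L = G_R holds exactly because segments are disjoint and
#' each carries one size class.
#'
#' @param roh Labelled segment tibble from [classify_roh()].
#' @param layout A [genome_layout()].
#' @param samples Optional character vector of all individuals, so that
#'   individuals without any ROH appear with zero coverage.
#' @return Tibble per individual: `sample`, `g_s`, `g_m`, `g_l`, `g_r`.
#' @export
coverage_profile <- function(roh, layout, samples = NULL) {
  gsize <- genome_size(layout)
  .check_disjoint(roh)
  wide <- roh |>
    dplyr::group_by(.data$sample, .data$size_class) |>
    dplyr::summarise(bp = sum(.data$length), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "size_class", values_from = "bp",
                       values_fill = 0)
  for (cl in c("S", "M", "L")) if (!cl %in% names(wide)) wide[[cl]] <- 0
  out <- tibble::tibble(sample = wide$sample,
                        g_s = wide$S / gsize, g_m = wide$M / gsize,
                        g_l = wide$L / gsize)
  if (!is.null(samples)) {
    missing <- setdiff(samples, out$sample)
    if (length(missing)) {
      out <- dplyr::bind_rows(out, tibble::tibble(sample = missing,
                                                  g_s = 0, g_m = 0, g_l = 0))
    }
    out <- out[match(samples, out$sample), ]
  }
  dplyr::mutate(out, g_r = .data$g_s + .data$g_m + .data$g_l)
}

#' ROH sharing across individuals per bin
#'
#' For every fixed-width bin of the genome, counts how many individuals
#' have at least one ROH overlapping the bin (half-open interval
#' intersection); with `count = "pairs"` the number of sharing pairs
#' `choose(k, 2)` is reported instead.
#'
#' @param roh Segment tibble (any individual set).
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp (default 10 kbp).
#' @param count `"individuals"` (default) or `"pairs"`.
#' @return Tibble over the full bin grid: `chrom`, `bin`, `bin_start`,
#'   `bin_end`, `sharing`.
#' @export
sharing_track <- function(roh, layout, bin_size = 10000,
                          count = c("individuals", "pairs")) {
  count <- match.arg(count)
  grid <- bin_grid(layout, bin_size)
  if (length(unique(roh$sample)) < 2)
    warning("fewer than 2 individuals; sharing track is trivial")
  if (nrow(roh)) {
    hits <- purrr::pmap_dfr(
      roh[, c("sample", "chrom", "start", "end")],
      function(sample, chrom, start, end) {
        b0 <- .pos_to_bin(start, bin_size)
        b1 <- .pos_to_bin(end - 1, bin_size)
        tibble::tibble(sample = sample, chrom = chrom, bin = b0:b1)
      })
    per_bin <- hits |>
      dplyr::distinct(.data$sample, .data$chrom, .data$bin) |>
      dplyr::count(.data$chrom, .data$bin, name = "k")
    grid <- dplyr::left_join(grid, per_bin, by = c("chrom", "bin"))
    grid$k[is.na(grid$k)] <- 0L
  } else {
    grid$k <- 0L
  }
  grid$sharing <- if (count == "pairs") choose(grid$k, 2) else grid$k
  grid[, c("chrom", "bin", "bin_start", "bin_end", "sharing")]
}

#' Randomize ROH placement over the genome
#'
#' Length-preserving shuffle used to build the demographic null for ROH
#' sharing: for each individual, the number of segments and the multiset
#' of segment lengths are kept exactly, but each segment is re-placed
#' uniformly (chromosome drawn proportional to length among chromosomes
#' that fit the segment, position uniform, resampled on within-individual
#' overlap). Placements are not re-aligned to the bin grid.
#'
#' @param roh Segment tibble; a `size_class` column, if present, travels
#'   with each segment (length is preserved, so the class is too).
#' @param layout A [genome_layout()].
#' @return A shuffled segment tibble with the same columns.
#' @export
randomize_roh <- function(roh, layout) {
  has_class <- "size_class" %in% names(roh)
  out <- purrr::map_dfr(unique(roh$sample), function(s) {
    r <- roh[roh$sample == s, ]
    r <- r[order(-r$length), ]  # place big segments first: fewer rejections
    placed <- tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric(), size_class = character())
    for (k in seq_len(nrow(r))) {
      placed <- .place_tracts(r$length[k],
                              if (has_class) r$size_class[k] else NA_character_,
                              placed, layout, who = s)
    }
    placed$sample <- s
    placed$length <- placed$end - placed$start
    placed
  })
  cols <- c("sample", "chrom", "start", "end", "length",
            if (has_class) "size_class")
  out[, cols]
}

#' Randomization null for the sharing track
#'
#' Repeatedly applies [randomize_roh()] to the whole cohort and summarises
#' each replicate's sharing track, giving the null distribution of sharing
#' under "ROH placement is pure demography, position-free".
#'
#' @param roh Segment tibble for the cohort.
#' @param layout A [genome_layout()].
#' @param reps Number of null replicates (default 200).
#' @param bin_size Bin width in bp.
#' @param count Passed to [sharing_track()].
#' @param seed Integer seed.
#' @return Tibble: `rep`, `max_sharing`, `mean_sharing`.
#' @export
sharing_null <- function(roh, layout, reps = 200, bin_size = 10000,
                         count = "individuals", seed = 1L) {
  set.seed(seed)
  purrr::map_dfr(seq_len(reps), function(r) {
    shuf <- randomize_roh(roh, layout)
    tr <- suppressWarnings(sharing_track(shuf, layout, bin_size, count))
    tibble::tibble(rep = r, max_sharing = max(tr$sharing),
                   mean_sharing = mean(tr$sharing))
  })
}

.check_disjoint <- function(roh) {
  if (!nrow(roh)) return(invisible(roh))
  bad <- roh |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(ovl = dplyr::n() > 1 &&
                       any(.data$start[-1] < .data$end[-dplyr::n()]),
                     .groups = "drop")
  if (any(bad$ovl))
    stop("overlapping ROH segments within an individual: ",
         paste(unique(bad$sample[bad$ovl]), collapse = ", "))
  invisible(roh)
}
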