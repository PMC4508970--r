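#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosomes (autosomes) over which
#' every binned track in the package is laid out. All internal coordinates
#' are 0-based, half-open; conversion to 1-based happens only at VCF
#' emission.
#'
#' @param chrom Character vector of chromosome names.
#' @param length Numeric vector of chromosome lengths in bp (same order).
#' @return A tibble with columns `chrom` and `length`, classed
#'   `genome_layout`.
#' @examples
#' genome_layout(c("1", "2"), c(5e6, 5e6))
#' @export
genome_layout <- function(chrom, length) {
  stopifnot(length(chrom) == length(length))
  if (anyDuplicated(chrom)) stop("duplicated chromosome names in layout")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  out <- tibble::tibble(chrom = as.character(chrom), length = as.numeric(length))
  class(out) <- c("genome_layout", class(out))
  out
}

#' Bin grid over a genome layout
#'
#' Tiles every chromosome with consecutive fixed-width bins; the last bin of
#' a chromosome may be partial.
#'
#' @param layout A [genome_layout()] tibble.
#' @param bin_size Bin width in bp (default 10 kbp).
#' @return Tibble with `chrom`, `bin` (0-based index within chromosome),
#'   `bin_start`, `bin_end` (0-based half-open) and `bin_bp` (= bin_end -
#'   bin_start).
#' @export
bin_grid <- function(layout, bin_size = 10000) {
  stopifnot(bin_size > 0)
  purrr::map2_dfr(layout$chrom, layout$length, function(cn, len) {
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    end <- pmin(start + bin_size, len)
    tibble::tibble(chrom = cn, bin = seq_len(n) - 1L,
                   bin_start = start, bin_end = end, bin_bp = end - start)
  })
}

#' Total genome length of a layout
#' @param layout A [genome_layout()] tibble.
#' @return Total length in bp.
#' @export
genome_size <- function(layout) sum(layout$length)

# map positions (0-based) to bin indices on one chromosome
.pos_to_bin <- function(pos, bin_size) as.integer(pos %/% bin_size)

.check_layout <- function(layout) {
  if (!all(c("chrom", "length") %in% names(layout)))
    stop("layout must have columns chrom and length")
  invisible(layout)
}
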