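#' Partition genotypes by functional class, alt-allele count and ROH class
#'
#' Builds the genotype-partition tensor g\[i, j, c, k\]: for each individual
#' i, ROH size class j in \{S, M, L, R, N\}, functional class c and
#' alternate-allele count k in \{0, 1, 2\}, the number of annotated sites
#' with that genotype falling in that ROH class. A site belongs to the
#' class of the (unique, because segments are disjoint) ROH containing its
#' position, or to N when it lies outside every ROH; R is the union
#' S + M + L, and `total` is R + N. Missing genotypes contribute nowhere.
#'
#' @param cohort An `roh_cohort` (annotated sites + genotypes).
#' @param roh Labelled segment tibble from [classify_roh()].
#' @return Long tibble: `sample`, `roh_class` (S, M, L, R, N, total),
#'   `func_class`, `k`, `count`, complete over all combinations.
#' @export
partition_genotypes <- function(cohort, roh) {
  sites <- cohort$sites
  geno <- cohort$geno
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("conflicting annotations: a site appears more than once")
  if (nrow(roh) && !"size_class" %in% names(roh))
    stop("roh must carry size_class labels; run classify_roh() first")
  if (!nrow(roh)) {
    roh <- tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          size_class = character())
  }
  .check_disjoint(roh)
  .check_sites_in_layout(sites, cohort$layout)

  res <- purrr::map_dfr(colnames(geno), function(s) {
    r <- roh[roh$sample == s, , drop = FALSE]
    jclass <- .site_roh_class(sites, r)
    g <- geno[, s]
    ok <- !is.na(g)
    tab <- table(j = jclass[ok], c = sites$class[ok], k = g[ok])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("roh_class", "func_class", "k", "count")
    df$sample <- s
    df
  })
  res$k <- as.integer(res$k)
  res$count <- as.integer(res$count)
  res <- tidyr::complete(res,
                         sample = colnames(geno),
                         roh_class = c("S", "M", "L", "N"),
                         func_class = sort(unique(sites$class)),
                         k = 0:2,
                         fill = list(count = 0L))
  res <- res[, c("sample", "roh_class", "func_class", "k", "count")]

  marg <- function(d, classes, label) {
    d |>
      dplyr::filter(.data$roh_class %in% classes) |>
      dplyr::group_by(.data$sample, .data$func_class, .data$k) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(roh_class = label)
  }
  out <- dplyr::bind_rows(res,
                          marg(res, c("S", "M", "L"), "R"),
                          marg(res, c("S", "M", "L", "N"), "total"))
  dplyr::arrange(out, .data$sample, .data$func_class,
                 match(.data$roh_class, c("S", "M", "L", "R", "N", "total")),
                 .data$k)
}

# ROH class ("S"/"M"/"L") of the segment containing each site, else "N"
.site_roh_class <- function(sites, segments) {
  out <- rep("N", nrow(sites))
  if (!nrow(segments)) return(out)
  for (cn in unique(segments$chrom)) {
    iv <- segments[segments$chrom == cn, ]
    iv <- iv[order(iv$start), ]
    on_c <- which(sites$chrom == cn)
    if (!length(on_c)) next
    idx <- findInterval(sites$pos[on_c], iv$start)
    hit <- idx > 0 & sites$pos[on_c] < iv$end[pmax(idx, 1)]
    out[on_c[hit]] <- iv$size_class[idx[hit]]
  }
  out
}

.check_sites_in_layout <- function(sites, layout) {
  if (is.null(layout)) return(invisible(sites))
  m <- match(sites$chrom, layout$chrom)
  if (anyNA(m)) stop("sites on chromosomes absent from the layout")
  if (any(sites$pos < 0 | sites$pos >= layout$length[m]))
    stop("site positions outside chromosome bounds")
  invisible(sites)
}

#' Proportion of alt homozygotes falling in each ROH class
#'
#' From the partition tensor, f\[i, j, c\] = g\[i, j, c, k = 2\] /
#' g_total\[i, c, k = 2\]: the fraction of individual i's genome-wide
#' alternate homozygotes of functional class c that lie inside ROH of size
#' class j (j in S, M, L, R). When an individual has no alternate
#' homozygote of class c the proportion is missing (`NA`), not zero.
#'
#' @param counts Output of [partition_genotypes()].
#' @return Tibble: `sample`, `roh_class`, `func_class`, `f`, `n_hom`
#'   (the denominator).
#' @export
roh_proportions <- function(counts) {
  hom <- dplyr::filter(counts, .data$k == 2L)
  denom <- hom |>
    dplyr::filter(.data$roh_class == "total") |>
    dplyr::select("sample", "func_class", n_hom = "count")
  hom |>
    dplyr::filter(.data$roh_class %in% c("S", "M", "L", "R")) |>
    dplyr::left_join(denom, by = c("sample", "func_class")) |>
    dplyr::mutate(f = ifelse(.data$n_hom > 0, .data$count / .data$n_hom,
                             NA_real_)) |>
    dplyr::select("sample", "roh_class", "func_class", "f", "n_hom")
}
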