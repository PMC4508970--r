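#' Write a cohort to VCF (GT:DP), annotation TSV, popmap, truth BED, layout
#'
#' Emits the standard file set for a synthetic cohort: an uncompressed VCF
#' with per-sample GT and DP, a variant-annotation TSV (chrom, pos, ref,
#' alt, class; 1-based positions matching the VCF), a population map TSV,
#' the planted truth tracts as 0-based half-open BED, a layout TSV, and a
#' YAML echo of the simulation parameters.
#'
#' @param cohort An `roh_cohort`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "cohort").
#' @return Invisibly, a named list of the written paths.
#' @export
write_cohort_vcf <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    annotations = file.path(dir, paste0(prefix, ".annotations.tsv")),
    popmap = file.path(dir, paste0(prefix, ".popmap.tsv")),
    truth = file.path(dir, paste0(prefix, ".truth.bed")),
    layout = file.path(dir, paste0(prefix, ".layout.tsv")),
    config = file.path(dir, paste0(prefix, ".config.yaml"))
  )
  sites <- cohort$sites
  n_sites <- nrow(sites)
  samples <- cohort$samples$sample

  # per-site DP: mean depth scaled by the containing bin's covered fraction
  mean_depth <- if (!is.null(cohort$params)) cohort$params$mean_depth else 10
  site_bin <- .pos_to_bin(sites$pos, cohort$bin_size)
  site_key <- paste(sites$chrom, site_bin)
  gt_str <- c("0/0", "0/1", "1/1")
  cols <- vapply(samples, function(s) {
    d <- cohort$depth[cohort$depth$sample == s, ]
    frac <- d$covered_bp / (d$bin_end - d$bin_start)
    names(frac) <- paste(d$chrom, d$bin)
    dp <- round(mean_depth * frac[site_key])
    dp[is.na(dp)] <- round(mean_depth)
    g <- cohort$geno[, s]
    paste0(ifelse(is.na(g), "./.", gt_str[g + 1L]), ":", dp)
  }, character(n_sites))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = n_sites)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rohscape-simulate",
    paste0("##contig=<ID=", cohort$layout$chrom,
           ",length=", format(cohort$layout$length, scientific = FALSE,
                              trim = TRUE), ">"),
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Functional class of the alternate allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos + 1, ".", sites$ref, sites$alt, ".",
                "PASS", paste0("CLASS=", sites$class), "GT:DP",
                apply(cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths$vcf)

  readr::write_tsv(dplyr::mutate(sites[, c("chrom", "pos", "ref", "alt", "class")],
                                 pos = .data$pos + 1),
                   paths$annotations)
  readr::write_tsv(cohort$samples, paths$popmap)
  tt <- cohort$truth_tracts
  readr::write_tsv(tt[, c("chrom", "start", "end", "sample", "size_class")],
                   paths$truth, col_names = FALSE)
  readr::write_tsv(cohort$layout, paths$layout)
  if (!is.null(cohort$params)) {
    p <- cohort$params
    yaml::write_yaml(list(
      n_pops = p$n_pops, n_per_pop = p$n_per_pop,
      site_density = as.list(p$site_density),
      freq_mean = as.list(p$freq_mean), freq_conc = p$freq_conc,
      ind_intensity = p$ind_intensity, mean_depth = p$mean_depth,
      depth_sdlog = p$depth_sdlog, het_error_rate = p$het_error_rate,
      seed = p$seed, bin_size = cohort$bin_size
    ), paths$config)
  }
  invisible(paths)
}

#' Read a cohort from VCF + population map + layout
#'
#' Parses GT and DP with vcfR and rebuilds the in-memory cohort the
#' pipeline operates on. Functional classes are taken from the annotation
#' TSV when given, else from the VCF INFO `CLASS=` tag. The per-bin depth
#' track is reconstructed from per-site DP: a bin's covered fraction is
#' its mean site DP relative to the individual's genome-wide mean site DP
#' (capped at 1); bins without any site are assumed fully covered.
#'
#' @param vcf Path to an uncompressed or bgzipped VCF with GT and DP.
#' @param popmap Path to a TSV with columns `sample`, `pop`.
#' @param layout Path to a TSV with columns `chrom`, `length`, or a
#'   [genome_layout()].
#' @param annotations Optional path to a TSV with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `class`.
#' @param bin_size Bin width in bp (default 10 kbp).
#' @return An `roh_cohort` (truth tracts empty, frequencies unknown).
#' @export
read_cohort_vcf <- function(vcf, popmap, layout, annotations = NULL,
                            bin_size = 10000) {
  for (p in c(vcf, popmap, if (is.character(layout)) layout, annotations)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  geno <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw),
                 dimnames = dimnames(gt_raw))
  geno[gt_raw %in% c("0/0", "0|0")] <- 0L
  geno[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt_raw %in% c("1/1", "1|1")] <- 2L

  cls <- rep(NA_character_, nrow(fix))
  info <- fix[, "INFO"]
  m <- regmatches(info, regexpr("CLASS=[^;]+", info))
  has <- grepl("CLASS=", info)
  cls[has] <- sub("CLASS=", "", m)
  sites <- tibble::tibble(site_id = seq_len(nrow(fix)),
                          chrom = fix[, "CHROM"],
                          pos = as.numeric(fix[, "POS"]) - 1,
                          ref = fix[, "REF"], alt = fix[, "ALT"],
                          class = cls)
  if (!is.null(annotations)) {
    ann <- readr::read_tsv(annotations, show_col_types = FALSE)
    key <- paste(sites$chrom, sites$pos + 1)
    sites$class <- ann$class[match(key, paste(ann$chrom, ann$pos))]
  }
  if (is.character(layout)) {
    lt <- readr::read_tsv(layout, show_col_types = FALSE)
    layout <- genome_layout(lt$chrom, lt$length)
  }
  pm <- readr::read_tsv(popmap, show_col_types = FALSE)
  missing_sm <- setdiff(colnames(geno), pm$sample)
  if (length(missing_sm))
    stop("samples absent from popmap: ", paste(missing_sm, collapse = ", "))
  pm <- pm[match(colnames(geno), pm$sample), ]

  grid <- bin_grid(layout, bin_size)
  site_key <- paste(sites$chrom, .pos_to_bin(sites$pos, bin_size))
  depth <- purrr::map_dfr(colnames(geno), function(s) {
    dp <- dp_raw[, s]
    mdp <- mean(dp, na.rm = TRUE)
    bin_mean <- tapply(dp, site_key, mean, na.rm = TRUE)
    frac <- pmin(1, as.numeric(bin_mean[paste(grid$chrom, grid$bin)]) / mdp)
    frac[is.na(frac)] <- 1
    dplyr::mutate(grid, sample = s,
                  covered_bp = round(.data$bin_bp * frac))
  })
  depth <- depth[, c("sample", "chrom", "bin", "bin_start", "bin_end",
                     "covered_bp")]

  structure(list(sites = sites, geno = geno,
                 samples = tibble::tibble(sample = pm$sample, pop = pm$pop),
                 freqs = NULL, depth = depth,
                 truth_tracts = tibble::tibble(sample = character(),
                                               chrom = character(),
                                               start = numeric(),
                                               end = numeric(),
                                               size_class = character()),
                 layout = layout, bin_size = bin_size, params = NULL),
            class = "roh_cohort")
}

#' Write a binned track as bedGraph
#'
#' @param track Tibble with `chrom`, `bin_start`, `bin_end` and a value
#'   column.
#' @param value Value column (tidy-eval).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, value, path) {
  v <- dplyr::pull(track, {{ value }})
  df <- data.frame(chrom = track$chrom,
                   start = format(track$bin_start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(track$bin_end, scientific = FALSE,
                                trim = TRUE),
                   value = v)
  df <- df[!is.na(df$value), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
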