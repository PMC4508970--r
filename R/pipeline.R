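#' Run the full ROH / functional-variant pipeline
#'
#' Orchestrates the stages end-to-end from one configuration: obtain a
#' cohort (simulate, or read VCF + popmap + layout), bin heterozygosity,
#' call and classify ROH, coverage profiles and nucleotide diversity,
#' genotype partition and proportions, the deleterious vs non-deleterious
#' interaction regression, ROH sharing with its randomization null, binned
#' pairwise Fst, and the 500-kbp sharing-Fst correlation. All tabular
#' outputs are written as TSV/bedGraph under `outdir`, stamped with the
#' seed and a config hash; deterministic stages re-run byte-identically
#' for the same config.
#'
#' @param config A named list, or a path to a YAML file with the same
#'   structure. Recognised fields: either `simulate` (a list with
#'   `chromosomes` = named lengths plus any [sim_params()] argument) or
#'   `paths` (`vcf`, `popmap`, `layout`, optional `annotations`);
#'   `outdir`; `bin_size` (default 10000); `threshold_factor` (0.25);
#'   `min_length` (10000); `short_max` (1e5); `long_min` (3e6);
#'   `low_high_cutoff` (0.2); `null_reps` (default 100); `agg_size`
#'   (5e5); `seed` (default 1).
#' @return A list of class `roh_report` with every stage's tibble, the
#'   config, its hash and the seed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(bin_size = 10000, threshold_factor = 0.25,
                                min_length = 10000, short_max = 1e5,
                                long_min = 3e6, low_high_cutoff = 0.2,
                                null_reps = 100, agg_size = 5e5, seed = 1L),
                           config)
  cfg_hash <- rlang::hash(cfg)

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    layout <- genome_layout(names(sim$chromosomes),
                            unlist(sim$chromosomes))
    pargs <- sim[setdiff(names(sim), "chromosomes")]
    pargs$seed <- pargs$seed %||% cfg$seed
    if (!is.null(pargs$tract_plan))
      pargs$tract_plan <- tibble::as_tibble(pargs$tract_plan)
    for (nm in c("site_density", "freq_mean"))
      if (!is.null(pargs[[nm]])) pargs[[nm]] <- unlist(pargs[[nm]])
    params <- do.call(sim_params, pargs)
    cohort <- simulate_cohort(layout, params, bin_size = cfg$bin_size)
  } else if (!is.null(cfg$paths)) {
    p <- cfg$paths
    for (f in c(p$vcf, p$popmap, p$layout)) {
      if (is.null(f) || !file.exists(f))
        stop("stage input: required path missing or not found: ",
             if (is.null(f)) "(unset)" else f)
    }
    cohort <- read_cohort_vcf(p$vcf, p$popmap, p$layout,
                              annotations = p$annotations,
                              bin_size = cfg$bin_size)
  } else {
    stop("config must contain either 'simulate' or 'paths'")
  }

  bins <- bin_heterozygosity(cohort)
  roh <- call_roh(bins, threshold_factor = cfg$threshold_factor,
                  min_length = cfg$min_length)
  roh <- classify_roh(roh, short_max = cfg$short_max,
                      long_min = cfg$long_min)
  profiles <- coverage_profile(roh, cohort$layout,
                               samples = cohort$samples$sample)
  profiles <- split_low_high(profiles, cutoff = cfg$low_high_cutoff)
  diversity <- nucleotide_diversity(bins, roh)

  counts <- partition_genotypes(cohort, roh)
  props <- roh_proportions(counts)

  fit <- NULL
  fr <- props |>
    dplyr::filter(.data$roh_class == "R",
                  .data$func_class %in% c("deleterious", "non_deleterious")) |>
    dplyr::left_join(profiles[, c("sample", "g_r")], by = "sample") |>
    dplyr::mutate(d = as.integer(.data$func_class == "deleterious"))
  if (sum(stats::complete.cases(fr[, c("f", "g_r")])) >= 10 &&
      length(unique(fr$d)) == 2) {
    fit <- tryCatch(fit_interaction_model(fr, f, g_r, d),
                    error = function(e) NULL)
  }

  sharing <- suppressWarnings(
    sharing_track(roh, cohort$layout, bin_size = cfg$bin_size))
  null <- NULL
  if (cfg$null_reps > 0 && nrow(roh)) {
    null <- sharing_null(roh, cohort$layout, reps = cfg$null_reps,
                         bin_size = cfg$bin_size, seed = cfg$seed)
  }

  fst <- NULL
  corr <- NULL
  if (length(unique(cohort$samples$pop)) >= 2) {
    fst <- fst_bins(cohort, bin_size = cfg$bin_size)
    fst_mean <- fst |>
      dplyr::group_by(.data$chrom, .data$bin, .data$bin_start,
                      .data$bin_end) |>
      dplyr::summarise(theta = if (all(is.na(.data$theta))) NA_real_
                       else mean(.data$theta, na.rm = TRUE),
                       .groups = "drop")
    agg_fst <- aggregate_track(fst_mean, theta, agg_size = cfg$agg_size)
    agg_share <- aggregate_track(sharing, sharing, agg_size = cfg$agg_size)
    corr <- tryCatch(correlate_tracks(agg_fst, agg_share),
                     error = function(e) NULL)
  }

  report <- structure(list(cohort = cohort, bins = bins, roh = roh,
                           profiles = profiles, diversity = diversity,
                           counts = counts, proportions = props,
                           interaction_fit = fit, sharing = sharing,
                           sharing_null = null, fst = fst,
                           fst_sharing_cor = corr,
                           config = cfg, config_hash = cfg_hash,
                           seed = cfg$seed),
                      class = "roh_report")
  if (!is.null(cfg$outdir)) .write_report(report, cfg$outdir)
  report
}

.write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(paste("# config_hash:", report$config_hash),
             paste("# seed:", report$seed))
  wt <- function(x, name) {
    if (is.null(x)) return(invisible())
    path <- file.path(outdir, name)
    writeLines(stamp, path)
    suppressWarnings(
      utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    invisible(path)
  }
  wt(report$roh, "roh_segments.tsv")
  wt(report$profiles, "coverage_profiles.tsv")
  wt(report$diversity, "diversity.tsv")
  wt(report$counts, "partition_counts.tsv")
  wt(report$proportions, "proportions.tsv")
  if (!is.null(report$interaction_fit))
    wt(tidy(report$interaction_fit), "interaction_fit.tsv")
  write_bedgraph(report$sharing, sharing,
                 file.path(outdir, "sharing.bedgraph"))
  wt(report$sharing_null, "sharing_null.tsv")
  if (!is.null(report$fst)) {
    wt(report$fst, "fst_bins.tsv")
  }
  if (!is.null(report$fst_sharing_cor))
    wt(report$fst_sharing_cor, "fst_sharing_correlation.tsv")
  invisible(outdir)
}

#' @export
print.roh_report <- function(x, ...) {
  cat("<roh_report>  seed", x$seed, " config", substr(x$config_hash, 1, 8),
      "\n")
  cat("  individuals:", nrow(x$profiles), "  ROH segments:", nrow(x$roh),
      "\n")
  cat("  mean G_R:", signif(mean(x$profiles$g_r), 3), "\n")
  if (!is.null(x$fst_sharing_cor))
    cat("  Fst~sharing r:", signif(x$fst_sharing_cor$r, 3), "\n")
  invisible(x)
}
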