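#' Simulation parameters for synthetic inbred cohorts
#'
#' Bundles everything [simulate_cohort()] needs: cohort structure, per-class
#' site densities and allele-frequency laws, the planted-tract plan, the
#' per-bin depth model, and the heterozygote-error rate. The defaults
#' emulate a small multi-breed dairy-cattle-like cohort: deleterious
#' alternate alleles are rarer (mean frequency 0.05) than non-deleterious
#' (0.2) and synonymous (0.3) ones, tract burden varies between individuals
#' so genome ROH coverage spreads around ~20%, and depth fluctuates
#' log-normally around the mean per bin.
#'
#' @param n_pops Number of populations (breeds).
#' @param n_per_pop Individuals per population.
#' @param site_density Named numeric: sites per bp for each functional class
#'   (`synonymous`, `non_deleterious`, `deleterious`, `nonsense`, `lof`).
#' @param freq_mean Named numeric in (0,1): mean of the Beta allele-frequency
#'   law per functional class.
#' @param freq_conc Concentration of the Beta law (shape1+shape2).
#' @param pop_divergence Balding-Nichols F: each population's allele
#'   frequency is a Beta draw around the site's ancestral frequency with
#'   this expected differentiation (default 0.05, typical for related
#'   livestock breeds). Ignored when `n_pops = 1`.
#' @param tract_plan Tibble with one row per size class: `size_class`
#'   ("S","M","L"), `count` (mean planted tracts per individual), `min_bp`,
#'   `max_bp` (uniform length law). The default plan targets ~20% genome
#'   coverage on a ~50 Mb genome.
#' @param ind_intensity Length-2 numeric: per-individual tract-count
#'   multiplier is drawn uniformly from this range, emulating the spread of
#'   inbreeding between individuals and breeds. The default keeps cohort
#'   coverage in the 3-30% band, below the regime where the proportion of
#'   homozygotes in ROH saturates for every class.
#' @param mean_depth Mean sequencing depth (x).
#' @param depth_sdlog sdlog of the multiplicative log-normal per-bin depth
#'   noise (the noise has mean 1).
#' @param het_error_rate Probability that a truly homozygous site is read as
#'   heterozygous.
#' @param tract_freq_mult Optional named numeric (names in "S", "M", "L"):
#'   multiplier applied to the alternate-allele frequency of *deleterious*
#'   sites lying inside planted tracts of that size class, for planting
#'   class-specific enrichment (default `NULL`: no bias).
#' @param sweep Optional list describing a planted selective sweep:
#'   `chrom`, `start`, `end` (0-based half-open), `carrier_frac` (fraction
#'   of individuals receiving an IBD tract exactly over the region, default
#'   1) and `freq_shift` (added to population 1 allele frequencies inside
#'   the region, creating Fst divergence; default 0).
#' @param seed Integer seed recorded in the cohort; [simulate_cohort()]
#'   seeds from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_pops = 3,
                       n_per_pop = 8,
                       site_density = c(synonymous = 2e-3,
                                        non_deleterious = 1.5e-3,
                                        deleterious = 1.5e-3,
                                        nonsense = 4e-5,
                                        lof = 4e-5),
                       freq_mean = c(synonymous = 0.30,
                                     non_deleterious = 0.20,
                                     deleterious = 0.05,
                                     nonsense = 0.03,
                                     lof = 0.03),
                       freq_conc = 2,
                       pop_divergence = 0.05,
                       tract_plan = default_tract_plan(),
                       ind_intensity = c(0.3, 1.2),
                       tract_freq_mult = NULL,
                       mean_depth = 10,
                       depth_sdlog = 0.15,
                       het_error_rate = 0.001,
                       sweep = NULL,
                       seed = 1L) {
  stopifnot(n_pops >= 1, n_per_pop >= 1,
            all(site_density >= 0),
            all(freq_mean > 0 & freq_mean < 1),
            freq_conc > 0,
            het_error_rate >= 0, het_error_rate < 1,
            mean_depth > 0)
  if (!setequal(names(site_density), names(freq_mean)))
    stop("site_density and freq_mean must cover the same functional classes")
  if (!is.null(tract_plan)) {
    stopifnot(all(c("size_class", "count", "min_bp", "max_bp") %in% names(tract_plan)),
              all(tract_plan$min_bp <= tract_plan$max_bp),
              all(tract_plan$min_bp >= 10000))
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop,
                 site_density = site_density, freq_mean = freq_mean,
                 freq_conc = freq_conc, pop_divergence = pop_divergence,
                 tract_plan = tract_plan,
                 ind_intensity = ind_intensity,
                 tract_freq_mult = tract_freq_mult,
                 mean_depth = mean_depth, depth_sdlog = depth_sdlog,
                 het_error_rate = het_error_rate, sweep = sweep,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Default planted-tract plan
#'
#' Mean counts per individual and uniform length laws for the three ROH
#' size classes. Short tracts are numerous but small, medium tracts carry
#' most of the planted coverage, long (> 3 Mbp) tracts are rare — the
#' qualitative pattern reported for inbred livestock genomes.
#'
#' @return Tibble with columns `size_class`, `count`, `min_bp`, `max_bp`.
#' @export
default_tract_plan <- function() {
  tibble::tibble(
    size_class = c("S", "M", "L"),
    count = c(25, 5, 0.7),
    min_bp = c(12000, 120000, 3.2e6),
    max_bp = c(95000, 9e5, 4.5e6)
  )
}

#' Demonstration genome layout
#'
#' Four 12.5-Mbp chromosomes (50 Mbp total) — the toy genome the package's
#' worked examples and default simulations run on. It is small enough for
#' desk-scale runs while long enough to host tracts of all three size
#' classes; with the default [sim_params()] site densities its total site
#' counts give per-individual homozygote numbers of the same order as a
#' real inbred-cattle cohort.
#'
#' @return A [genome_layout()].
#' @export
demo_layout <- function() {
  genome_layout(paste0("chr", 1:4), rep(12.5e6, 4))
}
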