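#' Simulation configuration
#'
#' Bundles every tunable of the forward simulator: genome geometry, gene
#' spacing, the polymorphism-density landscape, founder panel and race
#' structure, methylation probabilities by genomic context, recombination
#' geometry, and RIL population design. Defaults emulate the structure of a
#' grain-sorghum study system: gene-dense euchromatic arms (~1 gene / 12 Kbp),
#' a gene-poor pericentromere, local polymorphism intensities contrasting
#' 100-fold in blocks of tens to hundreds of Kbp, methylation concentrated in
#' intergenic and pericentromeric DNA, and a ~90-line selfed RIL population.
#'
#' @param seed Integer master seed; every stochastic stage derives its own
#'   substream from it via [stage_seed()].
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (recycled).
#' @param genetic_length_cM Genetic length of each chromosome in centimorgans
#'   (recycled).
#' @param pericentromere_fraction Length-2 numeric: start/end of the
#'   pericentromeric interval as fractions of chromosome length.
#' @param peri_crossover_share Share of crossovers falling inside the
#'   pericentromere (recombination suppression).
#' @param gene_spacing_arm,gene_spacing_peri Mean gene spacing (bp) on
#'   euchromatic arms and in the pericentromere.
#' @param founders Named character vector: founder id -> race label.
#' @param race_share Fraction of a race's variant pool shared by all founders
#'   of that race (imposes race clustering).
#' @param intensity_levels Numeric levels of pairwise SNP intensity per bp used
#'   by the default landscape; max/min sets the density contrast (default
#'   100-fold: 0.4 vs 40 SNP/Kbp).
#' @param block_range_bp Length-2 numeric: min/max landscape block size in bp.
#' @param indel_fraction Fraction of simulated variants that are short INDELs.
#' @param indel_mean_len Mean short-INDEL length (geometric).
#' @param n_large_deletions Number of 25-500 bp deletions per founder per
#'   chromosome.
#' @param large_del_range Length-2: min/max large-deletion size (bp).
#' @param p_methylated Named numeric: probability a restriction site is
#'   methylated in `genic`, `intergenic` and `pericentromeric` context.
#'   Defaults are calibrated so that whole-arm tag recovery lands near
#'   40-50% (low methylation in and near genes, heavy methylation of
#'   pericentromeric repeats).
#' @param ril_n RIL population size.
#' @param ril_generations Number of selfing rounds applied to the F1
#'   (11 rounds gives an F12-equivalent population).
#' @param depth_mean Mean re-sequencing read depth for simulated depth tracks.
#' @param dg_depth_mean Mean read depth per genotyping tag.
#' @param dg_min_depth Minimum tag depth to call a tag recovered.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 2e5)
#' cfg$founders
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 1e6,
                       genetic_length_cM = 120,
                       pericentromere_fraction = c(0.35, 0.65),
                       peri_crossover_share = 0.05,
                       gene_spacing_arm = 12000,
                       gene_spacing_peri = 100000,
                       founders = c(K1 = "Kafir", K2 = "Kafir",
                                    D1 = "Durra", D2 = "Durra",
                                    C1 = "Caudatum"),
                       race_share = 0.7,
                       intensity_levels = c(low = 4e-4, high = 4e-2),
                       block_range_bp = c(5e4, 3e5),
                       indel_fraction = 0.1,
                       indel_mean_len = 3,
                       n_large_deletions = 2L,
                       large_del_range = c(25, 500),
                       p_methylated = c(genic = 0.1, intergenic = 0.65,
                                        pericentromeric = 0.98),
                       ril_n = 90L,
                       ril_generations = 11L,
                       depth_mean = 25,
                       dg_depth_mean = 15,
                       dg_min_depth = 5L) {
  n_chromosomes <- as.integer(n_chromosomes)
  if (is.na(n_chromosomes) || n_chromosomes < 1L) {
    abort("`n_chromosomes` must be a positive integer")
  }
  chrom_length <- as.integer(rep_len(chrom_length, n_chromosomes))
  if (any(chrom_length <= 0L)) abort("chromosome lengths must be > 0")
  genetic_length_cM <- rep_len(genetic_length_cM, n_chromosomes)
  if (any(genetic_length_cM < 0)) abort("genetic lengths must be >= 0")
  if (length(pericentromere_fraction) != 2L ||
      pericentromere_fraction[1] >= pericentromere_fraction[2] ||
      pericentromere_fraction[1] < 0 || pericentromere_fraction[2] > 1) {
    abort("`pericentromere_fraction` must be an increasing pair in [0, 1]")
  }
  if (any(intensity_levels < 0)) abort("intensity levels must be >= 0")
  if (is.null(names(founders)) || anyDuplicated(names(founders))) {
    abort("`founders` must be a uniquely named race-label vector")
  }
  stopifnot(all(c("genic", "intergenic", "pericentromeric") %in%
                  names(p_methylated)),
            all(p_methylated >= 0 & p_methylated <= 1))
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = n_chromosomes,
    chrom_length = chrom_length,
    genetic_length_cM = genetic_length_cM,
    pericentromere_fraction = pericentromere_fraction,
    peri_crossover_share = peri_crossover_share,
    gene_spacing_arm = gene_spacing_arm,
    gene_spacing_peri = gene_spacing_peri,
    founders = founders,
    race_share = race_share,
    intensity_levels = intensity_levels,
    block_range_bp = block_range_bp,
    indel_fraction = indel_fraction,
    indel_mean_len = indel_mean_len,
    n_large_deletions = as.integer(n_large_deletions),
    large_del_range = large_del_range,
    p_methylated = p_methylated,
    ril_n = as.integer(ril_n),
    ril_generations = as.integer(ril_generations),
    depth_mean = depth_mean,
    dg_depth_mean = dg_depth_mean,
    dg_min_depth = as.integer(dg_min_depth)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  chromosomes: %d x %s bp (%s cM)\n", x$n_chromosomes,
              paste(unique(x$chrom_length), collapse = "/"),
              paste(unique(x$genetic_length_cM), collapse = "/")))
  cat(sprintf("  founders: %s\n",
              paste(sprintf("%s(%s)", names(x$founders), x$founders),
                    collapse = ", ")))
  cat(sprintf("  intensity contrast: %.0f-fold\n",
              max(x$intensity_levels) / min(x$intensity_levels)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
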