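#' Simulate site-level methylation by genomic context
#'
#' Each restriction site is methylated independently (Bernoulli) with a
#' probability set by its genomic context: low in genic DNA, high in
#' intergenic DNA and highest in the pericentromere — the pattern that makes
#' methylation-sensitive genotyping tags concentrate in and near genes.
#'
#' @param genome An `annotated_genome`.
#' @param sites Tibble with `chrom` and `pos` (0-based site positions).
#' @param config A [sim_config()] (`p_methylated`, seed).
#' @return Tibble (`chrom`, `pos`, `context`, `methylated`).
#' @export
simulate_methylation <- function(genome, sites, config) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  if (!all(sites$chrom %in% names(genome$chrom_lengths))) {
    abort("site on unknown chromosome")
  }
  if (any(sites$pos < 0 | sites$pos >= genome$chrom_lengths[sites$chrom])) {
    abort("site outside genome")
  }
  with_seed(stage_seed(config$seed, "methylation"), {
    ctx <- genomic_context(genome, sites$chrom, sites$pos)
    p <- unname(config$p_methylated[ctx])
    mutate(sites,
           context = ctx,
           methylated = runif(dplyr::n()) < p) |>
      select("chrom", "pos", "context", "methylated")
  })
}
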