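# haplomosaic

Inbred crop genomes — grain sorghum is the motivating case — are mosaics of
founder haplotypes assembled by a century of crossing and selection. Along
their chromosomes, DNA polymorphism density varies more than 100-fold in
blocks of tens to hundreds of Kbp, collapses to near zero where two lines
are identical by descent (IBD, often because breeders fixed the same
haplotype, e.g. around dwarfing loci), and drops across the heavily
methylated, recombination-suppressed pericentromere. haplomosaic implements
the full analysis chain used to characterize this structure, together with
a forward simulator that generates genomes, founder panels, pedigrees and
recombinant inbred line (RIL) populations with complete truth records, so
every estimator in the chain can be validated by parameter recovery.

The package is for quantitative geneticists and genome analysts who want
either the analysis tools (tag prediction, variant consequence and density
profiling, haplotype tracing, map construction, dendrograms) or a truthful
test bed for such tools.

## What it computes

* **Digital Genotyping (DG) tags** — in-silico prediction of 37/72-bp tags
  flanking NgoMIV restriction sites (`G^CCGGC`; methylation-sensitive, so
  tags are only recovered at unmethylated sites), uniqueness filtering,
  simulated Poisson recovery, windowed methylation profiles
  (recovered/predicted per window), and tag-vs-consensus QC with
  perfect / SNP-mismatch / indel-discordant / missing classes.
* **Variant classification and density** — depth/homozygosity call filter
  (5–150×, allele frequency > 0.75), location (intergenic/intron/UTR/coding
  with CDS > UTR > intron precedence) and coding consequence (synonymous,
  missense, stop gained/lost, frameshift, in-frame) by strand-aware codon
  translation; published-table-style category counts; 600-bp window,
  per-gene (SNP/Kbp/gene) and genic-vs-intergenic regional densities;
  large-INDEL detection as zero-depth runs ≥ 25 bp.
* **Haplotype tracing** — per-marker parental origin, recursive lifting to
  founder labels through a pedigree (with the tentative-other-parent rule
  when a parent is ungenotyped), haplotype-block segmentation with
  single-marker error smoothing, and IBD segments from low pairwise density
  (default < 0.05 SNP/Kbp) or shared labels.
* **Genetic maps** — RIL recombinant fractions with the selfed-RIL
  correction r = R/(2(1−R)), Kosambi distances d = 25·ln((1+2r)/(1−2r)),
  pairwise LOD with a LOD > 3 retention rule, co-segregating marker
  collapse, and cM/physical-window recombination profiles.
* **Dendrograms** — p-distance and Tamura–Nei (TN93) distances over marker
  character matrices (pairwise deletion), deterministic UPGMA with
  size-weighted linkage, bootstrap support by clade identity, Newick
  output.
* **Simulator + pipeline** — `sim_config()` / `run_pipeline()` tie it all
  together: simulate → digest → classify → density → trace → map → tree,
  with per-stage TSV/FASTA/GFF3/VCF/bedGraph artifacts and a checksummed
  manifest. A thin CLI (`exec/haplomosaic run --seed N --out DIR`) wraps
  the pipeline.

## A worked example

Simulate a small genome, profile methylation via tag recovery, build a
genetic map from a 90-line F12 RIL population, and cluster the founders:

```r
library(haplomosaic)

cfg    <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 5e5)
genome <- build_reference(cfg)
genome
#> <annotated_genome>
#>   1 chromosome(s), 500,000 bp total, 24 genes

panel <- simulate_founder_variants(genome, density_landscape(genome, cfg), cfg)
sites <- find_restriction_sites(genome)            # 110 NgoMIV sites
meth  <- simulate_methylation(genome, sites, cfg)
tags  <- flag_unique_tags(extract_dg_tags(genome, sites, 72L), genome)
rec   <- simulate_tag_recovery(tags, meth, depth_mean = 15, min_depth = 5,
                               seed = 2)
methylation_profile(rec, tile_windows(genome, 5e4))
#> # A tibble: 10 × 6
#>   chrom  start    end predicted recovered fraction
#> 1 chr01      0  50000         9         4    0.444
#> 2 chr01  50000 100000         8         2    0.25
#> 3 chr01 100000 150000        15         5    0.333
#> 4 chr01 150000 200000        12         2    0.167
#> # … 6 more rows
```

The fraction column is the recovered share of in-silico predicted sites per
window — high where DNA is unmethylated (gene-rich arms), near zero in the
pericentromere; `plot_methylation_profile()` draws it.

```r
pop <- generate_ril_population(founder_line(genome, "K1"),
                               founder_line(genome, "D1"),
                               n = 90, generations = 11,
                               genome = genome, config = cfg, seed = 3)
set.seed(4)
markers <- tibble::tibble(chrom = "chr01", pos = sort(sample.int(5e5, 150)))
map <- assemble_map(ril_genotypes(pop, markers))
map
#> <genetic_map> 107.2 cM over 1 chromosome(s), 72 markers (78 dropped)
```

The simulated chromosome is 120 cM; the estimate (107.2 cM here) is
anchored to the recombination junctions realized in this particular
population — see the methods vignette for the sampling-variance analysis.
The 78 dropped markers are almost all co-segregating duplicates, whose
removal never changes the map length. The analytic pieces are exact:

```r
kosambi(0.25)        #> 27.46531  (25·ln 3 cM)
pairwise_lod(90, 0.1) #> 14.38634
```

Founders cluster by race with full bootstrap support on the cherries:

```r
tr <- bootstrap_support(marker_character_matrix(panel), replicates = 1000,
                        seed = 5, method = "p-distance")
to_newick(tr)
#> ((C1:0.272,(K1:0.081,K2:0.081)100:0.192)74:0.002,
#>  (D1:0.081,D2:0.081)100:0.193);
```

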