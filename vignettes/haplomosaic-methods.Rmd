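---
title: "Models and methods behind haplomosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplomosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomosaic)
```

haplomosaic studies how DNA polymorphism density and haplotype structure are
distributed along the chromosomes of inbred crop genomes — the situation of
grain sorghum, where three historically important genotypes descend from a
handful of African founder accessions of distinct races, and where breeding
with strong selection has left long identical-by-descent (IBD) blocks, a
recombination-suppressed pericentromere, and >100-fold local variation in
SNP density across euchromatic arms. Because the raw sequencing data behind
such studies are rarely re-analysable at desk scale, the package couples
every analysis step to a forward simulator with complete truth records, so
each method can be validated by parameter recovery.

This vignette describes the models, the parameters that matter, the
numerical conventions, and the limits of what the simulation-based tests can
show.

## The synthetic genome

`build_reference()` draws random chromosome sequences and places gene models
along them with exponential spacing: a mean of one gene per 12 Kbp on the
euchromatic arms (the gene density reported for sorghum euchromatin) and one
per 100 Kbp inside a declared pericentromere (by default the central 30% of
each chromosome). Each gene carries 1–4 exons, UTRs, and a clean open
reading frame — ATG start, a single terminal stop, no internal stops —
written back into the chromosome so that coding-consequence calls are
exactly defined. All internal coordinates are 0-based half-open; conversion
to 1-based happens only in the VCF/GFF3 writers.

The default simulated genome is two chromosomes of 1 Mbp (the test suites
use 0.1–1 Mbp). These sizes keep every suite fast while leaving hundreds of
genes and tens of thousands of variants, enough for all the statistical
checks below; they are the package's chosen working scale, roughly a 1:40
reduction of a real sorghum chromosome.

## Polymorphism landscape and founder panels

Local polymorphism intensity is a blockwise landscape
(`density_landscape()`): blocks of 50–300 Kbp, each assigned one of two
intensity levels, by default 0.4 and 40 SNP/Kbp *pairwise* — a 100-fold
contrast matching the extremes reported for euchromatic DNA, with the high
level in the reported 40–80 SNP/Kbp range.

`simulate_founder_variants()` gives every founder variants at per-founder
rate intensity/2, so two founders of different races differ at the full
block intensity in expectation. Race structure is imposed by drawing a
fraction `race_share` (default 0.7) of each founder's variants from a
race-level shared pool; same-race founders then differ at only
`(1 - race_share)` of the intensity, which is what makes races cluster in
the dendrogram without a coalescent model. Private draws avoid the shared
pool's positions so pooling does not deflate the realized rate. 10% of
variants are short INDELs with geometric lengths (mean 3 bp), giving the
~10:1 SNP:INDEL ratio seen in the study system, plus a configurable number
of large 25–500 bp deletions per founder, which later surface as zero-depth
runs in the simulated depth tracks.

## Methylation

Restriction sites of the methylation-sensitive enzyme NgoMIV (recognition
GCCGGC, cut G^CCGGC) are methylated independently with probabilities by
context: genic 0.10, intergenic 0.65, pericentromeric 0.98. The genic and
intergenic defaults were calibrated once so that whole-arm tag recovery
(see below) lands near the 40–50% ceiling reported for chromosome ends,
given that roughly a quarter of arm sites fall in or near genes;
pericentromeric recovery is then essentially zero, as observed. Tests that
probe the Bernoulli machinery supply their own probabilities.

## Recombination and breeding

Crossovers per chromosome per meiosis are Poisson with mean equal to the
genetic length in Morgans, without interference. Crossover positions are
uniform in genetic distance and mapped to physical coordinates through a
piecewise-linear cM→bp map in which the pericentromere receives a fixed
share of crossovers (default 5%, `peri_crossover_share`). The source data
report strong pericentromeric suppression but no quantitative factor, so
this share is a free parameter; 5% over ~30% of the physical length gives
the flat Marey-plot core seen in real maps.

`breed()` walks a pedigree (F1, backcross, self, or `ssd:<g>` single-seed
descent) drawing gametes from each parent. Selection loci — intervals fixed
for a named founder, like the dwarfing loci fixed by breeders — are modelled
as complete selection: each child's mosaic is overwritten with the fixed
founder over the locus. This is deliberately deterministic; it produces
exactly the IBD-under-selection structure the analyses must detect.

`generate_ril_population()` applies `generations` selfing rounds to the F1
of two inbred parents; `generations = 11` emulates an F12 population with
residual heterozygosity (1/2)^11 per locus. One selfing round gives the
F2's ~50% heterozygosity, which the tests verify.

## Tag prediction, recovery and QC

`find_restriction_sites()` scans the forward strand (complete for the
palindromic GCCGGC), `extract_dg_tags()` emits one 37- or 72-bp tag per
side of the cut, dropping tags truncated by chromosome ends, and
`flag_unique_tags()` removes tags whose exact sequence occurs more than
once on either strand. Recovery is methylation-gated: methylated sites
yield no template; unmethylated tags receive Poisson read counts at mean
depth 15 and are recovered at ≥ 5 reads, so per-tag recovery is
P(Pois(15) ≥ 5) ≈ 0.9986. The windowed ratio of recovered to predicted
sites (`methylation_profile()`) is therefore an estimator of the local
unmethylated fraction times that constant; windows with no predicted site
report `NA`, never zero.

`compare_tags_to_consensus()` classifies validated tags against
re-sequenced consensus by exact equality, then by a global alignment
(match +1, mismatch −1, gap open 2, extend 1): any gap — including a
terminal gap — marks the pair indel-discordant, substitutions only mark it
SNP-mismatch. Tags are pre-paired by site, so no local-alignment search is
needed.

## Variant classification and densities

`apply_call_filter()` keeps candidate calls with depth in [5, 150] and
allele frequency strictly above 0.75 (homozygous calls only).
`classify_variants()` assigns one location per variant with precedence
CDS > UTR > intron > intergenic; a variant overlapping several genes takes
the most severe consequence (stop gained > frameshift > stop lost >
missense > in-frame > synonymous). Coding SNPs are resolved by strand-aware
codon lookup in the standard genetic code (no initiator-codon special
casing); coding INDELs are frameshift when the length change is not a
multiple of 3, otherwise in-frame with stop checks on the re-translated
edited CDS. The test suite holds this classifier against an independent
oracle that applies the variant to the chromosome, rebuilds the shifted
CDS, translates the whole protein and classifies from the protein diff;
1000 random gene/variant cases must agree exactly. Multi-base INDELs can be
left-normalized (`left_normalize_variants()`) so equivalent events compare
equal — alignment-induced INDEL placement was the dominant source of tag
discordance in the study system.

Densities are always variants per Kbp with the true interval length in the
denominator: 600-bp tiling windows (the last partial window normalized by
its own length), per-gene densities over full UTR-to-UTR spans, and large
regional bins (default 10 Mbp) split into genic and intergenic components
with the class's bp in the bin as denominator (`NA` when a class has no
sequence in a bin). Large INDELs are maximal runs of exactly-zero depth of
at least 25 bp in the per-base depth track.

## Haplotype tracing, blocks and IBD

`marker_origin()` is the elementary call: informative when the parents
differ and the offspring matches one. `trace_pedigree()` lifts these calls
recursively to founder labels, memoizing per node; when one parent is
ungenotyped (globally, or missing at a marker), non-matching alleles are
tentatively assigned to the other parent and flagged — the rule used in
practice when only one parent of a line is available.

`segment_blocks()` takes maximal runs of one label over informative
markers. Isolated discordant runs up to `smoothing` markers (default 1)
flanked by agreeing labels are absorbed, a minimal genotyping-error model;
runs under `min_markers` (default 5) are flagged low-confidence rather than
dropped. Block boundaries are placed at the midpoint of the inter-marker
gap, since marker data cannot localize a breakpoint further.

`detect_ibd()` tiles a region with windows (default 100 Kbp at full scale;
10–20 Kbp at the package's working scale) and reports maximal runs of
pairwise density below 0.05 SNP/Kbp totalling at least the minimum length
(1 Mbp at full scale). These three defaults are free parameters — the
source analyses quantify none of them. `detect_ibd_labels()` provides the
complementary haplotype-label evidence. Lowering the density threshold can
only shrink segments (a tested monotonicity).

## Genetic maps

Observed RIL recombinant fractions R between physically adjacent markers
are corrected to meiotic fractions by the selfed-RIL relation
r = R / (2(1 − R)) (the inverse of R = 2r/(1+2r), assuming F∞; the (1/2)^11
residual heterozygosity of F12 is ignored), converted to centimorgans by
Kosambi, d = 25 ln((1+2r)/(1−2r)), and summed. Markers with identical
genotype columns are collapsed to their first representative (they carry no
map information; collapsing never changes the length), and markers whose
best adjacent LOD, n(R log₁₀R + (1−R) log₁₀(1−R) − log₁₀½), does not exceed
3.0 are dropped. Marker order is taken from physical position, as in the
original mapping; maximum-likelihood reordering is out of scope. A Haldane
option (d = −50 ln(1 − 2r)) exists for exact-model checks, since the
simulator's meioses have no interference while Kosambi models some; at the
marker spacings used (<1 cM) the two differ negligibly.

A known limitation, quantified during development: with 90 lines on a
single 120-cM chromosome the estimate is anchored to the ~216 recombination
junctions realized in the population, whose sampling standard deviation
across replicates is 8–9% (Poisson plus fixation overdispersion). Single
replicates can therefore miss the true length by more than 15% even with a
faithful estimator — one of the 20 fixed-seed replicates in the acceptance
suite does, because it genuinely realized 15% fewer junctions than
expected. At the full ten-chromosome, 1462-marker scale the corresponding
relative SD is ~2.6% and the same bound is comfortable. The 20-replicate
mean lands within 1–2% of truth.

## Distances, UPGMA and bootstrap

Founder alleles at polymorphic SNP sites form a character matrix (one
column per site; INDEL alleles become gaps and are removed pairwise).
Distances are the p-distance or the Tamura–Nei (TN93) substitution
distance, computed with `ape::dist.dna` under pairwise deletion; saturated
pairs raise an error rather than returning NaN. UPGMA is implemented in the
package because its conventions are part of the contract: closest pair
first, size-weighted average linkage, node height = distance/2, and ties
broken by the lexicographically smallest pair of cluster labels (a cluster
is labelled by its alphabetically first taxon), which makes output unique.
`stats::hclust(method = "average")` serves as an independent cross-check in
the tests, and UPGMA must reconstruct random ultrametric matrices exactly.
Bootstrap support resamples alignment columns, rebuilds the tree, and
scores each original internal clade by leaf-set identity — supports attach
to the original tree, not a consensus. Trees serialize to Newick with
branch lengths and integer supports as internal node labels, round-tripping
through `ape::read.tree`.

Note that distances computed on polymorphic-site-only matrices are much
larger than genome-wide substitution rates — sites were selected for being
different. They order relationships correctly (same-race founders cluster
with ~100% support at the default race-sharing), but their absolute scale
is a convention, and reproducing any particular published branch-length sum
would require the original marker data.

## The pipeline

`run_pipeline()` executes simulate → digest → classify → density → trace →
map → tree over a default three-founder pedigree with one selection locus
shared by both terminal lines, writing FASTA/GFF3/VCF/bedGraph/TSV
artifacts plus a checksummed manifest; identical configurations give
identical checksums. Stage parameters live in a single validated
configuration (`pipeline_config()`, YAML-loadable, unknown keys rejected).
A thin `exec/haplomosaic` script exposes `run` from the shell.

## What the tests do and do not show

The simulator reproduces the *statistical* structure of the study system:
density contrasts, race clustering, pericentromeric suppression,
methylation context, selection-induced IBD, and RIL segregation. It does
not model transposon content, sequencing error inside tags, alignment
artifacts, reference bias, or demography; passing parameter-recovery tests
therefore demonstrates correctness of the estimators under the stated
generative model, not robustness to the full messiness of real
re-sequencing data. The worked-example checks (tag-QC percentages, variant
totals, mapping-function values) are exact arithmetic on published counts
and hold independently of the simulator.
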