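# Call filter, consequence classification (with an independent whole-CDS
# translation oracle), category tables, density profiles, large-INDEL spans.

test_that("the call filter applies the depth and homozygosity rules", {
  calls <- tibble::tibble(
    depth = c(4, 150, 20, 5, 151, 30),
    allele_freq = c(0.9, 0.80, 0.70, 0.76, 0.9, 0.751)
  )
  kept <- apply_call_filter(calls, call_filter())
  # depth 4 rejected; depth 150 AF .80 kept (inclusive bounds); AF .70
  # rejected (threshold exclusive); 151 rejected
  expect_equal(kept$depth, c(150, 5, 30))
  expect_error(call_filter(min_depth = 0), "min_depth")
  expect_error(call_filter(hom_af = 0.4), "hom_af")
})

test_that("coding SNP consequences follow the codon table (plus strand)", {
  # CDS ATG GCC TAA at [100, 109)
  set.seed(5)
  s <- random_dna_str(300)
  substr(s, 101, 109) <- "ATGGCCTAA"
  g <- toy_gene_genome(s, tibble::tibble(start = 100L, end = 109L))
  mk <- function(pos, alt, type = "SNP") {
    tibble::tibble(chrom = "chrT", pos = as.integer(pos),
                   ref = substr(s, pos + 1, pos + 1), alt = alt, type = type)
  }
  # GCC -> GAC: missense
  expect_equal(classify_variants(mk(104, "A"), g)$consequence, "missense")
  expect_equal(classify_variants(mk(104, "A"), g)$location, "coding")
  # GCC -> GCG: synonymous
  expect_equal(classify_variants(mk(105, "G"), g)$consequence, "synonymous")
  # TAA -> CAA: stop lost
  expect_equal(classify_variants(mk(106, "C"), g)$consequence, "stop_lost")
  # GCC -> TAA-like premature stop: GCC at 103..105, G->T gives TCC (Ser);
  # use codon 2 middle: GCC -> G A? craft stop: change 103 G->T: TCC no.
  # ATG GCC TAA; make GCC -> TGA is 2 edits, instead test stop_gained on a
  # TGG gene below.
  # 2-bp deletion inside the CDS: frameshift
  del <- tibble::tibble(chrom = "chrT", pos = 103L,
                        ref = substr(s, 104, 106), alt = substr(s, 104, 104),
                        type = "INDEL")
  expect_equal(classify_variants(del, g)$consequence, "frameshift")
  # SNP far from the gene: intergenic, none
  far <- mk(250, setdiff(c("A", "C", "G", "T"),
                         substr(s, 251, 251))[1])
  expect_equal(classify_variants(far, g)$location, "intergenic")
  expect_equal(classify_variants(far, g)$consequence, "none")
  # ref mismatch is a data error
  bad <- mk(104, "A"); bad$ref <- "N"
  expect_error(classify_variants(bad, g), "mismatch")
})

test_that("stop gains and minus-strand genes are handled", {
  set.seed(6)
  s <- random_dna_str(300)
  # plus strand: ATG TGG TAA; TGG -> TGA is a premature stop (105 G->A)
  substr(s, 101, 109) <- "ATGTGGTAA"
  g <- toy_gene_genome(s, tibble::tibble(start = 100L, end = 109L))
  v <- tibble::tibble(chrom = "chrT", pos = 105L, ref = "G", alt = "A",
                      type = "SNP")
  expect_equal(classify_variants(v, g)$consequence, "stop_gained")
  # minus strand: genomic revcomp of ATG GCC TAA is TTA GGC CAT
  substr(s, 101, 109) <- "TTAGGCCAT"
  gm <- toy_gene_genome(s, tibble::tibble(start = 100L, end = 109L),
                        strand = "-")
  # genomic 105 C (codon GCC middle base on transcript) -> T  => GAC?
  # transcript base = complement: C->T genomic means G->A at transcript
  # middle of codon 2: GCC -> GAC missense
  vm <- tibble::tibble(chrom = "chrT", pos = 104L, ref = "G", alt = "T",
                       type = "SNP")
  # genomic G at 104 is transcript C (third base of codon GCC -> GCA syn?)
  res <- classify_variants(dplyr::bind_rows(
    vm, tibble::tibble(chrom = "chrT", pos = 103L, ref = "G", alt = "A",
                       type = "SNP")), gm)
  # verify both against the independent oracle rather than hand arithmetic
  for (i in 1:2) {
    expect_equal(res$consequence[i], oracle_consequence(gm, res[i, ]))
  }
})

test_that("the classifier agrees with a whole-CDS translation oracle", {
  set.seed(123)
  n_cases <- 0L
  mismatches <- list()
  for (rep in 1:200) {
    g <- random_toy_gene()
    for (k in 1:5) {
      v <- random_cds_variant(g)
      got <- classify_variants(v, g)$consequence
      want <- oracle_consequence(g, v)
      n_cases <- n_cases + 1L
      if (!identical(got, want)) {
        mismatches[[length(mismatches) + 1L]] <-
          list(v = v, got = got, want = want, strand = g$genes$strand)
      }
    }
  }
  expect_gte(n_cases, 1000L)
  expect_length(mismatches, 0)
})

test_that("category tables partition the variant set", {
  set.seed(9)
  s <- random_dna_str(600)
  substr(s, 101, 109) <- "ATGGCCTAA"
  g <- toy_gene_genome(s, tibble::tibble(start = 100L, end = 109L))
  # known truth: 6 intergenic, 1 UTR (exon pad), 1 intron-free gene has no
  # intron; use coding + UTR + intergenic
  snp_at <- function(pos, alt) {
    tibble::tibble(chrom = "chrT", pos = as.integer(pos),
                   ref = substr(s, pos + 1, pos + 1), alt = alt,
                   type = "SNP")
  }
  mkalt <- function(pos) setdiff(c("A", "C", "G", "T"),
                                 substr(s, pos + 1, pos + 2))[1]
  vs <- dplyr::bind_rows(
    lapply(c(10, 20, 30, 40, 250, 260), function(p) snp_at(p, mkalt(p))),
    snp_at(85, mkalt(85)),    # UTR pad (exon outside CDS)
    snp_at(104, "A")          # coding
  )
  rec <- classify_variants(vs, g)
  counts <- summarize_categories(rec)
  expect_equal(counts$total, nrow(vs))
  expect_equal(counts$intergenic + counts$intron + counts$UTR +
                 counts$coding, counts$total)
  expect_equal(counts$intergenic, 6L)
  expect_equal(counts$UTR, 1L)
  expect_equal(counts$coding, 1L)
  expect_equal(counts$aa_change, 1L)
  # empty set: all zero
  empty <- summarize_categories(rec[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("window densities tile, normalize partial windows and conserve counts", {
  v <- tibble::tibble(chrom = "c", pos = c(10L, 20L, 599L, 700L, 1400L))
  region <- list(chrom = "c", start = 0L, end = 1500L)
  prof <- window_density(v, region, 600L)
  expect_equal(prof$end - prof$start, c(600L, 600L, 300L))
  expect_equal(prof$count, c(3L, 1L, 1L))
  expect_equal(prof$density[1], 3 / 0.6)
  expect_equal(prof$density[3], 1 / 0.3)
  expect_equal(sum(prof$count), nrow(v))
  # empty window is 0, not NA
  expect_equal(window_density(v[0, ], region, 600L)$count, c(0L, 0L, 0L))
  # invariance under variant reordering
  prof2 <- window_density(v[sample(nrow(v)), ], region, 600L)
  expect_equal(prof2, prof)
  # doubling the window size merges counts additively
  prof_big <- window_density(v, list(chrom = "c", start = 0L, end = 1200L),
                             1200L)
  prof_small <- window_density(v, list(chrom = "c", start = 0L, end = 1200L),
                               600L)
  expect_equal(prof_big$count, sum(prof_small$count))
  expect_error(window_density(v, list(chrom = "c", start = 5L, end = 5L)),
               "empty region")
})

test_that("per-gene and regional densities use the stated denominators", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "c",
                          start = c(0L, 5000L), end = c(2000L, 6000L))
  v <- tibble::tibble(chrom = "c",
                      pos = c(10L, 500L, 1000L, 1999L, 5500L))
  d <- per_gene_density(v, genes)
  expect_equal(d$density, c(4 / 2, 1 / 1))
  expect_equal(per_gene_density(v[0, ], genes)$density, c(0, 0))
  expect_error(per_gene_density(v, dplyr::mutate(genes, end = start)),
               "zero-length")
  # regional split: a bin with no genic bp has undefined genic density
  g <- toy_gene_genome(random_dna_str(4000),
                       tibble::tibble(start = 1000L, end = 1300L))
  gene_span <- c(g$genes$start[1], g$genes$end[1])
  vv <- tibble::tibble(chrom = "chrT",
                       pos = c(100L, 1100L, 1200L, 2500L, 3500L))
  rd <- regional_density(vv, g, list(chrom = "chrT", start = 0L,
                                     end = 4000L), bin_size = 2000L)
  expect_equal(rd$genic_count + rd$intergenic_count, c(3L, 2L))
  expect_true(is.na(rd$genic_density[2]))
  expect_equal(rd$genic_count[1], 2L)
  gbp <- gene_span[2] - gene_span[1]
  expect_equal(rd$genic_density[1], 2 / (gbp / 1000))
  expect_equal(sum(rd$genic_count) + sum(rd$intergenic_count), nrow(vv))
  expect_error(regional_density(vv, g, list(chrom = "chrT", start = 0L,
                                            end = 9000L)), "outside")
})

test_that("large INDELs are maximal zero-depth runs above the threshold", {
  track <- tibble::tibble(
    chrom = "c",
    start = c(0L, 100L, 130L, 200L, 210L, 300L),
    end = c(100L, 130L, 200L, 210L, 300L, 400L),
    depth = c(25, 0, 25, 0, 0, 25)
  )
  spans <- detect_large_indels(track, min_length = 25L)
  # 30-bp run kept; adjacent zero runs [200,210)+[210,300) merge to 100 bp
  expect_equal(spans$length, c(30L, 100L))
  expect_equal(spans$start, c(100L, 200L))
  # a 10-bp run is below the threshold
  short <- tibble::tibble(chrom = "c", start = c(0L, 50L, 60L),
                          end = c(50L, 60L, 100L), depth = c(5, 0, 5))
  expect_equal(nrow(detect_large_indels(short)), 0L)
  expect_error(detect_large_indels(dplyr::mutate(track, depth = -1)),
               "negative")
})

test_that("simulated large deletions are recovered at exact coordinates", {
  set.seed(30)
  g <- tiny_genome()
  s <- as.character(g$sequences[[1]])
  mkdel <- function(pos, len) {
    tibble::tibble(chrom = "chr01", pos = as.integer(pos),
                   ref = substr(s, pos + 1, pos + 1 + len),
                   alt = substr(s, pos + 1, pos + 1), type = "INDEL")
  }
  v <- dplyr::bind_rows(mkdel(10000, 60), mkdel(50000, 500))
  track <- depth_track_for_line(v, g, tiny_config())
  spans <- detect_large_indels(track, 25L)
  expect_equal(spans$start, c(10001L, 50001L))
  expect_equal(spans$length, c(60L, 500L))
})

test_that("INDELs left-normalize to their leftmost equivalent position", {
  s <- paste0(strrep("G", 10), "ATTTTC", strrep("G", 10))
  g <- toy_gene_genome(s, tibble::tibble(start = 2L, end = 5L))
  g$genes <- g$genes[0, ]
  # deletion of one T written at the last T (pos 13: ref "TT" -> "T")
  v <- tibble::tibble(chrom = "chrT", pos = 13L, ref = "TT", alt = "T",
                      type = "INDEL")
  norm <- left_normalize_variants(v, g)
  expect_equal(norm$pos, 10L)  # anchored at the A
  expect_equal(norm$ref, "AT")
  expect_equal(norm$alt, "A")
})
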