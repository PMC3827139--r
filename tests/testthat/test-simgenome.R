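# Reference builder, founder-variant simulator, methylation, breeding.

test_that("reference building is deterministic and validates its invariants", {
  cfg <- tiny_config(seed = 7, len = 1e5)
  g1 <- build_reference(cfg)
  g2 <- build_reference(cfg)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$genes$gene_id, g2$genes$gene_id)
  expect_silent(validate_genome(g1))
  # CDS divisible by 3, exons disjoint (validate_genome already checks;
  # spot-check one gene explicitly)
  cds <- g1$genes$cds[[1]]
  expect_equal(sum(cds$end - cds$start) %% 3L, 0L)
})

test_that("gene density is lower inside the pericentromere (via emitted GFF3)", {
  g <- tiny_genome()
  gff <- file.path(withr::local_tempdir(), "genes.gff3")
  haplomosaic:::write_genes_gff3(g, gff)
  genes <- read_genes_gff3(gff)
  peri <- g$pericentromere
  inside <- sum(genes$start >= peri$start[1] & genes$start < peri$end[1])
  outside <- nrow(genes) - inside
  peri_len <- peri$end[1] - peri$start[1]
  arm_len <- g$chrom_lengths[[1]] - peri_len
  expect_lt(inside / (peri_len / 1e5), outside / (arm_len / 1e5))
  # and the GFF3 round trip preserves the gene models exactly
  expect_equal(genes$start, sort(g$genes$start))
  i <- match(g$genes$gene_id, genes$gene_id)
  expect_equal(genes$cds[i], g$genes$cds)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_chromosomes = 0), "positive")
  expect_error(sim_config(chrom_length = -5), "> 0")
  expect_error(sim_config(intensity_levels = c(-1, 2)), ">= 0")
})

test_that("founder variants follow the landscape intensities", {
  cfg <- tiny_config(seed = 3, len = 1e5,
                     founders = c(A = "raceA", B = "raceB"),
                     indel_fraction = 0, n_large_deletions = 0L)
  g <- build_reference(cfg)
  # zero intensity everywhere -> founders identical to reference
  flat <- tibble::tibble(chrom = "chr01", start = 0L,
                         end = g$chrom_lengths[[1]], intensity = 0)
  p0 <- simulate_founder_variants(g, flat, cfg)
  expect_equal(nrow(p0$variants), 0L)
  # one interval at 40 SNP/Kbp: realized pairwise count within 3 sigma of
  # 100 Kbp * 0.04 = 4000
  hot <- tibble::tibble(chrom = "chr01", start = 0L,
                        end = g$chrom_lengths[[1]], intensity = 0.04)
  p1 <- simulate_founder_variants(g, hot, cfg)
  d <- founder_pair_differences(p1, "A", "B")
  expect_lt(abs(nrow(d) - 4000), 3 * sqrt(4000))
  expect_error(simulate_founder_variants(
    g, dplyr::mutate(flat, intensity = -1), cfg), "intensity")
})

test_that("a 100-fold intensity contrast produces >= 50-fold realized density", {
  cfg <- tiny_config(seed = 5, len = 2e5,
                     founders = c(A = "raceA", B = "raceB"),
                     indel_fraction = 0, n_large_deletions = 0L)
  g <- build_reference(cfg)
  half <- as.integer(g$chrom_lengths[[1]] / 2)
  lsc <- tibble::tibble(chrom = "chr01", start = c(0L, half),
                        end = c(half, g$chrom_lengths[[1]]),
                        intensity = c(4e-4, 4e-2))
  p <- simulate_founder_variants(g, lsc, cfg)
  d <- founder_pair_differences(p, "A", "B")
  dens <- vapply(seq_len(nrow(lsc)), function(i) {
    sum(d$pos >= lsc$start[i] & d$pos < lsc$end[i]) /
      ((lsc$end[i] - lsc$start[i]) / 1000)
  }, numeric(1))
  expect_gte(max(dens) / min(dens), 50)
})

test_that("methylation is Bernoulli by genomic context with truth retained", {
  g <- tiny_genome()
  sites <- find_restriction_sites(g)
  cfg0 <- tiny_config(p_methylated = c(genic = 0, intergenic = 1,
                                       pericentromeric = 1))
  m0 <- simulate_methylation(g, sites, cfg0)
  expect_true(all(!m0$methylated[m0$context == "genic"]))
  expect_true(all(m0$methylated[m0$context != "genic"]))
  # site outside the genome errors
  expect_error(simulate_methylation(
    g, tibble::tibble(chrom = "chr01", pos = g$chrom_lengths[[1]] + 10L),
    cfg0), "outside")
  # realized fractions within 99% binomial CI at p = (.5, .95), 1000 sites
  cfg1 <- tiny_config(seed = 9, p_methylated = c(genic = 0.5,
                                                 intergenic = 0.95,
                                                 pericentromeric = 0.95))
  many <- tibble::tibble(chrom = "chr01",
                         pos = sort(sample.int(g$chrom_lengths[[1]], 2000)))
  m1 <- simulate_methylation(g, many, cfg1)
  for (ctx in c("intergenic")) {
    sub <- m1[m1$context == ctx, ]
    p <- 0.95
    ci <- p + c(-1, 1) * qnorm(0.995) * sqrt(p * (1 - p) / nrow(sub))
    expect_gt(mean(sub$methylated), ci[1])
    expect_lt(mean(sub$methylated), ci[2])
  }
})

test_that("gametes carry Poisson crossovers mapped through the cM map", {
  cfg <- tiny_config(seed = 13, len = 1e6, genetic_length_cM = 100)
  g <- build_reference(cfg)
  gm <- cm_map(g, cfg)
  # zero genetic length: gamete equals one parental mosaic intact
  gm0 <- dplyr::mutate(gm, cm_start = 0, cm_end = 0)
  parent <- founder_line(g, "A")
  set.seed(1)
  g0 <- make_gamete(parent, gm0)
  expect_identical(g0$chr01$founder, "A")
  # negative genetic length errors
  expect_error(make_gamete(parent, dplyr::mutate(gm, cm_end = -1)),
               "negative")
  # inbred x itself: gametes identical in founder labels
  set.seed(2)
  for (k in 1:5) expect_identical(make_gamete(parent, gm)$chr01$founder, "A")
  # 1-Morgan chromosome: mean crossovers 1.0 +/- 0.03 over 10,000 gametes
  dip <- structure(list(line_id = "F1", haplotypes = list(
    founder_line(g, "P1")$haplotypes[[1]],
    founder_line(g, "P2")$haplotypes[[1]]
  )), class = "line_genome")
  set.seed(3)
  xo <- vapply(1:10000, function(i) {
    nrow(make_gamete(dip, gm)$chr01) - 1L
  }, integer(1))
  expect_lt(abs(mean(xo) - 1.0), 0.03)
})

test_that("breeding respects pedigrees, selection loci and founder closure", {
  cfg <- tiny_config(seed = 21, len = 2e5,
                     founders = c(A = "r1", B = "r2", C = "r3"))
  g <- build_reference(cfg)
  lsc <- density_landscape(g, cfg)
  panel <- simulate_founder_variants(g, lsc, cfg)
  sel <- tibble::tibble(chrom = "chr01", start = 50000L, end = 90000L,
                        founder = "A")
  ped <- tibble::tibble(
    child = c("F1", "BC1", "Z"),
    parent1 = c("A", "F1", "BC1"),
    parent2 = c("B", "B", "C"),
    cross = c("F1", "backcross", "ssd:6")
  )
  lines <- breed(ped, panel, g, cfg, selection = sel)
  # backcross child carries A exactly over the selection interval:
  # every probed base of the locus is A on both haplotypes
  for (ln in c("BC1", "Z")) {
    probe <- seq(50000, 89999, by = 1000)
    for (h in seq_along(lines[[ln]]$haplotypes)) {
      f <- haplomosaic:::founder_at(lines[[ln]]$haplotypes[[h]]$chr01, probe)
      expect_true(all(f == "A"))
    }
  }
  # closure: every segment label is a declared founder
  segs <- dplyr::bind_rows(lapply(lines[c("F1", "BC1", "Z")], line_segments))
  expect_true(all(segs$founder %in% c("A", "B", "C")))
  # conservation: line variants equal the union of founder variants over
  # the line's segments (independent recomputation)
  vz <- line_variants(lines$Z, panel)
  segs_z <- dplyr::filter(line_segments(lines$Z), hap == 1)
  manual <- dplyr::bind_rows(lapply(seq_len(nrow(segs_z)), function(i) {
    dplyr::filter(panel$variants,
                  founder == segs_z$founder[i],
                  chrom == segs_z$chrom[i],
                  pos >= segs_z$start[i], pos < segs_z$end[i])
  }))
  expect_equal(nrow(vz), nrow(manual))
  expect_equal(vz$pos, sort(manual$pos))
  # errors: missing parent
  expect_error(breed(tibble::tibble(child = "Q", parent1 = "nope",
                                    parent2 = "A", cross = "F1"),
                     panel, g, cfg), "missing parent")
})

test_that("RIL populations have the expected residual heterozygosity", {
  cfg <- tiny_config(seed = 31, len = 5e5)
  g <- build_reference(cfg)
  pA <- founder_line(g, "P1")
  pB <- founder_line(g, "P2")
  probe <- tibble::tibble(chrom = "chr01", pos = seq(10000L, 490000L,
                                                     by = 10000L))
  # one selfing round (F2): ~50% heterozygous loci
  pop1 <- generate_ril_population(pA, pB, n = 60, generations = 1,
                                  genome = g, config = cfg, seed = 100)
  het1 <- mean(vapply(pop1$lines, heterozygosity_fraction, numeric(1),
                      positions = probe))
  expect_gt(het1, 0.40)
  expect_lt(het1, 0.60)
  # F12-equivalent: residual heterozygosity below 0.1% of loci on average
  pop11 <- generate_ril_population(pA, pB, n = 90, generations = 11,
                                   genome = g, config = cfg, seed = 101)
  het11 <- mean(vapply(pop11$lines, heterozygosity_fraction, numeric(1),
                       positions = probe))
  expect_lt(het11, 0.005)
  # determinism and input checks
  pop11b <- generate_ril_population(pA, pB, n = 90, generations = 11,
                                    genome = g, config = cfg, seed = 101)
  expect_identical(line_segments(pop11$lines[[5]]),
                   line_segments(pop11b$lines[[5]]))
  expect_error(generate_ril_population(pA, pB, n = 0, generations = 1,
                                       genome = g, config = cfg), "n must")
  expect_error(generate_ril_population(pA, pA, n = 5, generations = 1,
                                       genome = g, config = cfg), "differ")
})
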