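# Restriction-site scanning, tag extraction, recovery simulation,
# methylation profiling, tag-vs-consensus QC.

test_that("restriction-site scanning finds all (overlapping) motif hits", {
  expect_equal(find_restriction_sites(c(chr = "TTGCCGGCAA"))$pos, 2L)
  expect_equal(find_restriction_sites(c(chr = "GCCGGCCGGC"))$pos, c(0L, 4L))
  expect_equal(nrow(find_restriction_sites(c(chr = "AAAA"))), 0L)
  expect_error(find_restriction_sites(c(chr = "ACGT"), motif = "GCNGGC"),
               "ambiguity")
  expect_error(find_restriction_sites(c(chr = "ACGT"), motif = ""),
               "non-empty")
})

test_that("site lists are palindromic-consistent under reverse complement", {
  set.seed(11)
  s <- random_dna_str(5000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- find_restriction_sites(c(chr = s))$pos
  rev <- find_restriction_sites(c(chr = rc))$pos
  # GCCGGC is its own reverse complement: positions map through coordinates
  expect_equal(sort(5000 - 6 - rev), sort(fwd))
})

test_that("tag extraction reads outward from the cut with boundary drops", {
  set.seed(4)
  s <- random_dna_str(1000)
  # plant one site centrally, none elsewhere
  s <- gsub("GCCGGC", "ACCGGT", s, fixed = TRUE)
  substr(s, 501, 506) <- "GCCGGC"
  genome <- Biostrings::DNAStringSet(c(chrX = s))
  sites <- find_restriction_sites(genome)
  expect_equal(sites$pos, 500L)
  tags <- extract_dg_tags(genome, sites, 72L)
  expect_equal(nrow(tags), 2L)
  expect_true(all(nchar(tags$sequence) == 72L))
  # oracle: tags equal independent substring extraction around the cut
  # (cut after base 1 of the motif, i.e. 0-based position 501)
  expect_equal(tags$sequence[tags$side == "left"],
               as.character(Biostrings::subseq(genome[[1]], 430, 501)))
  expect_equal(tags$sequence[tags$side == "right"],
               as.character(Biostrings::subseq(genome[[1]], 502, 573)))
  # site near the chromosome start loses its left tag only
  s2 <- paste0(strrep("A", 10), "GCCGGC", strrep("T", 200))
  g2 <- Biostrings::DNAStringSet(c(chrY = s2))
  t2 <- extract_dg_tags(g2, find_restriction_sites(g2), 72L)
  expect_equal(t2$side, "right")
  expect_equal(attr(t2, "dropped"), 1L)
  expect_error(extract_dg_tags(g2, find_restriction_sites(g2), 50L),
               "37 or 72")
})

test_that("non-unique tag sequences are flagged", {
  set.seed(8)
  body <- gsub("GCCGGC", "ACCGGT", random_dna_str(80), fixed = TRUE)
  s0 <- paste0(strrep("A", 50), "GCCGGC", body)
  g0 <- Biostrings::DNAStringSet(c(chrZ = s0))
  tags0 <- extract_dg_tags(g0, find_restriction_sites(g0), 37L)
  right_seq <- tags0$sequence[tags0$side == "right"]
  # duplicate the right tag's sequence elsewhere in the chromosome
  s <- paste0(s0, "AA", right_seq, strrep("T", 20))
  g <- Biostrings::DNAStringSet(c(chrZ = s))
  tags <- flag_unique_tags(extract_dg_tags(g, find_restriction_sites(g),
                                           37L), g)
  expect_false(tags$unique_hit[tags$side == "right"])
  expect_true(tags$unique_hit[tags$side == "left"])
})

test_that("tag recovery is methylation-gated Poisson sampling", {
  g <- tiny_genome()
  sites <- find_restriction_sites(g)
  tags <- extract_dg_tags(g, sites, 72L)
  all_meth <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                             context = "intergenic", methylated = TRUE)
  r0 <- simulate_tag_recovery(tags, all_meth, depth_mean = 15, min_depth = 5,
                              seed = 1)
  expect_equal(sum(r0$recovered), 0L)
  none_meth <- dplyr::mutate(all_meth, methylated = FALSE)
  rz <- simulate_tag_recovery(tags, none_meth, depth_mean = 0, min_depth = 5,
                              seed = 1)
  expect_equal(sum(rz$recovered), 0L)
  # missing methylation state errors
  expect_error(simulate_tag_recovery(tags, all_meth[-1, ], seed = 1),
               "missing")
  # depth 15 / min 5: per-tag recovery probability P(Pois(15) >= 5)
  r1 <- simulate_tag_recovery(tags, none_meth, depth_mean = 15,
                              min_depth = 5, seed = 2)
  p <- ppois(4, 15, lower.tail = FALSE)
  n <- nrow(r1)
  ci <- p + c(-1, 1) * qnorm(0.9995) * sqrt(p * (1 - p) / n)
  expect_gte(mean(r1$recovered), ci[1] - 1 / n)
  expect_lte(mean(r1$recovered), 1)
  # monotonicity: raising min depth never increases recovery
  r_strict <- simulate_tag_recovery(tags, none_meth, depth_mean = 15,
                                    min_depth = 10, seed = 2)
  expect_lte(sum(r_strict$recovered), sum(r1$recovered))
})

test_that("methylation profiles divide recovered by predicted per window", {
  rec <- tibble::tibble(
    chrom = "c", site_pos = c(1:10 * 10L, 200L),
    recovered = c(rep(c(TRUE, FALSE), c(4, 6)), FALSE)
  )
  win <- tibble::tibble(chrom = "c", start = c(0L, 150L, 300L),
                        end = c(150L, 300L, 450L))
  prof <- methylation_profile(rec, win)
  expect_equal(prof$fraction[1], 0.40)
  expect_equal(prof$predicted[3], 0L)
  expect_true(is.na(prof$fraction[3]))  # undefined, not zero
  bad <- tibble::tibble(chrom = "c", start = c(0L, 100L), end = c(150L, 250L))
  expect_error(methylation_profile(rec, bad), "overlapping")
})

test_that("profiles separate genic from pericentromeric unmethylation", {
  cfg <- tiny_config(seed = 17, p_methylated = c(genic = 0.5,
                                                 intergenic = 0.5,
                                                 pericentromeric = 0.98))
  g <- tiny_genome()
  sites <- find_restriction_sites(g)
  meth <- simulate_methylation(g, sites, cfg)
  tags <- extract_dg_tags(g, sites, 72L)
  rec <- simulate_tag_recovery(tags, meth, depth_mean = 15, min_depth = 5,
                               seed = 3)
  peri <- g$pericentromere
  win <- tibble::tibble(
    chrom = "chr01",
    start = c(0L, peri$start[1], peri$end[1]),
    end = c(peri$start[1], peri$end[1], g$chrom_lengths[[1]])
  )
  prof <- methylation_profile(rec, win)
  q <- ppois(4, 15, lower.tail = FALSE)
  # expected window fraction is (1 - p_meth) * q; arm windows ~0.5q,
  # pericentromeric window ~0.02q
  expect_gt(prof$fraction[1], prof$fraction[2])
  expect_gt(prof$fraction[3], prof$fraction[2])
  arm_expect <- 0.5 * q
  expect_lt(abs(prof$fraction[1] - arm_expect),
            3 * sqrt(arm_expect * (1 - arm_expect) / prof$predicted[1]) +
              0.02)
})

test_that("tag-vs-consensus comparison classifies and partitions", {
  tags <- tibble::tibble(
    chrom = "c", site_pos = c(10L, 50L, 90L, 130L), side = "right",
    sequence = c(strrep("ACGT", 18), paste0("T", strrep("ACGT", 17), "AC"),
                 strrep("GATC", 18), strrep("TTGC", 18))
  )
  consensus <- tibble::tibble(
    chrom = "c", site_pos = c(10L, 50L, 90L), side = "right",
    sequence = c(
      tags$sequence[1],                                 # perfect
      sub("^T", "G", tags$sequence[2]),                 # one substitution
      paste0(substr(tags$sequence[3], 2, 72), "A")      # 1-bp del + tail
    )
  )
  rep <- compare_tags_to_consensus(tags, consensus)
  cls <- setNames(rep$per_tag$class, as.character(rep$per_tag$site_pos))
  expect_equal(unname(cls[c("10", "50", "90", "130")]),
               c("perfect", "SNP-mismatch", "indel-discordant", "missing"))
  # classes partition the tag set
  expect_equal(sum(rep$summary$n), nrow(tags))
  # identical sets: 100% perfect
  rep2 <- compare_tags_to_consensus(tags, tags)
  expect_equal(rep2$perfect_pct, 100)
  expect_equal(glance(rep2)$perfect_pct, 100)
})

test_that("pooled perfect percentages follow the count arithmetic", {
  expect_equal(round(pooled_perfect_pct(c(1356, 1293), c(1462, 1462)), 1),
               90.6)
  expect_equal(pooled_perfect_pct(10, 10), 100)
  expect_error(pooled_perfect_pct(11, 10))
})
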