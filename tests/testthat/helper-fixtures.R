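# Shared fixtures: cached small simulated objects and hand-built toy genomes.

`%||%` <- function(x, y) if (is.null(x)) y else x

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_config <- function(seed = 42L, len = 2e5, ...) {
  sim_config(seed = seed, n_chromosomes = 1L, chrom_length = len, ...)
}

tiny_genome <- function() {
  cached("tiny_genome", build_reference(tiny_config()))
}

tiny_panel <- function() {
  cached("tiny_panel", {
    g <- tiny_genome()
    simulate_founder_variants(g, density_landscape(g, tiny_config()),
                              tiny_config())
  })
}

# annotated_genome with a single hand-specified gene on a short chromosome.
# cds_genomic: tibble of genomic CDS intervals; utr/intron structure inferred
# as a single exon block unless exons given.
toy_gene_genome <- function(seq, cds_genomic, strand = "+",
                            exons = NULL, utr5 = NULL, utr3 = NULL,
                            chrom = "chrT") {
  n <- nchar(seq)
  exons <- exons %||% tibble::tibble(start = min(cds_genomic$start) - 20L,
                                     end = max(cds_genomic$end) + 20L)
  left <- tibble::tibble(start = exons$start[1],
                         end = min(cds_genomic$start))
  right <- tibble::tibble(start = max(cds_genomic$end),
                          end = exons$end[nrow(exons)])
  genes <- tibble::tibble(
    gene_id = "toy1", chrom = chrom, strand = strand,
    start = exons$start[1], end = exons$end[nrow(exons)],
    exons = list(exons), cds = list(cds_genomic),
    utr5 = list(utr5 %||% (if (strand == "+") left else right)),
    utr3 = list(utr3 %||% (if (strand == "+") right else left))
  )
  structure(
    list(
      sequences = Biostrings::DNAStringSet(setNames(seq, chrom)),
      genes = genes,
      pericentromere = tibble::tibble(chrom = chrom, start = n, end = n),
      chrom_lengths = setNames(as.integer(n), chrom)
    ),
    class = "annotated_genome"
  )
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random single-gene genome with a clean ORF, optionally multi-exon and on
# either strand; used by the classifier oracle suite
random_toy_gene <- function() {
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample(1:3, 1)
  cds_lens <- 3L * sample(10:60, n_ex, replace = TRUE)
  introns <- if (n_ex > 1) sample(20:80, n_ex - 1, replace = TRUE) else
    integer()
  pre <- 100L
  pos <- pre
  cds <- list()
  for (j in seq_len(n_ex)) {
    cds[[j]] <- c(pos, pos + cds_lens[j])
    pos <- pos + cds_lens[j]
    if (j < n_ex) pos <- pos + introns[j]
  }
  total <- pos + 100L
  seq <- random_dna_str(total)
  cds_tb <- tibble::tibble(start = vapply(cds, `[`, numeric(1), 1),
                           end = vapply(cds, `[`, numeric(1), 2))
  cds_tb$start <- as.integer(cds_tb$start); cds_tb$end <- as.integer(cds_tb$end)
  exons <- tibble::tibble(start = pre - 30L, end = pos + 30L)
  g <- toy_gene_genome(seq, cds_tb, strand = strand, exons = exons)
  # write a clean ORF into the CDS (start codon, single terminal stop)
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  n_codons <- sum(cds_tb$end - cds_tb$start) %/% 3L
  orf <- paste0("ATG", paste(sample(codons, n_codons - 2L, replace = TRUE),
                             collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  if (strand == "-") {
    orf <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(orf)))
  }
  s <- as.character(g$sequences[[1]])
  off <- 0L
  for (j in seq_len(nrow(cds_tb))) {
    w <- cds_tb$end[j] - cds_tb$start[j]
    substr(s, cds_tb$start[j] + 1L, cds_tb$end[j]) <-
      substr(orf, off + 1L, off + w)
    off <- off + w
  }
  g$sequences <- Biostrings::DNAStringSet(setNames(s, names(g$chrom_lengths)))
  g
}

# Independent consequence oracle: apply the variant to the chromosome,
# rebuild the (coordinate-shifted) CDS, translate both whole proteins with
# Biostrings::translate, and classify from the protein diff.
oracle_consequence <- function(genome, v) {
  gene <- genome$genes[1, ]
  seq <- as.character(genome$sequences[[1]])
  cds <- gene$cds[[1]]
  extract_protein <- function(s, cds_iv) {
    parts <- vapply(seq_len(nrow(cds_iv)), function(j) {
      substr(s, cds_iv$start[j] + 1L, cds_iv$end[j])
    }, character(1))
    dna <- Biostrings::DNAString(paste(parts, collapse = ""))
    if (gene$strand == "-") dna <- Biostrings::reverseComplement(dna)
    len <- 3L * (length(dna) %/% 3L)
    as.character(Biostrings::translate(Biostrings::subseq(dna, 1, len),
                                       if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  }
  p_ref <- extract_protein(seq, cds)
  edited <- paste0(substr(seq, 1, v$pos), v$alt,
                   substr(seq, v$pos + nchar(v$ref) + 1L, nchar(seq)))
  shift <- nchar(v$alt) - nchar(v$ref)
  cds2 <- cds
  cds2$start[cds2$start > v$pos] <- cds2$start[cds2$start > v$pos] + shift
  cds2$end[cds2$end > v$pos] <- cds2$end[cds2$end > v$pos] + shift
  p_alt <- extract_protein(edited, cds2)
  if (v$type == "INDEL") {
    if (abs(shift) %% 3L != 0L) return("frameshift")
    internal <- function(p) grepl("\\*", substr(p, 1, nchar(p) - 1L))
    terminal <- function(p) substr(p, nchar(p), nchar(p)) == "*"
    if (internal(p_alt) && !internal(p_ref)) return("stop_gained")
    if (terminal(p_ref) && !terminal(p_alt) && !internal(p_alt)) {
      return("stop_lost")
    }
    return("inframe")
  }
  if (p_ref == p_alt) return("synonymous")
  ra <- strsplit(p_ref, "")[[1]]
  aa <- strsplit(p_alt, "")[[1]]
  d <- which(ra != aa)
  if (aa[d[1]] == "*") "stop_gained"
  else if (ra[d[1]] == "*") "stop_lost"
  else "missense"
}

# random SNP or in/del inside the gene's CDS of a toy genome
random_cds_variant <- function(genome) {
  gene <- genome$genes[1, ]
  cds <- gene$cds[[1]]
  seq <- as.character(genome$sequences[[1]])
  j <- sample(nrow(cds), 1)
  kind <- sample(c("snp", "del", "ins"), 1, prob = c(0.6, 0.2, 0.2))
  if (kind == "snp") {
    pos <- sample(seq(cds$start[j], cds$end[j] - 1L), 1)
    ref <- substr(seq, pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    return(tibble::tibble(chrom = names(genome$chrom_lengths), pos = pos,
                          ref = ref, alt = alt, type = "SNP"))
  }
  len <- sample(1:6, 1)
  # anchor just inside the CDS so the edit stays within this exon
  pos <- sample(seq(cds$start[j], cds$end[j] - len - 2L), 1)
  if (kind == "del") {
    ref <- substr(seq, pos + 1L, pos + 1L + len)
    alt <- substr(seq, pos + 1L, pos + 1L)
  } else {
    ref <- substr(seq, pos + 1L, pos + 1L)
    alt <- paste0(ref, random_dna_str(len))
  }
  tibble::tibble(chrom = names(genome$chrom_lengths), pos = pos,
                 ref = ref, alt = alt, type = "INDEL")
}

# pedigree-tracing fixture shared by the haplotrace and acceptance suites
trace_fixture <- function(seed = 77) {
  cached(paste0("trace_fixture_", seed), {
    cfg <- tiny_config(seed = seed, len = 3e5,
                       founders = c(A = "r1", B = "r2", C = "r3"))
    g <- build_reference(cfg)
    panel <- simulate_founder_variants(g, density_landscape(g, cfg), cfg)
    ped <- tibble::tibble(
      child = c("X1", "TERM"),
      parent1 = c("A", "X1"),
      parent2 = c("B", "C"),
      cross = c("ssd:6", "ssd:6")
    )
    lines <- breed(ped, panel, g, cfg)
    sites <- polymorphic_sites(panel)
    geno <- genotype_lines(lines, panel, sites)
    list(cfg = cfg, g = g, panel = panel, ped = ped, lines = lines,
         sites = sites, geno = geno)
  })
}

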