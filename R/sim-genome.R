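# Reference-genome simulator: chromosome sequences with clean ORFs, gene
# models (exon/CDS/UTR), and a declared pericentromere with low gene density.

#' Build a synthetic annotated reference genome
#'
#' Generates random chromosome sequences and places gene models along them,
#' densely on the euchromatic arms and sparsely inside the declared
#' pericentromere. Each gene gets 1-4 exons, UTRs, and a clean open reading
#' frame (ATG start, single terminal stop, no internal stop codons) written
#' back into the chromosome sequence so that coding-consequence calls are
#' well defined.
#'
#' @param config A [sim_config()].
#' @return An object of class `annotated_genome`: a list with `sequences`
#'   (a [Biostrings::DNAStringSet]), `genes` (a tibble with list-columns of
#'   exon/CDS/UTR intervals, 0-based half-open), `pericentromere` (tibble of
#'   per-chromosome intervals) and `chrom_lengths`.
#' @examples
#' g <- build_reference(sim_config(seed = 7, n_chromosomes = 1,
#'                                 chrom_length = 2e5))
#' nrow(g$genes)
#' @export
build_reference <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  with_seed(stage_seed(config$seed, "reference"), {
    chrom_ids <- sprintf("chr%02d", seq_len(config$n_chromosomes))
    lens <- setNames(config$chrom_length, chrom_ids)
    peri <- tibble(
      chrom = chrom_ids,
      start = as.integer(floor(lens * config$pericentromere_fraction[1])),
      end = as.integer(floor(lens * config$pericentromere_fraction[2]))
    )
    seqs <- character(length(chrom_ids))
    genes <- vector("list", length(chrom_ids))
    for (i in seq_along(chrom_ids)) {
      seqs[i] <- random_dna(lens[i])
      placed <- place_genes(chrom_ids[i], lens[i],
                            peri$start[i], peri$end[i], config)
      seqs[i] <- write_clean_orfs(seqs[i], placed)
      genes[[i]] <- placed
    }
    genome <- structure(
      list(
        sequences = Biostrings::DNAStringSet(setNames(seqs, chrom_ids)),
        genes = bind_rows(genes),
        pericentromere = peri,
        chrom_lengths = lens
      ),
      class = "annotated_genome"
    )
    validate_genome(genome)
    genome
  })
}

# lay genes along one chromosome; spacing mean depends on pericentromere
place_genes <- function(chrom, len, peri_start, peri_end, config) {
  out <- list()
  cursor <- 200L
  k <- 0L
  repeat {
    in_peri <- cursor >= peri_start && cursor < peri_end
    spacing <- stats::rexp(1, 1 / if (in_peri) config$gene_spacing_peri else
      config$gene_spacing_arm)
    cursor <- cursor + as.integer(ceiling(spacing))
    gm <- draw_gene_model(cursor)
    if (gm$end > len - 200L) break
    k <- k + 1L
    gm$gene_id <- sprintf("%s.g%04d", chrom, k)
    gm$chrom <- chrom
    out[[k]] <- gm
    cursor <- gm$end
  }
  if (length(out) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  exons = list(), cds = list(), utr5 = list(), utr3 = list()))
  }
  tibble(
    gene_id = map_chr(out, "gene_id"),
    chrom = map_chr(out, "chrom"),
    strand = map_chr(out, "strand"),
    start = map_int(out, "start"),
    end = map_int(out, "end"),
    exons = map(out, "exons"),
    cds = map(out, "cds"),
    utr5 = map(out, "utr5"),
    utr3 = map(out, "utr3")
  )
}

# one gene model starting at `start` (genomic 0-based); CDS length % 3 == 0
draw_gene_model <- function(start) {
  strand <- sample(c("+", "-"), 1L)
  n_exons <- sample(1:4, 1L)
  cds_lens <- as.integer(3 * sample(40:160, n_exons, replace = TRUE))
  introns <- if (n_exons > 1L) sample(80:400, n_exons - 1L, replace = TRUE)
             else integer()
  u5 <- sample(50:200, 1L)
  u3 <- sample(50:300, 1L)
  # genomic layout left->right; for "-" the left UTR is the 3' UTR
  left_utr <- if (strand == "+") u5 else u3
  right_utr <- if (strand == "+") u3 else u5
  cds_geno <- if (strand == "+") cds_lens else rev(cds_lens)

  pos <- as.integer(start)
  exon_iv <- cds_iv <- list()
  for (j in seq_len(n_exons)) {
    ex_start <- pos
    if (j == 1L) pos <- pos + left_utr
    cds_start <- pos
    pos <- pos + cds_geno[j]
    cds_iv[[j]] <- c(cds_start, pos)
    if (j == n_exons) pos <- pos + right_utr
    exon_iv[[j]] <- c(ex_start, pos)
    if (j < n_exons) pos <- pos + introns[j]
  }
  iv_tbl <- function(lst) {
    tibble(start = as.integer(map_dbl(lst, 1)),
           end = as.integer(map_dbl(lst, 2)))
  }
  exons <- iv_tbl(exon_iv)
  cds <- iv_tbl(cds_iv)
  left_iv <- tibble(start = exons$start[1], end = cds$start[1])
  right_iv <- tibble(start = cds$end[n_exons], end = exons$end[n_exons])
  list(
    strand = strand,
    start = exons$start[1],
    end = exons$end[n_exons],
    exons = exons,
    cds = cds,
    utr5 = if (strand == "+") left_iv else right_iv,
    utr3 = if (strand == "+") right_iv else left_iv
  )
}

# overwrite each gene's CDS with a clean ORF (ATG ... stop, no internal stops)
write_clean_orfs <- function(seq, genes) {
  if (nrow(genes) == 0L) return(seq)
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[[i]]
    total <- sum(cds$end - cds$start)
    n_codons <- total %/% 3L
    body <- sample(codons, n_codons - 2L, replace = TRUE)
    orf <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
    if (genes$strand[i] == "-") {
      orf <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(orf)))
    }
    # orf is in genomic orientation now; split across CDS intervals in
    # genomic order
    off <- 0L
    for (j in seq_len(nrow(cds))) {
      w <- cds$end[j] - cds$start[j]
      substr(seq, cds$start[j] + 1L, cds$end[j]) <-
        substr(orf, off + 1L, off + w)
      off <- off + w
    }
  }
  seq
}

#' Validate the structural invariants of an annotated genome
#'
#' Checks that gene spans lie within their chromosome, CDS lengths are
#' divisible by 3, exons are sorted and non-overlapping, and CDS/UTR intervals
#' are contained in exons.
#'
#' @param genome An `annotated_genome`.
#' @return The genome, invisibly; errors on violation.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (any(genome$chrom_lengths <= 0)) abort("chromosome lengths must be > 0")
  g <- genome$genes
  if (nrow(g) == 0L) return(invisible(genome))
  lens <- genome$chrom_lengths[g$chrom]
  if (any(g$start < 0L | g$end > lens)) {
    abort("gene spans must lie within their chromosome")
  }
  ok <- map_lgl(seq_len(nrow(g)), function(i) {
    ex <- g$exons[[i]]; cds <- g$cds[[i]]
    total_cds <- sum(cds$end - cds$start)
    in_exons <- function(iv) {
      all(map_lgl(seq_len(nrow(iv)), function(j) {
        iv$end[j] <= iv$start[j] ||  # empty intervals are vacuously contained
          any(ex$start <= iv$start[j] & iv$end[j] <= ex$end)
      }))
    }
    total_cds %% 3L == 0L &&
      is_disjoint_sorted(ex$start, ex$end) &&
      in_exons(cds) && in_exons(g$utr5[[i]]) && in_exons(g$utr3[[i]])
  })
  if (!all(ok)) abort("invalid gene model(s)")
  invisible(genome)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome>\n")
  cat(sprintf("  %d chromosome(s), %s bp total, %d genes\n",
              length(x$chrom_lengths), format(sum(x$chrom_lengths),
                                              big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Genomic context of positions (genic / intergenic / pericentromeric)
#'
#' Pericentromeric context takes precedence over genic/intergenic; a position
#' inside a gene span (UTR to UTR) outside the pericentromere is `genic`.
#'
#' @param genome An `annotated_genome`.
#' @param chrom,pos Parallel vectors of chromosome ids and 0-based positions.
#' @return Character vector of contexts.
#' @export
genomic_context <- function(genome, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- rep("intergenic", length(pos))
  for (cid in unique(chrom)) {
    sel <- chrom == cid
    p <- pos[sel]
    genes <- dplyr::filter(genome$genes, .data$chrom == cid)
    genic <- rep(FALSE, length(p))
    if (nrow(genes) > 0L) {
      for (i in seq_len(nrow(genes))) {
        genic <- genic | (p >= genes$start[i] & p < genes$end[i])
      }
    }
    peri <- dplyr::filter(genome$pericentromere, .data$chrom == cid)
    in_peri <- p >= peri$start[1] & p < peri$end[1]
    ctx <- ifelse(in_peri, "pericentromeric",
                  ifelse(genic, "genic", "intergenic"))
    out[sel] <- ctx
  }
  out
}
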