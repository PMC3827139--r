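# Variant context and consequence classification, Table-1-style category
# accounting, and windowed / per-gene / regional density profiles, plus
# zero-depth large-INDEL detection.

#' Variant call filter
#'
#' The depth and homozygosity filter applied to candidate calls: coverage
#' between `min_depth` and `max_depth` inclusive, and allele frequency
#' strictly above `hom_af` to call the locus homozygous (heterozygous
#' survivors are excluded).
#'
#' @param min_depth,max_depth Inclusive depth bounds.
#' @param hom_af Homozygosity allele-frequency threshold (exclusive).
#' @return A `call_filter` list.
#' @export
call_filter <- function(min_depth = 5L, max_depth = 150L, hom_af = 0.75) {
  if (!(min_depth > 0 && min_depth <= max_depth)) {
    abort("need 0 < min_depth <= max_depth")
  }
  if (!(hom_af > 0.5 && hom_af <= 1)) abort("hom_af must be in (0.5, 1]")
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 hom_af = hom_af), class = "call_filter")
}

#' Apply the call filter to candidate variant calls
#'
#' @param calls Tibble with `depth` and `allele_freq` columns.
#' @param filter A [call_filter()].
#' @return The rows passing the filter.
#' @examples
#' calls <- tibble::tibble(depth = c(4, 150, 20), allele_freq = c(.9, .8, .7))
#' nrow(apply_call_filter(calls, call_filter()))  # 1
#' @export
apply_call_filter <- function(calls, filter = call_filter()) {
  stopifnot(all(c("depth", "allele_freq") %in% names(calls)))
  dplyr::filter(calls,
                .data$depth >= filter$min_depth,
                .data$depth <= filter$max_depth,
                .data$allele_freq > filter$hom_af)
}

#' Left-normalize INDELs
#'
#' Shifts anchored multi-base INDELs to their leftmost equivalent position so
#' that identical events called at different offsets compare equal.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`, `type`).
#' @param genome An `annotated_genome`.
#' @return The variants with INDELs left-shifted.
#' @export
left_normalize_variants <- function(variants, genome) {
  seqs <- as.character(genome$sequences)
  for (i in which(variants$type == "INDEL")) {
    chrom <- variants$chrom[i]
    pos <- variants$pos[i]; ref <- variants$ref[i]; alt <- variants$alt[i]
    repeat {
      # shiftable while ref and alt end with the same base and we can prepend
      if (pos <= 0L || nchar(ref) < 1L || nchar(alt) < 1L) break
      last_r <- substr(ref, nchar(ref), nchar(ref))
      last_a <- substr(alt, nchar(alt), nchar(alt))
      if (last_r != last_a) break
      prev <- substr(seqs[[chrom]], pos, pos)
      pos <- pos - 1L
      ref <- paste0(prev, substr(ref, 1, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1, nchar(alt) - 1L))
    }
    variants$pos[i] <- pos
    variants$ref[i] <- ref
    variants$alt[i] <- alt
  }
  variants
}

severity_order <- c("stop_gained", "frameshift", "stop_lost", "missense",
                    "inframe", "synonymous", "none")

# CDS sequence of a gene in transcript orientation
gene_cds_seq <- function(seq, gene_row) {
  cds <- gene_row$cds[[1]]
  s <- paste(vapply(seq_len(nrow(cds)), function(j) {
    substr(seq, cds$start[j] + 1L, cds$end[j])
  }, character(1)), collapse = "")
  if (gene_row$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# genomic position -> 0-based offset in the transcript-oriented CDS
cds_offset <- function(gene_row, pos) {
  cds <- gene_row$cds[[1]]
  if (gene_row$strand == "+") {
    off <- 0L
    for (j in seq_len(nrow(cds))) {
      if (pos >= cds$start[j] && pos < cds$end[j]) {
        return(off + (pos - cds$start[j]))
      }
      off <- off + (cds$end[j] - cds$start[j])
    }
  } else {
    off <- 0L
    for (j in rev(seq_len(nrow(cds)))) {
      if (pos >= cds$start[j] && pos < cds$end[j]) {
        return(off + (cds$end[j] - 1L - pos))
      }
      off <- off + (cds$end[j] - cds$start[j])
    }
  }
  NA_integer_
}

translate_str <- function(s) {
  if (nchar(s) < 3L) return("")
  s <- substr(s, 1, 3L * (nchar(s) %/% 3L))
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

# consequence of a SNP at CDS offset `off` (transcript orientation)
snp_consequence <- function(cds_seq, off, alt_base) {
  codon_i <- off %/% 3L
  within <- off %% 3L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_base
  ref_aa <- codon_aa(codon)
  alt_aa <- codon_aa(alt_codon)
  if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "stop_gained"
  else if (ref_aa == "*") "stop_lost"
  else "missense"
}

#' Classify variants by genomic context and coding consequence
#'
#' Location category uses the precedence CDS > UTR > intron > intergenic; a
#' variant overlapping several genes takes the most severe consequence.
#' Coding SNPs are resolved by strand-aware codon translation; coding INDELs
#' are `frameshift` when their length change is not a multiple of 3,
#' otherwise `inframe` with stop-gained/lost checks on the re-translated
#' edited window.
#'
#' @param variants Tibble (`chrom`, `pos` 0-based, `ref`, `alt`, `type`).
#' @param genome An `annotated_genome`.
#' @param check_ref Verify each `ref` allele against the genome (data error
#'   on mismatch).
#' @return `variants` plus `location` (intergenic/intron/UTR/coding) and
#'   `consequence` (none for non-coding).
#' @export
classify_variants <- function(variants, genome, check_ref = TRUE) {
  seqs <- as.character(genome$sequences)
  if (check_ref && nrow(variants) > 0L) {
    obs <- vapply(seq_len(nrow(variants)), function(i) {
      substr(seqs[[variants$chrom[i]]], variants$pos[i] + 1L,
             variants$pos[i] + nchar(variants$ref[i]))
    }, character(1))
    if (any(obs != variants$ref)) {
      abort("ref allele mismatch with genome sequence")
    }
  }
  location <- character(nrow(variants))
  consequence <- character(nrow(variants))
  genes_by_chr <- split(genome$genes, genome$genes$chrom)
  gene_rows <- lapply(genes_by_chr, function(gtab) {
    lapply(seq_len(nrow(gtab)), function(h) as.list(gtab[h, ]))
  })
  cds_cache <- new.env(parent = emptyenv())
  vchrom <- variants$chrom; vpos <- variants$pos
  vref <- variants$ref
  for (i in seq_len(nrow(variants))) {
    chrom <- vchrom[i]
    pos <- vpos[i]
    span_end <- pos + nchar(vref[i])
    genes <- genes_by_chr[[chrom]]
    loc <- "intergenic"; cons <- "none"
    if (!is.null(genes)) {
      hits <- which(genes$start < span_end & genes$end > pos)
      best_rank <- Inf
      for (h in hits) {
        gr <- gene_rows[[chrom]][[h]]
        res <- classify_in_gene(seqs[[chrom]], gr, variants[i, ], pos,
                                span_end, cds_cache)
        rank <- match(res$location,
                      c("coding", "UTR", "intron", "intergenic"))
        crank <- match(res$consequence, severity_order)
        if (rank < match(loc, c("coding", "UTR", "intron", "intergenic")) ||
            (res$location == "coding" && loc == "coding" &&
             crank < best_rank)) {
          loc <- res$location; cons <- res$consequence
          if (res$location == "coding") best_rank <- crank
        }
      }
    }
    location[i] <- loc
    consequence[i] <- cons
  }
  mutate(variants, location = location, consequence = consequence)
}

classify_in_gene <- function(seq, gr, v, pos, span_end, cds_cache = NULL) {
  overlaps <- function(iv) {
    any(iv$start < span_end & iv$end > pos)
  }
  if (overlaps(gr$cds[[1]])) {
    cds_seq <- if (!is.null(cds_cache) && !is.null(cds_cache[[gr$gene_id]])) {
      cds_cache[[gr$gene_id]]
    } else {
      cs <- gene_cds_seq(seq, gr)
      if (!is.null(cds_cache)) cds_cache[[gr$gene_id]] <- cs
      cs
    }
    if (v$type == "SNP") {
      off <- cds_offset(gr, pos)
      alt_b <- if (gr$strand == "+") v$alt else comp_base[[v$alt]]
      return(list(location = "coding",
                  consequence = snp_consequence(cds_seq, off, alt_b)))
    }
    len_change <- nchar(v$alt) - nchar(v$ref)
    if (len_change %% 3L != 0L) {
      return(list(location = "coding", consequence = "frameshift"))
    }
    cons <- inframe_stop_check(seq, gr, v, cds_seq)
    return(list(location = "coding", consequence = cons))
  }
  if (overlaps(gr$utr5[[1]]) || overlaps(gr$utr3[[1]])) {
    return(list(location = "UTR", consequence = "none"))
  }
  list(location = "intron", consequence = "none")
}

# in-frame coding INDEL: apply the edit to the chromosome, rebuild and
# translate the edited CDS against the reference protein over the affected
# region only (coordinates downstream of the edit shift by a multiple of 3)
inframe_stop_check <- function(seq, gr, v, cds_seq) {
  edited <- paste0(substr(seq, 1, v$pos),
                   v$alt,
                   substr(seq, v$pos + nchar(v$ref) + 1L, nchar(seq)))
  shift <- nchar(v$alt) - nchar(v$ref)
  cds <- gr$cds[[1]]
  # shift CDS intervals beyond the edit
  cds2 <- cds
  after <- cds2$start > v$pos
  cds2$start[after] <- cds2$start[after] + shift
  cds2$end[cds2$end > v$pos] <- cds2$end[cds2$end > v$pos] + shift
  gr2 <- gr
  gr2$cds <- list(cds2)
  cds_seq2 <- gene_cds_seq(edited, gr2)
  p_ref <- translate_str(cds_seq)
  p_alt <- translate_str(cds_seq2)
  alt_internal_stop <- grepl("\\*", substr(p_alt, 1, nchar(p_alt) - 1L))
  ref_internal_stop <- grepl("\\*", substr(p_ref, 1, nchar(p_ref) - 1L))
  ref_terminal_stop <- substr(p_ref, nchar(p_ref), nchar(p_ref)) == "*"
  alt_terminal_stop <- substr(p_alt, nchar(p_alt), nchar(p_alt)) == "*"
  if (alt_internal_stop && !ref_internal_stop) "stop_gained"
  else if (ref_terminal_stop && !alt_terminal_stop && !alt_internal_stop)
    "stop_lost"
  else "inframe"
}

#' Tabulate variant categories in the published-table layout
#'
#' Counts per variant type: intergenic, intron, UTR and coding locations
#' (which partition the set), plus amino-acid-changing, premature-stop,
#' stop-loss and frameshift consequences among coding variants.
#'
#' @param records Classified variants from [classify_variants()]; an optional
#'   `comparison` column splits the accounting.
#' @return Tibble with one row per (comparison,) type.
#' @export
summarize_categories <- function(records) {
  if (!"comparison" %in% names(records)) records$comparison <- "all"
  records |>
    group_by(.data$comparison, .data$type) |>
    summarise(
      intergenic = sum(.data$location == "intergenic"),
      intron = sum(.data$location == "intron"),
      UTR = sum(.data$location == "UTR"),
      coding = sum(.data$location == "coding"),
      aa_change = sum(.data$consequence == "missense"),
      premature_stop = sum(.data$consequence == "stop_gained"),
      stop_loss = sum(.data$consequence == "stop_lost"),
      frameshift = sum(.data$consequence == "frameshift"),
      total = dplyr::n(),
      .groups = "drop"
    )
}

#' Windowed variant density profile
#'
#' Half-open tiling of the region from its start; the last partial window is
#' normalized by its true length. Density is variants per Kbp.
#'
#' @param variants Variant tibble (`chrom`, `pos`).
#' @param region List or one-row tibble with `chrom`, `start`, `end`.
#' @param window_size Window size in bp (default 600).
#' @return Tibble (`chrom`, `start`, `end`, `count`, `density`) of class
#'   `density_profile`.
#' @export
window_density <- function(variants, region, window_size = 600L) {
  if (window_size <= 0) abort("window size must be > 0")
  if (region$end <= region$start) abort("empty region")
  starts <- seq(region$start, region$end - 1L, by = window_size)
  ends <- pmin(starts + window_size, region$end)
  v <- dplyr::filter(variants, .data$chrom == region$chrom,
                     .data$pos >= region$start, .data$pos < region$end)
  counts <- vapply(seq_along(starts), function(i) {
    sum(v$pos >= starts[i] & v$pos < ends[i])
  }, integer(1))
  out <- tibble(chrom = region$chrom, start = as.integer(starts),
                end = as.integer(ends), count = counts,
                density = counts / ((ends - starts) / 1000))
  class(out) <- c("density_profile", class(out))
  out
}

#' Per-gene variant density (variants per Kbp of gene span)
#'
#' Variants are assigned by full gene span (UTR to UTR).
#'
#' @param variants Variant tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return Tibble (`gene_id`, `chrom`, `start`, `end`, `count`, `density`).
#' @export
per_gene_density <- function(variants, genes) {
  if (any(genes$end <= genes$start)) abort("zero-length gene span")
  counts <- vapply(seq_len(nrow(genes)), function(i) {
    sum(variants$chrom == genes$chrom[i] & variants$pos >= genes$start[i] &
          variants$pos < genes$end[i])
  }, integer(1))
  tibble(gene_id = genes$gene_id, chrom = genes$chrom, start = genes$start,
         end = genes$end, count = counts,
         density = counts / ((genes$end - genes$start) / 1000))
}

#' Mean genic and intergenic variant density in large physical bins
#'
#' Splits each bin's variants by genic/intergenic membership (full gene
#' spans) and divides by the genic (resp. intergenic) bp in the bin, per Kbp.
#' A class with zero bp in a bin gets `NA`.
#'
#' @param variants Variant tibble.
#' @param genome An `annotated_genome`.
#' @param region List with `chrom`, `start`, `end`.
#' @param bin_size Bin size in bp (default 10 Mbp).
#' @return Tibble (`chrom`, `start`, `end`, `genic_count`,
#'   `intergenic_count`, `genic_bp`, `intergenic_bp`, `genic_density`,
#'   `intergenic_density`).
#' @export
regional_density <- function(variants, genome, region, bin_size = 1e7) {
  if (region$end > genome$chrom_lengths[[region$chrom]] || region$start < 0) {
    abort("region outside genome")
  }
  genes <- dplyr::filter(genome$genes, .data$chrom == region$chrom)
  gene_iv <- if (nrow(genes) > 0L) {
    red <- IRanges::reduce(IRanges::IRanges(start = genes$start + 1L,
                                            end = genes$end))
    tibble(start = IRanges::start(red) - 1L, end = IRanges::end(red))
  } else tibble(start = integer(), end = integer())
  in_gene <- function(pos) {
    if (nrow(gene_iv) == 0L) return(rep(FALSE, length(pos)))
    vapply(pos, function(p) any(gene_iv$start <= p & p < gene_iv$end),
           logical(1))
  }
  starts <- seq(region$start, region$end - 1L, by = bin_size)
  ends <- pmin(starts + bin_size, region$end)
  v <- dplyr::filter(variants, .data$chrom == region$chrom,
                     .data$pos >= region$start, .data$pos < region$end)
  v$genic <- in_gene(v$pos)
  rows <- map(seq_along(starts), function(i) {
    sel <- v$pos >= starts[i] & v$pos < ends[i]
    gbp <- sum(overlap_bp(gene_iv$start, gene_iv$end, starts[i], ends[i]))
    ibp <- (ends[i] - starts[i]) - gbp
    tibble(
      chrom = region$chrom, start = as.integer(starts[i]),
      end = as.integer(ends[i]),
      genic_count = sum(sel & v$genic),
      intergenic_count = sum(sel & !v$genic),
      genic_bp = gbp, intergenic_bp = ibp,
      genic_density = if (gbp > 0) sum(sel & v$genic) / (gbp / 1000)
                      else NA_real_,
      intergenic_density = if (ibp > 0)
        sum(sel & !v$genic) / (ibp / 1000) else NA_real_
    )
  })
  bind_rows(rows)
}

#' Detect large INDELs as zero-depth spans
#'
#' Maximal runs of exactly-zero depth with length at least `min_length`
#' (default 25 bp); runs separated by any covered base are distinct.
#'
#' @param depth_track Tibble (`chrom`, `start`, `end`, `depth`) of depth runs.
#' @param min_length Minimum span length in bp.
#' @return Tibble (`chrom`, `start`, `end`, `length`).
#' @export
detect_large_indels <- function(depth_track, min_length = 25L) {
  if (any(depth_track$depth < 0)) abort("negative depth")
  z <- dplyr::filter(depth_track, .data$depth == 0) |>
    arrange(.data$chrom, .data$start)
  if (nrow(z) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer()))
  }
  grp <- cumsum(c(TRUE, !(z$chrom[-1] == z$chrom[-nrow(z)] &
                            z$start[-1] == z$end[-nrow(z)])))
  z |>
    mutate(grp = grp) |>
    group_by(.data$grp) |>
    summarise(chrom = dplyr::first(.data$chrom), start = min(.data$start),
              end = max(.data$end), .groups = "drop") |>
    mutate(length = .data$end - .data$start) |>
    dplyr::filter(.data$length >= min_length) |>
    select("chrom", "start", "end", "length") |>
    arrange(.data$chrom, .data$start)
}
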