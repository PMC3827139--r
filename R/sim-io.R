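# Dataset export/import: FASTA genome, GFF3 gene models, per-line VCF,
# bedGraph depth tracks, TSV marker matrices and truth tables. Internal
# coordinates are 0-based half-open; VCF and GFF3 are written 1-based.

#' @importClassesFrom vcfR vcfR
NULL

#' Write an annotated genome, line genomes and marker data to disk
#'
#' @param genome An `annotated_genome`.
#' @param out_dir Output directory (created if needed).
#' @param lines Optional named list of `line_genome`s; each gets a VCF, a
#'   bedGraph depth track (zero depth over its large deletions) and a truth
#'   segment table.
#' @param panel Optional `founder_panel` (required with `lines`).
#' @param markers Optional marker/genotype tibble written as TSV.
#' @param config A [sim_config()] (depth parameters).
#' @return Tibble manifest (`artifact`, `path`).
#' @export
export_dataset <- function(genome, out_dir, lines = NULL, panel = NULL,
                           markers = NULL, config = sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort("cannot create output directory")
  paths <- list()
  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome$sequences, fa)
  paths$genome_fasta <- fa
  gff <- file.path(out_dir, "genes.gff3")
  write_genes_gff3(genome, gff)
  paths$genes_gff3 <- gff
  peri <- file.path(out_dir, "pericentromere.tsv")
  readr::write_tsv(genome$pericentromere, peri)
  paths$pericentromere_tsv <- peri
  if (!is.null(lines)) {
    stopifnot(!is.null(panel))
    for (ln in names(lines)) {
      v <- line_variants(lines[[ln]], panel)
      vcf <- file.path(out_dir, paste0(ln, ".vcf.gz"))
      write_line_vcf(v, ln, genome, vcf)
      paths[[paste0("vcf_", ln)]] <- vcf
      bg <- file.path(out_dir, paste0(ln, ".depth.bedGraph"))
      write_depth_bedgraph(depth_track_for_line(v, genome, config), bg)
      paths[[paste0("depth_", ln)]] <- bg
      tr <- file.path(out_dir, paste0(ln, ".truth.tsv"))
      readr::write_tsv(line_segments(lines[[ln]]), tr)
      paths[[paste0("truth_", ln)]] <- tr
    }
  }
  if (!is.null(markers)) {
    mk <- file.path(out_dir, "markers.tsv")
    readr::write_tsv(markers, mk)
    paths$markers_tsv <- mk
  }
  tibble(artifact = names(paths), path = unlist(unname(paths)))
}

#' @rdname export_dataset
#' @param path File path.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

write_genes_gff3 <- function(genome, path) {
  g <- genome$genes
  feat <- function(tb, type, gene_id, chrom, strand) {
    tb <- dplyr::filter(tb, .data$end > .data$start)
    if (nrow(tb) == 0L) return(NULL)
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = tb$start + 1L, end = tb$end),
      strand = strand,
      type = type,
      ID = if (type == "gene") gene_id else
        if (type == "mRNA") paste0(gene_id, ".t") else NA_character_,
      Parent = if (type == "gene") NA_character_ else
        if (type == "mRNA") gene_id else paste0(gene_id, ".t")
    )
  }
  grl <- list()
  for (i in seq_len(nrow(g))) {
    span <- tibble(start = g$start[i], end = g$end[i])
    grl <- c(grl, list(
      feat(span, "gene", g$gene_id[i], g$chrom[i], g$strand[i]),
      feat(span, "mRNA", g$gene_id[i], g$chrom[i], g$strand[i]),
      feat(g$exons[[i]], "exon", g$gene_id[i], g$chrom[i], g$strand[i]),
      feat(g$cds[[i]], "CDS", g$gene_id[i], g$chrom[i], g$strand[i]),
      feat(g$utr5[[i]], "five_prime_UTR", g$gene_id[i], g$chrom[i],
           g$strand[i]),
      feat(g$utr3[[i]], "three_prime_UTR", g$gene_id[i], g$chrom[i],
           g$strand[i])
    ))
  }
  grl <- grl[!vapply(grl, is.null, logical(1))]
  gr <- if (length(grl) > 0L) {
    suppressWarnings(do.call(c, grl))
  } else {
    GenomicRanges::GRanges()
  }
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reconstructs the package's gene tibble (0-based half-open intervals with
#' exon/CDS/UTR list-columns) from gene/mRNA/exon/CDS/UTR features.
#'
#' @param path GFF3 file path.
#' @return Tibble in the layout of `annotated_genome$genes`.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  genes <- dplyr::filter(df, .data$type == "gene")
  iv <- function(sub) {
    sub <- arrange(sub, .data$start)
    tibble(start = as.integer(sub$start - 1L), end = as.integer(sub$end))
  }
  out <- map(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    kids <- dplyr::filter(df, .data$Parent %in% paste0(gid, ".t"))
    list(
      gene_id = gid,
      chrom = as.character(genes$seqnames[i]),
      strand = as.character(genes$strand[i]),
      start = as.integer(genes$start[i] - 1L),
      end = as.integer(genes$end[i]),
      exons = iv(dplyr::filter(kids, .data$type == "exon")),
      cds = iv(dplyr::filter(kids, .data$type == "CDS")),
      utr5 = iv(dplyr::filter(kids, .data$type == "five_prime_UTR")),
      utr3 = iv(dplyr::filter(kids, .data$type == "three_prime_UTR"))
    )
  })
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
  ) |> arrange(.data$chrom, .data$start)
}

write_line_vcf <- function(variants, line_id, genome, path) {
  v <- arrange(variants, .data$chrom, .data$pos)
  fix <- cbind(
    CHROM = v$chrom,
    POS = as.character(v$pos + 1L),
    ID = rep(NA_character_, nrow(v)),
    REF = v$ref,
    ALT = v$alt,
    QUAL = rep(NA_character_, nrow(v)),
    FILTER = rep("PASS", nrow(v)),
    INFO = paste0("TYPE=", v$type)
  )
  gt <- cbind(FORMAT = rep("GT", nrow(v)),
              line = rep("1/1", nrow(v)))
  colnames(gt)[2] <- line_id
  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$chrom_lengths),
            unname(genome$chrom_lengths)),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  obj <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read a single-sample VCF into the package's variant tibble
#'
#' @param path VCF path (plain or gzipped).
#' @return Tibble (`chrom`, `pos` 0-based, `ref`, `alt`, `type`).
#' @export
read_line_vcf <- function(path) {
  obj <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(obj)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), type = character()))
  }
  tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    type = ifelse(nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L,
                  "SNP", "INDEL")
  )
}

#' Simulated depth track for a line (bedGraph-style runs)
#'
#' Constant mean depth with zero-depth runs over the line's large deletions
#' (the signature used downstream to call large INDELs).
#'
#' @param variants Line variant tibble (from [line_variants()]).
#' @param genome An `annotated_genome`.
#' @param config A [sim_config()] (`depth_mean`, `large_del_range`).
#' @return Tibble (`chrom`, `start`, `end`, `depth`).
#' @export
depth_track_for_line <- function(variants, genome, config = sim_config()) {
  dels <- dplyr::filter(variants,
                        nchar(.data$ref) - nchar(.data$alt) >=
                          config$large_del_range[1])
  out <- list()
  for (cid in names(genome$chrom_lengths)) {
    len <- genome$chrom_lengths[[cid]]
    d <- dplyr::filter(dels, .data$chrom == cid) |> arrange(.data$pos)
    # deleted bases start one after the anchored ref base
    zs <- d$pos + 1L
    ze <- d$pos + nchar(d$ref)
    bounds <- c(0L, rbind(zs, ze), len)
    depth <- rep(c(config$depth_mean, 0), length.out = length(bounds) - 1L)
    tb <- tibble(chrom = cid, start = bounds[-length(bounds)],
                 end = bounds[-1], depth = depth)
    out[[cid]] <- dplyr::filter(tb, .data$end > .data$start)
  }
  bind_rows(out)
}

write_depth_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$depth
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph depth track
#'
#' @param path bedGraph path.
#' @return Tibble (`chrom`, `start`, `end`, `depth`), 0-based half-open.
#' @export
read_depth_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.integer(GenomicRanges::start(gr) - 1L),
    end = as.integer(GenomicRanges::end(gr)),
    depth = as.numeric(gr$score)
  )
}

#' Read a marker/genotype TSV
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_marker_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
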