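# Derive per-line variant sets and marker/genotype tables from simulated
# mosaics and the founder panel.

#' Variants carried by a line genome
#'
#' The union of founder variants restricted to the segments each haplotype
#' inherited from that founder.
#'
#' @param line A `line_genome`.
#' @param panel A `founder_panel`.
#' @param hap Haplotype index (default 1; inbred lines have one haplotype).
#' @return Tibble (`chrom`, `pos`, `ref`, `alt`, `type`), sorted.
#' @export
line_variants <- function(line, panel, hap = 1L) {
  mos <- line$haplotypes[[min(hap, length(line$haplotypes))]]
  out <- list()
  for (cid in names(mos)) {
    segs <- mos[[cid]]
    pv <- dplyr::filter(panel$variants, .data$chrom == cid)
    if (nrow(pv) == 0L) next
    for (i in seq_len(nrow(segs))) {
      hit <- dplyr::filter(pv, .data$founder == segs$founder[i],
                           .data$pos >= segs$start[i],
                           .data$pos < segs$end[i])
      if (nrow(hit) > 0L) out[[length(out) + 1L]] <- hit
    }
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), type = character()))
  }
  bind_rows(out) |>
    select("chrom", "pos", "ref", "alt", "type") |>
    arrange(.data$chrom, .data$pos)
}

#' Sites polymorphic among a set of founders
#'
#' @param panel A `founder_panel`.
#' @param founders Founder ids (default all).
#' @return Tibble (`chrom`, `pos`, `ref`) plus one allele column per founder
#'   (the founder's alt allele at the site, or the reference allele).
#' @export
polymorphic_sites <- function(panel, founders = names(panel$founders)) {
  v <- dplyr::filter(panel$variants, .data$founder %in% founders)
  if (nrow(v) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character()))
  }
  wide <- tidyr::pivot_wider(
    select(v, "founder", "chrom", "pos", "ref", "alt"),
    names_from = "founder", values_from = "alt"
  )
  for (f in founders) {
    if (!f %in% names(wide)) wide[[f]] <- NA_character_
    wide[[f]] <- dplyr::coalesce(wide[[f]], wide$ref)
  }
  allele_cols <- as.matrix(wide[founders])
  keep <- apply(allele_cols, 1L, function(x) length(unique(x)) > 1L)
  arrange(wide[keep, c("chrom", "pos", "ref", founders)],
          .data$chrom, .data$pos)
}

#' Genotype lines at marker sites
#'
#' For each (inbred) line the allele at a marker is the allele of the founder
#' owning the segment containing the marker. Diploid lines are called with
#' haplotype agreement: discordant haplotypes yield `NA` (heterozygous).
#'
#' @param lines Named list of `line_genome`s.
#' @param panel A `founder_panel`.
#' @param markers Tibble with `chrom`, `pos`, `ref` and one allele column per
#'   founder, as from [polymorphic_sites()].
#' @return Tibble (`marker_id`, `chrom`, `pos`) with one call column per line.
#' @export
genotype_lines <- function(lines, panel, markers) {
  out <- tibble(
    marker_id = sprintf("m_%s_%d", markers$chrom, markers$pos),
    chrom = markers$chrom, pos = markers$pos
  )
  founder_cols <- setdiff(names(markers),
                          c("marker_id", "chrom", "pos", "ref"))
  allele_of <- function(fs, idx) {
    # allele of founder fs[j] at marker idx[j]; unknown founders -> ref
    al <- markers$ref[idx]
    for (f in unique(fs)) {
      if (f %in% founder_cols) {
        sel <- fs == f
        al[sel] <- markers[[f]][idx[sel]]
      }
    }
    al
  }
  for (ln in names(lines)) {
    line <- lines[[ln]]
    hap_alleles <- lapply(line$haplotypes, function(mos) {
      al <- character(nrow(markers))
      for (cid in unique(markers$chrom)) {
        sel <- which(markers$chrom == cid)
        fs <- founder_at(mos[[cid]], markers$pos[sel])
        al[sel] <- allele_of(fs, sel)
      }
      al
    })
    if (length(hap_alleles) == 1L) {
      out[[ln]] <- hap_alleles[[1]]
    } else {
      same <- hap_alleles[[1]] == hap_alleles[[2]]
      out[[ln]] <- ifelse(same, hap_alleles[[1]], NA_character_)
    }
  }
  out
}

#' RIL genotype matrix relative to the two parents
#'
#' Calls each RIL `A` where both haplotypes descend from parent 1, `B` for
#' parent 2, and `H` where the line is still heterozygous at the marker.
#'
#' @param pop Result of [generate_ril_population()].
#' @param markers Tibble (`chrom`, `pos`); a `marker_id` is added if missing.
#' @return Tibble (`marker_id`, `chrom`, `pos`, one column per RIL).
#' @export
ril_genotypes <- function(pop, markers) {
  out <- tibble(
    marker_id = if ("marker_id" %in% names(markers)) markers$marker_id else
      sprintf("m_%s_%d", markers$chrom, markers$pos),
    chrom = markers$chrom, pos = markers$pos
  )
  for (ln in names(pop$lines)) {
    line <- pop$lines[[ln]]
    hap_f <- lapply(line$haplotypes, function(mos) {
      f <- character(nrow(markers))
      for (cid in unique(markers$chrom)) {
        sel <- which(markers$chrom == cid)
        f[sel] <- founder_at(mos[[cid]], markers$pos[sel])
      }
      f
    })
    if (length(hap_f) == 1L) hap_f[[2]] <- hap_f[[1]]
    out[[ln]] <- ifelse(
      hap_f[[1]] == pop$p1$line_id & hap_f[[2]] == pop$p1$line_id, "A",
      ifelse(hap_f[[1]] == pop$p2$line_id & hap_f[[2]] == pop$p2$line_id,
             "B", "H"))
  }
  out
}
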