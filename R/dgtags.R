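# Digital Genotyping (DG) tag prediction and QC: in-silico restriction-site
# scanning for a methylation-sensitive enzyme (NgoMIV, G^CCGGC), extraction
# of fixed-length flanking tags, simulated methylation-dependent recovery,
# windowed methylation profiling, and comparison of validated tags against
# re-sequenced consensus.

#' NgoMIV recognition motif
#' @export
NGOMIV_MOTIF <- "GCCGGC"

# cut offset within the motif: G^CCGGC
NGOMIV_CUT_OFFSET <- 1L

#' Find all occurrences of a restriction motif
#'
#' Scans the forward strand for exact motif matches, keeping overlapping
#' occurrences. For a palindromic motif (NgoMIV's GCCGGC is its own reverse
#' complement) the forward scan is complete.
#'
#' @param sequences A [Biostrings::DNAStringSet], an `annotated_genome`, or a
#'   character vector of sequences (named by chromosome).
#' @param motif Uppercase ACGT motif (ambiguity codes unsupported).
#' @return Tibble (`chrom`, `pos`, `motif`) with 0-based motif start positions.
#' @examples
#' find_restriction_sites(c(chr = "TTGCCGGCAA"))$pos  # 2
#' @export
find_restriction_sites <- function(sequences, motif = NGOMIV_MOTIF) {
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    abort("motif must be non-empty uppercase ACGT (no ambiguity codes)")
  }
  if (inherits(sequences, "annotated_genome")) {
    sequences <- sequences$sequences
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- sprintf("seq%d", seq_along(sequences))
    }
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  out <- list()
  for (i in seq_along(sequences)) {
    m <- Biostrings::matchPattern(motif, sequences[[i]])
    if (length(m) == 0L) next
    out[[length(out) + 1L]] <- tibble(
      chrom = names(sequences)[i],
      pos = as.integer(Biostrings::start(m) - 1L),
      motif = motif
    )
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), pos = integer(), motif = character()))
  }
  bind_rows(out)
}

#' Extract DG tags flanking restriction sites
#'
#' For each site, one tag per side of the cut position (cut after base 1 of
#' the motif): the left tag is the `tag_length` bases ending at the cut, the
#' right tag the `tag_length` bases starting at the cut, both reported on the
#' forward strand. Tags that would run past a chromosome end are dropped (and
#' counted in the `dropped` attribute).
#'
#' @param genome An `annotated_genome` or named [Biostrings::DNAStringSet].
#' @param sites Tibble from [find_restriction_sites()].
#' @param tag_length Tag length, 37 or 72.
#' @return Tibble (`chrom`, `site_pos`, `side`, `length`, `sequence`) with a
#'   `dropped` attribute counting boundary-truncated tags.
#' @export
extract_dg_tags <- function(genome, sites, tag_length = 72L) {
  if (!tag_length %in% c(37L, 72L)) abort("tag_length must be 37 or 72")
  seqs <- if (inherits(genome, "annotated_genome")) genome$sequences else
    genome
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  chars <- as.character(seqs)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    cid <- sites$chrom[i]
    cut <- sites$pos[i] + NGOMIV_CUT_OFFSET
    if (cut - tag_length >= 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = cid, site_pos = sites$pos[i], side = "left",
        length = tag_length,
        sequence = substr(chars[[cid]], cut - tag_length + 1L, cut)
      )
    } else {
      dropped <- dropped + 1L
    }
    if (cut + tag_length <= lens[[cid]]) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = cid, site_pos = sites$pos[i], side = "right",
        length = tag_length,
        sequence = substr(chars[[cid]], cut + 1L, cut + tag_length)
      )
    } else {
      dropped <- dropped + 1L
    }
  }
  out <- if (length(rows) > 0L) bind_rows(rows) else
    tibble(chrom = character(), site_pos = integer(), side = character(),
           length = integer(), sequence = character())
  attr(out, "dropped") <- dropped
  out
}

#' Flag tags whose sequence maps to more than one genomic location
#'
#' Counts exact occurrences of each tag sequence on both strands of the
#' genome; tags occurring more than once are flagged non-unique and should be
#' excluded from marker use.
#'
#' @param tags Tibble from [extract_dg_tags()] (one tag length).
#' @param genome An `annotated_genome` or [Biostrings::DNAStringSet].
#' @return `tags` with logical column `unique_hit`.
#' @export
flag_unique_tags <- function(tags, genome) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$sequences else
    genome
  if (nrow(tags) == 0L) return(mutate(tags, unique_hit = logical(0)))
  pd <- Biostrings::PDict(tags$sequence)
  counts <- rep(0L, nrow(tags))
  for (i in seq_along(seqs)) {
    counts <- counts + Biostrings::countPDict(pd, seqs[[i]]) +
      Biostrings::countPDict(pd, Biostrings::reverseComplement(seqs[[i]]))
  }
  mutate(tags, unique_hit = counts == 1L)
}

#' Simulate methylation-dependent tag recovery
#'
#' A tag is only producible when its restriction site is unmethylated (the
#' enzyme does not cut methylated sites). Unmethylated sites receive Poisson
#' read counts at the configured mean depth; a tag is recovered when its
#' count reaches the minimum depth.
#'
#' @param tags Tag tibble.
#' @param methylation Tibble from [simulate_methylation()].
#' @param depth_mean Mean reads per tag.
#' @param min_depth Minimum count to call a tag recovered.
#' @param seed Integer seed.
#' @return `tags` plus `methylated`, `count`, `recovered`.
#' @export
simulate_tag_recovery <- function(tags, methylation, depth_mean = 15,
                                  min_depth = 5L, seed = 1L) {
  key <- left_join(tags,
                   select(methylation, "chrom", site_pos = "pos",
                          "methylated"),
                   by = c("chrom", "site_pos"))
  if (anyNA(key$methylated)) abort("methylation state missing for some sites")
  with_seed(seed, {
    key$count <- ifelse(key$methylated, 0L, rpois(nrow(key), depth_mean))
    key$recovered <- !key$methylated & key$count >= min_depth
    key
  })
}

#' Windowed methylation profile from tag recovery
#'
#' Per window: the number of in-silico predicted restriction sites, the
#' number recovered by (simulated) sequencing, and the recovered fraction —
#' the profile used to read local DNA methylation off methylation-sensitive
#' genotyping data. Windows with no predicted site get `NA`, not 0.
#'
#' @param recovery Tibble from [simulate_tag_recovery()].
#' @param windows Tibble (`chrom`, `start`, `end`), non-overlapping.
#' @return Tibble (`chrom`, `start`, `end`, `predicted`, `recovered`,
#'   `fraction`) of class `methylation_profile`.
#' @export
methylation_profile <- function(recovery, windows) {
  windows <- arrange(windows, .data$chrom, .data$start)
  by_chr <- split(windows, windows$chrom)
  for (w in by_chr) {
    if (!is_disjoint_sorted(w$start, w$end)) abort("overlapping windows")
  }
  sites <- recovery |>
    group_by(.data$chrom, .data$site_pos) |>
    summarise(recovered = any(.data$recovered), .groups = "drop")
  res <- windows
  res$predicted <- 0L
  res$recovered <- 0L
  for (i in seq_len(nrow(res))) {
    hit <- sites$chrom == res$chrom[i] & sites$site_pos >= res$start[i] &
      sites$site_pos < res$end[i]
    res$predicted[i] <- sum(hit)
    res$recovered[i] <- sum(sites$recovered[hit])
  }
  res$fraction <- ifelse(res$predicted > 0L,
                         res$recovered / res$predicted, NA_real_)
  class(res) <- c("methylation_profile", class(res))
  res
}

#' Compare validated tags to re-sequenced consensus sequences
#'
#' Tags and consensus are paired by site key. Exact equality is `perfect`;
#' pairs whose best global alignment has substitutions only are
#' `SNP-mismatch`; pairs of unequal length or whose best alignment is gapped
#' are `indel-discordant`; tags absent from the consensus are `missing`.
#'
#' @param tags Tibble (`chrom`, `site_pos`, `side`, `sequence`).
#' @param consensus Tibble with the same key columns and column `sequence`
#'   (the consensus allele of the tag region).
#' @return A `tag_match_report`: list with `per_tag` tibble and `summary`
#'   (class counts and perfect percentage).
#' @export
compare_tags_to_consensus <- function(tags, consensus) {
  m <- left_join(tags,
                 rename(consensus, consensus = "sequence"),
                 by = c("chrom", "site_pos", "side"))
  cls <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    s <- m$sequence[i]; cns <- m$consensus[i]
    if (is.na(cns)) {
      cls[i] <- "missing"
    } else if (s == cns) {
      cls[i] <- "perfect"
    } else {
      aln <- Biostrings::pairwiseAlignment(
        s, cns, type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1),
        gapOpening = 2, gapExtension = 1)
      gapped <- paste0(as.character(Biostrings::alignedPattern(aln)),
                       as.character(Biostrings::alignedSubject(aln)))
      cls[i] <- if (grepl("-", gapped, fixed = TRUE)) "indel-discordant"
                else "SNP-mismatch"
    }
  }
  per_tag <- mutate(m, class = cls)
  counts <- table(factor(cls, levels = c("perfect", "SNP-mismatch",
                                         "indel-discordant", "missing")))
  structure(
    list(per_tag = per_tag,
         summary = tibble(class = names(counts), n = as.integer(counts)),
         n_total = nrow(per_tag),
         perfect_pct = 100 * counts[["perfect"]] / max(1L, nrow(per_tag))),
    class = "tag_match_report"
  )
}

#' @export
print.tag_match_report <- function(x, ...) {
  cat("<tag_match_report>\n")
  print(x$summary)
  cat(sprintf("  perfect: %.1f%% of %d tags\n", x$perfect_pct, x$n_total))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tag_match_report <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.tag_match_report <- function(x, ...) {
  tibble(n_tags = x$n_total, perfect_pct = x$perfect_pct)
}

#' Pooled perfect-match percentage across genotypes
#'
#' Pools per-genotype perfect-match counts over per-genotype totals, e.g. two
#' genotypes with 1356 and 1293 perfect matches out of 1462 validated tags
#' each pool to 90.6%.
#'
#' @param perfect Integer vector of perfect-match counts per genotype.
#' @param total Integer vector of validated-tag totals per genotype.
#' @return Pooled percentage (one value).
#' @examples
#' pooled_perfect_pct(c(1356, 1293), c(1462, 1462))
#' @export
pooled_perfect_pct <- function(perfect, total) {
  stopifnot(length(perfect) == length(total), all(perfect <= total))
  100 * sum(perfect) / sum(total)
}
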