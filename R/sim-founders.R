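# Founder-panel simulator: a block landscape of local polymorphism intensity
# (100-fold contrast by default) and Poisson-placed variants per founder, with
# race structure imposed through shared within-race variant pools.

#' Generate a blockwise polymorphism-intensity landscape
#'
#' Tiles each chromosome with blocks of random size (default 50-300 Kbp) and
#' assigns each block one of the configured intensity levels: the expected
#' pairwise SNP density per bp between founders of different races. With the
#' default two levels the contrast is 100-fold, mimicking the alternation of
#' very high and low local polymorphism density observed in crop genomes.
#'
#' @param genome An `annotated_genome`.
#' @param config A [sim_config()].
#' @return A tibble (`chrom`, `start`, `end`, `intensity`) whose intervals
#'   tile each chromosome exactly.
#' @export
density_landscape <- function(genome, config) {
  if (any(config$intensity_levels < 0)) abort("intensities must be >= 0")
  with_seed(stage_seed(config$seed, "landscape"), {
    out <- list()
    for (cid in names(genome$chrom_lengths)) {
      len <- genome$chrom_lengths[[cid]]
      starts <- integer()
      cursor <- 0L
      while (cursor < len) {
        starts <- c(starts, cursor)
        cursor <- cursor +
          as.integer(round(runif(1, config$block_range_bp[1],
                                 config$block_range_bp[2])))
      }
      ends <- c(starts[-1], len)
      out[[cid]] <- tibble(
        chrom = cid, start = starts, end = as.integer(ends),
        intensity = sample(unname(config$intensity_levels), length(starts),
                           replace = TRUE)
      )
    }
    lsc <- bind_rows(out)
    for (cid in names(genome$chrom_lengths)) {
      check_tiling(dplyr::filter(lsc, .data$chrom == cid),
                   genome$chrom_lengths[[cid]], "landscape blocks")
    }
    lsc
  })
}

#' Simulate founder variant panels over an intensity landscape
#'
#' Each founder receives variants relative to the reference. Variants are
#' drawn from two Poisson pools per landscape block: a race-level pool shared
#' by all founders of a race (fraction `race_share` of the per-founder rate)
#' and a private pool per founder. With per-founder rate `intensity/2`, the
#' expected pairwise difference density between founders of different races
#' equals the block intensity. A configured fraction of variants are short
#' INDELs (geometric lengths), and each founder additionally carries a few
#' large 25-500 bp deletions per chromosome.
#'
#' @param genome An `annotated_genome`.
#' @param landscape Tibble from [density_landscape()].
#' @param config A [sim_config()] (provides founders, race structure, INDEL
#'   settings and the seed).
#' @return A `founder_panel`: list with `founders` (id -> race) and `variants`
#'   (tibble: `founder`, `chrom`, `pos` 0-based, `ref`, `alt`, `type`).
#' @export
simulate_founder_variants <- function(genome, landscape, config) {
  if (any(landscape$intensity < 0)) abort("intensity < 0")
  for (cid in names(genome$chrom_lengths)) {
    check_tiling(dplyr::filter(landscape, .data$chrom == cid),
                 genome$chrom_lengths[[cid]], "landscape blocks")
  }
  founders <- config$founders
  with_seed(stage_seed(config$seed, "founders"), {
    seqs <- as.character(genome$sequences)
    races <- unique(unname(founders))
    race_pool <- list()
    # race-level shared pools
    for (rc in races) {
      race_pool[[rc]] <- draw_variant_set(
        landscape, seqs, rate_factor = config$race_share / 2, config)
    }
    per_founder <- list()
    for (f in names(founders)) {
      private <- draw_variant_set(
        landscape, seqs, rate_factor = (1 - config$race_share) / 2, config,
        exclude = race_pool[[founders[[f]]]])
      v <- bind_rows(race_pool[[founders[[f]]]], private)
      v <- draw_large_deletions(v, genome, seqs, config)
      v <- dplyr::distinct(v, .data$chrom, .data$pos, .keep_all = TRUE)
      per_founder[[f]] <- mutate(v, founder = f, .before = 1)
    }
    panel <- structure(
      list(founders = founders,
           variants = arrange(bind_rows(per_founder), .data$founder,
                              .data$chrom, .data$pos)),
      class = "founder_panel"
    )
    panel
  })
}

# Poisson placement of SNPs/short INDELs over landscape blocks at
# rate = intensity * rate_factor per bp; positions in `exclude` (e.g. the
# race-level shared pool) are avoided so pooling does not deflate the rate
draw_variant_set <- function(landscape, seqs, rate_factor, config,
                             exclude = NULL) {
  rows <- list()
  for (i in seq_len(nrow(landscape))) {
    blk <- landscape[i, ]
    width <- blk$end - blk$start
    n <- rpois(1, blk$intensity * rate_factor * width)
    if (n == 0L) next
    avoid <- if (is.null(exclude)) integer() else
      exclude$pos[exclude$chrom == blk$chrom] - blk$start + 1L
    cand <- sample.int(width, min(width, n + length(avoid)),
                       replace = FALSE)
    cand <- setdiff(cand, avoid)
    pos <- sort(cand[seq_len(min(n, length(cand)))]) - 1L + blk$start
    seq <- seqs[[blk$chrom]]
    is_indel <- runif(length(pos)) < config$indel_fraction
    ref <- vapply(pos, function(p) substr(seq, p + 1, p + 1), character(1))
    keep <- ref %in% c("A", "C", "G", "T")
    pos <- pos[keep]; ref <- ref[keep]; is_indel <- is_indel[keep]
    if (length(pos) == 0L) next
    alt <- character(length(pos))
    type <- ifelse(is_indel, "INDEL", "SNP")
    alt[!is_indel] <- substitute_base(ref[!is_indel])
    if (any(is_indel)) {
      idx <- which(is_indel)
      ilen <- rgeom(length(idx), 1 / config$indel_mean_len) + 1L
      is_del <- runif(length(idx)) < 0.5
      for (k in seq_along(idx)) {
        p <- pos[idx[k]]
        if (is_del[k] && p + 1 + ilen[k] <= nchar(seq)) {
          ref[idx[k]] <- substr(seq, p + 1, p + 1 + ilen[k])
          alt[idx[k]] <- substr(seq, p + 1, p + 1)
        } else {
          alt[idx[k]] <- paste0(ref[idx[k]], random_dna(ilen[k]))
        }
      }
    }
    rows[[length(rows) + 1L]] <-
      tibble(chrom = blk$chrom, pos = pos, ref = ref, alt = alt, type = type)
  }
  if (length(rows) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), type = character()))
  }
  bind_rows(rows)
}

# a few large deletions per chromosome per founder (anchored VCF style)
draw_large_deletions <- function(v, genome, seqs, config) {
  if (config$n_large_deletions <= 0L) return(v)
  rows <- list()
  for (cid in names(genome$chrom_lengths)) {
    len <- genome$chrom_lengths[[cid]]
    n <- config$n_large_deletions
    pos <- sort(sample.int(len - config$large_del_range[2] - 2L, n))
    dlen <- as.integer(round(runif(n, config$large_del_range[1],
                                   config$large_del_range[2])))
    rows[[cid]] <- tibble(
      chrom = cid, pos = pos,
      ref = vapply(seq_len(n), function(k) {
        substr(seqs[[cid]], pos[k] + 1, pos[k] + 1 + dlen[k])
      }, character(1)),
      alt = vapply(seq_len(n), function(k) {
        substr(seqs[[cid]], pos[k] + 1, pos[k] + 1)
      }, character(1)),
      type = "INDEL"
    )
  }
  bind_rows(v, bind_rows(rows))
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("<founder_panel>\n")
  tb <- dplyr::count(x$variants, .data$founder, .data$type)
  print(tidyr::pivot_wider(tb, names_from = "type", values_from = "n"))
  invisible(x)
}

#' Pairwise variant differences between two founders
#'
#' Sites where exactly one founder carries a variant, or both carry different
#' alleles, relative to the reference.
#'
#' @param panel A `founder_panel`.
#' @param f1,f2 Founder ids.
#' @return Tibble of differing sites (`chrom`, `pos`, `type`).
#' @export
founder_pair_differences <- function(panel, f1, f2) {
  v1 <- dplyr::filter(panel$variants, .data$founder == f1)
  v2 <- dplyr::filter(panel$variants, .data$founder == f2)
  m <- dplyr::full_join(
    select(v1, "chrom", "pos", "type", alt1 = "alt"),
    select(v2, "chrom", "pos", type2 = "type", alt2 = "alt"),
    by = c("chrom", "pos")
  )
  m <- dplyr::filter(m, is.na(.data$alt1) | is.na(.data$alt2) |
                       .data$alt1 != .data$alt2)
  mutate(m, type = dplyr::coalesce(.data$type, .data$type2)) |>
    select("chrom", "pos", "type") |>
    arrange(.data$chrom, .data$pos)
}
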