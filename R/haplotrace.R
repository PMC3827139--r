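# Pedigree haplotype tracing: per-marker origin calls, recursive founder
# lifting through a pedigree, haplotype-block segmentation, and
# identity-by-descent segment detection.

#' Origin of a single marker allele given both parent alleles
#'
#' @param offspring,p1,p2 Allele strings (or `NA` for missing).
#' @return One of `"parent1"`, `"parent2"`, `"unknown-uninformative"`,
#'   `"conflict"`, `"unknown-missing"`.
#' @examples
#' marker_origin("A", "A", "G")  # parent1
#' @export
marker_origin <- function(offspring, p1, p2) {
  if (is.na(offspring) || is.na(p1) || is.na(p2)) return("unknown-missing")
  if (p1 == p2) return("unknown-uninformative")
  if (offspring == p1) return("parent1")
  if (offspring == p2) return("parent2")
  "conflict"
}

#' Trace marker origins through a pedigree to founder labels
#'
#' For every genotyped non-founder node, each marker allele is matched
#' against the node's parents where both parents differ; the matching
#' parent's own origin at that marker is then lifted recursively until a
#' founder is reached (or the lift stalls at an unresolved ancestor, which
#' yields that ancestor's id). When only one parent is genotyped, alleles not
#' matching it are tentatively assigned to the other parent and flagged.
#'
#' @param pedigree Tibble (`child`, `parent1`, `parent2`); founders are nodes
#'   never appearing as a child. `parent2` may be `NA`.
#' @param genotypes Tibble (`marker_id`, `chrom`, `pos`, one allele column
#'   per genotyped node), as from [genotype_lines()].
#' @param lines Character vector of nodes to trace (default: all genotyped
#'   non-founders).
#' @return Tibble (`line`, `marker_id`, `chrom`, `pos`, `label`,
#'   `tentative`); `label` is a founder id or one of the unknown/conflict
#'   codes from [marker_origin()].
#' @export
trace_pedigree <- function(pedigree, genotypes, lines = NULL) {
  nodes <- unique(c(pedigree$child, pedigree$parent1, pedigree$parent2))
  nodes <- nodes[!is.na(nodes)]
  founders <- setdiff(nodes, pedigree$child)
  genotyped <- intersect(nodes, names(genotypes))
  n_mark <- nrow(genotypes)
  cache <- new.env(parent = emptyenv())

  resolve <- function(node) {
    if (!is.null(cache[[node]])) return(cache[[node]])
    if (node %in% founders) {
      res <- list(label = rep(node, n_mark),
                  tentative = rep(FALSE, n_mark))
      cache[[node]] <- res
      return(res)
    }
    row <- pedigree[pedigree$child == node, ][1, ]
    p1 <- row$parent1; p2 <- row$parent2
    if (!node %in% genotyped) {
      # ungenotyped internal node: origin unresolved, label is the node id
      res <- list(label = rep(node, n_mark),
                  tentative = rep(TRUE, n_mark))
      cache[[node]] <- res
      return(res)
    }
    off <- genotypes[[node]]
    g1 <- if (!is.na(p1) && p1 %in% genotyped) genotypes[[p1]] else NULL
    g2 <- if (!is.na(p2) && p2 %in% genotyped) genotypes[[p2]] else NULL
    label <- rep("unknown-missing", n_mark)
    tentative <- rep(FALSE, n_mark)
    if (!is.null(g1) && !is.null(g2)) {
      r1 <- resolve(p1); r2 <- resolve(p2)
      both <- !is.na(off) & !is.na(g1) & !is.na(g2)
      uninf <- both & g1 == g2
      m1 <- both & !uninf & off == g1
      m2 <- both & !uninf & off == g2
      label[uninf] <- "unknown-uninformative"
      label[m1] <- r1$label[m1]; tentative[m1] <- r1$tentative[m1]
      label[m2] <- r2$label[m2]; tentative[m2] <- r2$tentative[m2]
      label[both & !uninf & !m1 & !m2] <- "conflict"
      # one parent missing at this marker: fall back to the one-parent rule
      only1 <- !is.na(off) & !is.na(g1) & is.na(g2)
      o1m <- only1 & off == g1
      label[o1m] <- r1$label[o1m]; tentative[o1m] <- r1$tentative[o1m]
      label[only1 & !o1m] <- p2; tentative[only1 & !o1m] <- TRUE
      only2 <- !is.na(off) & is.na(g1) & !is.na(g2)
      o2m <- only2 & off == g2
      label[o2m] <- r2$label[o2m]; tentative[o2m] <- r2$tentative[o2m]
      label[only2 & !o2m] <- p1; tentative[only2 & !o2m] <- TRUE
    } else if (!is.null(g1) || !is.null(g2)) {
      gp <- if (!is.null(g1)) p1 else p2
      go <- if (!is.null(g1)) g1 else g2
      other <- if (!is.null(g1)) p2 else p1
      rp <- resolve(gp)
      miss <- is.na(off) | is.na(go)
      mp <- !miss & off == go
      label[mp] <- rp$label[mp]; tentative[mp] <- rp$tentative[mp]
      rest <- !miss & !mp
      label[rest] <- if (is.na(other)) "conflict" else other
      tentative[rest] <- TRUE
    }
    res <- list(label = label, tentative = tentative)
    cache[[node]] <- res
    res
  }

  lines <- lines %||% intersect(genotyped, pedigree$child)
  out <- map(lines, function(ln) {
    r <- resolve(ln)
    tibble(line = ln, marker_id = genotypes$marker_id,
           chrom = genotypes$chrom, pos = genotypes$pos,
           label = r$label, tentative = r$tentative)
  })
  bind_rows(out)
}

unknown_labels <- c("unknown-missing", "unknown-uninformative", "conflict")

#' Segment per-marker origin calls into haplotype blocks
#'
#' Maximal runs of a single founder label over informative markers, after
#' absorbing isolated discordant runs of length `<= smoothing` whose flanks
#' agree (genotyping-error absorption). Runs supported by fewer than
#' `min_markers` markers are flagged low-confidence. Block boundaries are
#' placed at the midpoint between the last marker of one run and the first
#' of the next.
#'
#' @param calls Origin calls for one line (`chrom`, `pos`, `label`), sorted
#'   by position within chromosome.
#' @param min_markers Minimum supporting markers for a confident block.
#' @param smoothing Maximum length of a discordant run absorbed into equal
#'   flanks (0 disables smoothing).
#' @return Tibble (`chrom`, `start`, `end`, `boundary_start`, `boundary_end`,
#'   `founder`, `n_markers`, `low_confidence`); `start`/`end` are the first
#'   and last supporting marker positions.
#' @export
segment_blocks <- function(calls, min_markers = 5L, smoothing = 1L) {
  out <- list()
  for (cid in unique(calls$chrom)) {
    cc <- dplyr::filter(calls, .data$chrom == cid) |> arrange(.data$pos)
    inf <- dplyr::filter(cc, !.data$label %in% unknown_labels)
    if (nrow(inf) == 0L) next
    lab <- inf$label
    if (smoothing > 0L && length(lab) > 2L) {
      r <- rle(lab)
      if (length(r$lengths) > 2L) {
        for (j in 2:(length(r$lengths) - 1L)) {
          if (r$lengths[j] <= smoothing &&
              r$values[j - 1L] == r$values[j + 1L] &&
              r$values[j] != r$values[j - 1L]) {
            r$values[j] <- r$values[j - 1L]
          }
        }
      }
      lab <- inverse.rle(r)
    }
    r <- rle(lab)
    ends_i <- cumsum(r$lengths)
    starts_i <- c(1L, head(ends_i, -1L) + 1L)
    for (j in seq_along(r$values)) {
      first_pos <- inf$pos[starts_i[j]]
      last_pos <- inf$pos[ends_i[j]]
      b_start <- if (j == 1L) first_pos else
        (inf$pos[starts_i[j] - 1L] + first_pos) %/% 2L
      b_end <- if (j == length(r$values)) last_pos else
        (last_pos + inf$pos[ends_i[j] + 1L]) %/% 2L
      out[[length(out) + 1L]] <- tibble(
        chrom = cid, start = first_pos, end = last_pos,
        boundary_start = as.integer(b_start), boundary_end = as.integer(b_end),
        founder = r$values[j], n_markers = r$lengths[j],
        low_confidence = r$lengths[j] < min_markers
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  boundary_start = integer(), boundary_end = integer(),
                  founder = character(), n_markers = integer(),
                  low_confidence = logical()))
  }
  bind_rows(out)
}

#' Detect identity-by-descent segments from pairwise variant density
#'
#' Tiles the region with windows, computes the pairwise variant density per
#' window, and reports maximal runs of windows below the density threshold
#' whose total length reaches `min_length` — regions where two lines are
#' identical (or nearly identical) by descent.
#'
#' @param pair_variants Variants differing between the two lines (`chrom`,
#'   `pos`), e.g. from [founder_pair_differences()].
#' @param region List with `chrom`, `start`, `end`.
#' @param density_threshold Maximum density (variants/Kbp) for an IBD window.
#' @param min_length Minimum segment length in bp.
#' @param window Window size in bp.
#' @return Tibble (`chrom`, `start`, `end`, `length`, `mean_density`,
#'   `evidence`).
#' @export
detect_ibd <- function(pair_variants, region, density_threshold = 0.05,
                       min_length = 1e6, window = 1e5) {
  prof <- window_density(pair_variants, region, window_size = window)
  low <- prof$density < density_threshold
  r <- rle(low)
  ends_i <- cumsum(r$lengths)
  starts_i <- c(1L, head(ends_i, -1L) + 1L)
  out <- list()
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    s <- prof$start[starts_i[j]]
    e <- prof$end[ends_i[j]]
    if (e - s < min_length) next
    out[[length(out) + 1L]] <- tibble(
      chrom = region$chrom, start = s, end = e, length = e - s,
      mean_density = sum(prof$count[starts_i[j]:ends_i[j]]) /
        ((e - s) / 1000),
      evidence = "density"
    )
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), mean_density = numeric(),
                  evidence = character()))
  }
  bind_rows(out)
}

#' Detect IBD segments from shared haplotype labels
#'
#' Maximal runs of markers where two lines carry the same founder label.
#'
#' @param calls1,calls2 Origin calls for two lines over the same markers
#'   (`chrom`, `pos`, `label`).
#' @param min_markers Minimum run length in markers.
#' @return Tibble (`chrom`, `start`, `end`, `founder`, `n_markers`,
#'   `evidence`).
#' @export
detect_ibd_labels <- function(calls1, calls2, min_markers = 5L) {
  m <- dplyr::inner_join(
    select(calls1, "chrom", "pos", label1 = "label"),
    select(calls2, "chrom", "pos", label2 = "label"),
    by = c("chrom", "pos")
  ) |> arrange(.data$chrom, .data$pos)
  out <- list()
  for (cid in unique(m$chrom)) {
    mm <- dplyr::filter(m, .data$chrom == cid)
    shared <- !mm$label1 %in% unknown_labels & mm$label1 == mm$label2
    r <- rle(shared)
    ends_i <- cumsum(r$lengths)
    starts_i <- c(1L, head(ends_i, -1L) + 1L)
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < min_markers) next
      out[[length(out) + 1L]] <- tibble(
        chrom = cid, start = mm$pos[starts_i[j]], end = mm$pos[ends_i[j]],
        founder = mm$label1[starts_i[j]], n_markers = r$lengths[j],
        evidence = "haplotype-label"
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  founder = character(), n_markers = integer(),
                  evidence = character()))
  }
  bind_rows(out)
}
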