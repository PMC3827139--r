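# Pedigree breeding simulator: haploid mosaics, Poisson crossovers mapped
# through a cM->bp map with suppressed pericentromeric recombination,
# crossing/backcrossing/selfing/single-seed descent, and selection loci that
# fix a founder haplotype in all descendants.

#' Create a founder line genome
#'
#' A fully inbred line whose single mosaic attributes every chromosome to one
#' founder label.
#'
#' @param genome An `annotated_genome`.
#' @param founder_id Label carried by the mosaic.
#' @return A `line_genome`.
#' @export
founder_line <- function(genome, founder_id) {
  mosaic <- lapply(genome$chrom_lengths, function(len) {
    tibble(start = 0L, end = as.integer(len), founder = founder_id)
  })
  structure(list(line_id = founder_id, haplotypes = list(mosaic)),
            class = "line_genome")
}

is_inbred <- function(line) length(line$haplotypes) == 1L

#' @export
print.line_genome <- function(x, ...) {
  cat(sprintf("<line_genome> %s (%s)\n", x$line_id,
              if (is_inbred(x)) "inbred" else "diploid"))
  print(line_segments(x))
  invisible(x)
}

#' Truth segment table of a line genome
#'
#' @param line A `line_genome`.
#' @return Tibble (`line`, `hap`, `chrom`, `start`, `end`, `founder`).
#' @export
line_segments <- function(line) {
  bind_rows(imap(line$haplotypes, function(mos, h) {
    bind_rows(imap(mos, function(tb, cid) {
      mutate(tb, chrom = cid, .before = 1)
    })) |> mutate(hap = as.integer(h), .before = 1)
  })) |> mutate(line = line$line_id, .before = 1)
}

#' Piecewise-linear genetic map of the simulated genome
#'
#' Distributes each chromosome's genetic length over three physical segments:
#' the two euchromatic arms share `1 - peri_crossover_share` of the length in
#' proportion to their physical size, and the pericentromere receives
#' `peri_crossover_share` (default 5%), modelling suppressed pericentromeric
#' recombination.
#'
#' @param genome An `annotated_genome`.
#' @param config A [sim_config()].
#' @return Tibble (`chrom`, `start`, `end`, `cm_start`, `cm_end`).
#' @export
cm_map <- function(genome, config) {
  out <- list()
  for (i in seq_along(genome$chrom_lengths)) {
    cid <- names(genome$chrom_lengths)[i]
    len <- genome$chrom_lengths[[i]]
    L <- config$genetic_length_cM[i]
    peri <- dplyr::filter(genome$pericentromere, .data$chrom == cid)
    arm_bp <- c(peri$start, len - peri$end)
    arm_cm <- L * (1 - config$peri_crossover_share) * arm_bp / sum(arm_bp)
    cm_breaks <- cumsum(c(0, arm_cm[1], L * config$peri_crossover_share,
                          arm_cm[2]))
    out[[cid]] <- tibble(
      chrom = cid,
      start = c(0L, peri$start, peri$end),
      end = c(peri$start, peri$end, as.integer(len)),
      cm_start = cm_breaks[1:3],
      cm_end = cm_breaks[2:4]
    )
  }
  bind_rows(out)
}

# map genetic positions (cM) to physical bp through one chromosome's map
cm_to_bp <- function(map_chr, cm) {
  vapply(cm, function(u) {
    seg <- which(u >= map_chr$cm_start & u <= map_chr$cm_end)[1]
    w <- map_chr$cm_end[seg] - map_chr$cm_start[seg]
    frac <- if (w <= 0) 0.5 else (u - map_chr$cm_start[seg]) / w
    as.integer(round(map_chr$start[seg] +
                       frac * (map_chr$end[seg] - map_chr$start[seg])))
  }, numeric(1))
}

# slice a one-chromosome mosaic to [s, e)
mosaic_slice <- function(tb, s, e) {
  keep <- tb$end > s & tb$start < e
  out <- tb[keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    out$start <- pmax(out$start, as.integer(s))
    out$end <- pmin(out$end, as.integer(e))
  }
  out
}

# bare-bones tibble constructor for the recombination hot path
fast_mosaic <- function(start, end, founder) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 founder = founder),
            class = c("tbl_df", "tbl", "data.frame"),
            row.names = c(NA_integer_, -length(start)))
}

# merge adjacent rows with identical founder labels (hot path: base R)
mosaic_merge <- function(tb) {
  if (nrow(tb) <= 1L) return(tb)
  r <- rle(tb$founder)
  ends_i <- cumsum(r$lengths)
  starts_i <- c(1L, head(ends_i, -1L) + 1L)
  fast_mosaic(tb$start[starts_i], tb$end[ends_i], r$values)
}

#' Draw one gamete (haploid mosaic) from a line
#'
#' Crossover counts per chromosome are Poisson with mean equal to the genetic
#' length in Morgans (no interference); crossover positions are uniform in
#' genetic distance and mapped to physical coordinates through the cM->bp map,
#' so the pericentromere receives few breakpoints.
#'
#' @param line A `line_genome` (inbred or diploid).
#' @param genetic_map Tibble from [cm_map()].
#' @return A haploid mosaic (named list of per-chromosome segment tibbles).
#' @export
make_gamete <- function(line, genetic_map) {
  if (any(genetic_map$cm_end < genetic_map$cm_start)) {
    abort("negative genetic length")
  }
  h1 <- line$haplotypes[[1]]
  h2 <- if (is_inbred(line)) h1 else line$haplotypes[[2]]
  out <- list()
  for (cid in names(h1)) {
    map_chr <- dplyr::filter(genetic_map, .data$chrom == cid)
    L <- max(map_chr$cm_end)
    k <- rpois(1, L / 100)
    len <- max(h1[[cid]]$end)
    cur <- if (runif(1) < 0.5) 1L else 2L
    if (k == 0L) {
      out[[cid]] <- if (cur == 1L) h1[[cid]] else h2[[cid]]
      next
    }
    bp <- sort(unique(cm_to_bp(map_chr, runif(k, 0, L))))
    bp <- bp[bp > 0 & bp < len]
    cuts <- sort(unique(c(0L, bp, h1[[cid]]$start, h2[[cid]]$start, len)))
    cuts <- cuts[cuts >= 0L & cuts <= len]
    s <- head(cuts, -1L)
    # haplotype active on [s, next): switches at each crossover breakpoint
    active <- (cur - 1L + findInterval(s, bp)) %% 2L + 1L
    f1 <- h1[[cid]]$founder[findInterval(s, h1[[cid]]$start)]
    f2 <- h2[[cid]]$founder[findInterval(s, h2[[cid]]$start)]
    out[[cid]] <- mosaic_merge(fast_mosaic(
      s, cuts[-1], ifelse(active == 1L, f1, f2)))
  }
  out
}

# force selection loci: overwrite mosaic over each locus with its fixed founder
apply_selection <- function(haps, selection) {
  if (is.null(selection) || nrow(selection) == 0L) return(haps)
  lapply(haps, function(mos) {
    for (i in seq_len(nrow(selection))) {
      cid <- selection$chrom[i]
      if (!cid %in% names(mos)) next
      tb <- mos[[cid]]
      s <- selection$start[i]; e <- selection$end[i]
      forced <- tibble(start = as.integer(s), end = as.integer(e),
                       founder = selection$founder[i])
      tb <- bind_rows(mosaic_slice(tb, 0, s), forced,
                      mosaic_slice(tb, e, max(tb$end))) |>
        arrange(.data$start)
      mos[[cid]] <- mosaic_merge(tb)
    }
    mos
  })
}

cross_lines <- function(p1, p2, genetic_map, child_id, selection = NULL) {
  haps <- list(make_gamete(p1, genetic_map), make_gamete(p2, genetic_map))
  haps <- apply_selection(haps, selection)
  structure(list(line_id = child_id, haplotypes = haps),
            class = "line_genome")
}

self_line <- function(line, genetic_map, child_id, selection = NULL) {
  cross_lines(line, line, genetic_map, child_id, selection)
}

# fix a diploid line to a single mosaic (used after enough selfing when a
# line is treated as inbred); takes haplotype 1
as_inbred <- function(line) {
  line$haplotypes <- line$haplotypes[1]
  line
}

#' Breed a pedigree from a founder panel
#'
#' Processes pedigree rows in order (parents must precede children). Cross
#' types: `F1` and `backcross` draw one gamete from each parent; `self` selfs
#' `parent1`; `ssd:<g>` crosses the parents and then applies `g` rounds of
#' single-seed-descent selfing. Selection loci (e.g. dwarfing loci fixed by
#' breeders) overwrite every child's mosaic with the stated founder over the
#' locus interval.
#'
#' @param pedigree Tibble (`child`, `parent1`, `parent2`, `cross`); `parent2`
#'   may be `NA` for `self`.
#' @param panel A `founder_panel` (founder ids seed the base lines).
#' @param genome An `annotated_genome`.
#' @param config A [sim_config()].
#' @param selection Optional tibble (`chrom`, `start`, `end`, `founder`).
#' @return Named list of `line_genome` objects (founders included).
#' @export
breed <- function(pedigree, panel, genome, config, selection = NULL) {
  genetic_map <- cm_map(genome, config)
  lines <- lapply(setNames(nm = names(panel$founders)),
                  function(f) founder_line(genome, f))
  with_seed(stage_seed(config$seed, "breed"), {
    for (i in seq_len(nrow(pedigree))) {
      row <- pedigree[i, ]
      if (row$child %in% names(lines)) abort("duplicate child in pedigree")
      get_parent <- function(id) {
        if (is.na(id) || !id %in% names(lines)) {
          abort(sprintf("missing parent '%s' (pedigree must be ordered)", id))
        }
        lines[[id]]
      }
      p1 <- get_parent(row$parent1)
      cross <- row$cross
      child <- if (cross == "self") {
        self_line(p1, genetic_map, row$child, selection)
      } else if (cross %in% c("F1", "backcross")) {
        cross_lines(p1, get_parent(row$parent2), genetic_map, row$child,
                    selection)
      } else if (grepl("^ssd:[0-9]+$", cross)) {
        g <- as.integer(sub("^ssd:", "", cross))
        cur <- cross_lines(p1, get_parent(row$parent2), genetic_map,
                           row$child, selection)
        for (k in seq_len(g)) {
          cur <- self_line(cur, genetic_map, row$child, selection)
        }
        as_inbred(cur)
      } else {
        abort(sprintf("unknown cross type '%s'", cross))
      }
      lines[[row$child]] <- child
    }
    lines
  })
}

founder_at <- function(mosaic_chr, pos) {
  i <- findInterval(pos, mosaic_chr$start)
  mosaic_chr$founder[i]
}

#' Fraction of heterozygous loci in a diploid line
#'
#' Probes positions and reports the fraction where the two haplotypes carry
#' different founder labels.
#'
#' @param line A `line_genome`.
#' @param positions Tibble (`chrom`, `pos`).
#' @return Numeric fraction in `[0, 1]` (0 for inbred lines).
#' @export
heterozygosity_fraction <- function(line, positions) {
  if (is_inbred(line)) return(0)
  h1 <- line$haplotypes[[1]]; h2 <- line$haplotypes[[2]]
  het <- map_lgl(seq_len(nrow(positions)), function(i) {
    cid <- positions$chrom[i]
    founder_at(h1[[cid]], positions$pos[i]) !=
      founder_at(h2[[cid]], positions$pos[i])
  })
  mean(het)
}

#' Generate a recombinant inbred line population
#'
#' F1 of the two parents followed by `generations` rounds of single-seed
#' descent selfing per line (11 rounds emulates an F12 population, residual
#' heterozygosity ~(1/2)^11 per locus). Parent mosaics are relabelled by
#' parent line id so every RIL segment is attributable to parent 1 or 2.
#'
#' @param p1,p2 Inbred `line_genome` parents (distinct ids).
#' @param n Number of lines (> 0).
#' @param generations Selfing rounds applied to the F1.
#' @param genome An `annotated_genome`.
#' @param config A [sim_config()].
#' @param seed Optional seed overriding the config substream.
#' @return List with `lines` (list of diploid `line_genome`s labelled by
#'   parent id), `p1`, `p2`.
#' @export
generate_ril_population <- function(p1, p2, n, generations, genome, config,
                                    seed = NULL) {
  if (n <= 0) abort("n must be > 0")
  if (identical(p1$line_id, p2$line_id)) abort("p1 and p2 must differ")
  relabel <- function(line) {
    line$haplotypes <- lapply(line$haplotypes, function(mos) {
      lapply(mos, function(tb) mutate(tb, founder = line$line_id))
    })
    line
  }
  p1 <- relabel(p1); p2 <- relabel(p2)
  genetic_map <- cm_map(genome, config)
  seed <- seed %||% stage_seed(config$seed, "ril")
  with_seed(seed, {
    lines <- lapply(seq_len(n), function(i) {
      id <- sprintf("RIL%03d", i)
      cur <- cross_lines(p1, p2, genetic_map, id)
      for (g in seq_len(generations)) {
        cur <- self_line(cur, genetic_map, id)
      }
      cur
    })
    names(lines) <- map_chr(lines, "line_id")
    list(lines = lines, p1 = p1, p2 = p2)
  })
}
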