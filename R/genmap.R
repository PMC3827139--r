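# RIL genetic-map construction: recombination fractions with the selfed-RIL
# correction, Kosambi (and Haldane) mapping functions, pairwise LOD scores,
# co-segregating marker collapse and per-chromosome map assembly with a
# physical recombination profile.

#' Recombination estimate between two marker columns
#'
#' `k` counts lines whose two calls differ (A/B or B/A), `n` lines with both
#' markers called (calls other than A/B are treated as missing and dropped
#' pairwise). The observed RIL fraction `R = k/n` is corrected to the
#' per-meiosis fraction `r = R / (2 (1 - R))` (the inverse of
#' `R = 2r / (1 + 2r)` for selfed RILs), clipped to `[0, 0.5]`.
#'
#' @param calls1,calls2 Character vectors of calls (`"A"`, `"B"`, else
#'   missing).
#' @return Tibble (`n`, `k`, `R`, `r`).
#' @examples
#' recomb_fraction(rep(c("A", "B"), c(45, 45)),
#'                 rep(c("A", "B", "A"), c(41, 45, 4)))
#' @export
recomb_fraction <- function(calls1, calls2) {
  ok <- calls1 %in% c("A", "B") & calls2 %in% c("A", "B")
  n <- sum(ok)
  if (n == 0L) abort("no informative lines for this marker pair")
  k <- sum(calls1[ok] != calls2[ok])
  R <- k / n
  r <- if (R >= 0.5) 0.5 else max(0, R / (2 * (1 - R)))
  tibble(n = n, k = k, R = R, r = min(r, 0.5))
}

#' Kosambi map distance
#'
#' `d = 25 ln((1 + 2r) / (1 - 2r))` centimorgans; accounts for crossover
#' interference.
#'
#' @param r Meiotic recombination fraction in `[0, 0.5)`.
#' @return Distance in cM.
#' @examples
#' kosambi(0.25)  # 25 * log(3) = 27.465
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5)) abort("r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi function
#'
#' @param d Distance in cM.
#' @return Recombination fraction.
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0)) abort("d must be >= 0")
  e <- exp(4 * d / 100)
  (e - 1) / (2 * (e + 1))
}

#' Haldane map distance and inverse (no interference)
#'
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Distance in cM.
#' @export
haldane <- function(r) {
  if (any(r < 0 | r >= 0.5)) abort("r must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane
#' @param d Distance in cM.
#' @export
haldane_inv <- function(d) {
  if (any(d < 0)) abort("d must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

#' Pairwise LOD score for linkage
#'
#' `LOD = n (R log10 R + (1 - R) log10(1 - R) - log10 0.5)` with the
#' convention `0 log10 0 = 0`; the likelihood ratio of linkage at the
#' observed fraction against free recombination.
#'
#' @param n Informative line count.
#' @param R Observed recombinant fraction.
#' @return LOD score.
#' @examples
#' pairwise_lod(90, 0.1)  # 14.39
#' @export
pairwise_lod <- function(n, R) {
  xlx <- function(p) ifelse(p > 0, p * log10(p), 0)
  n * (xlx(R) + xlx(1 - R) - log10(0.5))
}

#' Assemble a genetic map from RIL genotypes
#'
#' Markers are taken in physical order per chromosome. Groups of markers with
#' identical genotype columns are collapsed to their first member
#' (co-segregating markers carry no extra map information); markers whose
#' best adjacent LOD does not exceed `lod_min` are dropped; cumulative cM
#' positions are the running sum of mapping-function distances over adjacent
#' retained pairs.
#'
#' @param genotypes Tibble from [ril_genotypes()]: `marker_id`, `chrom`,
#'   `pos` plus one call column per line.
#' @param lod_min LOD retention threshold (exclusive; default 3).
#' @param map_fun `"kosambi"` (default) or `"haldane"`.
#' @return A `genetic_map`: list with `markers` (tibble: `marker_id`,
#'   `chrom`, `pos`, `r`, `d_cM`, `cM`), `dropped` (tibble with reasons),
#'   `length_cM` (total), `chrom_length_cM`.
#' @export
assemble_map <- function(genotypes, lod_min = 3, map_fun = "kosambi") {
  mfun <- switch(map_fun, kosambi = kosambi, haldane = haldane,
                 abort("unknown mapping function"))
  line_cols <- setdiff(names(genotypes), c("marker_id", "chrom", "pos"))
  dropped <- list()
  maps <- list()
  for (cid in unique(genotypes$chrom)) {
    g <- dplyr::filter(genotypes, .data$chrom == cid) |> arrange(.data$pos)
    mat <- as.matrix(g[line_cols])
    # collapse identical genotype columns to the first representative
    sig <- apply(mat, 1L, paste, collapse = "")
    dup <- duplicated(sig)
    if (any(dup)) {
      dropped[[length(dropped) + 1L]] <- tibble(
        marker_id = g$marker_id[dup], chrom = cid,
        reason = "co-segregating")
    }
    g <- g[!dup, , drop = FALSE]
    mat <- mat[!dup, , drop = FALSE]
    if (nrow(g) < 2L) abort("fewer than 2 retained markers on a chromosome")
    # adjacent-pair estimates; drop markers with best adjacent LOD <= lod_min
    repeat {
      est <- map(seq_len(nrow(g) - 1L), function(i) {
        e <- recomb_fraction(mat[i, ], mat[i + 1L, ])
        mutate(e, lod = pairwise_lod(.data$n, .data$R))
      })
      est <- bind_rows(est)
      best <- c(est$lod[1], pmax(head(est$lod, -1L), tail(est$lod, -1L)),
                est$lod[nrow(est)])
      bad <- which(best <= lod_min)
      if (length(bad) == 0L) break
      dropped[[length(dropped) + 1L]] <- tibble(
        marker_id = g$marker_id[bad], chrom = cid, reason = "low LOD")
      g <- g[-bad, , drop = FALSE]
      mat <- mat[-bad, , drop = FALSE]
      if (nrow(g) < 2L) abort("fewer than 2 retained markers on a chromosome")
    }
    d <- mfun(est$r)
    maps[[cid]] <- mutate(
      select(g, "marker_id", "chrom", "pos"),
      r = c(NA, est$r), d_cM = c(0, d), cM = cumsum(c(0, d))
    )
  }
  markers <- bind_rows(maps)
  chrom_len <- markers |>
    group_by(.data$chrom) |>
    summarise(length_cM = max(.data$cM), n_markers = dplyr::n(),
              .groups = "drop")
  structure(
    list(markers = markers,
         dropped = if (length(dropped) > 0L) bind_rows(dropped) else
           tibble(marker_id = character(), chrom = character(),
                  reason = character()),
         chrom_length_cM = chrom_len,
         length_cM = sum(chrom_len$length_cM),
         map_fun = map_fun),
    class = "genetic_map"
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %.1f cM over %d chromosome(s), %d markers (%d dropped)\n",
              x$length_cM, nrow(x$chrom_length_cM), nrow(x$markers),
              nrow(x$dropped)))
  print(x$chrom_length_cM)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.genetic_map <- function(x, ...) x$markers

#' @exportS3Method generics::glance
glance.genetic_map <- function(x, ...) {
  tibble(length_cM = x$length_cM,
         n_chromosomes = nrow(x$chrom_length_cM),
         n_markers = nrow(x$markers),
         n_dropped = nrow(x$dropped),
         map_fun = x$map_fun)
}

#' Recombination profile in physical windows
#'
#' Attributes each inter-marker interval's cM proportionally to the physical
#' windows it overlaps; the window sum equals the total map length.
#'
#' @param map A `genetic_map`.
#' @param window Physical window size in bp (default 10 Mbp).
#' @return Tibble (`chrom`, `start`, `end`, `cM`).
#' @export
map_density <- function(map, window = 1e7) {
  out <- list()
  for (cid in unique(map$markers$chrom)) {
    m <- dplyr::filter(map$markers, .data$chrom == cid)
    iv <- tibble(start = head(m$pos, -1L), end = tail(m$pos, -1L),
                 cM = tail(m$d_cM, -1L))
    max_pos <- max(m$pos)
    starts <- seq(0L, max_pos, by = window)
    ends <- starts + window
    cm <- vapply(seq_along(starts), function(i) {
      w <- overlap_bp(iv$start, iv$end, starts[i], ends[i])
      len <- pmax(1L, iv$end - iv$start)
      sum(iv$cM * w / len)
    }, numeric(1))
    out[[cid]] <- tibble(chrom = cid, start = as.integer(starts),
                         end = as.integer(ends), cM = cm)
  }
  bind_rows(out)
}
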