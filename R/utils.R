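# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based, half-open [start, end).
# Conversion to 1-based inclusive coordinates happens only at the VCF/GFF3
# boundary.

#' Derive a reproducible sub-seed for a named stage
#'
#' One master seed drives the whole pipeline; each stochastic stage draws from
#' its own substream so that rerunning a single stage reproduces its output
#' regardless of what ran before it.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer(((abs(seed) %% 65521) * 31013 + h * 7919 + 17) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# intervals: tibble with start/end columns; checks half-open tiling of [0, len)
check_tiling <- function(intervals, len, what = "intervals") {
  iv <- dplyr::arrange(intervals, .data$start)
  if (nrow(iv) == 0L || iv$start[1] != 0L || iv$end[nrow(iv)] != len ||
      (nrow(iv) > 1L && any(iv$end[-nrow(iv)] != iv$start[-1]))) {
    abort(sprintf("%s must tile [0, %d) exactly", what, len))
  }
  invisible(iv)
}

# sorted, non-overlapping check for interval tibbles
is_disjoint_sorted <- function(start, end) {
  if (length(start) <= 1L) return(TRUE)
  all(diff(start) > 0) && all(start[-1] >= end[-length(end)])
}

# total overlap (bp) of [s1,e1) with [s2,e2) vectors against one window [ws,we)
overlap_bp <- function(start, end, ws, we) {
  pmax(0, pmin(end, we) - pmax(start, ws))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

other_bases <- c(
  A = "CGT", C = "AGT", G = "ACT", T = "ACG"
)

substitute_base <- function(ref) {
  vapply(ref, function(b) {
    pool <- strsplit(other_bases[[b]], "")[[1]]
    sample(pool, 1L)
  }, character(1), USE.NAMES = FALSE)
}
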