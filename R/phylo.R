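# Marker-based genetic distances and UPGMA dendrograms with bootstrap
# support. Distances (p-distance, Tamura-Nei 93) come from ape::dist.dna
# with pairwise deletion; the UPGMA agglomeration is implemented here because
# its tie-breaking and bootstrap conventions are part of the method contract.

#' Character matrix from a founder panel's polymorphic sites
#'
#' One aligned column per polymorphic SNP site (one taxon row per founder);
#' the state is the founder's allele at the site. Sites with INDEL alleles
#' become gaps and are removed pairwise by the distance methods.
#'
#' @param panel A `founder_panel`.
#' @param founders Taxa to include (default all).
#' @return Character matrix (taxa x positions) with A/C/G/T/"-" states.
#' @export
marker_character_matrix <- function(panel, founders = names(panel$founders)) {
  sites <- polymorphic_sites(panel, founders)
  if (nrow(sites) == 0L) abort("no polymorphic sites among these founders")
  m <- t(as.matrix(sites[founders]))
  m[nchar(m) != 1L] <- "-"
  rownames(m) <- founders
  colnames(m) <- sprintf("%s_%d", sites$chrom, sites$pos)
  m
}

#' Pairwise genetic distances from a character matrix
#'
#' `p-distance` is the mismatch fraction over pairwise-complete positions;
#' `TN93` is the Tamura-Nei 1993 distance (unequal base frequencies, separate
#' purine and pyrimidine transition rates), in substitutions per site.
#' Positions with a gap or ambiguity in either taxon of a pair are removed
#' for that pair. Saturated pairs (undefined TN93 logarithm) raise an error.
#'
#' @param mat Character matrix from [marker_character_matrix()] (or any
#'   taxa x positions A/C/G/T matrix).
#' @param method `"p-distance"` or `"TN93"`.
#' @return A symmetric [stats::dist] with zero diagonal.
#' @export
pairwise_distance <- function(mat, method = c("TN93", "p-distance")) {
  method <- match.arg(method)
  if (nrow(mat) < 2L) abort("need at least 2 taxa")
  dna <- ape::as.DNAbin(tolower(mat))
  model <- if (method == "TN93") "TN93" else "raw"
  d <- ape::dist.dna(dna, model = model, pairwise.deletion = TRUE)
  if (anyNA(d) || any(!is.finite(d))) {
    abort(sprintf("%s distance undefined (saturation or no shared positions) for some pair",
                  method))
  }
  d
}

#' UPGMA clustering to an ultrametric tree
#'
#' Iteratively merges the closest pair of clusters; the distance from a new
#' cluster to the others is the size-weighted average of its members'
#' distances, and the merge node sits at height distance/2, giving equal
#' root-to-leaf path lengths. Ties are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its
#' alphabetically first taxon), so the output is deterministic.
#'
#' @param D A [stats::dist] or symmetric matrix with taxon labels.
#' @return An `upgma_tree`: list with `root` (nested node structure),
#'   `taxa`, `newick`, `phylo` ([ape::read.tree] of the Newick) and
#'   `total_branch_length`.
#' @examples
#' D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(D)$total_branch_length  # 5
#' @export
upgma <- function(D) {
  M <- as.matrix(D)
  n <- nrow(M)
  if (n < 2L) abort("need at least 2 taxa")
  taxa <- rownames(M) %||% sprintf("t%d", seq_len(n))
  rownames(M) <- colnames(M) <- taxa
  nodes <- lapply(taxa, function(t) {
    list(leaf = TRUE, name = t, height = 0, members = t)
  })
  names(nodes) <- taxa
  sizes <- setNames(rep(1L, n), taxa)
  active <- taxa  # each cluster keyed by its lexicographically first taxon
  while (length(active) > 1L) {
    sub <- M[active, active, drop = FALSE]
    off <- sub; diag(off) <- Inf
    dmin <- min(off)
    cand <- which(off <= dmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- t(apply(cand, 1L, function(ij) {
      sort(c(active[ij[1]], active[ij[2]]))
    }))
    pick <- order(keys[, 1], keys[, 2])[1]
    a <- keys[pick, 1]; b <- keys[pick, 2]
    h <- M[a, b] / 2
    new_key <- min(a, b)
    merged <- list(
      leaf = FALSE, height = h,
      children = list(nodes[[a]], nodes[[b]]),
      members = sort(c(nodes[[a]]$members, nodes[[b]]$members))
    )
    others <- setdiff(active, c(a, b))
    if (length(others) > 0L) {
      dnew <- (sizes[a] * M[a, others] + sizes[b] * M[b, others]) /
        (sizes[a] + sizes[b])
      M[new_key, others] <- dnew
      M[others, new_key] <- dnew
    }
    sizes[new_key] <- sizes[a] + sizes[b]
    nodes[[new_key]] <- merged
    active <- c(others, new_key)
  }
  root <- nodes[[active]]
  nwk <- paste0(newick_node(root, NULL, root = TRUE), ";")
  structure(
    list(root = root, taxa = sort(taxa), newick = nwk,
         phylo = ape::read.tree(text = nwk),
         total_branch_length = tree_branch_sum(root)),
    class = "upgma_tree"
  )
}

# serialize a node; branch lengths are parent height - child height
newick_node <- function(node, supports, root = FALSE) {
  if (node$leaf) return(node$name)
  inner <- paste(vapply(node$children, function(ch) {
    paste0(newick_node(ch, supports), ":",
           format(node$height - ch$height, digits = 10))
  }, character(1)), collapse = ",")
  label <- if (!root && !is.null(supports)) {
    key <- paste(node$members, collapse = "|")
    if (!is.null(supports[[key]])) as.character(round(supports[[key]])) else ""
  } else ""
  paste0("(", inner, ")", label)
}

tree_branch_sum <- function(node) {
  if (node$leaf) return(0)
  sum(vapply(node$children, function(ch) {
    (node$height - ch$height) + tree_branch_sum(ch)
  }, numeric(1)))
}

tree_clades <- function(node, acc = NULL) {
  if (node$leaf) return(acc)
  acc <- c(acc, paste(node$members, collapse = "|"))
  for (ch in node$children) acc <- tree_clades(ch, acc)
  acc
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("<upgma_tree>\n")
  cat(sprintf("  %d taxa, total branch length %.6f\n", length(x$taxa),
              x$total_branch_length))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.upgma_tree <- function(x, ...) {
  clades <- tree_clades(x$root)
  sup <- attr(x, "supports")
  tibble(
    clade = clades,
    n_taxa = lengths(strsplit(clades, "\\|")),
    support = if (is.null(sup)) NA_real_ else
      map_dbl(clades, ~ sup[[.x]] %||% NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.upgma_tree <- function(x, ...) {
  tibble(n_taxa = length(x$taxa),
         total_branch_length = x$total_branch_length,
         ultrametric = TRUE)
}

#' Bootstrap support for UPGMA clades
#'
#' Resamples alignment positions with replacement, rebuilds the distance
#' matrix and UPGMA tree per replicate, and reports for each internal clade
#' of the original tree the percentage of replicates containing it (by
#' leaf-set identity). Supports are attached to the original tree and
#' written into its Newick string as internal node labels.
#'
#' @param mat Character matrix (taxa x positions).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @param method Distance method passed to [pairwise_distance()].
#' @return The original `upgma_tree` with a `supports` attribute (named
#'   percentages) and supports embedded in `$newick`/`$phylo`.
#' @export
bootstrap_support <- function(mat, replicates = 1000L, seed = 1L,
                              method = "TN93") {
  if (replicates < 1L) abort("replicates must be >= 1")
  tree <- upgma(pairwise_distance(mat, method))
  clades <- setdiff(tree_clades(tree$root),
                    paste(tree$root$members, collapse = "|"))
  hits <- setNames(rep(0L, length(clades)), clades)
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      db <- try(pairwise_distance(mat[, cols, drop = FALSE], method),
                silent = TRUE)
      if (inherits(db, "try-error")) next
      tb <- upgma(db)
      cb <- tree_clades(tb$root)
      hit <- clades %in% cb
      hits[hit] <- hits[hit] + 1L
    }
  })
  supports <- as.list(100 * hits / replicates)
  nwk <- paste0(newick_node(tree$root, supports, root = TRUE), ";")
  tree$newick <- nwk
  tree$phylo <- ape::read.tree(text = nwk)
  attr(tree, "supports") <- supports
  tree
}

#' Serialize an UPGMA tree to Newick text
#'
#' Branch lengths are included; bootstrap supports (if attached) appear as
#' integer internal-node labels. The text round-trips through
#' [read_newick()].
#'
#' @param tree An `upgma_tree`.
#' @return Newick string.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  tree$newick
}

#' @rdname to_newick
#' @param text Newick text.
#' @return For `read_newick()`, an [ape::read.tree] `phylo`.
#' @export
read_newick <- function(text) {
  ape::read.tree(text = text)
}

#' Cophenetic distances of an UPGMA tree
#'
#' @param tree An `upgma_tree`.
#' @return Symmetric matrix of tree distances between taxa.
#' @export
cophenetic_distances <- function(tree) {
  ph <- tree$phylo
  m <- ape::cophenetic.phylo(ph)
  m[order(rownames(m)), order(colnames(m))]
}
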