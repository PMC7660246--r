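# Core-genome tree and patristic evolutionary distances.

#' Kimura-corrected protein distance between two aligned rows
#'
#' Over columns where neither row has a gap, the observed proportion of
#' differing residues p is corrected as `d = -ln(1 - p - 0.2 p^2)`
#' (substitutions/site).  Saturated pairs (p >= 0.85) are capped at d = 5
#' with a warning.
#'
#' @param row_a,row_b Equal-length aligned sequences.
#' @return Distance in substitutions per site.
#' @examples
#' protein_distance("MKV", "MKV")  # 0
#' @export
protein_distance <- function(row_a, row_b) {
  stopifnot(nchar(row_a) == nchar(row_b))
  a <- strsplit(row_a, "", fixed = TRUE)[[1]]
  b <- strsplit(row_b, "", fixed = TRUE)[[1]]
  ok <- a != "-" & b != "-"
  if (!any(ok)) abort("no comparable (ungapped) columns")
  p <- mean(a[ok] != b[ok])
  if (p >= 0.85) {
    warn(sprintf("saturated pair (p = %.2f); distance capped at 5", p))
    return(5)
  }
  -log(1 - p - 0.2 * p^2)
}

#' Pairwise distance matrix from a supermatrix or alignment
#'
#' @param x A `supermatrix` from [concatenate_alignments()] or a named
#'   character vector of aligned rows.
#' @return Symmetric labelled matrix of Kimura-corrected protein distances.
#' @export
distance_matrix <- function(x) {
  aln <- if (inherits(x, "supermatrix")) x$alignment else x
  m <- aln_char_matrix(aln)
  ids <- names(aln)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) abort(sprintf(
        "no comparable columns between '%s' and '%s'", ids[i], ids[j]))
      p <- mean(m[i, ok] != m[j, ok])
      d[i, j] <- d[j, i] <- if (p >= 0.85) {
        warn(sprintf("saturated pair %s-%s; distance capped at 5",
                     ids[i], ids[j]))
        5
      } else -log(1 - p - 0.2 * p^2)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative branch-length
#' estimates are clamped to 0.  The tree is rooted at the midpoint of the
#' outgroup's pendant edge when an outgroup is given, otherwise by midpoint
#' rooting.
#'
#' @param d Symmetric labelled distance matrix (>= 3 taxa).
#' @param outgroup Optional leaf label to root on.
#' @return Rooted `ape::phylo` tree.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  stopifnot(is.matrix(d), nrow(d) >= 3)
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix is not symmetric")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label)
      abort(sprintf("outgroup '%s' is not a leaf", outgroup))
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    # split the outgroup's attachment evenly across the two root edges
    root_node <- ape::Ntip(tr) + 1L
    re <- which(tr$edge[, 1] == root_node)
    if (length(re) == 2) {
      tot <- sum(tr$edge.length[re])
      tr$edge.length[re] <- tot / 2
    }
  } else {
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every leaf pair — the
#' "evolutionary distance" used for genus demarcation.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @return A [similarity_matrix()] with metric `"EVODIST"`.
#' @export
patristic_distances <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  ids <- sort(rownames(m))
  similarity_matrix(m[ids, ids], metric = "EVODIST")
}
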