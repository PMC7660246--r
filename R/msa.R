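# Progressive multiple sequence alignment: k-mer guide tree (UPGMA) and
# profile-profile global alignment with affine gaps.

aln_char_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

collapse_rows <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

# frequency profile over the protein alphabet from a character matrix
# (gaps contribute nothing, so gappy columns carry proportionally less
# score)
profile_of <- function(m) {
  codes <- matrix(.alphabet("protein")$lookup[utf8ToInt(paste(t(m), collapse = ""))],
                  nrow = nrow(m), byrow = TRUE)
  p <- matrix(0, length(AA_LETTERS), ncol(m))
  for (i in seq_len(nrow(m))) {
    idx <- which(!is.na(codes[i, ]))
    if (length(idx))
      p[cbind(codes[i, idx], idx)] <- p[cbind(codes[i, idx], idx)] + 1
  }
  p / nrow(m)
}

# 3-mer count distance used for the guide tree
kmer_distance_matrix <- function(seqs, k = 3) {
  words <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      wi <- words[[i]]; wj <- words[[j]]
      common <- intersect(names(wi), names(wj))
      shared <- sum(pmin(wi[common], wj[common]))
      denom <- max(1, min(nchar(seqs[[i]]), nchar(seqs[[j]])) - k + 1)
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  d
}

# align two sub-alignments (character matrices) via their profiles
merge_profiles <- function(ma, mb, M, gap_open, gap_extend) {
  S <- crossprod(profile_of(ma), M %*% profile_of(mb))
  path <- cpp_nw_profile(S, gap_open, gap_extend)
  pick <- function(m, cols) {
    res <- matrix("-", nrow(m), length(cols))
    ok <- cols != 0
    res[, ok] <- m[, cols[ok], drop = FALSE]
    rownames(res) <- rownames(m)
    res
  }
  rbind(pick(ma, path[, 1]), pick(mb, path[, 2]))
}

#' Progressive multiple sequence alignment
#'
#' Aligns protein sequences progressively: a guide tree is built by UPGMA
#' on 3-mer count distances, then profiles are merged bottom-up with
#' affine-gap global profile-profile alignment (BLOSUM62 expected scores,
#' gap open 11 / extend 1).  Sequences are ordered lexicographically by id
#' before guide-tree construction, making the result independent of input
#' order.
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param gap_open,gap_extend Profile gap penalties.
#' @return Named character vector of aligned rows (equal length, gap `-`),
#'   in the input id order.
#' @export
progressive_msa <- function(seqs, gap_open = 11, gap_extend = 1) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  input_order <- names(seqs)
  seqs <- toupper(seqs[order(names(seqs))])
  if (length(seqs) == 1) return(seqs[input_order])
  M <- blosum62_matrix()
  storage.mode(M) <- "double"
  as_mat <- function(i) {
    m <- matrix(strsplit(seqs[[i]], "", fixed = TRUE)[[1]], nrow = 1)
    rownames(m) <- names(seqs)[i]
    m
  }
  if (length(seqs) == 2) {
    merged <- merge_profiles(as_mat(1), as_mat(2), M, gap_open, gap_extend)
    return(collapse_rows(merged)[input_order])
  }
  d <- kmer_distance_matrix(seqs)
  hc <- hclust(as.dist(d), method = "average")
  merged_list <- vector("list", nrow(hc$merge))
  get_aln <- function(i) if (i < 0) as_mat(-i) else merged_list[[i]]
  for (k in seq_len(nrow(hc$merge))) {
    merged_list[[k]] <- merge_profiles(get_aln(hc$merge[k, 1]),
                                       get_aln(hc$merge[k, 2]),
                                       M, gap_open, gap_extend)
  }
  collapse_rows(merged_list[[nrow(hc$merge)]])[input_order]
}

#' Trim gappy alignment columns
#'
#' Keeps exactly the columns whose gap fraction is <= `max_gap_fraction`;
#' row order is preserved.
#'
#' @param aln Named character vector of equal-length aligned rows.
#' @param max_gap_fraction Maximum tolerated per-column gap fraction.
#' @return Trimmed alignment.
#' @export
trim_alignment <- function(aln, max_gap_fraction = 0.2) {
  stopifnot(length(unique(nchar(aln))) == 1)
  m <- aln_char_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep))
    abort("trimming removed every column; raise max_gap_fraction")
  collapse_rows(m[, keep, drop = FALSE])
}

#' Concatenate per-cluster alignments into a supermatrix
#'
#' Every alignment must contain every id exactly once.  The partition map
#' records each source cluster's column interval (0-based, half-open).
#'
#' @param alignments Named list of alignments (names are cluster ids).
#' @param ids Genome ids to include; defaults to the ids of the first
#'   alignment.
#' @return A `supermatrix`: list with `alignment` (named character vector)
#'   and `partitions` (tibble `cluster_id`, `start`, `end`).
#' @export
concatenate_alignments <- function(alignments, ids = NULL) {
  stopifnot(length(alignments) >= 1)
  if (is.null(names(alignments)))
    names(alignments) <- sprintf("part%03d", seq_along(alignments))
  ids <- ids %||% sort(names(alignments[[1]]))
  for (cid in names(alignments)) {
    a <- alignments[[cid]]
    for (id in ids) {
      if (sum(names(a) == id) != 1)
        abort(sprintf("cluster '%s' does not contain genome '%s' exactly once",
                      cid, id))
    }
  }
  lens <- map_int(alignments, ~ nchar(.x[[1]]))
  ends <- cumsum(lens)
  starts <- ends - lens
  rows <- vapply(ids, function(id)
    paste(map_chr(alignments, ~ .x[[id]]), collapse = ""), character(1))
  structure(list(
    alignment = setNames(rows, ids),
    partitions = tibble(cluster_id = names(alignments),
                        start = as.integer(starts), end = as.integer(ends))),
    class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d genomes x %d columns, %d partitions\n",
              length(x$alignment), nchar(x$alignment[[1]]),
              nrow(x$partitions)))
  invisible(x)
}
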