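# Genome similarity metrics: AAI, fragment-based ANI, POCP.

#' Similarity matrix container
#'
#' A labelled symmetric matrix tagged with its metric.  Percentage metrics
#' (`AAI`, `ANI`, `POCP`) have a diagonal of 100; `EVODIST` (patristic
#' distance in substitutions/site) has a zero diagonal.
#'
#' @param values Symmetric labelled numeric matrix.
#' @param metric One of `"AAI"`, `"ANI"`, `"POCP"`, `"EVODIST"` (or a
#'   custom label).
#' @export
similarity_matrix <- function(values, metric) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) abort("matrix must be labelled")
  colnames(values) <- rownames(values)
  ok <- is.na(values) | is.na(t(values)) | abs(values - t(values)) <= 1e-9
  if (!all(ok)) abort("matrix is not symmetric")
  structure(values, metric = metric,
            class = c("similarity_matrix", class(values)))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %s, %d genomes\n",
              attr(x, "metric"), nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

metric_diag <- function(metric) if (metric == "EVODIST") 0 else 100

#' Average amino-acid identity (AAI)
#'
#' Unweighted mean percent identity over the reciprocal-best-hit ortholog
#' pairs of two proteomes, at E <= `evalue_max` and both coverages >=
#' `cov_min`; no identity floor is applied, so AAI remains computable well
#' below the orthologous-clustering threshold.  With no reciprocal pairs
#' the value is missing (`NA`), never 0.
#'
#' @param a,b Genomes ([genome_record()] or named protein vectors).
#' @param cov_min Coverage threshold (both sides), percent.
#' @param evalue_max E-value ceiling.
#' @return AAI percentage, or `NA` with a warning.
#' @export
compute_aai <- function(a, b, cov_min = 50, evalue_max = 1e-5) {
  scan <- pair_scan(as_proteome(a), as_proteome(b))
  e <- rbh_from_scan(scan, identity_min = 0, cov_min = cov_min,
                     evalue_max = evalue_max)
  if (nrow(e) == 0) {
    warn("no reciprocal best hits; AAI is undefined for this pair")
    return(NA_real_)
  }
  mean(e$identity_pct)
}

#' Percentage of conserved proteins (POCP)
#'
#' `POCP = (C1 + C2) / (T1 + T2) * 100`, where `C_i` counts proteins of
#' genome i with at least one one-way hit in the other proteome passing
#' identity >= `identity_min`, both coverages >= `cov_min` and
#' E <= `evalue_max`, and `T_i` is the proteome size.
#'
#' @inheritParams compute_aai
#' @param identity_min Identity threshold, percent (40 by default, the
#'   conserved-protein filter).
#' @return POCP percentage.
#' @export
compute_pocp <- function(a, b, identity_min = 40, cov_min = 50,
                         evalue_max = 1e-5) {
  pa <- as_proteome(a); pb <- as_proteome(b)
  scan <- pair_scan(pa, pb)
  c1 <- length(scan_conserved(scan, "ab", identity_min, cov_min, evalue_max))
  c2 <- length(scan_conserved(scan, "ba", identity_min, cov_min, evalue_max))
  100 * (c1 + c2) / (length(pa) + length(pb))
}

# cut contigs into consecutive non-overlapping windows (0-based half-open
# coordinates internally); the trailing remainder is discarded.  Windows
# are taken on each contig's canonical strand (the lexicographically
# smaller of the contig and its reverse complement) so that fragment
# coordinates — and hence ANI — do not depend on assembly orientation.
cut_fragments <- function(contigs, fragment_len) {
  frags <- character(0)
  for (ci in seq_along(contigs)) {
    s <- contigs[[ci]]
    rc <- reverse_complement(s)
    if (rc < s) s <- rc
    n <- nchar(s)
    k <- n %/% fragment_len
    if (k == 0) next
    starts <- (seq_len(k) - 1) * fragment_len + 1
    f <- substring(s, starts, starts + fragment_len - 1)
    names(f) <- sprintf("%s|%d", names(contigs)[ci] %||% ci, starts - 1)
    frags <- c(frags, f)
  }
  frags
}

#' Orthologous average nucleotide identity (ANI)
#'
#' Fragment-based ANI: both assemblies are cut into consecutive
#' non-overlapping windows of `fragment_len` bp (default 1020, trailing
#' remainder discarded); fragments are aligned all-vs-all on both strands;
#' reciprocal best fragment pairs covering >= 70 % of both fragments are
#' retained; ANI is the mean identity over retained pairs.  Missing (`NA`)
#' when no reciprocal fragment pairs survive.
#'
#' @param a_contigs,b_contigs Assemblies ([genome_record()] with contigs or
#'   character vectors of contig sequences).
#' @param fragment_len Window size in bp.
#' @param match,mismatch,gap_open,gap_extend Nucleotide scoring parameters.
#' @return ANI percentage, or `NA` with a warning.
#' @export
compute_ani <- function(a_contigs, b_contigs, fragment_len = 1020,
                        match = 1, mismatch = -2, gap_open = 5,
                        gap_extend = 2) {
  ca <- toupper(as_contigs(a_contigs)); cb <- toupper(as_contigs(b_contigs))
  if (sum(nchar(ca)) < 2 * fragment_len || sum(nchar(cb)) < 2 * fragment_len)
    abort("assemblies must each total at least 2 * fragment_len")
  fa <- cut_fragments(ca, fragment_len)
  fb <- cut_fragments(cb, fragment_len)
  if (length(fa) == 0 || length(fb) == 0) {
    warn("no complete fragments; ANI is undefined")
    return(NA_real_)
  }
  # forward + reverse-complement subjects; strand folded into the index
  fb2 <- c(fb, setNames(reverse_complement(fb), paste0(names(fb), "|rc")))
  nb <- length(fb)
  al <- .alphabet("nucleotide")
  sm <- nucleotide_matrix(match, mismatch)
  ea <- encode_seqs(fa, "nucleotide")
  eb <- encode_seqs(fb2, "nucleotide")
  cand <- kmer_candidate_pairs(ea, eb, k = 12, alpha = length(NT_LETTERS),
                               min_shared = 1)
  if (nrow(cand) == 0) {
    warn("no candidate fragment pairs; ANI is undefined")
    return(NA_real_)
  }
  scores <- cpp_score_pairs(ea, eb, cand$ai, cand$bi, sm,
                            as.integer(gap_open), as.integer(gap_extend))
  keep <- scores > 0
  cand <- cand[keep, , drop = FALSE]; scores <- scores[keep]
  if (nrow(cand) == 0) {
    warn("no positive-scoring fragment pairs; ANI is undefined")
    return(NA_real_)
  }
  bj <- ifelse(cand$bi > nb, cand$bi - nb, cand$bi)  # strand-folded b index
  # best subject per a-fragment and best query per b-fragment (by raw
  # score; ties prefer the forward strand, then the smaller index)
  pick_best <- function(group, other, strand_rc) {
    best <- rep(NA_integer_, max(group))
    for (r in order(-scores, strand_rc, other)) {
      g <- group[r]
      if (is.na(best[g])) best[g] <- r
    }
    best
  }
  strand_rc <- as.integer(cand$bi > nb)
  best_a <- pick_best(cand$ai, bj, strand_rc)      # row index per a-fragment
  best_b <- pick_best(bj, cand$ai, strand_rc)      # row index per b-fragment
  ids <- double(0)
  for (i in seq_along(best_a)) {
    r <- best_a[i]
    if (is.na(r)) next
    rb <- best_b[bj[r]]
    if (is.na(rb) || cand$ai[rb] != i) next       # not reciprocal
    st <- cpp_align_pair(ea[[cand$ai[r]]], eb[[cand$bi[r]]], sm,
                         as.integer(gap_open), as.integer(gap_extend),
                         al$match_ok)
    if (st$score <= 0) next
    qcov <- (st$qend - st$qstart + 1) / nchar(fa[[cand$ai[r]]])
    scov <- (st$send - st$sstart + 1) / nchar(fb2[[cand$bi[r]]])
    if (qcov >= 0.7 && scov >= 0.7)
      ids <- c(ids, 100 * st$matches / st$aligned_cols)
  }
  if (length(ids) == 0) {
    warn("no reciprocal fragment pairs pass coverage; ANI is undefined")
    return(NA_real_)
  }
  mean(ids)
}

#' Pairwise similarity matrix over a genome set
#'
#' Computes one metric for every unordered genome pair and assembles the
#' symmetric matrix (diagonal 100 for percentage metrics).  Missing pair
#' values propagate as `NA`.
#'
#' @param genomes List of [genome_record()] objects.
#' @param metric `"aai"`, `"ani"` or `"pocp"`.
#' @param ... Passed to the per-pair metric function.
#' @return A [similarity_matrix()].
#' @export
metric_matrix <- function(genomes, metric = c("aai", "ani", "pocp"), ...) {
  metric <- match.arg(metric)
  ids <- map_chr(genomes, "genome_id")
  names(genomes) <- ids
  if (length(ids) < 2) abort("need at least 2 genomes")
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(m) <- 100
  fun <- switch(metric, aai = compute_aai, ani = compute_ani,
                pocp = compute_pocp)
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      v <- fun(genomes[[i]], genomes[[j]], ...)
      m[i, j] <- v; m[j, i] <- v
    }
  }
  similarity_matrix(m, metric = toupper(metric))
}
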