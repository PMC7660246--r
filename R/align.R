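# Local alignment interface over the C++ affine-gap Smith-Waterman kernel.

#' Bit score and E-value from a raw alignment score
#'
#' Karlin-Altschul statistics: `bits = (lambda * S - ln K) / ln 2` and
#' `E = m * n * 2^(-bits)` with `m` the query length and
#' `n = subject_len * search_space_seqs`.  Constants are fixed per scoring
#' scheme (gapped BLOSUM62: lambda 0.267, K 0.041; match 1 / mismatch -2
#' nucleotide: lambda 1.28, K 0.46); finite-size edge corrections are not
#' applied.
#'
#' @param raw_score Positive integer alignment score.
#' @param query_len,subject_len Sequence lengths (positive).
#' @param search_space_seqs Effective number of subject sequences.
#' @param scoring `"blosum62"` or `"nucleotide"`.
#' @return Tibble with `bit_score` and `e_value`.
#' @export
estimate_evalue <- function(raw_score, query_len, subject_len,
                            search_space_seqs = 1,
                            scoring = c("blosum62", "nucleotide")) {
  if (any(raw_score <= 0)) abort("raw_score must be positive")
  if (any(query_len <= 0) || any(subject_len <= 0) ||
      any(search_space_seqs <= 0))
    abort("lengths and search space must be positive")
  p <- ka_params(match.arg(scoring))
  bits <- (p$lambda * raw_score - log(p$K)) / log(2)
  tibble(bit_score = bits,
         e_value = query_len * (subject_len * search_space_seqs) * 2^(-bits))
}

.hit_tibble <- function(st, a, b, type, search_n = NULL, strand = "+") {
  qlen <- nchar(a); slen <- nchar(b)
  ev <- estimate_evalue(st$score, qlen, search_n %||% slen,
                        scoring = if (type == "protein") "blosum62"
                                  else "nucleotide")
  tibble(
    raw_score = st$score,
    bit_score = ev$bit_score,
    e_value = ev$e_value,
    identity_pct = 100 * st$matches / st$aligned_cols,
    query_cov_pct = 100 * (st$qend - st$qstart + 1) / qlen,
    subject_cov_pct = 100 * (st$send - st$sstart + 1) / slen,
    aligned_columns = st$aligned_cols,
    matches = st$matches, mismatches = st$mismatches,
    gap_columns = st$gapcols, gap_opens = st$gapopens,
    qstart = st$qstart, qend = st$qend,
    sstart = st$sstart, send = st$send,
    strand = strand)
}

#' Optimal local protein alignment
#'
#' Smith-Waterman with affine gaps (gap of length L costs
#' `gap_open + L * gap_extend`) under BLOSUM62.  Identity is computed over
#' the optimal local alignment; ambiguity codes never count as matches.
#' Returns `NULL` when no positive-scoring local alignment exists.
#'
#' @param a,b Protein sequences (single strings).
#' @param scoring Substitution matrix name; only `"BLOSUM62"` is shipped.
#' @param gap_open,gap_extend Gap penalties (positive).
#' @return One-row tibble of alignment statistics, or `NULL`.
#' @examples
#' local_align_protein("MKVLAW", "MKVLAW")$identity_pct  # 100
#' @export
local_align_protein <- function(a, b, scoring = "BLOSUM62",
                                gap_open = 11, gap_extend = 1) {
  if (!identical(toupper(scoring), "BLOSUM62"))
    abort("only BLOSUM62 is available for protein scoring")
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  al <- .alphabet("protein")
  st <- cpp_align_pair(encode_seq(toupper(a), "protein"),
                       encode_seq(toupper(b), "protein"),
                       blosum62_matrix(), as.integer(gap_open),
                       as.integer(gap_extend), al$match_ok)
  if (st$score <= 0) return(NULL)
  .hit_tibble(st, toupper(a), toupper(b), "protein")
}

#' Optimal local nucleotide alignment
#'
#' Both strands of `b` are tried and the better-scoring alignment kept
#' (ties prefer the forward strand); reported coordinates are always on the
#' forward query.  `N` scores as a mismatch.
#'
#' @param a,b Nucleotide sequences (single strings).
#' @param match,mismatch Match score and mismatch penalty.
#' @param gap_open,gap_extend Gap penalties (positive).
#' @return One-row tibble of alignment statistics (with a `strand` column),
#'   or `NULL` if no positive-scoring alignment exists.
#' @export
local_align_nucleotide <- function(a, b, match = 1, mismatch = -2,
                                   gap_open = 5, gap_extend = 2) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  al <- .alphabet("nucleotide")
  sm <- nucleotide_matrix(match, mismatch)
  ea <- encode_seq(a, "nucleotide")
  st_f <- cpp_align_pair(ea, encode_seq(b, "nucleotide"), sm,
                         as.integer(gap_open), as.integer(gap_extend),
                         al$match_ok)
  brc <- reverse_complement(b)
  st_r <- cpp_align_pair(ea, encode_seq(brc, "nucleotide"), sm,
                         as.integer(gap_open), as.integer(gap_extend),
                         al$match_ok)
  if (max(st_f$score, st_r$score) <= 0) return(NULL)
  if (st_f$score >= st_r$score) .hit_tibble(st_f, a, b, "nucleotide")
  else .hit_tibble(st_r, a, brc, "nucleotide", strand = "-")
}

# ---- k-mer prefilter ------------------------------------------------------

kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

# index: k-mer -> integer indices of target sequences containing it
kmer_index <- function(seqs, k) {
  words <- lapply(seqs, kmers_of, k = k)
  idx <- rep(seq_along(seqs), lengths(words))
  split(idx, unlist(words, use.names = FALSE))
}

#' Shared k-mer candidate prefilter
#'
#' Returns the names (or indices) of `targets` sharing at least
#' `min_shared` distinct exact k-words with `query`.  With the defaults
#' (k = 4, min_shared = 1 for proteins; k = 12 for nucleotides) this is a
#' superset of every subject whose optimal hit can pass the orthology
#' filter, making all-vs-all searches feasible.
#'
#' @param query Single sequence string.
#' @param targets Named character vector of candidate subjects.
#' @param k Word size (>= 2).
#' @param min_shared Minimum number of distinct shared words.
#' @return Character vector of target names.
#' @export
kmer_prefilter <- function(query, targets, k = 4, min_shared = 1) {
  if (k < 2) abort("k must be >= 2")
  idx <- kmer_index(targets, k)
  qw <- kmers_of(toupper(query), k)
  hit <- unlist(idx[qw], use.names = FALSE)
  if (is.null(hit) || length(hit) == 0) return(character(0))
  counts <- tabulate(hit, nbins = length(targets))
  names(targets)[counts >= min_shared]
}

# candidate (ai, bi) pairs sharing >= min_shared distinct k-mers, over
# already-encoded sequences; the shared-k-mer relation is symmetric, so
# one pass serves both directions
kmer_candidate_pairs <- function(enc_a, enc_b, k, alpha, min_shared = 1) {
  m <- cpp_kmer_pairs(enc_a, enc_b, as.integer(k), as.integer(alpha),
                      as.integer(min_shared))
  tibble(ai = m[, 1], bi = m[, 2])
}

# ---- proteome pair scan ---------------------------------------------------

# One scan per unordered proteome pair: candidate pairs, score-only SW for
# all of them, and lazy full tracebacks.  Both search directions and every
# downstream metric (orthologous clustering, AAI, POCP) reuse it.
pair_scan <- function(seqs_a, seqs_b, gap_open = 11, gap_extend = 1,
                      k = 4, min_shared = 1) {
  enc_a <- encode_seqs(seqs_a, "protein")
  enc_b <- encode_seqs(seqs_b, "protein")
  cand <- kmer_candidate_pairs(enc_a, enc_b, k, length(AA_LETTERS),
                               min_shared)
  sm <- blosum62_matrix()
  scores <- if (nrow(cand) > 0)
    cpp_score_pairs(enc_a, enc_b, cand$ai, cand$bi, sm,
                    as.integer(gap_open), as.integer(gap_extend))
  else integer(0)
  keep <- scores > 0
  env <- new.env(parent = emptyenv())
  env$cand <- cand[keep, , drop = FALSE]
  env$score <- scores[keep]
  env$seqs_a <- seqs_a; env$seqs_b <- seqs_b
  env$enc_a <- enc_a; env$enc_b <- enc_b
  env$len_a <- nchar(seqs_a); env$len_b <- nchar(seqs_b)
  env$db_a <- sum(env$len_a); env$db_b <- sum(env$len_b)
  env$gap_open <- as.integer(gap_open)
  env$gap_extend <- as.integer(gap_extend)
  env$sm <- sm
  env$match_ok <- .alphabet("protein")$match_ok
  env$stats <- new.env(parent = emptyenv())
  env
}

# full-traceback statistics for one candidate pair, memoised
scan_stats <- function(scan, ai, bi) {
  key <- paste0(ai, ":", bi)
  st <- scan$stats[[key]]
  if (is.null(st)) {
    st <- cpp_align_pair(scan$enc_a[[ai]], scan$enc_b[[bi]], scan$sm,
                         scan$gap_open, scan$gap_extend, scan$match_ok)
    scan$stats[[key]] <- st
  }
  st
}

# Best passing hit per query for one direction of a scan.
# direction "ab": queries are seqs_a, subjects seqs_b; "ba" swaps roles.
# Among hits passing identity/coverage/E thresholds, the highest bit score
# wins; ties break by identity, then aligned columns, then subject id.
scan_best_hits <- function(scan, direction = c("ab", "ba"),
                           identity_min = 50, cov_min = 50,
                           evalue_max = 1e-5) {
  direction <- match.arg(direction)
  cand <- scan$cand
  empty <- tibble(query_id = character(0), subject_id = character(0),
                  raw_score = integer(0), bit_score = double(0),
                  e_value = double(0), identity_pct = double(0),
                  query_cov_pct = double(0), subject_cov_pct = double(0),
                  aligned_columns = double(0))
  if (nrow(cand) == 0) return(empty)
  if (direction == "ab") {
    qi <- cand$ai; si <- cand$bi
    qlen <- unname(scan$len_a); slen <- unname(scan$len_b)
    qnames <- names(scan$seqs_a); snames <- names(scan$seqs_b)
    db <- scan$db_b
  } else {
    qi <- cand$bi; si <- cand$ai
    qlen <- unname(scan$len_b); slen <- unname(scan$len_a)
    qnames <- names(scan$seqs_b); snames <- names(scan$seqs_a)
    db <- scan$db_a
  }
  p <- ka_params("blosum62")
  bits <- (p$lambda * scan$score - log(p$K)) / log(2)
  ev <- qlen[qi] * db * 2^(-bits)
  ok_e <- ev <= evalue_max
  by_query <- split(which(ok_e), qi[ok_e])
  n_max <- length(by_query)
  o_q <- character(n_max); o_s <- character(n_max)
  o_raw <- integer(n_max); o_bits <- double(n_max); o_ev <- double(n_max)
  o_id <- double(n_max); o_qc <- double(n_max); o_sc <- double(n_max)
  o_cols <- double(n_max)
  n_out <- 0L
  for (qk in names(by_query)) {
    q <- as.integer(qk)
    sel <- by_query[[qk]]
    sel <- sel[order(-scan$score[sel])]
    chosen <- NULL
    for (sc in unique(scan$score[sel])) {
      grp <- sel[scan$score[sel] == sc]
      passing <- list()
      for (ci in grp) {
        ai <- if (direction == "ab") qi[ci] else si[ci]
        bi <- if (direction == "ab") si[ci] else qi[ci]
        st <- scan_stats(scan, ai, bi)
        idp <- 100 * st$matches / st$aligned_cols
        # query/subject spans swap with direction
        qspan <- if (direction == "ab") st$qend - st$qstart + 1
                 else st$send - st$sstart + 1
        sspan <- if (direction == "ab") st$send - st$sstart + 1
                 else st$qend - st$qstart + 1
        qcov <- 100 * qspan / qlen[q]
        scov <- 100 * sspan / slen[si[ci]]
        if (idp >= identity_min && qcov >= cov_min && scov >= cov_min) {
          passing[[length(passing) + 1]] <-
            list(ci = ci, idp = idp, cols = st$aligned_cols,
                 qcov = qcov, scov = scov)
        }
      }
      if (length(passing) > 0) {
        ord <- order(-map_dbl(passing, "idp"), -map_dbl(passing, "cols"),
                     snames[si[map_int(passing, "ci")]])
        chosen <- passing[[ord[1]]]
        break
      }
    }
    if (!is.null(chosen)) {
      ci <- chosen$ci
      n_out <- n_out + 1L
      o_q[n_out] <- qnames[q]; o_s[n_out] <- snames[si[ci]]
      o_raw[n_out] <- scan$score[ci]; o_bits[n_out] <- bits[ci]
      o_ev[n_out] <- ev[ci]; o_id[n_out] <- chosen$idp
      o_qc[n_out] <- chosen$qcov; o_sc[n_out] <- chosen$scov
      o_cols[n_out] <- chosen$cols
    }
  }
  if (n_out == 0) return(empty)
  k <- seq_len(n_out)
  tibble(query_id = o_q[k], subject_id = o_s[k], raw_score = o_raw[k],
         bit_score = o_bits[k], e_value = o_ev[k], identity_pct = o_id[k],
         query_cov_pct = o_qc[k], subject_cov_pct = o_sc[k],
         aligned_columns = o_cols[k])
}

# queries with >= 1 passing one-way hit (POCP's "conserved protein" count)
scan_conserved <- function(scan, direction = c("ab", "ba"),
                           identity_min = 40, cov_min = 50,
                           evalue_max = 1e-5) {
  direction <- match.arg(direction)
  cand <- scan$cand
  if (nrow(cand) == 0) return(character(0))
  if (direction == "ab") {
    qi <- cand$ai; si <- cand$bi
    qlen <- scan$len_a; slen <- scan$len_b
    qnames <- names(scan$seqs_a); db <- scan$db_b
  } else {
    qi <- cand$bi; si <- cand$ai
    qlen <- scan$len_b; slen <- scan$len_a
    qnames <- names(scan$seqs_b); db <- scan$db_a
  }
  p <- ka_params("blosum62")
  bits <- (p$lambda * scan$score - log(p$K)) / log(2)
  ev <- qlen[qi] * db * 2^(-bits)
  ok_e <- ev <= evalue_max
  conserved <- character(0)
  for (q in unique(qi)) {
    sel <- which(qi == q & ok_e)
    if (length(sel) == 0) next
    sel <- sel[order(-scan$score[sel])]
    for (ci in sel) {
      ai <- if (direction == "ab") qi[ci] else si[ci]
      bi <- if (direction == "ab") si[ci] else qi[ci]
      st <- scan_stats(scan, ai, bi)
      idp <- 100 * st$matches / st$aligned_cols
      qspan <- if (direction == "ab") st$qend - st$qstart + 1
               else st$send - st$sstart + 1
      sspan <- if (direction == "ab") st$send - st$sstart + 1
               else st$qend - st$qstart + 1
      if (idp >= identity_min && 100 * qspan / qlen[q] >= cov_min &&
          100 * sspan / slen[si[ci]] >= cov_min) {
        conserved <- c(conserved, qnames[q])
        break
      }
    }
  }
  conserved
}
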