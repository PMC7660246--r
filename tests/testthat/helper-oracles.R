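# Shared fixtures and independent reference implementations used as
# oracles.  The reference aligner is a plain three-matrix affine dynamic
# program with none of the rolling-array optimisations of the package
# kernel.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

rand_prot <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
rand_nt <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                             collapse = "")

# reference local affine alignment score (gap of length L costs go + L*ge)
naive_sw_score <- function(a, b, sub, go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  NEG <- -1e9
  M <- matrix(0, la + 1, lb + 1)
  E <- matrix(NEG, la + 1, lb + 1)
  F <- matrix(NEG, la + 1, lb + 1)
  best <- 0
  for (i in seq_len(la) + 1) {
    for (j in seq_len(lb) + 1) {
      E[i, j] <- max(M[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(M[i - 1, j] - go - ge, F[i - 1, j] - ge)
      M[i, j] <- max(0, M[i - 1, j - 1] + sub[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# mutate exactly m interior positions of a protein (positions 6..len-5),
# so the full-length alignment stays optimal and identity is exact
mutate_protein <- function(seq, m) {
  x <- strsplit(seq, "")[[1]]
  pos <- round(seq(6, length(x) - 5, length.out = m))
  x[pos] <- vapply(x[pos], function(ch)
    sample(setdiff(AA20, ch), 1), character(1))
  paste(x, collapse = "")
}

# a small two-genome simulation at a given pairwise divergence
sim_pair <- function(seed, d, n_core = 20, ...) {
  simulate_pangenome(simulation_config(
    seed = seed, tree = sprintf("(A:%g,B:%g);", d / 2, d / 2),
    n_core = n_core, gain_rate = 0, loss_rate = 0, dup_prob = 0, ...))
}

# brute-force directed best hits by aligning every pair of proteins
brute_best_hits <- function(pa, pb, identity_min = 50, cov_min = 50,
                            evalue_max = 1e-5) {
  db <- sum(nchar(pb))
  out <- list()
  for (q in names(pa)) {
    best <- NULL
    for (s in names(pb)) {
      h <- local_align_protein(pa[[q]], pb[[s]])
      if (is.null(h)) next
      ev <- estimate_evalue(h$raw_score, nchar(pa[[q]]), db)
      if (ev$e_value > evalue_max) next
      if (h$identity_pct < identity_min) next
      if (h$query_cov_pct < cov_min || h$subject_cov_pct < cov_min) next
      cand <- list(subject = s, score = h$raw_score, id = h$identity_pct,
                   cols = h$aligned_columns)
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$id > best$id) ||
          (cand$score == best$score && cand$id == best$id &&
           cand$cols > best$cols) ||
          (cand$score == best$score && cand$id == best$id &&
           cand$cols == best$cols && cand$subject < best$subject))
        best <- cand
    }
    if (!is.null(best))
      out[[q]] <- tibble::tibble(query_id = q, subject_id = best$subject)
  }
  if (length(out) == 0)
    return(tibble::tibble(query_id = character(0), subject_id = character(0)))
  dplyr::bind_rows(out)
}
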