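# Statistical comparison of similarity matrices: inter/intra splits,
# cross-metric correlation, Welch t-tests.

as_labeling <- function(labeling) {
  if (is.data.frame(labeling)) {
    grp_col <- setdiff(names(labeling), "genome_id")[1]
    setNames(as.character(labeling[[grp_col]]), labeling$genome_id)
  } else if (!is.null(names(labeling))) {
    setNames(as.character(labeling), names(labeling))
  } else abort("labeling must be a named vector or a tibble with genome_id")
}

#' Split matrix values into intra- and inter-group pairs
#'
#' Upper-triangle entries are partitioned by whether the two genomes share
#' a group label; missing values are dropped.
#'
#' @param mat Labelled symmetric matrix (e.g. a [similarity_matrix()]).
#' @param labeling Named vector `genome_id -> group`, or a tibble with a
#'   `genome_id` column and one label column.
#' @return Tibble `(genome_a, genome_b, value, pair_type)` with `pair_type`
#'   `"intra"` or `"inter"`.
#' @export
split_inter_intra <- function(mat, labeling) {
  lab <- as_labeling(labeling)
  ids <- rownames(mat)
  if (!all(ids %in% names(lab)))
    abort(sprintf("genome '%s' has no group label",
                  setdiff(ids, names(lab))[1]))
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  out <- tibble(genome_a = ids[ut[, 1]], genome_b = ids[ut[, 2]],
                value = mat[ut],
                pair_type = ifelse(lab[ids[ut[, 1]]] == lab[ids[ut[, 2]]],
                                   "intra", "inter"))
  out |> filter(!is.na(.data$value))
}

#' Correlation between two similarity matrices
#'
#' Pearson (default) product-moment correlation over the shared
#' upper-triangle entries of two matrices on the same genome set; pairs
#' missing in either matrix are excluded.
#'
#' @param matrix_x,matrix_y Labelled symmetric matrices.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation coefficient.
#' @export
metric_correlation <- function(matrix_x, matrix_y,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ids <- intersect(rownames(matrix_x), rownames(matrix_y))
  if (length(ids) < 3) abort("need at least 3 shared genomes")
  mx <- matrix_x[ids, ids]; my <- matrix_y[ids, ids]
  ut <- upper.tri(mx)
  x <- mx[ut]; y <- my[ut]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) abort("need at least 3 shared non-missing pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    abort("zero variance; correlation undefined")
  cor(x[ok], y[ok], method = method)
}

#' Cross-correlation report over several matrices
#'
#' @param mats Named list of labelled symmetric matrices.
#' @inheritParams metric_correlation
#' @return Tibble `(metric_x, metric_y, r_cc, n)` for every unordered pair.
#' @export
correlation_report <- function(mats, method = "pearson") {
  stopifnot(length(mats) >= 2, !is.null(names(mats)))
  pairs <- combn(names(mats), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    mx <- mats[[pairs[1, k]]]; my <- mats[[pairs[2, k]]]
    ids <- intersect(rownames(mx), rownames(my))
    ut <- upper.tri(mx[ids, ids])
    n <- sum(!is.na(mx[ids, ids][ut]) & !is.na(my[ids, ids][ut]))
    tibble(metric_x = pairs[1, k], metric_y = pairs[2, k],
           r_cc = metric_correlation(mx, my, method = method), n = n)
  })
}

#' Welch two-sample t-test of intra vs inter values
#'
#' Two-sided Welch (unequal-variance) t-test.  Degenerate inputs are
#' handled explicitly: identical constant samples give t = 0, p = 1;
#' fully separated constant samples give infinite t and p = 0.  P-values
#' below 2.2e-16 carry the conventional text label `"<2.2e-16"`.
#'
#' @param intra,inter Numeric samples (each n >= 2).
#' @return Tibble `(t_statistic, p_value, p_label)`.
#' @export
inter_intra_ttest <- function(intra, inter) {
  stopifnot(length(intra) >= 2, length(inter) >= 2)
  res <- tryCatch(t.test(intra, inter), error = function(e) NULL)
  if (is.null(res)) {  # constant data
    if (isTRUE(all.equal(mean(intra), mean(inter)))) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(intra) - mean(inter)) * Inf; p <- 0
    }
  } else {
    t_stat <- unname(res$statistic); p <- res$p.value
  }
  tibble(t_statistic = t_stat, p_value = p,
         p_label = if (p < 2.2e-16) "<2.2e-16" else format(p, digits = 4))
}
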