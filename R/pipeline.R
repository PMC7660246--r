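# End-to-end orchestration: manifest -> clusters -> matrices -> tree ->
# comparisons -> genus partition, with every stage artifact written as
# plain TSV / FASTA / Newick.

aai_from_scan <- function(scan, cov_min = 50, evalue_max = 1e-5) {
  e <- rbh_from_scan(scan, identity_min = 0, cov_min = cov_min,
                     evalue_max = evalue_max)
  if (nrow(e) == 0) NA_real_ else mean(e$identity_pct)
}

pocp_from_scan <- function(scan, identity_min = 40, cov_min = 50,
                           evalue_max = 1e-5) {
  c1 <- length(scan_conserved(scan, "ab", identity_min, cov_min, evalue_max))
  c2 <- length(scan_conserved(scan, "ba", identity_min, cov_min, evalue_max))
  100 * (c1 + c2) / (length(scan$seqs_a) + length(scan$seqs_b))
}

#' Run the full demarcation pipeline
#'
#' Orthologous clustering, pan-genome accounting, AAI / POCP (and ANI when
#' assemblies are present) matrices, single-copy core-genome tree with
#' patristic distances, metric correlations and inter/intra statistics,
#' and the genus partition.  All stage outputs are written to `out_dir` as
#' diffable text files; reruns on the same inputs are byte-identical
#' (the log carries the only timestamp).
#'
#' @param genomes Named list of [genome_record()] objects, or a manifest
#'   path handed to [load_genomes()].
#' @param out_dir Output directory (created if needed).
#' @param oc_identity,oc_cov,oc_evalue Orthologous-cluster filter triple.
#' @param pocp_identity POCP conserved-protein identity threshold.
#' @param config [demarcation_config()] thresholds.
#' @param fragment_len ANI fragment length (bp).
#' @param n_clades Number of major clades for the inter/intra split.
#' @param max_gap_fraction Alignment-trimming threshold.
#' @return Invisibly, a list with every intermediate result.
#' @export
run_all <- function(genomes, out_dir, oc_identity = 50, oc_cov = 50,
                    oc_evalue = 1e-5, pocp_identity = 40,
                    config = demarcation_config(), fragment_len = 1020,
                    n_clades = 3, max_gap_fraction = 0.2) {
  if (is.character(genomes)) genomes <- load_genomes(genomes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("genustax run %s", format(Sys.time())),
                 sprintf("OC filter: identity>=%g cov>=%g evalue<=%g",
                         oc_identity, oc_cov, oc_evalue),
                 sprintf("POCP filter: identity>=%g cov>=%g evalue<=%g",
                         pocp_identity, oc_cov, oc_evalue),
                 sprintf("demarcation: aai_min=%g dist_max=%g pass_fraction=%g",
                         config$aai_min, config$dist_max,
                         config$aai_pass_fraction))
  ids <- map_chr(genomes, "genome_id")
  names(genomes) <- ids
  outgroup <- ids[map_dbl(genomes, ~ as.numeric(.x$is_outgroup)) == 1]
  outgroup <- if (length(outgroup) >= 1) outgroup[1] else NULL
  ingroup <- setdiff(ids, outgroup)
  if (length(ingroup) < 2)
    abort("stage pairwise: need at least 2 non-outgroup genomes")

  # one scan per unordered genome pair, reused by clustering, AAI and POCP
  scans <- all_pair_scans(genomes)
  edges <- purrr::map_dfr(scans, function(s) {
    e <- rbh_from_scan(s$scan, oc_identity, oc_cov, oc_evalue)
    if (nrow(e) == 0) return(NULL)
    tibble(genome_a = s$a, protein_a = e$protein_a,
           genome_b = s$b, protein_b = e$protein_b)
  })
  inventory <- purrr::map_dfr(genomes, function(g)
    tibble(genome_id = g$genome_id, protein_id = names(g$proteome)))
  clusters <- build_clusters(edges, inventory)
  summary <- classify_clusters(clusters, ids, outgroup = outgroup)
  write_cluster_table(clusters, summary, ids, file.path(out_dir, "clusters.tsv"))
  readr::write_tsv(summary$per_genome,
                   file.path(out_dir, "pangenome_summary.tsv"))

  # similarity matrices over the ingroup
  fill_matrix <- function(fun) {
    m <- matrix(NA_real_, length(ingroup), length(ingroup),
                dimnames = list(ingroup, ingroup))
    diag(m) <- 100
    for (s in scans) {
      if (s$a %in% ingroup && s$b %in% ingroup) {
        v <- fun(s$scan)
        m[s$a, s$b] <- v; m[s$b, s$a] <- v
      }
    }
    m
  }
  aai <- similarity_matrix(fill_matrix(function(sc)
    aai_from_scan(sc, oc_cov, oc_evalue)), "AAI")
  pocp <- similarity_matrix(fill_matrix(function(sc)
    pocp_from_scan(sc, pocp_identity, oc_cov, oc_evalue)), "POCP")
  write_matrix_tsv(aai, file.path(out_dir, "aai.tsv"))
  write_matrix_tsv(pocp, file.path(out_dir, "pocp.tsv"))
  mats <- list(AAI = aai, POCP = pocp)
  if (all(map_dbl(genomes[ingroup], ~ length(.x$contigs) %||% 0) > 0)) {
    ani <- metric_matrix(genomes[ingroup], "ani", fragment_len = fragment_len)
    write_matrix_tsv(ani, file.path(out_dir, "ani.tsv"))
    mats$ANI <- ani
  }

  # single-copy core tree over all genomes (outgroup included for rooting)
  sc_ids <- single_copy_clusters(clusters, ids)
  if (length(sc_ids) == 0)
    abort("stage tree: no single-copy clusters span all genomes")
  seq_of <- function(cid) {
    rows <- clusters |> filter(.data$cluster_id == cid)
    setNames(map_chr(seq_len(nrow(rows)), function(i)
      genomes[[rows$genome_id[i]]]$proteome[[rows$protein_id[i]]]),
      rows$genome_id)
  }
  alns <- list()
  for (cid in sc_ids) {
    aln <- progressive_msa(seq_of(cid))
    tr <- tryCatch(trim_alignment(aln, max_gap_fraction),
                   error = function(e) NULL)
    if (!is.null(tr)) alns[[cid]] <- tr
  }
  if (length(alns) == 0)
    abort("stage tree: every single-copy alignment trimmed away")
  log_lines <- c(log_lines,
                 sprintf("tree: %d single-copy clusters, %d after trimming",
                         length(sc_ids), length(alns)))
  sm <- concatenate_alignments(alns, ids = sort(ids))
  write_fasta(sm$alignment, file.path(out_dir, "supermatrix.faa"))
  readr::write_tsv(sm$partitions, file.path(out_dir, "partitions.tsv"))
  d <- distance_matrix(sm)
  tree <- nj_tree(d, outgroup = outgroup)
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  tree_in <- if (!is.null(outgroup)) ape::drop.tip(tree, outgroup) else tree
  evodist <- patristic_distances(tree_in)
  write_matrix_tsv(evodist, file.path(out_dir, "evodist.tsv"))
  mats$EVODIST <- evodist

  correlations <- correlation_report(mats)
  readr::write_tsv(correlations, file.path(out_dir, "correlations.tsv"))

  clades <- major_clades(tree_in, n_top = min(n_clades, length(ingroup)))
  inter_intra <- purrr::map_dfr(names(mats), function(mn)
    split_inter_intra(mats[[mn]][clades$genome_id, clades$genome_id],
                      clades) |>
      mutate(metric = mn, .before = 1))
  readr::write_tsv(inter_intra, file.path(out_dir, "inter_intra.tsv"))
  ttests <- inter_intra |>
    group_by(.data$metric) |>
    group_modify(function(.x, .y) {
      intra <- .x$value[.x$pair_type == "intra"]
      inter <- .x$value[.x$pair_type == "inter"]
      if (length(intra) < 2 || length(inter) < 2) {
        return(tibble(t_statistic = NA_real_, p_value = NA_real_,
                      p_label = NA_character_))
      }
      inter_intra_ttest(intra, inter)
    }) |>
    ungroup()

  partition <- demarcate(tree_in, mats$AAI, evodist, config)
  readr::write_tsv(partition$membership, file.path(out_dir, "genera.tsv"))
  readr::write_tsv(partition$diagnostics,
                   file.path(out_dir, "genus_diagnostics.tsv"))
  log_lines <- c(log_lines,
                 sprintf("demarcation: %d genera over %d ingroup genomes",
                         nrow(partition$diagnostics), length(ingroup)))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(genomes = genomes, clusters = clusters, summary = summary,
                 matrices = mats, supermatrix = sm, tree = tree,
                 tree_ingroup = tree_in, evodist = evodist,
                 correlations = correlations, clades = clades,
                 inter_intra = inter_intra, ttests = ttests,
                 partition = partition, out_dir = out_dir))
}

# cluster table: one row per cluster, one column per genome with
# comma-joined protein ids ("-" if absent)
write_cluster_table <- function(clusters, summary, ids, path) {
  wide <- clusters |>
    group_by(.data$cluster_id, .data$genome_id) |>
    summarise(proteins = paste(sort(.data$protein_id), collapse = ","),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "genome_id", values_from = "proteins",
                       values_fill = "-")
  for (id in setdiff(ids, names(wide))) wide[[id]] <- "-"
  out <- summary$clusters |>
    left_join(wide, by = "cluster_id") |>
    arrange(.data$cluster_id)
  readr::write_tsv(out, path)
  invisible(path)
}
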