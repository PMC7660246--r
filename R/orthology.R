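# Reciprocal-best-hit orthologous clustering across genomes.

#' Directed best hits between two proteomes
#'
#' For every query protein the single highest-bit-score subject whose local
#' alignment passes the filter triple (identity, both coverages, E-value) is
#' reported; queries with no passing hit are absent.  The defaults are the
#' orthology filter used throughout the pipeline: identity >= 50 %, both
#' coverages >= 50 %, E <= 1e-5.
#'
#' @param a,b Query and subject genomes ([genome_record()] or named
#'   character vectors of proteins).
#' @param identity_min,cov_min Percent thresholds (inclusive).
#' @param evalue_max E-value ceiling (inclusive).
#' @return Tibble with one row per query that has a passing hit.
#' @export
best_hits <- function(a, b, identity_min = 50, cov_min = 50,
                      evalue_max = 1e-5) {
  pa <- as_proteome(a); pb <- as_proteome(b)
  if (length(pa) == 0 || length(pb) == 0) abort("proteomes must be non-empty")
  scan <- pair_scan(pa, pb)
  scan_best_hits(scan, "ab", identity_min, cov_min, evalue_max)
}

#' Reciprocal best-hit pairs
#'
#' @param best_ab,best_ba Directed best-hit tables from [best_hits()] for
#'   the two directions of the same proteome pair.
#' @return Tibble of reciprocal pairs `(protein_a, protein_b)` with the
#'   a-direction alignment statistics.
#' @export
rbh_edges <- function(best_ab, best_ba) {
  if (nrow(best_ab) == 0 || nrow(best_ba) == 0) {
    return(tibble(protein_a = character(0), protein_b = character(0),
                  identity_pct = double(0)))
  }
  back <- setNames(best_ba$subject_id, best_ba$query_id)
  keep <- !is.na(back[best_ab$subject_id]) &
    back[best_ab$subject_id] == best_ab$query_id
  kept <- best_ab[which(keep), ]
  tibble(protein_a = kept$query_id, protein_b = kept$subject_id,
         identity_pct = if ("identity_pct" %in% names(kept))
           kept$identity_pct else rep(NA_real_, nrow(kept)))
}

# all-pairs scans with RBH edge tables; reused by clustering and AAI
all_pair_scans <- function(genomes) {
  ids <- map_chr(genomes, "genome_id")
  names(genomes) <- ids
  pairs <- if (length(ids) >= 2) combn(sort(ids), 2) else
    matrix(character(0), 2, 0)
  scans <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    scans[[k]] <- list(
      a = pairs[1, k], b = pairs[2, k],
      scan = pair_scan(as_proteome(genomes[[pairs[1, k]]]),
                       as_proteome(genomes[[pairs[2, k]]])))
  }
  scans
}

rbh_from_scan <- function(scan, identity_min = 50, cov_min = 50,
                          evalue_max = 1e-5) {
  rbh_edges(scan_best_hits(scan, "ab", identity_min, cov_min, evalue_max),
            scan_best_hits(scan, "ba", identity_min, cov_min, evalue_max))
}

#' Orthologous clusters from reciprocal best hits
#'
#' Clusters are the connected components of the union graph of all pairwise
#' reciprocal-best-hit edges; every protein of every genome lands in
#' exactly one cluster (proteins without edges become singletons).  Cluster
#' ids are assigned deterministically, ordered by each cluster's smallest
#' (genome, protein) member.
#'
#' @param genomes List of [genome_record()] objects.
#' @inheritParams best_hits
#' @return Tibble `(cluster_id, genome_id, protein_id)`, one row per
#'   protein.
#' @export
orthologous_clusters <- function(genomes, identity_min = 50, cov_min = 50,
                                 evalue_max = 1e-5) {
  scans <- all_pair_scans(genomes)
  edges <- purrr::map_dfr(scans, function(s) {
    e <- rbh_from_scan(s$scan, identity_min, cov_min, evalue_max)
    if (nrow(e) == 0) return(NULL)
    tibble(genome_a = s$a, protein_a = e$protein_a,
           genome_b = s$b, protein_b = e$protein_b)
  })
  inventory <- purrr::map_dfr(genomes, function(g)
    tibble(genome_id = g$genome_id, protein_id = names(g$proteome)))
  build_clusters(edges, inventory)
}

#' Build clusters from an edge table
#'
#' Lower-level entry point: connected components of an explicit undirected
#' RBH edge set over a fixed protein inventory.
#'
#' @param edges Tibble `(genome_a, protein_a, genome_b, protein_b)`; may
#'   have zero rows.
#' @param inventory Tibble `(genome_id, protein_id)` listing every protein.
#' @return Tibble `(cluster_id, genome_id, protein_id)`.
#' @export
build_clusters <- function(edges, inventory) {
  stopifnot(all(c("genome_id", "protein_id") %in% names(inventory)))
  key <- function(g, p) paste(g, p, sep = "\r")
  nodes <- key(inventory$genome_id, inventory$protein_id)
  if (anyDuplicated(nodes)) abort("duplicate (genome, protein) in inventory")
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (!is.null(edges) && nrow(edges) > 0) {
    ek <- rbind(key(edges$genome_a, edges$protein_a),
                key(edges$genome_b, edges$protein_b))
    if (!all(ek %in% nodes)) abort("edge references a protein absent from inventory")
    g <- igraph::add_edges(g, match(as.vector(ek), nodes))
  }
  comp <- igraph::components(g)$membership
  # deterministic ids ordered by each component's lexicographically
  # smallest member (igraph numbers components 1..n)
  smallest <- vapply(split(nodes, comp), min, character(1))
  relabel <- integer(length(smallest))
  relabel[order(smallest)] <- seq_along(smallest)
  cid <- relabel[comp]
  tibble(cluster_id = sprintf("OC%06d", cid),
         genome_id = inventory$genome_id,
         protein_id = inventory$protein_id) |>
    arrange(.data$cluster_id, .data$genome_id, .data$protein_id)
}

#' Classify clusters into core / accessory / unique
#'
#' Core clusters have at least one member in every genome of the analysis
#' set; unique clusters have members from exactly one genome (including
#' orphan singletons); the rest are accessory.  Single-copy core clusters
#' have exactly one member per genome.  An outgroup genome, if named, is
#' excluded from the accounting.
#'
#' @param clusters Cluster membership tibble from [orthologous_clusters()].
#' @param genome_ids Genomes making up the analysis set.
#' @param outgroup Optional genome id to exclude.
#' @return A `pan_genome_summary`: list with `clusters` (per-cluster class
#'   and single-copy flag), `per_genome` (per-genome core/accessory/unique
#'   cluster counts) and `totals`.
#' @export
classify_clusters <- function(clusters, genome_ids, outgroup = NULL) {
  genome_ids <- setdiff(genome_ids, outgroup)
  if (length(genome_ids) == 0) abort("empty analysis set")
  memb <- clusters |> filter(.data$genome_id %in% genome_ids)
  missing <- setdiff(genome_ids, unique(memb$genome_id))
  if (length(missing) > 0)
    abort(sprintf("genome '%s' is absent from every cluster", missing[1]))
  per_cluster <- memb |>
    group_by(.data$cluster_id) |>
    summarise(n_genomes = dplyr::n_distinct(.data$genome_id),
              n_proteins = dplyr::n(),
              max_copy = max(table(.data$genome_id)),
              .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$n_genomes == length(genome_ids) ~ "core",
      .data$n_genomes == 1 ~ "unique",
      TRUE ~ "accessory"),
      single_copy_core = .data$class == "core" & .data$max_copy == 1 &
        .data$n_proteins == .data$n_genomes)
  per_genome <- memb |>
    distinct(.data$cluster_id, .data$genome_id) |>
    left_join(per_cluster |> select("cluster_id", "class"), by = "cluster_id") |>
    count(.data$genome_id, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("core", "accessory", "unique"))
    if (!cl %in% names(per_genome)) per_genome[[cl]] <- 0L
  per_genome <- per_genome |>
    select("genome_id", core_count = "core", accessory_count = "accessory",
           unique_count = "unique")
  totals <- list(
    total_oc_count = nrow(per_cluster),
    core_oc_count = sum(per_cluster$class == "core"),
    single_copy_core_count = sum(per_cluster$single_copy_core))
  structure(list(clusters = per_cluster |>
                   select("cluster_id", "class", "single_copy_core"),
                 per_genome = per_genome, totals = totals,
                 genome_ids = genome_ids),
            class = "pan_genome_summary")
}

#' @export
print.pan_genome_summary <- function(x, ...) {
  cat(sprintf(paste0("<pan_genome_summary> %d genomes: %d clusters ",
                     "(%d core, %d single-copy core)\n"),
              length(x$genome_ids), x$totals$total_oc_count,
              x$totals$core_oc_count, x$totals$single_copy_core_count))
  invisible(x)
}

#' Single-copy clusters spanning a genome set
#'
#' Returns ids of clusters with exactly one member in every genome of
#' `genome_ids` — the input to the core-genome phylogeny.
#'
#' @inheritParams classify_clusters
#' @export
single_copy_clusters <- function(clusters, genome_ids) {
  clusters |>
    filter(.data$genome_id %in% genome_ids) |>
    group_by(.data$cluster_id) |>
    summarise(ok = dplyr::n() == length(genome_ids) &&
                dplyr::n_distinct(.data$genome_id) == length(genome_ids),
              .groups = "drop") |>
    filter(.data$ok) |>
    pull("cluster_id")
}
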