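# Threshold-plus-monophyly genus demarcation on the core-genome tree.

#' Demarcation thresholds
#'
#' The proposed genus boundaries: AAI 70 % and evolutionary (patristic)
#' distance 0.4 substitutions/site.  The AAI criterion is a pass fraction
#' rather than a strict minimum: a clade qualifies when at least
#' `aai_pass_fraction` of its non-missing pairwise AAI values reach
#' `aai_min`, which tolerates isolated low-AAI pairs inside an otherwise
#' coherent genus.  The distance criterion is a strict maximum over all
#' intra-clade pairs.
#'
#' @param aai_min Minimum AAI, percent (0 < aai_min < 100).
#' @param dist_max Maximum pairwise patristic distance, substitutions/site.
#' @param aai_pass_fraction Required fraction of pairs with
#'   AAI >= `aai_min` (in (0.5, 1]).
#' @return A `demarcation_config` list.
#' @export
demarcation_config <- function(aai_min = 70, dist_max = 0.4,
                               aai_pass_fraction = 0.95) {
  stopifnot(aai_min > 0, aai_min < 100, dist_max > 0,
            aai_pass_fraction > 0.5, aai_pass_fraction <= 1)
  structure(list(aai_min = aai_min, dist_max = dist_max,
                 aai_pass_fraction = aai_pass_fraction),
            class = "demarcation_config")
}

# children of a node in an ape tree
tree_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

tree_root <- function(tree) {
  setdiff(tree$edge[, 1], tree$edge[, 2])[1]
}

# leaf labels under a node
node_leaves <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  desc <- phangorn::Descendants(tree, node, type = "tips")[[1]]
  tree$tip.label[desc]
}

clade_passes <- function(leaves, aai, evodist, config) {
  if (length(leaves) == 1) return(TRUE)
  dsub <- evodist[leaves, leaves]
  if (max(dsub[upper.tri(dsub)]) > config$dist_max) return(FALSE)
  asub <- aai[leaves, leaves][upper.tri(aai[leaves, leaves])]
  asub <- asub[!is.na(asub)]
  frac <- if (length(asub) == 0) 1 else mean(asub >= config$aai_min)
  frac >= config$aai_pass_fraction
}

#' Partition genomes into genera
#'
#' Pre-order traversal from the root of a rooted tree: each visited clade
#' is emitted as a genus when all its pairwise patristic distances are at
#' most `dist_max` and at least `aai_pass_fraction` of its non-missing
#' pairwise AAI values reach `aai_min`; otherwise the traversal descends
#' into the children.  Leaves always qualify, so singleton genera are
#' possible.  Every emitted genus is by construction a monophyletic clade,
#' and the selection is maximal (coarsest-first).
#'
#' @param tree Rooted `ape::phylo` over the ingroup genomes (outgroup
#'   already removed).
#' @param aai AAI [similarity_matrix()] (missing entries allowed).
#' @param evodist Patristic-distance [similarity_matrix()].
#' @param config A [demarcation_config()].
#' @return A `genus_partition`: list with `membership`
#'   (tibble `genome_id`, `group_id`), `diagnostics` (per-group summary),
#'   the config and the tree.
#' @export
demarcate <- function(tree, aai, evodist, config = demarcation_config()) {
  leaves_all <- tree$tip.label
  for (m in list(aai, evodist)) {
    absent <- setdiff(leaves_all, rownames(m))
    if (length(absent) > 0)
      abort(sprintf("genome '%s' is missing from a similarity matrix",
                    absent[1]))
  }
  groups <- list()
  visit <- function(node) {
    leaves <- node_leaves(tree, node)
    if (clade_passes(leaves, aai, evodist, config)) {
      groups[[length(groups) + 1]] <<- leaves
    } else {
      for (ch in tree_children(tree, node)) visit(ch)
    }
  }
  visit(tree_root(tree))
  membership <- purrr::map_dfr(seq_along(groups), function(i)
    tibble(genome_id = groups[[i]],
           group_id = sprintf("genus_%02d", i)))
  diagnostics <- purrr::map_dfr(seq_along(groups), function(i) {
    lv <- groups[[i]]
    if (length(lv) == 1) {
      return(tibble(group_id = sprintf("genus_%02d", i), n = 1L,
                    min_aai = NA_real_, median_aai = NA_real_,
                    max_evodist = NA_real_, aai_pass_fraction = NA_real_))
    }
    asub <- aai[lv, lv][upper.tri(aai[lv, lv])]
    asub <- asub[!is.na(asub)]
    dsub <- evodist[lv, lv][upper.tri(evodist[lv, lv])]
    tibble(group_id = sprintf("genus_%02d", i), n = length(lv),
           min_aai = if (length(asub)) min(asub) else NA_real_,
           median_aai = if (length(asub)) median(asub) else NA_real_,
           max_evodist = max(dsub),
           aai_pass_fraction = if (length(asub))
             mean(asub >= config$aai_min) else NA_real_)
  })
  structure(list(membership = membership, diagnostics = diagnostics,
                 config = config, tree = tree),
            class = "genus_partition")
}

#' @export
print.genus_partition <- function(x, ...) {
  cat(sprintf("<genus_partition> %d genomes in %d genera\n",
              nrow(x$membership), nrow(x$diagnostics)))
  print(x$diagnostics, ...)
  invisible(x)
}

#' Major clades of a rooted tree
#'
#' Splits the rooted tree into its `n_top` deepest disjoint clades by
#' repeatedly replacing the largest remaining clade with its root's
#' children until `n_top` groups exist (ties break on the smaller node
#' number, so the result is deterministic).
#'
#' @param tree Rooted `ape::phylo` (outgroup removed).
#' @param n_top Number of clades to produce.
#' @return Tibble `(genome_id, clade)` with clades labelled `clade_1` ...
#'   in descending clade size.
#' @export
major_clades <- function(tree, n_top = 3) {
  ntip <- ape::Ntip(tree)
  if (n_top > ntip) abort("n_top exceeds the number of leaves")
  nodes <- tree_root(tree)
  repeat {
    sizes <- map_int(nodes, ~ length(node_leaves(tree, .x)))
    if (length(nodes) >= n_top) break
    expandable <- nodes[sizes > 1]
    if (length(expandable) == 0) break
    sizes_exp <- sizes[sizes > 1]
    pick <- expandable[order(-sizes_exp, expandable)][1]
    nodes <- c(setdiff(nodes, pick), tree_children(tree, pick))
  }
  sizes <- map_int(nodes, ~ length(node_leaves(tree, .x)))
  nodes <- nodes[order(-sizes, nodes)]
  purrr::map_dfr(seq_along(nodes), function(i)
    tibble(genome_id = node_leaves(tree, nodes[i]),
           clade = sprintf("clade_%d", i)))
}

#' Per-group diagnostics for a partition
#'
#' Intra-group and corresponding inter-group summary statistics per metric
#' for each group of a partition; singleton groups report `NA` intra
#' statistics.
#'
#' @param partition A `genus_partition` (or membership tibble).
#' @param aai,evodist Similarity matrices.
#' @param ani Optional ANI matrix.
#' @return Tibble with one row per group x metric.
#' @export
partition_report <- function(partition, aai, evodist, ani = NULL) {
  memb <- if (inherits(partition, "genus_partition"))
    partition$membership else partition
  lab <- setNames(memb$group_id, memb$genome_id)
  mats <- list(AAI = aai, EVODIST = evodist)
  if (!is.null(ani)) mats$ANI <- ani
  purrr::map_dfr(names(mats), function(mn) {
    m <- mats[[mn]]
    long <- split_inter_intra(m[names(lab), names(lab)], lab)
    purrr::map_dfr(unique(memb$group_id), function(g) {
      members <- memb$genome_id[memb$group_id == g]
      intra <- long |>
        filter(.data$pair_type == "intra",
               .data$genome_a %in% members) |> pull("value")
      inter <- long |>
        filter(.data$pair_type == "inter",
               .data$genome_a %in% members |
                 .data$genome_b %in% members) |> pull("value")
      tibble(group_id = g, n = length(members), metric = mn,
             intra_min = if (length(intra)) min(intra) else NA_real_,
             intra_median = if (length(intra)) median(intra) else NA_real_,
             intra_max = if (length(intra)) max(intra) else NA_real_,
             inter_min = if (length(inter)) min(inter) else NA_real_,
             inter_median = if (length(inter)) median(inter) else NA_real_,
             inter_max = if (length(inter)) max(inter) else NA_real_)
    })
  })
}
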