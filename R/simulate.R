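# Pan-genome simulator with known truth: planted tree, genus labels,
# orthologous families and per-pair divergences.

#' Simulation settings
#'
#' Defaults emulate a small family-level study: 3 genera of 4 genomes with
#' within-genus pairwise divergence 0.25 substitutions/site (leaf depth
#' 0.125) and between-genus divergence 0.75 (leaf depth 0.375), a shared
#' single-copy core of 100 ancestral genes of 150-300 residues, plus
#' moderate gene gain, loss and duplication generating accessory and
#' unique gene content.
#'
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @param tree Optional explicit tree (`ape::phylo` or Newick string) to
#'   evolve along instead of the planted-genera topology.
#' @param n_genera,genomes_per_genus Planted topology dimensions.
#' @param intra_depth,inter_depth Leaf depth to the genus ancestor and to
#'   the root, substitutions/site (`intra_depth < inter_depth`).
#' @param n_core Number of ancestral single-copy genes.
#' @param gene_len_range Gene length range, residues.
#' @param gain_rate,loss_rate Gene gain/loss events per gene per unit
#'   branch length.
#' @param dup_prob Per-gene per-branch duplication probability.
#' @param aa_subst_rate Amino-acid substitutions/site per unit branch
#'   length (1 = branch lengths are in substitutions/site).
#' @param make_nucleotide Also emit codon-backed nucleotide genes packed
#'   into contigs (with synonymous wobble; half of each genome's contigs
#'   are reverse-complemented on output).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed, tree = NULL, n_genera = 3,
                              genomes_per_genus = 4, intra_depth = 0.125,
                              inter_depth = 0.375, n_core = 100,
                              gene_len_range = c(150, 300),
                              gain_rate = 0.2, loss_rate = 0.1,
                              dup_prob = 0.02, aa_subst_rate = 1,
                              make_nucleotide = FALSE) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(gain_rate >= 0, loss_rate >= 0, dup_prob >= 0,
            aa_subst_rate >= 0, n_core >= 1,
            length(gene_len_range) == 2,
            gene_len_range[1] <= gene_len_range[2])
  if (is.null(tree) && intra_depth >= inter_depth)
    abort("intra_depth must be smaller than inter_depth")
  structure(list(seed = as.integer(seed), tree = tree, n_genera = n_genera,
                 genomes_per_genus = genomes_per_genus,
                 intra_depth = intra_depth, inter_depth = inter_depth,
                 n_core = n_core, gene_len_range = gene_len_range,
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 dup_prob = dup_prob, aa_subst_rate = aa_subst_rate,
                 make_nucleotide = make_nucleotide),
            class = "simulation_config")
}

planted_tree <- function(cfg) {
  bl_leaf <- cfg$intra_depth
  bl_genus <- cfg$inter_depth - cfg$intra_depth
  genus <- vapply(seq_len(cfg$n_genera), function(g) {
    tips <- sprintf("G%dS%d:%g", g, seq_len(cfg$genomes_per_genus), bl_leaf)
    sprintf("(%s):%g", paste(tips, collapse = ","), bl_genus)
  }, character(1))
  ape::read.tree(text = sprintf("(%s);", paste(genus, collapse = ",")))
}

.codon_tables <- function() {
  if (is.null(the$codons)) {
    gc <- Biostrings::GENETIC_CODE
    gc <- gc[gc != "*"]
    the$codons <- split(names(gc), unname(gc))
  }
  the$codons
}

random_gene <- function(len, family, make_nt) {
  aa <- sample(AA_STANDARD, len, replace = TRUE)
  codons <- if (make_nt) {
    tab <- .codon_tables()
    vapply(aa, function(r) {
      cs <- tab[[r]]
      cs[sample.int(length(cs), 1)]
    }, character(1), USE.NAMES = FALSE)
  } else NULL
  list(family = family, aa = aa, codons = codons)
}

evolve_branch <- function(genes, bl, cfg, state) {
  if (bl > 0 && cfg$loss_rate > 0) {
    keep <- runif(length(genes)) < exp(-cfg$loss_rate * bl)
    genes <- genes[keep]
  }
  tab <- if (cfg$make_nucleotide) .codon_tables() else NULL
  if (bl > 0) {
    for (i in seq_along(genes)) {
      g <- genes[[i]]
      len <- length(g$aa)
      nsub <- rpois(1, cfg$aa_subst_rate * bl * len)
      if (nsub > 0) {
        pos <- sample.int(len, nsub, replace = TRUE)
        res <- sample(AA_STANDARD, nsub, replace = TRUE)
        g$aa[pos] <- res
        if (!is.null(g$codons)) {
          for (k in seq_len(nsub)) {
            cs <- tab[[res[k]]]
            g$codons[pos[k]] <- cs[sample.int(length(cs), 1)]
          }
        }
      }
      if (!is.null(g$codons)) {  # synonymous wobble
        nsyn <- rpois(1, 0.5 * bl * len)
        if (nsyn > 0) {
          pos <- sample.int(len, nsyn, replace = TRUE)
          for (k in seq_len(nsyn)) {
            cs <- tab[[g$aa[pos[k]]]]
            g$codons[pos[k]] <- cs[sample.int(length(cs), 1)]
          }
        }
      }
      genes[[i]] <- g
    }
    # duplications
    if (cfg$dup_prob > 0 && length(genes) > 0) {
      dup <- which(runif(length(genes)) < cfg$dup_prob)
      for (i in dup) genes[[length(genes) + 1]] <- genes[[i]]
    }
    # gains: novel unrelated genes
    if (cfg$gain_rate > 0 && length(genes) > 0) {
      ngain <- rpois(1, cfg$gain_rate * bl * length(genes))
      for (k in seq_len(ngain)) {
        state$gain_counter <- state$gain_counter + 1L
        len <- sample(seq(cfg$gene_len_range[1], cfg$gene_len_range[2]), 1)
        genes[[length(genes) + 1]] <-
          random_gene(len, sprintf("FG%04d", state$gain_counter),
                      cfg$make_nucleotide)
      }
    }
  }
  genes
}

random_spacer <- function() {
  paste(sample(c("A", "C", "G", "T"), sample(50:200, 1), replace = TRUE),
        collapse = "")
}

#' Simulate a pan-genome with known truth
#'
#' Ancestral genes are drawn i.i.d. from a uniform residue model and
#' evolved down the (planted or supplied) tree: Poisson substitution counts
#' per branch with uniform replacement residues, Poisson gene gain and
#' loss, and per-branch duplications.  The same seed gives byte-identical
#' output.
#'
#' @param config A [simulation_config()].
#' @return List with `genomes` (named list of [genome_record()]) and
#'   `truth` (planted `tree`, `genus_labels`, `orthology` map
#'   protein -> family, `divergence` patristic matrix of the planted tree,
#'   `inventories` per-genome gene counts).
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::local_seed(config$seed)
  tree <- if (is.null(config$tree)) planted_tree(config)
          else if (inherits(config$tree, "phylo")) config$tree
          else ape::read.tree(text = config$tree)
  if (is.null(tree$edge.length))
    abort("simulation tree must have branch lengths")
  state <- new.env(parent = emptyenv())
  state$gain_counter <- 0L
  state$leaves <- list()
  lens <- sample(seq(config$gene_len_range[1], config$gene_len_range[2]),
                 config$n_core, replace = TRUE)
  ancestor <- lapply(seq_len(config$n_core), function(i)
    random_gene(lens[i], sprintf("F%04d", i), config$make_nucleotide))
  root <- tree_root(tree)
  descend <- function(node, genes) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(children) == 0) {
      state$leaves[[tree$tip.label[node]]] <- genes
      return(invisible())
    }
    for (ch in children) {
      bl <- tree$edge.length[which(tree$edge[, 1] == node &
                                     tree$edge[, 2] == ch)]
      descend(ch, evolve_branch(genes, bl, config, state))
    }
  }
  descend(root, ancestor)
  if (any(lengths(state$leaves) == 0))
    abort("simulation produced an empty genome; lower loss_rate")
  orthology <- list()
  genomes <- list()
  for (leaf in tree$tip.label) {
    genes <- state$leaves[[leaf]]
    pids <- sprintf("%s_p%04d", leaf, seq_along(genes))
    prot <- setNames(vapply(genes, function(g)
      paste(g$aa, collapse = ""), character(1)), pids)
    contigs <- NULL
    if (config$make_nucleotide) {
      nts <- vapply(genes, function(g)
        paste(g$codons, collapse = ""), character(1))
      pieces <- as.vector(rbind(vapply(seq_along(nts),
                                       function(i) random_spacer(),
                                       character(1)), nts))
      n_ctg <- sample(2:5, 1)
      grp <- sort(rep_len(seq_len(n_ctg), length(pieces)))
      contigs <- vapply(split(pieces, grp), paste, character(1),
                        collapse = "")
      names(contigs) <- sprintf("%s_ctg%d", leaf, seq_len(n_ctg))
      rc <- seq_along(contigs) %% 2 == 0
      contigs[rc] <- reverse_complement(contigs[rc])
    }
    genomes[[leaf]] <- genome_record(leaf, prot, contigs = contigs)
    orthology[[leaf]] <- tibble(
      genome_id = leaf, protein_id = pids,
      family_id = vapply(genes, function(g) g$family, character(1)))
  }
  genus_labels <- tibble(
    genome_id = tree$tip.label,
    genus = if (is.null(config$tree))
      sub("S\\d+$", "", tree$tip.label) else NA_character_)
  truth <- list(tree = tree, genus_labels = genus_labels,
                orthology = dplyr::bind_rows(orthology),
                divergence = ape::cophenetic.phylo(tree),
                inventories = tibble(
                  genome_id = tree$tip.label,
                  n_proteins = unname(lengths(state$leaves)[tree$tip.label])))
  list(genomes = genomes, truth = truth)
}

#' Expected identity under the uniform replacement model
#'
#' With substitutions at rate d per site and uniform replacement over the
#' alphabet, `E[identity] = 100 (e^-d + (1 - e^-d)/A)` for alphabet size
#' A (20 for proteins, 4 for nucleotides).
#'
#' @param path_divergence Divergence d in substitutions/site (>= 0).
#' @param alphabet_size 20 (protein) or 4 (nucleotide).
#' @return Expected percent identity.
#' @examples
#' expected_identity(0)    # 100
#' expected_identity(1e9)  # ~5
#' @export
expected_identity <- function(path_divergence, alphabet_size = 20) {
  stopifnot(all(path_divergence >= 0))
  e <- exp(-path_divergence)
  100 * (e + (1 - e) / alphabet_size)
}

#' Point-mutate nucleotide sequences
#'
#' Each site is substituted with probability `p` by a uniformly chosen
#' different base — the closed-form companion of [compute_ani()] tests:
#' expected identity is `100 (1 - p)`.  Uses the current RNG state.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param p Per-site substitution probability.
#' @export
mutate_nucleotides <- function(seqs, p) {
  stopifnot(p >= 0, p <= 1)
  vapply(seqs, function(s) {
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(x)) < p & x %in% c("A", "C", "G", "T"))
    if (length(hit) > 0) {
      x[hit] <- vapply(x[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    paste(x, collapse = "")
  }, character(1))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical groupings.  Inputs are matched by name when both are
#' named.
#'
#' @param x,y Label vectors.
#' @export
adjusted_rand_index <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) y <- y[names(x)]
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- b * c_ / n2
  maxidx <- (b + c_) / 2
  if (maxidx == expected) return(1)
  (a - expected) / (maxidx - expected)
}

#' Write a simulation to disk in pipeline layout
#'
#' Emits per-genome FASTA files, the manifest, and truth files (planted
#' tree as Newick, genus labels and orthology as TSV).
#'
#' @param sim Result of [simulate_pangenome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(sim$genomes, function(g) {
    pfile <- paste0(g$genome_id, ".faa")
    write_fasta(g$proteome, file.path(dir, pfile))
    cfile <- ""
    if (!is.null(g$contigs)) {
      cfile <- paste0(g$genome_id, ".fna")
      write_fasta(g$contigs, file.path(dir, cfile))
    }
    tibble(genome_id = g$genome_id, proteome = pfile, contigs = cfile,
           outgroup = as.integer(g$is_outgroup))
  })
  write_manifest(rows, file.path(dir, "manifest.tsv"))
  write_newick(sim$truth$tree, file.path(dir, "truth_tree.nwk"))
  readr::write_tsv(sim$truth$genus_labels, file.path(dir, "truth_genera.tsv"))
  readr::write_tsv(sim$truth$orthology, file.path(dir, "truth_orthology.tsv"))
  invisible(dir)
}
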