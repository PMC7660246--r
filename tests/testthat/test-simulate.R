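test_that("identical seeds reproduce byte-identical pan-genomes", {
  cfg <- simulation_config(seed = 121, n_core = 8, n_genera = 2,
                           genomes_per_genus = 2, make_nucleotide = TRUE)
  s1 <- simulate_pangenome(cfg)
  s2 <- simulate_pangenome(cfg)
  expect_identical(lapply(s1$genomes, function(g) g$proteome),
                   lapply(s2$genomes, function(g) g$proteome))
  expect_identical(lapply(s1$genomes, function(g) g$contigs),
                   lapply(s2$genomes, function(g) g$contigs))
  s3 <- simulate_pangenome(simulation_config(seed = 122, n_core = 8,
                                             n_genera = 2,
                                             genomes_per_genus = 2))
  expect_false(identical(s1$genomes[[1]]$proteome,
                         s3$genomes[[1]]$proteome))
  expect_error(simulation_config(n_core = 5), "seed is mandatory")
})

test_that("null evolution produces identical genomes with planted orthology", {
  sim <- simulate_pangenome(simulation_config(
    seed = 123, n_core = 10, aa_subst_rate = 0, gain_rate = 0,
    loss_rate = 0, dup_prob = 0))
  prots <- lapply(sim$genomes, function(g) unname(g$proteome))
  for (i in 2:length(prots)) expect_identical(prots[[i]], prots[[1]])
  fam <- sim$truth$orthology
  expect_equal(dplyr::n_distinct(fam$family_id), 10)
  expect_true(all(table(fam$family_id) == length(sim$genomes)))
})

test_that("simulation truth is consistent with the emitted records", {
  sim <- simulate_pangenome(simulation_config(
    seed = 125, n_genera = 2, genomes_per_genus = 3, n_core = 12,
    gain_rate = 0.4, loss_rate = 0.2, dup_prob = 0.05))
  orth <- sim$truth$orthology
  # every protein appears exactly once in the truth map
  emitted <- unlist(lapply(sim$genomes, function(g)
    paste(g$genome_id, names(g$proteome))), use.names = FALSE)
  expect_setequal(paste(orth$genome_id, orth$protein_id), emitted)
  expect_equal(anyDuplicated(paste(orth$genome_id, orth$protein_id)), 0)
  # inventory counts match record counts
  counts <- vapply(sim$genomes, function(g) length(g$proteome), integer(1))
  expect_equal(sim$truth$inventories$n_proteins,
               unname(counts[sim$truth$inventories$genome_id]))
})

test_that("expected identity has the right limits and closed form", {
  expect_equal(expected_identity(0), 100)
  expect_equal(expected_identity(1e9), 5)
  expect_equal(expected_identity(1e9, alphabet_size = 4), 25)
  d <- 0.37
  expect_equal(expected_identity(d),
               100 * (exp(-d) + (1 - exp(-d)) / 20))
  expect_error(expected_identity(-1))
})

test_that("contigs are codon-backed translations of the proteome", {
  sim <- simulate_pangenome(simulation_config(
    seed = 127, n_genera = 2, genomes_per_genus = 2, n_core = 6,
    gain_rate = 0, loss_rate = 0, dup_prob = 0, make_nucleotide = TRUE))
  g <- sim$genomes[[1]]
  expect_true(length(g$contigs) >= 2 && length(g$contigs) <= 5)
  tab <- genustax:::.codon_tables()
  codon2aa <- setNames(rep(names(tab), lengths(tab)), unlist(tab))
  translate_frames <- function(ctg) {
    vapply(1:3, function(off) {
      starts <- seq(off, nchar(ctg) - 2, by = 3)
      paste(codon2aa[substring(ctg, starts, starts + 2)], collapse = "")
    }, character(1))
  }
  frames <- unlist(lapply(c(g$contigs,
                            genustax:::reverse_complement(g$contigs)),
                          translate_frames))
  for (p in g$proteome[1:3]) {
    # every emitted protein occurs verbatim in some translation frame
    expect_true(any(vapply(frames, function(f)
      grepl(p, f, fixed = TRUE), logical(1))))
  }
})

test_that("the adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(131)
  for (i in 1:10) {
    x <- sample(letters[1:4], 30, TRUE)
    y <- sample(letters[1:3], 30, TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y))
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
})

test_that("written simulations reload through the manifest reader", {
  dir <- withr::local_tempdir()
  sim <- simulate_pangenome(simulation_config(
    seed = 133, n_genera = 2, genomes_per_genus = 2, n_core = 5,
    make_nucleotide = TRUE))
  write_simulation(sim, dir)
  gl <- load_genomes(file.path(dir, "manifest.tsv"))
  expect_setequal(names(gl), names(sim$genomes))
  expect_equal(gl[[1]]$proteome, sim$genomes[[1]]$proteome)
  expect_equal(gl[[1]]$contigs, sim$genomes[[1]]$contigs)
  tr <- read_newick(file.path(dir, "truth_tree.nwk"))
  expect_setequal(tr$tip.label, names(gl))
})
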