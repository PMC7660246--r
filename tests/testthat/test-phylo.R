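test_that("Kimura protein distance matches direct formula evaluation", {
  expect_equal(protein_distance("MKV", "MKV"), 0)
  r1 <- strrep("A", 100)
  r2 <- paste0(strrep("A", 90), strrep("C", 10))
  expect_equal(protein_distance(r1, r2), -log(1 - 0.1 - 0.2 * 0.01))
  # monotone in p below saturation
  ps <- seq(0.05, 0.8, by = 0.05)
  ds <- -log(1 - ps - 0.2 * ps^2)
  expect_true(all(diff(ds) > 0))
  # saturation cap
  r3 <- paste0(strrep("C", 90), strrep("A", 10))
  expect_warning(dcap <- protein_distance(r1, r3), "capped")
  expect_equal(dcap, 5)
  # gapped columns are excluded; all-gap overlap is an error
  expect_equal(protein_distance("MK-V", "MKAV"), 0)
  expect_error(protein_distance("--", "AA"), "comparable")
})

test_that("neighbor joining recovers additive trees exactly", {
  tr0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  m <- ape::cophenetic.phylo(tr0)
  tr <- nj_tree(m)
  pm <- patristic_distances(tr)
  expect_equal(unclass(pm)[rownames(m), colnames(m)], m, tolerance = 1e-12)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))))
})

test_that("three taxa give the unique unrooted topology", {
  m <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(m)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(unclass(patristic_distances(tr))[rownames(m), colnames(m)],
               m, tolerance = 1e-12)
})

test_that("midpoint rooting of an ultrametric matrix equalises root depths", {
  tr0 <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  m <- ape::cophenetic.phylo(tr0)
  tr <- nj_tree(m)
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(max(depths), min(depths), tolerance = 1e-9)
})

test_that("outgroup rooting places the outgroup sister to the ingroup", {
  tr0 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):3,OG:6);")
  tr <- nj_tree(ape::cophenetic.phylo(tr0), outgroup = "OG")
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.monophyletic(tr, c("A", "B", "C")))
  # rooting preserves the patristic matrix
  expect_equal(unclass(patristic_distances(tr))[c("A", "B", "C", "OG"),
                                                c("A", "B", "C", "OG")],
               ape::cophenetic.phylo(tr0)[c("A", "B", "C", "OG"),
                                          c("A", "B", "C", "OG")],
               tolerance = 1e-9)
  expect_error(nj_tree(ape::cophenetic.phylo(tr0), outgroup = "ZZ"),
               "not a leaf")
})

test_that("patristic distances are path sums with metric properties", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.3);")
  p <- patristic_distances(tr)
  expect_equal(p["A", "B"], 0.3)
  expect_equal(p["A", "C"], 0.45)
  expect_equal(p["B", "C"], 0.55)
  expect_true(all(unclass(p) >= 0))
  ids <- rownames(p)
  for (i in ids) for (j in ids) for (k in ids)
    expect_lte(p[i, j], p[i, k] + p[k, j] + 1e-12)
})

test_that("supermatrix distances correlate with planted divergence", {
  sim <- simulate_pangenome(simulation_config(
    seed = 91, n_genera = 2, genomes_per_genus = 3, intra_depth = 0.1,
    inter_depth = 0.3, n_core = 8, gain_rate = 0, loss_rate = 0,
    dup_prob = 0))
  cl <- orthologous_clusters(sim$genomes)
  ids <- names(sim$genomes)
  sc <- single_copy_clusters(cl, ids)
  alns <- lapply(sc, function(cid) {
    rows <- cl[cl$cluster_id == cid, ]
    seqs <- setNames(vapply(seq_len(nrow(rows)), function(i)
      unname(sim$genomes[[rows$genome_id[i]]]$proteome[rows$protein_id[i]]),
      character(1)), rows$genome_id)
    progressive_msa(seqs)
  })
  names(alns) <- sc
  smx <- concatenate_alignments(alns, ids = sort(ids))
  d <- distance_matrix(smx)
  planted <- sim$truth$divergence[rownames(d), colnames(d)]
  ut <- upper.tri(d)
  expect_gt(cor(d[ut], planted[ut]), 0.95)
})
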