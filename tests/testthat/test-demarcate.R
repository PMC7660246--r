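sym_mat <- function(v, ids, diag_val) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_val
  m
}

test_that("a clade satisfying both thresholds becomes a single genus", {
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);")
  ids <- c("A", "B", "C", "D")
  aai <- sym_mat(rep(90, 6), ids, 100)
  evo <- unclass(patristic_distances(tr))
  p <- demarcate(tr, aai, evo)
  expect_equal(nrow(p$diagnostics), 1)
  expect_equal(sort(p$membership$genome_id), ids)
})

test_that("hand-built matrices split a four-leaf tree into two genera", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.3,(C:0.1,D:0.1):0.3);")
  ids <- c("A", "B", "C", "D")
  aai <- sym_mat(c(85, 60, 60, 60, 60, 85), ids, 100)  # AB and CD high
  evo <- unclass(patristic_distances(tr))               # cross pairs 0.8
  p <- demarcate(tr, aai, evo)
  expect_equal(nrow(p$diagnostics), 2)
  groups <- split(p$membership$genome_id, p$membership$group_id)
  expect_setequal(vapply(groups, paste, character(1), collapse = ""),
                  c("AB", "CD"))
  expect_equal(p$diagnostics$max_evodist, c(0.2, 0.2))
  expect_equal(p$diagnostics$min_aai, c(85, 85))
})

test_that("every emitted genus is the full leaf set of its ancestor node", {
  sim <- simulate_pangenome(simulation_config(seed = 111))
  tr <- sim$truth$tree
  ids <- tr$tip.label
  d <- sim$truth$divergence[ids, ids]
  aai <- expected_identity(d); diag(aai) <- 100
  p <- demarcate(tr, aai, d)
  for (g in unique(p$membership$group_id)) {
    members <- p$membership$genome_id[p$membership$group_id == g]
    if (length(members) == 1) next
    mrca <- ape::getMRCA(tr, members)
    clade <- ape::extract.clade(tr, mrca)$tip.label
    expect_setequal(members, clade)
  }
})

test_that("tightening thresholds only refines the partition", {
  refines <- function(fine, coarse) {
    f <- setNames(fine$membership$group_id, fine$membership$genome_id)
    c_ <- setNames(coarse$membership$group_id, coarse$membership$genome_id)
    all(tapply(c_[names(f)], f, function(x) length(unique(x))) == 1)
  }
  set.seed(113)
  for (rep in 1:5) {
    ntax <- sample(6:10, 1)
    tr <- ape::rtree(ntax, br = function(n) runif(n, 0.02, 0.3))
    ids <- tr$tip.label
    evo <- unclass(patristic_distances(tr))[ids, ids]
    aai <- expected_identity(evo); diag(aai) <- 100
    coarse <- demarcate(tr, aai, evo, demarcation_config(aai_min = 60,
                                                         dist_max = 0.6))
    fine <- demarcate(tr, aai, evo, demarcation_config(aai_min = 75,
                                                       dist_max = 0.3))
    expect_true(refines(fine, coarse))
  }
})

test_that("extreme thresholds collapse or shatter the partition", {
  tr <- ape::read.tree(text = "((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  ids <- c("A", "B", "C", "D")
  aai <- sym_mat(rep(95, 6), ids, 100)
  evo <- unclass(patristic_distances(tr))
  all_one <- demarcate(tr, aai, evo,
                       demarcation_config(aai_pass_fraction = 1))
  expect_equal(nrow(all_one$diagnostics), 1)
  shattered <- demarcate(tr, aai, evo,
                         demarcation_config(dist_max = 1e-9))
  expect_equal(nrow(shattered$diagnostics), 4)
  expect_true(all(shattered$diagnostics$n == 1))
})

test_that("partitions are deterministic and complain about missing genomes", {
  sim <- simulate_pangenome(simulation_config(seed = 115, n_genera = 2,
                                              genomes_per_genus = 3,
                                              n_core = 5))
  tr <- sim$truth$tree
  ids <- tr$tip.label
  evo <- sim$truth$divergence[ids, ids]
  aai <- expected_identity(evo); diag(aai) <- 100
  p1 <- demarcate(tr, aai, evo)
  p2 <- demarcate(tr, aai[rev(ids), rev(ids)], evo)
  expect_equal(p1$membership, p2$membership)
  expect_error(demarcate(tr, aai[ids[-1], ids[-1]], evo), "missing")
})

test_that("the AAI pass fraction tolerates isolated low pairs", {
  # one aberrant low-AAI pair inside an otherwise coherent clade of 7
  tr_text <- sprintf("(%s):0.01;",
                     paste(sprintf("T%d:0.1", 1:7), collapse = ","))
  tr <- ape::read.tree(text = tr_text)
  ids <- tr$tip.label
  aai <- sym_mat(rep(85, 21), ids, 100)
  aai["T1", "T2"] <- aai["T2", "T1"] <- 67.3
  evo <- unclass(patristic_distances(tr))
  p <- demarcate(tr, aai, evo)   # 20/21 pairs pass: fraction 0.952 >= 0.95
  expect_equal(nrow(p$diagnostics), 1)
  strict <- demarcate(tr, aai, evo,
                      demarcation_config(aai_pass_fraction = 1))
  expect_gt(nrow(strict$diagnostics), 1)
})

test_that("major clades split the deepest branches deterministically", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")  # caterpillar
  two <- major_clades(tr, n_top = 2)
  expect_equal(sort(unique(two$clade)), c("clade_1", "clade_2"))
  expect_setequal(two$genome_id[two$clade == "clade_1"], c("A", "B", "C"))
  one <- major_clades(tr, n_top = 1)
  expect_equal(unique(one$clade), "clade_1")
  expect_equal(nrow(one), 4)
  expect_error(major_clades(tr, n_top = 5), "exceeds")
})

test_that("major clades recover planted deep clades", {
  sim <- simulate_pangenome(simulation_config(seed = 117))
  tr <- sim$truth$tree
  cl <- major_clades(tr, n_top = 3)
  truth <- setNames(sim$truth$genus_labels$genus,
                    sim$truth$genus_labels$genome_id)
  expect_equal(adjusted_rand_index(
    truth, setNames(cl$clade, cl$genome_id)), 1)
})

test_that("partition reports mark singleton groups as NA", {
  ids <- c("A", "B", "C")
  memb <- tibble::tibble(genome_id = ids,
                         group_id = c("g1", "g1", "g2"))
  aai <- sym_mat(c(90, 60, 60), ids, 100)
  evo <- sym_mat(c(0.1, 0.8, 0.8), ids, 0)
  rep <- partition_report(memb, aai, evo)
  expect_equal(nrow(rep), 4)  # 2 groups x 2 metrics
  g2 <- rep[rep$group_id == "g2" & rep$metric == "AAI", ]
  expect_true(is.na(g2$intra_min))
  g1 <- rep[rep$group_id == "g1" & rep$metric == "AAI", ]
  expect_equal(g1$intra_min, 90)
  expect_equal(g1$inter_max, 60)
})
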