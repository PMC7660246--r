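test_that("identical proteomes map every protein to its namesake", {
  set.seed(31)
  p <- setNames(vapply(c(80, 100, 120), rand_prot, character(1)),
                c("p1", "p2", "p3"))
  bh <- best_hits(p, p)
  expect_equal(nrow(bh), 3)
  expect_equal(bh$subject_id, bh$query_id)
  e <- rbh_edges(bh, bh)
  expect_equal(nrow(e), 3)
  expect_equal(e$protein_a, e$protein_b)
})

test_that("the identity threshold is inclusive at 50 percent", {
  set.seed(33)
  base <- rand_prot(200)
  at50 <- mutate_protein(base, 100)   # identity exactly 50.0
  below <- mutate_protein(base, 101)  # identity 49.5
  q <- c(q1 = base)
  expect_equal(nrow(best_hits(q, c(s1 = at50))), 1)
  expect_equal(nrow(best_hits(q, c(s1 = below))), 0)
})

test_that("one-sided best hits are not reciprocal edges", {
  ab <- tibble::tibble(query_id = "p", subject_id = "q")
  ba_hit <- tibble::tibble(query_id = "q", subject_id = "p")
  ba_other <- tibble::tibble(query_id = "q", subject_id = "r")
  expect_equal(nrow(rbh_edges(ab, ba_hit)), 1)
  expect_equal(nrow(rbh_edges(ab, ba_other)), 0)
  expect_equal(nrow(rbh_edges(ab, ba_hit[0, ])), 0)
})

test_that("reciprocal edges on a simulated pair match the brute-force oracle", {
  sim <- sim_pair(seed = 35, d = 0.2, n_core = 12)
  pa <- sim$genomes$A$proteome; pb <- sim$genomes$B$proteome
  e <- rbh_edges(best_hits(pa, pb), best_hits(pb, pa))
  brute <- rbh_edges(
    dplyr::mutate(brute_best_hits(pa, pb), identity_pct = NA_real_),
    dplyr::mutate(brute_best_hits(pb, pa), identity_pct = NA_real_))
  expect_equal(nrow(e), nrow(brute))
  # and the planted one-to-one orthology is recovered exactly
  truth_a <- sim$truth$orthology |> dplyr::filter(genome_id == "A")
  expect_equal(nrow(e), nrow(truth_a))
})

test_that("clusters partition every protein exactly once", {
  set.seed(41)
  p <- setNames(vapply(rep(100, 4), rand_prot, character(1)),
                paste0("p", 1:4))
  gs <- list(genome_record("g1", p), genome_record("g2", p),
             genome_record("g3", p))
  cl <- orthologous_clusters(gs)
  expect_equal(nrow(cl), 12)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 4)
  expect_true(all(table(cl$cluster_id) == 3))
  # empty edge set: every protein its own singleton
  inv <- tibble::tibble(genome_id = rep(c("x", "y"), each = 2),
                        protein_id = c("a", "b", "a", "b"))
  singletons <- build_clusters(NULL, inv)
  expect_equal(dplyr::n_distinct(singletons$cluster_id), 4)
})

test_that("cluster partition is invariant under genome input order", {
  sim <- simulate_pangenome(simulation_config(
    seed = 43, n_genera = 2, genomes_per_genus = 2, n_core = 10,
    gain_rate = 0.3, loss_rate = 0.1, dup_prob = 0.05))
  g <- sim$genomes
  cl1 <- orthologous_clusters(g)
  cl2 <- orthologous_clusters(rev(g))
  key <- function(cl) {
    members <- split(paste(cl$genome_id, cl$protein_id), cl$cluster_id)
    sort(vapply(members, function(m) paste(sort(m), collapse = "|"),
                character(1)))
  }
  expect_identical(unname(key(cl1)), unname(key(cl2)))
})

test_that("cluster recovery matches planted families at moderate divergence", {
  sim <- simulate_pangenome(simulation_config(
    seed = 45, n_genera = 2, genomes_per_genus = 3, intra_depth = 0.05,
    inter_depth = 0.15, n_core = 15, gain_rate = 0.2, loss_rate = 0.1,
    dup_prob = 0))
  cl <- orthologous_clusters(sim$genomes)
  truth <- sim$truth$orthology
  got <- cl |> dplyr::arrange(genome_id, protein_id)
  want <- truth |> dplyr::arrange(genome_id, protein_id)
  expect_equal(adjusted_rand_index(
    setNames(got$cluster_id, paste(got$genome_id, got$protein_id)),
    setNames(want$family_id, paste(want$genome_id, want$protein_id))), 1)
})

test_that("raising the identity threshold never adds reciprocal edges", {
  sim <- sim_pair(seed = 47, d = 0.4, n_core = 15)
  pa <- sim$genomes$A$proteome; pb <- sim$genomes$B$proteome
  n_edges <- vapply(c(0, 30, 50, 70, 90), function(idmin)
    nrow(rbh_edges(best_hits(pa, pb, identity_min = idmin),
                   best_hits(pb, pa, identity_min = idmin))), numeric(1))
  expect_true(all(diff(n_edges) <= 0))
})

test_that("core/accessory/unique accounting is exact on identical proteomes", {
  set.seed(51)
  p <- setNames(vapply(rep(90, 5), rand_prot, character(1)), paste0("p", 1:5))
  gs <- list(genome_record("g1", p), genome_record("g2", p),
             genome_record("g3", p))
  cl <- orthologous_clusters(gs)
  s <- classify_clusters(cl, c("g1", "g2", "g3"))
  expect_equal(s$totals$total_oc_count, 5)
  expect_equal(s$totals$core_oc_count, 5)
  expect_equal(s$totals$single_copy_core_count, 5)
  expect_true(all(s$per_genome$accessory_count == 0))
  expect_true(all(s$per_genome$unique_count == 0))
  expect_error(classify_clusters(cl, c("g1", "g4")), "absent")
})

test_that("outgroup genomes are excluded from pan-genome accounting", {
  set.seed(53)
  shared <- setNames(vapply(rep(90, 3), rand_prot, character(1)),
                     paste0("p", 1:3))
  gs <- list(genome_record("g1", shared), genome_record("g2", shared),
             genome_record("og", c(shared, x1 = rand_prot(90)),
                           is_outgroup = TRUE))
  cl <- orthologous_clusters(gs)
  s <- classify_clusters(cl, c("g1", "g2", "og"), outgroup = "og")
  expect_equal(s$totals$core_oc_count, 3)
  expect_false("og" %in% s$per_genome$genome_id)
})
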