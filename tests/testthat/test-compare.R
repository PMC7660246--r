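make_mat <- function(v, ids) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("inter/intra splitting counts pairs correctly", {
  ids <- c("a1", "a2", "b1", "b2")
  lab <- setNames(c("A", "A", "B", "B"), ids)
  m <- make_mat(1:6, ids)
  sp <- split_inter_intra(m, lab)
  expect_equal(sum(sp$pair_type == "intra"), 2)
  expect_equal(sum(sp$pair_type == "inter"), 4)
  # a single group makes every pair intra
  sp1 <- split_inter_intra(m, setNames(rep("A", 4), ids))
  expect_true(all(sp1$pair_type == "intra"))
  expect_error(split_inter_intra(m, lab[1:3]), "no group label")
})

test_that("inter/intra splitting matches a brute-force double loop", {
  set.seed(95)
  ids <- paste0("g", 1:10)
  lab <- setNames(sample(c("X", "Y", "Z"), 10, TRUE), ids)
  m <- make_mat(runif(45), ids)
  sp <- split_inter_intra(m, lab)
  intra <- c(); inter <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    if (lab[ids[i]] == lab[ids[j]]) intra <- c(intra, m[i, j])
    else inter <- c(inter, m[i, j])
  }
  expect_setequal(sp$value[sp$pair_type == "intra"], intra)
  expect_setequal(sp$value[sp$pair_type == "inter"], inter)
})

test_that("metric correlation reproduces the closed-form Pearson r", {
  ids <- paste0("g", 1:5)
  set.seed(97)
  x <- runif(10)
  mx <- make_mat(x, ids)
  expect_equal(metric_correlation(mx, make_mat(2 * x + 1, ids)), 1)
  expect_equal(metric_correlation(mx, make_mat(-x, ids)), -1)
  y <- runif(10)
  my <- make_mat(y, ids)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(metric_correlation(mx, my), r_hand)
  expect_error(metric_correlation(mx, make_mat(rep(1, 10), ids)),
               "zero variance")
  # missing entries are excluded pairwise
  my_na <- my; my_na[1, 2] <- my_na[2, 1] <- NA
  ut <- upper.tri(mx)
  ok <- !is.na(my_na[ut])
  expect_equal(metric_correlation(mx, my_na), cor(mx[ut][ok], my_na[ut][ok]))
})

test_that("correlation is symmetric and invariant to positive affine maps", {
  set.seed(99)
  ids <- paste0("g", 1:8)
  mx <- make_mat(runif(28), ids); my <- make_mat(runif(28), ids)
  expect_equal(metric_correlation(mx, my), metric_correlation(my, mx))
  expect_equal(metric_correlation(3 * mx + 7, 0.5 * my - 2),
               metric_correlation(mx, my))
})

test_that("correlation report covers every unordered metric pair", {
  set.seed(103)
  ids <- paste0("g", 1:6)
  mats <- list(AAI = make_mat(runif(15), ids),
               ANI = make_mat(runif(15), ids),
               EVODIST = make_mat(runif(15), ids))
  rep <- correlation_report(mats)
  expect_equal(nrow(rep), 3)
  expect_true(all(abs(rep$r_cc) <= 1))
  expect_true(all(rep$n == 15))
})

test_that("Welch t-test handles textbook and degenerate cases", {
  x <- c(1, 2, 3, 4, 5, 6); y <- c(2, 4, 6, 8, 10, 12)
  tt <- inter_intra_ttest(x, y)
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 6 + var(y) / 6)
  expect_equal(tt$t_statistic, t_hand)
  expect_equal(tt$p_value, t.test(x, y)$p.value)
  same <- inter_intra_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- inter_intra_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(sep$p_label, "<2.2e-16")
  expect_equal(sep$p_value, 0)
  const <- inter_intra_ttest(c(5, 5), c(5, 5))
  expect_equal(const$t_statistic, 0)
  expect_equal(const$p_value, 1)
})

test_that("intra-clade AAI stochastically dominates inter-clade AAI", {
  sim <- simulate_pangenome(simulation_config(
    seed = 105, n_genera = 2, genomes_per_genus = 3, n_core = 10,
    gain_rate = 0, loss_rate = 0, dup_prob = 0))
  aai <- metric_matrix(sim$genomes, "aai")
  lab <- setNames(sim$truth$genus_labels$genus,
                  sim$truth$genus_labels$genome_id)
  sp <- split_inter_intra(aai, lab)
  w <- wilcox.test(sp$value[sp$pair_type == "intra"],
                   sp$value[sp$pair_type == "inter"],
                   alternative = "greater")
  expect_lt(w$p.value, 0.01)
})
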