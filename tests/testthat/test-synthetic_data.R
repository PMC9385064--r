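test_that("simulated trees are clock-like with the configured root age", {
  cfg <- sim_config(n_tips = 2, root_age_years = 10000, seed = 5)
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(unname(tr$edge.length), c(10000, 10000))
  # same seed -> identical tree; different seed -> (almost surely) not
  tr2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  cfg20 <- sim_config(n_tips = 20, root_age_years = 20000, seed = 5)
  tr20 <- simulate_tree(cfg20)
  ages <- attr(tr20, "node_ages")
  # ultrametric: tips at 0, root at root_age, child ages below parents
  expect_equal(max(ages), 20000)
  expect_true(all(abs(ages[1:20]) < 1e-6))
  parent_age <- ages[tr20$edge[, 1]]; child_age <- ages[tr20$edge[, 2]]
  expect_true(all(parent_age > child_age))
})

test_that("mutation counts follow Poisson(mu * L * t) and infinite sites", {
  # single cherry, branch 10,000 years, L = 10.45 Mb, mu = 0.76e-9:
  # expected count per branch 79.42; check the mean over replicates
  lam <- 0.76e-9 * 10.45e6 * 10000
  expect_equal(round(lam, 2), 79.42)
  counts <- vapply(1:300, function(i) {
    cfg <- sim_config(n_tips = 2, root_age_years = 10000,
                      seed = case_seed(3, i))
    truth <- drop_mutations(simulate_tree(cfg), cfg)
    nrow(truth$mutations)
  }, numeric(1))
  # two branches: total mean 2*lam, SE = sqrt(2*lam/300)
  expect_lt(abs(mean(counts) - 2 * lam), 3 * sqrt(2 * lam / 300))
  # zero rate -> zero mutations
  cfg0 <- sim_config(n_tips = 4, root_age_years = 10000, seed = 1,
                     rate = mutation_rate(1e-30, 0.5e-30, 2e-30))
  expect_equal(nrow(drop_mutations(simulate_tree(cfg0), cfg0)$mutations), 0L)
  # recurrence off -> all positions unique and inside the mask
  cfg1 <- sim_config(n_tips = 10, root_age_years = 20000, seed = 17)
  truth <- drop_mutations(simulate_tree(cfg1), cfg1)
  expect_equal(anyDuplicated(truth$mutations$position), 0L)
  expect_true(all(mask_contains(cfg1$mask, truth$mutations$position)))
})

test_that("recurrent mutations reuse positions on unrelated branches", {
  cfg <- sim_config(n_tips = 12, root_age_years = 20000, seed = 23,
                    recurrent_fraction = 0.05)
  truth <- drop_mutations(simulate_tree(cfg), cfg)
  rec <- truth$mutations[truth$mutations$recurrent, ]
  expect_gt(nrow(rec), 0)
  for (p in unique(rec$position)) {
    hits <- truth$mutations[truth$mutations$position == p, ]
    expect_gte(nrow(hits), 2L)
    tipsets <- lapply(hits$child, function(v)
      ylineage:::node_descendant_tips(truth$tree, v))
    expect_equal(length(intersect(tipsets[[1]], tipsets[[2]])), 0L)
  }
})

test_that("emitted VCF carrier sets equal the truth; outgroup all-REF", {
  cfg <- sim_config(n_tips = 8, root_age_years = 10000, seed = 41)
  truth <- drop_mutations(simulate_tree(cfg), cfg)
  dir <- tempfile(); paths <- emit_dataset(truth, dir)
  gm <- read_haploid_vcf(paths$vcf)
  expect_equal(n_sites(gm), length(unique(truth$mutations$position)))
  expect_true(all(gm$calls["OUTGROUP", ] == 0L))
  for (r in sample(nrow(truth$mutations), min(20, nrow(truth$mutations)))) {
    tips <- truth$tree$tip.label[
      ylineage:::node_descendant_tips(truth$tree, truth$mutations$child[r])]
    col <- as.character(truth$mutations$position[r])
    expect_setequal(gm$sample_ids[gm$calls[, col] == 1L], tips)
  }
  tr_back <- read_tree_newick(paths$newick)
  expect_setequal(tr_back$tip.label, truth$tree$tip.label)
  ages <- read.table(paths$node_ages, header = TRUE, sep = "\t")
  expect_equal(max(ages$age_years), 10000)
})

test_that("corruption rates hit their binomial targets and seeds reproduce", {
  cfg <- sim_config(n_tips = 10, root_age_years = 20000, seed = 71,
                    missingness_rate = 0.1, low_depth_rate = 0.07)
  sim <- simulate_dataset(sim_config(n_tips = 10, root_age_years = 20000,
                                     seed = 71))
  gm <- corrupt_matrix(sim$matrix, cfg)
  ncalls <- length(gm$calls)
  expect_gt(ncalls, 2000)
  f_na <- mean(is.na(gm$calls))
  expect_lt(abs(f_na - 0.1), 3 * sqrt(0.1 * 0.9 / ncalls))
  f_lo <- mean(gm$depths == 1L)
  expect_lt(abs(f_lo - 0.07), 3 * sqrt(0.07 * 0.93 / ncalls))
  # identity when rates are zero
  cfg0 <- sim_config(n_tips = 10, root_age_years = 20000, seed = 71)
  expect_equal(corrupt_matrix(sim$matrix, cfg0)$calls, sim$matrix$calls)
  # determinism
  expect_equal(corrupt_matrix(sim$matrix, cfg)$calls, gm$calls)
})
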