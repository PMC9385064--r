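test_that("polarization orients states by the outgroup and drops bad sites", {
  samples <- c("S1", "S2", "OG")
  calls <- rbind(S1 = c(1, 0, 1, 0),
                 S2 = c(0, 0, 1, 1),
                 OG = c(0, 1, NA, 1))
  gm <- genotype_matrix(samples, c(10, 20, 30, 40), rep("A", 4), rep("G", 4),
                        calls)
  bm <- polarize(gm, "OG")
  expect_equal(bm$sample_ids, c("S1", "S2"))
  # outgroup REF, sample ALT -> derived
  expect_equal(unname(bm$states["S1", "10"]), 1L)
  # outgroup ALT -> polarity flips: REF call is derived
  expect_equal(unname(bm$states["S1", "20"]), 1L)
  expect_equal(unname(bm$states["S2", "40"]), 0L)
  # outgroup-missing site dropped and counted
  expect_false(30 %in% bm$positions)
  expect_equal(bm$dropped$n_sites[bm$dropped$reason == "outgroup_missing"], 1L)
  expect_error(polarize(gm, "NOPE"), "not found")
})

test_that("pairwise compatibility is the rooted three-gamete test", {
  bm <- binary_matrix(c("A", "B", "C"), c(1, 2, 3, 4),
                      states = rbind(c(1, 1, 1, 0),
                                     c(1, 0, 1, 1),
                                     c(0, 0, 0, 1)))
  # site1 {A,B}: vs site2 {A} nested ok; vs site4 {B,C} overlapping bad
  inc <- check_pairwise_compatibility(bm)
  expect_equal(nrow(inc), 2L)          # (1,4) and (3,4) overlap-without-nesting
  expect_true(all(inc$pos_j == 4))
  # disjoint and nested pairs never flagged
  bm2 <- binary_matrix(c("A", "B", "C"), 1:2,
                       states = rbind(c(1, 1), c(0, 0), c(0, 1)))
  expect_equal(nrow(check_pairwise_compatibility(bm2)), 0L)
})

test_that("perfect phylogeny clades are exactly the distinct derived sets", {
  # nested sets {A,B,C},{A,B},{A} give the caterpillar (((A),B),C)
  bm <- binary_matrix(c("A", "B", "C", "D"), c(100, 200, 300),
                      states = rbind(c(1, 1, 1), c(1, 1, 0),
                                     c(1, 0, 0), c(0, 0, 0)))
  st <- build_tree(bm)
  expect_setequal(sapply(tree_clades(st), paste, collapse = ","),
                  c("A,B,C", "A,B"))
  # each compatible site contributes exactly one event
  expect_equal(nrow(st$events), 3L)
  expect_equal(length(st$recurrent_positions), 0L)
  # identical samples become siblings under one node
  bm2 <- binary_matrix(c("A", "B", "C"), c(1, 2),
                       states = rbind(c(1, 1), c(1, 1), c(0, 0)))
  st2 <- build_tree(bm2)
  expect_setequal(sapply(tree_clades(st2), paste, collapse = ","), "A,B")
  expect_error(build_tree(binary_matrix(character(0), integer(0),
                                        matrix(integer(0), 0, 0))), "empty")
})

test_that("reconstruction recovers simulated infinite-sites topology", {
  cfg <- sim_config(n_tips = 20, root_age_years = 20000, seed = 202)
  sim <- simulate_dataset(cfg)
  bm <- polarize(sim$matrix, "OUTGROUP")
  st <- build_tree(bm)
  # truth clades supported by >= 1 mutation must all be recovered, and no
  # spurious clades invented
  truth <- sim$truth
  counts <- tabulate(truth$mutations$edge, nbins = nrow(truth$tree$edge))
  supported <- lapply(which(counts > 0 &
                              truth$tree$edge[, 2] > length(truth$tree$tip.label)),
                      function(e) sort(truth$tree$tip.label[
                        ylineage:::node_descendant_tips(truth$tree,
                                                        truth$tree$edge[e, 2])]))
  supported <- unique(Filter(function(s)
    length(s) >= 2 && length(s) < 20, supported))
  got <- tree_clades(st)
  expect_setequal(sapply(got, paste, collapse = ","),
                  sapply(supported, paste, collapse = ","))
})

test_that("branch assignment flags recurrence and pushes events root-ward", {
  phy <- ape::read.tree(text = "((A,B),(C,D));")
  # site 10 clade-concordant on (A,B); site 20 derived in A + (C,D)
  bm <- binary_matrix(c("A", "B", "C", "D"), c(10, 20),
                      states = rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 1)))
  st <- assign_snps_to_branches(phy, bm)
  expect_equal(unname(st$site_scores["10"]), 1L)
  expect_equal(unname(st$site_scores["20"]), 2L)   # recurrent
  expect_equal(st$recurrent_positions, 20L)
  ev20 <- st$events[st$events$position == 20, ]
  expect_equal(nrow(ev20), 2L)
  # missing tips are wildcards absorbed root-ward: B missing, A derived,
  # sisters -> single event on the (A,B) stem, B implicitly derived
  bm2 <- binary_matrix(c("A", "B", "C", "D"), 5,
                       states = matrix(c(1L, NA, 0L, 0L), ncol = 1))
  st2 <- assign_snps_to_branches(phy, bm2)
  expect_equal(nrow(st2$events), 1L)
  stem_tips <- sort(st2$tree$tip.label[
    ylineage:::node_descendant_tips(st2$tree, st2$events$child[1])])
  expect_equal(stem_tips, c("A", "B"))
  expect_error(assign_snps_to_branches(phy,
    binary_matrix(c("A", "B", "C"), 1, matrix(c(1L, 0L, 0L), ncol = 1))),
    "without data")
})

test_that("fitch_score equals the exhaustive-labeling oracle", {
  # crafted cases
  phy <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_score(phy, c(A = 1, B = 1, C = 0, D = 0)), 1L)
  expect_equal(fitch_score(phy, c(A = 1, B = 1, C = 1, D = 1)), 1L) # MRCA stem
  expect_equal(fitch_score(phy, c(A = 1, B = 0, C = 1, D = 0)), 2L)
  # randomized patterns on random rooted trees up to 6 tips, incl. missing
  for (i in 1:60) {
    set.seed(case_seed(7, i))
    n <- sample(2:6, 1)
    tr <- random_rooted_tree(n)
    states <- sample(c(0L, 1L, NA), n, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    names(states) <- tr$tip.label
    expect_equal(fitch_score(tr, states), oracle_min_changes(tr, states),
                 info = sprintf("case %d", i))
  }
})

test_that("branch event totals are invariant to tip-order permutation", {
  cfg <- sim_config(n_tips = 8, root_age_years = 8000, seed = 31)
  sim <- simulate_dataset(cfg)
  bm <- polarize(sim$matrix, "OUTGROUP")
  st <- build_tree(bm)
  set.seed(99)
  perm <- sample(length(bm$sample_ids))
  bm_p <- binary_matrix(bm$sample_ids[perm], bm$positions,
                        bm$states[perm, , drop = FALSE])
  st_p <- build_tree(bm_p)
  expect_equal(nrow(st_p$events), nrow(st$events))
  key <- function(s) {
    ev <- s$events
    tips <- vapply(ev$child, function(v) paste(sort(s$tree$tip.label[
      ylineage:::node_descendant_tips(s$tree, v)]), collapse = ","),
      character(1))
    sort(paste(ev$position, ev$direction, tips))
  }
  expect_equal(key(st_p), key(st))
})
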