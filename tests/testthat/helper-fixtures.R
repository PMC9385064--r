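# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately naive (enumeration / brute force) and never call
# the code paths they check.

# ---- brute-force interval membership (1-based positions, BED intervals) --
brute_in_mask <- function(pos, start, end) {
  vapply(pos, function(p) any(p > start & p <= end), logical(1))
}

# ---- exhaustive small-parsimony oracle -----------------------------------
# Minimum number of state changes of a binary site on a rooted tree with the
# ancestral root constraint, by enumerating every labeling of the free
# nodes.  A virtual ancestor (state 0) above the root supplies the stem, the
# same convention the package documents.  Missing tips are free as well.
oracle_min_changes <- function(phy, tip_states) {
  ntip <- length(phy$tip.label)
  st <- if (is.null(names(tip_states))) tip_states else
    tip_states[phy$tip.label]
  edges <- phy$edge
  root <- setdiff(unique(edges[, 1]), edges[, 2])[1]
  internal <- sort(unique(edges[, 1]))            # all free (root included)
  free_tips <- which(is.na(st))
  free <- c(internal, free_tips)
  k <- length(free)
  best <- Inf
  for (code in 0:(2^k - 1)) {
    lab <- rep(NA_integer_, max(edges))
    lab[seq_len(ntip)] <- st
    bits <- as.integer(intToBits(code))[seq_len(k)]
    lab[free] <- bits
    changes <- sum(lab[edges[, 1]] != lab[edges[, 2]]) +
      (lab[root] != 0L)                           # virtual stem edge
    best <- min(best, changes)
  }
  as.integer(best)
}

# random rooted binary tree with n labeled tips (sequential random joins)
random_rooted_tree <- function(n, labels = LETTERS[seq_len(n)]) {
  stopifnot(n >= 2)
  tr <- ape::rtree(n, rooted = TRUE, tip.label = labels)
  tr$edge.length <- NULL
  tr
}

# ---- hand-enumerated six-site filter fixture -----------------------------
# 10 samples, 6 sites; defects: s1 indel, s2 off-mask, s3 missingness 0.2,
# plus one low-depth genotype on s6 that leaves its missingness exactly at
# the 0.1 boundary (kept: the threshold is strict ">").  Hand enumeration:
# mask/indel removes s1+s2; depth sets one genotype missing on s6 (still
# polymorphic); missingness removes s3 only; monomorphic removes nothing;
# s4, s5, s6 survive.
filter_fixture <- function() {
  samples <- LETTERS[1:10]
  positions <- c(50, 150, 250, 350, 450, 550)
  calls <- matrix(0L, 10, 6, dimnames = list(samples, positions))
  calls["A", ] <- c(1, 1, 1, 1, 0, 1)
  calls["B", 3] <- NA; calls["C", 3] <- NA        # missingness 0.2 at s3
  calls["D", c(2, 4)] <- 1
  calls["B", c(5, 6)] <- 1
  depths <- matrix(30L, 10, 6, dimnames = list(samples, positions))
  depths["B", 6] <- 1L                      # low depth -> call set missing
  gm <- genotype_matrix(samples, positions,
                        ref = rep("A", 6), alt = rep("G", 6),
                        calls = calls, depths = depths,
                        is_indel = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  mask <- region_mask(start = c(0, 200), end = c(100, 600))  # excludes 150
  list(matrix = gm, mask = mask,
       expected_surviving = c(350, 450, 550),
       expected_report = data.frame(
         stage = c("mask_indel", "depth", "missingness", "monomorphic"),
         sites_in = c(6L, 4L, 4L, 3L),
         sites_removed = c(2L, 0L, 1L, 0L),
         genotypes_set_missing = c(0L, 1L, 0L, 0L)))
}

# ---- 4-sample clade fixture: all 15 non-empty carrier sets ---------------
clade_fixture <- function() {
  samples <- c("A", "B", "C", "D")
  subsets <- lapply(1:15, function(code) which(intToBits(code)[1:4] == 1))
  states <- t(vapply(seq_len(4), function(i)
    vapply(subsets, function(s) as.integer(i %in% s), integer(1)),
    integer(15)))
  bm <- binary_matrix(samples, positions = seq(100, 1500, by = 100),
                      states = states)
  list(bm = bm, subsets = subsets, positions = seq(100, 1500, by = 100))
}

# brute-force classification of one carrier set relative to a clade
brute_classify <- function(carriers, clade, all_samples) {
  outside <- setdiff(all_samples, clade)
  if (length(intersect(carriers, outside))) return("excluded")
  inside <- intersect(carriers, clade)
  if (!length(inside)) return("no_derived_in_clade")
  if (setequal(inside, clade)) return("defining")
  if (length(inside) == 1L) return("private")
  "internal"
}

# ---- caterpillar snp_tree with enumerated branch counts ------------------
# sites: {A,B,C} x2, {A,B} x3, {A} x1, {B} x4, {C} x2, {D} x5
caterpillar_fixture <- function() {
  samples <- c("A", "B", "C", "D")
  sets <- c(rep(list(c(1, 2, 3)), 2), rep(list(c(1, 2)), 3),
            rep(list(1), 1), rep(list(2), 4), rep(list(3), 2),
            rep(list(4), 5))
  states <- t(vapply(1:4, function(i)
    vapply(sets, function(s) as.integer(i %in% s), integer(1)),
    integer(length(sets))))
  bm <- binary_matrix(samples, positions = seq_along(sets) * 10,
                      states = states)
  # brute-force tip-to-node mutation path sums from the generating sets:
  # events below the MRCA of {A,B,C,D}: A path = |{A,B,C}|+|{A,B}|+|{A}| etc.
  path_from_root <- c(A = 2 + 3 + 1, B = 2 + 3 + 4, C = 2 + 2, D = 5)
  list(bm = bm, path_from_root = path_from_root)
}

# deterministic per-case seeds below 2^31 for parameterised loops
case_seed <- function(base, i) (as.integer(base) * 1000L + i) %% .Machine$integer.max
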