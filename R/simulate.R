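#' Simulation configuration
#'
#' Parameters of the clock-tree generator used to produce haploid SNP
#' datasets with known truth.  The defaults mirror the study conditions of
#' the dating model: callable length 10.45 Mb, mutation rate 0.76e-9 per
#' site per year (95% CI 0.67e-9-0.86e-9), and a clean dataset (no
#' recurrence, no missingness, no low-depth corruption) unless asked for.
#'
#' @param n_tips Number of ingroup samples (>= 2).
#' @param root_age_years Age of the ingroup MRCA in years (> 0).
#' @param rate A [mutation_rate()].
#' @param mask A [region_mask()]; mutations fall uniformly inside it.
#'   Default: one interval of 10.45 Mb.
#' @param recurrent_fraction Probability that a mutation reuses a position
#'   already mutated on an unrelated branch, in `[0, 1)` (default 0).
#' @param missingness_rate Per-call missing probability in `[0, 1]`
#'   (default 0).
#' @param low_depth_rate Per-call probability of depth 1 instead of 30, in
#'   `[0, 1]` (default 0).
#' @param seed Integer seed; per-stage substreams are derived from it.
#' @param tree Optional user-supplied rooted ultrametric `phylo` with edge
#'   lengths in years; overrides the random topology.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tips = 20L, root_age_years = 20000,
                       rate = mutation_rate(),
                       mask = region_mask(0, 10450000),
                       recurrent_fraction = 0, missingness_rate = 0,
                       low_depth_rate = 0, seed = 1L, tree = NULL) {
  if (root_age_years <= 0) stop("root_age_years must be positive")
  if (is.null(tree) && n_tips < 2L) stop("n_tips must be >= 2")
  for (p in c(recurrent_fraction, missingness_rate, low_depth_rate)) {
    if (p < 0 || p >= 1 + 1e-12) stop("rates/fractions must lie in [0, 1)")
  }
  structure(list(n_tips = as.integer(n_tips),
                 root_age_years = root_age_years, rate = rate, mask = mask,
                 recurrent_fraction = recurrent_fraction,
                 missingness_rate = missingness_rate,
                 low_depth_rate = low_depth_rate,
                 seed = as.integer(seed), tree = tree),
            class = "sim_config")
}

#' Simulate a clock-like rooted tree
#'
#' Draws a random coalescent topology and rescales it to be ultrametric
#' with the configured root age: tips at age 0, ingroup MRCA at
#' `root_age_years`.  A user-supplied tree in the config (edge lengths in
#' years) is passed through unchanged, covering arbitrary demographies.
#'
#' @param config A [sim_config()].
#' @return An ape `phylo` with edge lengths in years and a `node_ages`
#'   attribute (years, indexed by ape node id).
#' @export
simulate_tree <- function(config) {
  if (!is.null(config$tree)) {
    phy <- config$tree
  } else {
    set.seed(config$seed)
    phy <- ape::rcoal(config$n_tips,
                      tip.label = sprintf("S%02d", seq_len(config$n_tips)))
    depth <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * config$root_age_years / depth
  }
  attr(phy, "node_ages") <- node_ages(phy)
  phy
}

# age (years before present) of every node of an ultrametric rooted tree
node_ages <- function(phy) {
  d <- ape::node.depth.edgelength(phy)   # distance from root
  round(max(d) - d, 9)
}

#' Drop Poisson mutations on tree branches
#'
#' Each branch receives `Poisson(mu * L * branch_years)` mutations placed
#' at positions drawn uniformly without replacement over the region mask
#' (infinite sites).  With probability `recurrent_fraction` a mutation
#' instead reuses a position already used on an unrelated branch (neither
#' ancestor nor descendant), injecting controlled infinite-sites
#' violations.
#'
#' @param phy Tree from [simulate_tree()] (edge lengths in years).
#' @param config A [sim_config()].
#' @return A `sim_truth`: list with `tree`, `node_ages`, `mutations`
#'   (data frame `position`, `edge`, `child`, `recurrent`) and `config`.
#' @export
drop_mutations <- function(phy, config) {
  set.seed(config$seed + 1L)
  L <- config$mask$effective_length_bp
  lam <- config$rate$central * L * phy$edge.length
  counts <- stats::rpois(length(lam), lam)
  total <- sum(counts)
  offs <- if (total) sample.int(L, total, replace = FALSE) else integer(0)
  pos <- mask_offset_to_position(config$mask, offs)
  edge_of <- rep(seq_along(counts), counts)
  recurrent <- rep(FALSE, total)
  if (config$recurrent_fraction > 0 && total > 1L) {
    ntip <- length(phy$tip.label)
    tipsets <- lapply(phy$edge[, 2], function(v) node_descendant_tips(phy, v))
    reuse <- stats::runif(total) < config$recurrent_fraction
    for (i in which(reuse)) {
      if (recurrent[i]) next               # already paired as a donor
      unrelated <- which(vapply(seq_len(total), function(k) {
        k != i && length(intersect(tipsets[[edge_of[k]]],
                                   tipsets[[edge_of[i]]])) == 0L
      }, logical(1)))
      unrelated <- setdiff(unrelated, which(recurrent))
      if (length(unrelated)) {
        donor <- unrelated[sample.int(length(unrelated), 1L)]
        pos[i] <- pos[donor]
        recurrent[i] <- TRUE
        recurrent[donor] <- TRUE
      }
    }
  }
  mut <- data.frame(position = pos, edge = edge_of,
                    child = phy$edge[edge_of, 2], recurrent = recurrent)
  mut <- mut[order(mut$position, mut$edge), ]
  rownames(mut) <- NULL
  structure(list(tree = phy, node_ages = node_ages(phy), mutations = mut,
                 config = config), class = "sim_truth")
}

# truth -> haploid genotype matrix (ALT = derived), outgroup appended
truth_to_matrix <- function(truth, outgroup_id = "OUTGROUP") {
  phy <- truth$tree
  ntip <- length(phy$tip.label)
  upos <- sort(unique(truth$mutations$position))
  calls <- matrix(0L, nrow = ntip + 1L, ncol = length(upos),
                  dimnames = list(c(phy$tip.label, outgroup_id), upos))
  for (r in seq_len(nrow(truth$mutations))) {
    j <- match(truth$mutations$position[r], upos)
    tips <- node_descendant_tips(phy, truth$mutations$child[r])
    calls[tips, j] <- 1L
  }
  set.seed(truth$config$seed + 2L)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, length(upos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
  genotype_matrix(sample_ids = c(phy$tip.label, outgroup_id),
                  positions = upos, ref = ref, alt = alt, calls = calls,
                  depths = matrix(30L, nrow = ntip + 1L, ncol = length(upos)))
}

#' Inject missingness and low-depth corruption
#'
#' Stress input for the filter cascade: each call is set missing with
#' probability `missingness_rate`, and assigned read depth 1 (instead of
#' 30) with probability `low_depth_rate`.
#'
#' @param x A [genotype_matrix()].
#' @param config A [sim_config()] (its `seed + 3` feeds this stage).
#' @return The corrupted matrix.
#' @export
corrupt_matrix <- function(x, config) {
  set.seed(config$seed + 3L)
  nc <- length(x$calls)
  if (config$missingness_rate > 0) {
    x$calls[stats::runif(nc) < config$missingness_rate] <- NA_integer_
  }
  if (is.null(x$depths)) {
    x$depths <- matrix(30L, nrow = nrow(x$calls), ncol = ncol(x$calls),
                       dimnames = dimnames(x$calls))
  }
  if (config$low_depth_rate > 0) {
    x$depths[stats::runif(nc) < config$low_depth_rate] <- 1L
  }
  x
}

#' Simulate a full dataset with truth
#'
#' Convenience wrapper: tree, mutations, genotype matrix (outgroup
#' appended all-ancestral), optional corruption.
#'
#' @param config A [sim_config()].
#' @param outgroup_id Sample id given to the appended outgroup.
#' @return List with `truth` (`sim_truth`), `matrix`
#'   ([genotype_matrix()]) and `meta` (all tips flagged high-coverage).
#' @export
simulate_dataset <- function(config, outgroup_id = "OUTGROUP") {
  phy <- simulate_tree(config)
  truth <- drop_mutations(phy, config)
  gm <- truth_to_matrix(truth, outgroup_id)
  if (config$missingness_rate > 0 || config$low_depth_rate > 0) {
    gm <- corrupt_matrix(gm, config)
  }
  meta <- data.frame(sample = gm$sample_ids,
                     population = "SIM",
                     high_coverage = TRUE)
  list(truth = truth, matrix = gm, meta = meta)
}

#' Write a simulated dataset to disk
#'
#' Emits the VCF (derived allele as ALT, outgroup all-reference), the true
#' tree as Newick, and truth TSVs (`node_ages.tsv`, `branch_mutations.tsv`)
#' plus sample metadata — everything the pipeline needs end-to-end.
#'
#' @param truth A `sim_truth` from [drop_mutations()].
#' @param dir Output directory (created if needed).
#' @param outgroup_id Outgroup sample id in the VCF.
#' @return Named list of written paths, invisibly.
#' @export
emit_dataset <- function(truth, dir, outgroup_id = "OUTGROUP") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- truth_to_matrix(truth, outgroup_id)
  paths <- list(vcf = file.path(dir, "sim.vcf"),
                newick = file.path(dir, "tree.nwk"),
                node_ages = file.path(dir, "node_ages.tsv"),
                branch_mutations = file.path(dir, "branch_mutations.tsv"),
                meta = file.path(dir, "sample_meta.tsv"))
  write_haploid_vcf(gm, paths$vcf)
  ape::write.tree(truth$tree, file = paths$newick)
  ages <- data.frame(node = seq_along(truth$node_ages),
                     age_years = truth$node_ages)
  utils::write.table(ages, paths$node_ages, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bm_counts <- as.data.frame(table(factor(truth$mutations$edge,
                                          levels = seq_len(nrow(truth$tree$edge)))))
  names(bm_counts) <- c("edge", "n_mutations")
  bm_counts$parent <- truth$tree$edge[, 1]
  bm_counts$child <- truth$tree$edge[, 2]
  utils::write.table(bm_counts[, c("edge", "parent", "child", "n_mutations")],
                     paths$branch_mutations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample = c(truth$tree$tip.label, outgroup_id),
                     population = "SIM", high_coverage = TRUE)
  utils::write.table(meta, paths$meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
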