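#' Polarize a genotype matrix against an outgroup
#'
#' Orients REF/ALT calls into ancestral/derived states using a designated
#' outgroup sample (for haplogroup work, a sequence from an outgroup
#' haplogroup used purely as the phylogenetic root).  The ancestral state at
#' a site is the outgroup's allele; the outgroup itself is removed from the
#' sample set.  Sites where the outgroup is missing, and sites with no
#' derived ingroup call after polarization, are dropped and counted.
#'
#' @param x A [genotype_matrix()].
#' @param outgroup_id Sample id of the outgroup; must be present in `x`.
#' @return A `binary_matrix`: fields `sample_ids` (ingroup), `positions`,
#'   `states` (0 = ancestral, 1 = derived, NA = missing), `outgroup_id`,
#'   and a `dropped` data frame with per-reason counts.
#' @export
polarize <- function(x, outgroup_id) {
  og <- match(outgroup_id, x$sample_ids)
  if (is.na(og)) stop("outgroup '", outgroup_id, "' not found in matrix")
  ing <- setdiff(seq_along(x$sample_ids), og)
  og_calls <- x$calls[og, ]
  states <- x$calls[ing, , drop = FALSE]
  flip <- which(og_calls == 1L)           # outgroup carries ALT: polarity flips
  states[, flip] <- 1L - states[, flip]
  og_missing <- is.na(og_calls)
  no_derived <- !og_missing &
    colSums(states == 1L, na.rm = TRUE) == 0L
  keep <- !og_missing & !no_derived
  structure(
    list(sample_ids = x$sample_ids[ing],
         positions = x$positions[keep],
         states = states[, keep, drop = FALSE],
         outgroup_id = outgroup_id,
         dropped = data.frame(
           reason = c("outgroup_missing", "no_derived_ingroup"),
           n_sites = c(sum(og_missing), sum(no_derived)))),
    class = "binary_matrix")
}

#' Constructor for a polarized binary matrix
#'
#' Builds a `binary_matrix` directly from ancestral/derived states, for
#' simulated or programmatic input.
#'
#' @param sample_ids Ingroup sample ids.
#' @param positions 1-based site positions, strictly increasing.
#' @param states Samples x sites matrix with 0 (ancestral), 1 (derived), NA.
#' @param outgroup_id Label recorded as the polarizing outgroup.
#' @return A `binary_matrix`.
#' @export
binary_matrix <- function(sample_ids, positions, states,
                          outgroup_id = "OUTGROUP") {
  states <- matrix(as.integer(states), nrow = length(sample_ids),
                   dimnames = list(sample_ids, positions))
  if (length(positions) > 1L && any(diff(as.integer(positions)) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  structure(list(sample_ids = as.character(sample_ids),
                 positions = as.integer(positions), states = states,
                 outgroup_id = outgroup_id,
                 dropped = data.frame(reason = character(0),
                                      n_sites = integer(0))),
            class = "binary_matrix")
}

# Derived-carrier index sets per site (missing calls excluded).
derived_sets <- function(bm) {
  lapply(seq_along(bm$positions), function(j) which(bm$states[, j] == 1L))
}

#' Pairwise compatibility of polarized sites
#'
#' Rooted three-gamete test: two sites are incompatible when, over samples
#' non-missing at both, their derived-carrier sets overlap without one
#' containing the other — the signature of recurrent mutation (or
#' genotyping error) under the infinite-sites assumption.
#'
#' @param bm A `binary_matrix`.
#' @return Data frame of incompatible pairs (`pos_i`, `pos_j`); zero rows
#'   when all sites are mutually compatible.
#' @export
check_pairwise_compatibility <- function(bm) {
  m <- length(bm$positions)
  out_i <- integer(0); out_j <- integer(0)
  if (m >= 2L) {
    S <- bm$states
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        ok <- !is.na(S[, i]) & !is.na(S[, j])
        a <- S[ok, i]; b <- S[ok, j]
        if (any(a == 1L & b == 1L) && any(a == 1L & b == 0L) &&
            any(a == 0L & b == 1L)) {
          out_i <- c(out_i, i); out_j <- c(out_j, j)
        }
      }
    }
  }
  data.frame(pos_i = bm$positions[out_i], pos_j = bm$positions[out_j])
}

# TRUE iff two index sets are disjoint or nested.
sets_compatible <- function(a, b) {
  ov <- length(intersect(a, b))
  ov == 0L || ov == length(a) || ov == length(b)
}

#' Build the perfect phylogeny of a compatible site set
#'
#' For mutually compatible sites the rooted perfect phylogeny is unique up
#' to the ordering within polytomies: its clades are exactly the distinct
#' derived-carrier sets.  Sites incompatible with the retained set (greedy,
#' largest carrier sets first) are set aside and placed afterwards by
#' parsimony, where they surface as recurrent.  The returned tree always
#' carries an explicit ancestor root with a single child (the ingroup
#' MRCA), so that sites derived in every sample map to the MRCA stem.
#'
#' @param bm A `binary_matrix` with at least one sample and one site.
#' @return An `snp_tree`: the topology plus per-branch mutation events from
#'   [assign_snps_to_branches()].
#' @export
build_tree <- function(bm) {
  n <- length(bm$sample_ids)
  if (n == 0L || length(bm$positions) == 0L) stop("empty binary matrix")
  ds <- derived_sets(bm)
  sig <- vapply(ds, function(s) paste(s, collapse = ","), character(1))
  uniq <- !duplicated(sig)
  usets <- ds[uniq]
  # deterministic greedy retention: big clades first, then by signature
  ord <- order(-lengths(usets), sig[uniq])
  usets <- usets[ord]
  kept <- list()
  for (s in usets) {
    if (all(vapply(kept, sets_compatible, logical(1), b = s))) {
      kept <- c(kept, list(s))
    }
  }
  phy <- perfect_phylogeny_topology(kept, bm$sample_ids)
  assign_snps_to_branches(phy, bm)
}

# Topology from a laminar family of carrier sets: tips 1..n, root = ancestor
# node with single child (ingroup MRCA); internal nodes for kept sets of
# size >= 2 (the full set is the MRCA itself).
perfect_phylogeny_topology <- function(kept, sample_ids) {
  n <- length(sample_ids)
  full <- seq_len(n)
  nodes <- Filter(function(s) length(s) >= 2L && length(s) < n, kept)
  nodes <- nodes[order(-lengths(nodes))]
  k <- length(nodes)
  # ape ids: tips 1..n, root n+1, MRCA n+2, set nodes n+2+1..n+2+k
  root_id <- n + 1L; mrca_id <- n + 2L
  node_ids <- if (k) seq.int(n + 3L, n + 2L + k) else integer(0)
  parent_of_set <- function(s) {
    best <- mrca_id; best_size <- n
    for (i in seq_len(k)) {
      t <- nodes[[i]]
      if (length(t) > length(s) && all(s %in% t) && length(t) < best_size) {
        best <- node_ids[i]; best_size <- length(t)
      }
    }
    best
  }
  edges <- matrix(c(root_id, mrca_id), ncol = 2)
  for (i in seq_len(k)) {
    edges <- rbind(edges, c(parent_of_set(nodes[[i]]), node_ids[i]))
  }
  for (tip in seq_len(n)) {
    best <- mrca_id; best_size <- n
    for (i in seq_len(k)) {
      t <- nodes[[i]]
      if (tip %in% t && length(t) < best_size) {
        best <- node_ids[i]; best_size <- length(t)
      }
    }
    edges <- rbind(edges, c(best, tip))
  }
  phy <- structure(list(edge = edges, tip.label = sample_ids,
                        Nnode = 2L + k), class = "phylo")
  stats::reorder(phy, "cladewise")
}

# --- rooted-tree helpers over an ape phylo edge matrix ------------------

tree_parent_vector <- function(phy) {
  p <- rep(NA_integer_, max(phy$edge))
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

tree_root <- function(phy) {
  setdiff(unique(phy$edge[, 1]), phy$edge[, 2])[1]
}

# internal node ids in postorder (children before parents), root last
tree_postorder <- function(phy) {
  po <- stats::reorder(phy, "postorder")
  unique(po$edge[, 1])
}

tree_children <- function(phy) {
  split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(max(phy$edge))))
}

# tip indices descending from each node (a tip descends from itself)
node_descendant_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- tree_children(phy)
  out <- integer(0); stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= ntip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  sort(out)
}

# Ensure the rooted tree has a unary ancestor root above the ingroup MRCA,
# so a site derived in all tips costs one event (on the MRCA stem).
ensure_root_stem <- function(phy) {
  root <- tree_root(phy)
  if (sum(phy$edge[, 1] == root) == 1L) return(phy)
  shift <- function(v) ifelse(v > length(phy$tip.label), v + 1L, v)
  edge <- cbind(shift(phy$edge[, 1]) + 0L, shift(phy$edge[, 2]) + 0L)
  new_root <- length(phy$tip.label) + 1L
  edge <- rbind(c(new_root, shift(root) + 0L), edge)
  out <- structure(list(edge = edge, tip.label = phy$tip.label,
                        Nnode = phy$Nnode + 1L), class = "phylo")
  stats::reorder(out, "cladewise")
}

#' Minimum mutation count of a site on a rooted tree
#'
#' Small-parsimony (Sankoff) score for one binary site with the root state
#' fixed ancestral; missing tips are unconstrained wildcards.  As in
#' [assign_snps_to_branches()], a stem branch above the ingroup MRCA is
#' assumed (added when absent), so a site derived in every tip costs one
#' change, placed on that stem.
#'
#' @param tree An ape `phylo` (rooted) or an `snp_tree`.
#' @param site_states Named vector over tip labels: 0 (ancestral),
#'   1 (derived) or NA (missing).  Unnamed vectors are taken in tip order.
#' @return Integer minimum number of state changes.
#' @export
fitch_score <- function(tree, site_states) {
  phy <- if (inherits(tree, "snp_tree")) tree$tree else tree
  st <- if (is.null(names(site_states))) site_states else
    site_states[phy$tip.label]
  phy <- ensure_root_stem(phy)
  cost <- sankoff_costs(phy, st)
  as.integer(cost[tree_root(phy), 1])
}

# DP cost table: cost[v, s+1] = min changes in subtree of v given state s.
sankoff_costs <- function(phy, tip_states) {
  ntip <- length(phy$tip.label)
  nmax <- max(phy$edge)
  cost <- matrix(0, nrow = nmax, ncol = 2)
  obs <- !is.na(tip_states)
  cost[seq_len(ntip), 1][obs & tip_states == 1L] <- Inf
  cost[seq_len(ntip), 2][obs & tip_states == 0L] <- Inf
  kids <- tree_children(phy)
  for (v in tree_postorder(phy)) {
    c0 <- 0; c1 <- 0
    for (w in kids[[v]]) {
      c0 <- c0 + min(cost[w, 1], cost[w, 2] + 1)
      c1 <- c1 + min(cost[w, 2], cost[w, 1] + 1)
    }
    cost[v, 1] <- c0; cost[v, 2] <- c1
  }
  cost
}

# Traceback of one minimum assignment; ties resolved toward the derived
# state, which pushes mutation events root-ward deterministically.
# Returns data.frame(edge_row, direction) of state-change events.
sankoff_events <- function(phy, cost) {
  root <- tree_root(phy)
  kids <- tree_children(phy)
  state <- rep(NA_integer_, max(phy$edge))
  state[root] <- 0L
  ev_edge <- integer(0); ev_dir <- character(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    s <- state[v]
    for (w in kids[[v]]) {
      keep_cost <- cost[w, s + 1L]
      flip_cost <- cost[w, 2L - s] + 1
      t <- if (flip_cost < keep_cost) 1L - s
           else if (keep_cost < flip_cost) s
           else 1L                        # tie: prefer derived
      state[w] <- t
      if (t != s) {
        row <- which(phy$edge[, 1] == v & phy$edge[, 2] == w)
        ev_edge <- c(ev_edge, row)
        ev_dir <- c(ev_dir, if (t == 1L) "anc>der" else "der>anc")
      }
      if (w > length(phy$tip.label)) stack <- c(stack, w)
    }
  }
  data.frame(edge = ev_edge, direction = ev_dir)
}

#' Assign every site to tree branches by parsimony
#'
#' Maps each polarized site onto a rooted topology with a minimum-mutation
#' (Fitch) assignment, root state fixed ancestral and missing tips free.
#' Sites needing two or more changes are flagged recurrent.  When the
#' supplied topology lacks a stem above the ingroup MRCA one is added, so
#' sites derived in every sample land on the MRCA stem with one event.
#'
#' @param tree A rooted ape `phylo` (e.g. an externally estimated topology)
#'   or an `snp_tree`; its tips must all carry data in `bm`.
#' @param bm A `binary_matrix` covering every tip.
#' @return An `snp_tree`: list with `tree` (phylo), `events` (data frame
#'   `position`, `edge`, `child`, `direction`), `site_scores` (per-site
#'   parsimony score) and `recurrent_positions`.
#' @export
assign_snps_to_branches <- function(tree, bm) {
  phy <- if (inherits(tree, "snp_tree")) tree$tree else tree
  missing_tips <- setdiff(phy$tip.label, bm$sample_ids)
  if (length(missing_tips)) {
    stop("tree tips without data: ", paste(missing_tips, collapse = ", "))
  }
  phy <- ensure_root_stem(phy)
  m <- length(bm$positions)
  ev_pos <- vector("list", m)
  scores <- integer(m)
  for (j in seq_len(m)) {
    st <- bm$states[, j][phy$tip.label]
    cost <- sankoff_costs(phy, st)
    scores[j] <- as.integer(cost[tree_root(phy), 1])
    ev <- sankoff_events(phy, cost)
    if (nrow(ev)) ev$position <- bm$positions[j]
    ev_pos[[j]] <- ev
  }
  events <- do.call(rbind, ev_pos[vapply(ev_pos, nrow, integer(1)) > 0])
  if (is.null(events)) {
    events <- data.frame(edge = integer(0), direction = character(0),
                         position = integer(0))
  }
  events$child <- phy$edge[events$edge, 2]
  events <- events[, c("position", "edge", "child", "direction")]
  rownames(events) <- NULL
  structure(list(tree = phy, events = events,
                 site_scores = stats::setNames(scores, bm$positions),
                 recurrent_positions = bm$positions[scores >= 2L]),
            class = "snp_tree")
}

#' @export
print.snp_tree <- function(x, ...) {
  cat(sprintf(
    "snp_tree: %d tips, %d internal nodes, %d mutation events (%d recurrent sites)\n",
    length(x$tree$tip.label), x$tree$Nnode, nrow(x$events),
    length(x$recurrent_positions)))
  invisible(x)
}

#' Per-branch SNP table
#'
#' One row per edge of the tree: its endpoints, the number of assigned
#' mutation events, their positions, and whether any is a flagged
#' recurrent site.  Sites assigned to the same branch form an equivalence
#' class (they cannot be ordered by the sample set).
#'
#' @param st An `snp_tree`.
#' @return Data frame with columns `edge`, `parent`, `child`, `n_snps`,
#'   `positions`, `recurrent_flag`.
#' @export
branch_snp_table <- function(st) {
  phy <- st$tree
  ne <- nrow(phy$edge)
  counts <- integer(ne); poss <- character(ne); rec <- logical(ne)
  for (e in seq_len(ne)) {
    p <- st$events$position[st$events$edge == e]
    counts[e] <- length(p)
    poss[e] <- paste(sort(p), collapse = ",")
    rec[e] <- any(p %in% st$recurrent_positions)
  }
  data.frame(edge = seq_len(ne), parent = phy$edge[, 1],
             child = phy$edge[, 2], n_snps = counts, positions = poss,
             recurrent_flag = rec)
}

# number of events on each edge (vector over edge rows)
edge_event_counts <- function(st) {
  tabulate(st$events$edge, nbins = nrow(st$tree$edge))
}

#' Rooted clades of a tree as tip-label sets
#'
#' Utility for topology comparison: the set of tip-label groups descending
#' from each internal node (trivial full set and singletons excluded).
#'
#' @param phy A rooted ape `phylo` or `snp_tree`.
#' @return List of character vectors, each sorted; unique.
#' @export
tree_clades <- function(phy) {
  if (inherits(phy, "snp_tree")) phy <- phy$tree
  ntip <- length(phy$tip.label)
  nodes <- unique(phy$edge[, 1])
  cl <- lapply(nodes, function(v) sort(phy$tip.label[node_descendant_tips(phy, v)]))
  cl <- cl[lengths(cl) >= 2 & lengths(cl) < ntip]
  unique(cl)
}
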