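#' Mutation rate with a 95% confidence interval
#'
#' Defaults are the Y-chromosome single-nucleotide rate commonly used for
#' haplogroup dating: 0.76e-9 mutations per site per year, 95% CI
#' 0.67e-9 to 0.86e-9.
#'
#' @param central Point rate, mutations per site per year.
#' @param ci_low,ci_high 95% interval bounds, same units.
#' @return A `mutation_rate` list.
#' @export
mutation_rate <- function(central = 0.76e-9, ci_low = 0.67e-9,
                          ci_high = 0.86e-9) {
  if (!(ci_low > 0 && ci_low <= central && central <= ci_high)) {
    stop("require 0 < ci_low <= central <= ci_high")
  }
  structure(list(central = central, ci_low = ci_low, ci_high = ci_high),
            class = "mutation_rate")
}

#' Rho statistic of a node
#'
#' The mean number of mutation events separating each eligible descendant
#' tip from the node: for every tip, events on the branches of the
#' tip-to-node path are summed, and rho is the arithmetic mean over tips.
#'
#' @param st An `snp_tree` with branch assignments.
#' @param node Internal node id (ape numbering) or a tip.
#' @param eligible_tips Tip labels entering the mean; defaults to all
#'   descendant tips.  Must be non-empty descendants of `node`.
#' @return List with `rho` and `n_tips`.
#' @export
compute_rho <- function(st, node, eligible_tips = NULL) {
  phy <- st$tree
  parent <- tree_parent_vector(phy)
  counts <- edge_event_counts(st)
  edge_of_child <- match(seq_len(max(phy$edge)), phy$edge[, 2])
  desc <- node_descendant_tips(phy, node)
  tips <- if (is.null(eligible_tips)) desc else
    match(eligible_tips, phy$tip.label)
  if (any(is.na(tips))) stop("eligible tip not found in tree")
  if (!length(tips) || !all(tips %in% desc)) {
    stop("eligible tips must be a non-empty subset of the node's descendants")
  }
  path_sum <- vapply(tips, function(tip) {
    s <- 0; v <- tip
    while (v != node) {
      s <- s + counts[edge_of_child[v]]
      v <- parent[v]
    }
    s
  }, numeric(1))
  list(rho = mean(path_sum), n_tips = length(tips))
}

#' Convert rho to calendar time with rate-interval bounds
#'
#' `T = rho / (L * mu)` years; the 95% bounds come from evaluating the same
#' expression at the rate interval's endpoints (high rate gives the lower
#' time bound).  No sampling variance of rho enters this interval; see
#' [sigma_rho()] for the star-genealogy standard error, reported separately.
#'
#' @param rho Mean mutation count (dimensionless, >= 0).
#' @param L Callable sequence length in base pairs (> 0).
#' @param rate A [mutation_rate()].
#' @param node_id,n_tips Optional bookkeeping carried into the result.
#' @return A one-row data frame: `node_id`, `n_tips`, `rho`, `t_years`,
#'   `t_low_years`, `t_high_years`.
#' @export
rho_to_time <- function(rho, L, rate = mutation_rate(), node_id = NA,
                        n_tips = NA_integer_) {
  if (L <= 0) stop("callable length L must be positive")
  if (rho < 0) stop("rho must be non-negative")
  data.frame(node_id = node_id, n_tips = n_tips, rho = rho,
             t_years = rho / (L * rate$central),
             t_low_years = rho / (L * rate$ci_high),
             t_high_years = rho / (L * rate$ci_low))
}

# round half away from zero at `digits` decimals (R's round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Rescale a point date by mutation-rate bounds
#'
#' Reproduces printed confidence bounds from a published point estimate:
#' `t_low = t * central / ci_high`, `t_high = t * central / ci_low`,
#' rounded half away from zero to `decimals` places.  This is the rate-only
#' interval: its width is proportional to the point date.
#'
#' @param t_point_kya Point estimate in kya (>= 0).
#' @param rate A [mutation_rate()].
#' @param decimals Decimal places of the printed value (default 1).
#' @return Named numeric vector `c(t_low_kya, t_high_kya)`.
#' @export
rescale_by_rate_bounds <- function(t_point_kya, rate = mutation_rate(),
                                   decimals = 1) {
  if (t_point_kya < 0) stop("t_point_kya must be non-negative")
  c(t_low_kya = round_half_up(t_point_kya * rate$central / rate$ci_high,
                              decimals),
    t_high_kya = round_half_up(t_point_kya * rate$central / rate$ci_low,
                               decimals))
}

#' Star-genealogy standard error of rho
#'
#' `sqrt(rho / n_tips)`: the classical Poisson-based standard error under a
#' star genealogy.  Reported for inspection; it never enters the primary
#' rate-interval bounds.
#'
#' @param rho Mean mutation count.
#' @param n_tips Number of tips contributing to the mean.
#' @return Numeric standard error.
#' @export
sigma_rho <- function(rho, n_tips) {
  if (n_tips <= 0) stop("n_tips must be positive")
  sqrt(rho / n_tips)
}

#' Date every internal node of an SNP tree
#'
#' Computes rho and calendar time per internal node, restricted to eligible
#' tips.  When `high_coverage_only` is set, only tips whose metadata flags
#' them as complete (high-coverage) sequences enter rho — incomplete
#' sequences under-count mutations and would bias dates young.  Nodes with
#' fewer than two eligible descendant tips are reported undated rather
#' than dropped.
#'
#' @param st An `snp_tree` with branch assignments.
#' @param meta Metadata data frame (`sample`, `population`,
#'   `high_coverage`); may be `NULL` when `high_coverage_only = FALSE`.
#' @param mask A [region_mask()] supplying the callable length `L`, or a
#'   numeric length in bp.
#' @param rate A [mutation_rate()].
#' @param high_coverage_only Restrict rho to high-coverage tips
#'   (default `TRUE`).
#' @return Data frame, one row per internal node: `node_id`, `dated`,
#'   `n_tips`, `rho`, `sigma_rho`, `t_years`, `t_low_years`,
#'   `t_high_years`, `t_kya`, `t_low_kya`, `t_high_kya` (kya columns
#'   formatted at printing precision: one decimal >= 1 kya, two below).
#' @export
date_all_nodes <- function(st, meta = NULL, mask, rate = mutation_rate(),
                           high_coverage_only = TRUE) {
  phy <- st$tree
  L <- if (inherits(mask, "region_mask")) mask$effective_length_bp else
    as.numeric(mask)
  ntip <- length(phy$tip.label)
  eligible <- phy$tip.label
  if (high_coverage_only) {
    if (is.null(meta)) stop("high_coverage_only requires metadata")
    eligible <- meta$sample[meta$high_coverage]
  }
  nodes <- sort(unique(phy$edge[, 1]))
  rows <- lapply(nodes, function(v) {
    desc <- phy$tip.label[node_descendant_tips(phy, v)]
    el <- intersect(desc, eligible)
    if (length(el) < 2L) {
      return(data.frame(node_id = v, dated = FALSE, n_tips = length(el),
                        rho = NA_real_, sigma_rho = NA_real_,
                        t_years = NA_real_, t_low_years = NA_real_,
                        t_high_years = NA_real_))
    }
    r <- compute_rho(st, v, el)
    tt <- rho_to_time(r$rho, L, rate, node_id = v, n_tips = r$n_tips)
    data.frame(node_id = v, dated = TRUE, n_tips = r$n_tips, rho = r$rho,
               sigma_rho = sigma_rho(r$rho, r$n_tips),
               t_years = tt$t_years, t_low_years = tt$t_low_years,
               t_high_years = tt$t_high_years)
  })
  out <- do.call(rbind, rows)
  out$t_kya <- round_kya(out$t_years / 1000)
  out$t_low_kya <- round_kya(out$t_low_years / 1000)
  out$t_high_kya <- round_kya(out$t_high_years / 1000)
  out
}

# printing precision for kya values: one decimal at >= 1 kya, two below
round_kya <- function(x) {
  ifelse(is.na(x), NA_real_,
         ifelse(abs(x) >= 1, round_half_up(x, 1), round_half_up(x, 2)))
}

#' Format a dated node the way haplogroup studies print it
#' @param t_kya Point estimate in kya.
#' @param t_low_kya,t_high_kya Interval bounds in kya.
#' @return Character like `"15.4 kya (13.6-17.4)"`.
#' @export
format_kya <- function(t_kya, t_low_kya, t_high_kya) {
  fmt1 <- function(x) {
    d <- ifelse(abs(x) >= 1, 1L, 2L)
    vapply(seq_along(x), function(i) {
      formatC(round_half_up(x[i], d[i]), format = "f", digits = d[i])
    }, character(1))
  }
  sprintf("%s kya (%s-%s)", fmt1(t_kya), fmt1(t_low_kya), fmt1(t_high_kya))
}
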