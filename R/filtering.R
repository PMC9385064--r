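#' Filter configuration
#'
#' Thresholds of the site/genotype quality cascade.  Defaults follow common
#' haploid Y-chromosome practice: per-genotype depth below 2 is unreliable,
#' sites missing in more than 10% of samples are dropped (strict `>`, so a
#' missingness of exactly the threshold is kept), indels and off-mask sites
#' are excluded, and monomorphic sites carry no phylogenetic signal.
#'
#' @param min_depth Minimum per-genotype read depth; calls below it are set
#'   missing (default 2).
#' @param max_missingness Maximum tolerated fraction of missing calls per
#'   site, in `[0, 1]` (default 0.1); strictly greater removes the site.
#' @param drop_indels Remove indel-flagged sites (default `TRUE`).
#' @param require_mask Remove sites outside the region mask (default `TRUE`).
#' @param drop_monomorphic Remove sites invariant over non-missing calls
#'   (default `TRUE`).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 2L, max_missingness = 0.1,
                          drop_indels = TRUE, require_mask = TRUE,
                          drop_monomorphic = TRUE) {
  if (min_depth < 0) stop("min_depth must be non-negative")
  if (max_missingness < 0 || max_missingness > 1) {
    stop("max_missingness must lie in [0, 1]")
  }
  structure(list(min_depth = as.integer(min_depth),
                 max_missingness = max_missingness,
                 drop_indels = isTRUE(drop_indels),
                 require_mask = isTRUE(require_mask),
                 drop_monomorphic = isTRUE(drop_monomorphic)),
            class = "filter_config")
}

#' Set low-depth genotypes missing
#'
#' Converts every call whose read depth is below `min_depth` to missing.
#' No site is removed at this stage; site removal is governed by the
#' missingness filter, keeping the two stages composable.  When no depths
#' are recorded the matrix is returned unchanged with a warning.
#'
#' @param x A [genotype_matrix()].
#' @param min_depth Minimum acceptable depth (default 2).
#' @return The matrix with low-depth calls set missing.
#' @export
apply_depth_filter <- function(x, min_depth = 2L) {
  if (min_depth < 0) stop("min_depth must be non-negative")
  if (is.null(x$depths)) {
    warning("no depths recorded; depth filter is a no-op")
    return(x)
  }
  low <- !is.na(x$depths) & x$depths < min_depth
  x$calls[low] <- NA_integer_
  x
}

#' Remove high-missingness sites
#'
#' Sites whose missing fraction exceeds `max_missingness` (strict
#' inequality) are removed; a site at exactly the threshold is kept.
#'
#' @param x A [genotype_matrix()].
#' @param max_missingness Tolerated missing fraction (default 0.1).
#' @return The matrix restricted to passing sites.
#' @export
apply_missingness_filter <- function(x, max_missingness = 0.1) {
  frac <- colMeans(is.na(x$calls))
  subset_sites(x, frac <= max_missingness)
}

#' Remove indel sites and sites outside the callable mask
#' @param x A [genotype_matrix()].
#' @param mask Optional [region_mask()]; when `NULL` only indels are removed.
#' @return The matrix restricted to SNV sites inside the mask.
#' @export
drop_indels_and_masked <- function(x, mask = NULL) {
  keep <- !x$is_indel
  if (!is.null(mask)) keep <- keep & mask_contains(mask, x$positions)
  subset_sites(x, keep)
}

#' Remove monomorphic sites
#'
#' A site is monomorphic when all its non-missing calls are identical
#' (all-missing sites count as monomorphic too).
#'
#' @param x A [genotype_matrix()].
#' @return The matrix restricted to polymorphic sites.
#' @export
drop_monomorphic <- function(x) {
  poly <- vapply(seq_len(n_sites(x)), function(j) {
    u <- unique(x$calls[, j])
    length(u[!is.na(u)]) > 1L
  }, logical(1))
  subset_sites(x, poly)
}

#' Run the full filter cascade
#'
#' Stages run in order: mask/indel removal, depth-to-missing conversion,
#' missingness site removal, monomorphic site removal.  The monomorphic
#' stage runs last because the depth stage can render sites monomorphic.
#' The cascade is idempotent: re-running it on its own output changes
#' nothing.
#'
#' @param x A [genotype_matrix()].
#' @param mask Optional [region_mask()].
#' @param config A [filter_config()].
#' @return A list with elements `matrix` (filtered [genotype_matrix()]) and
#'   `report` (data frame of per-stage `sites_in`, `sites_removed`,
#'   `genotypes_set_missing`).
#' @export
run_filter_cascade <- function(x, mask = NULL, config = filter_config()) {
  stages <- character(0); s_in <- integer(0); s_rm <- integer(0); g_na <- integer(0)
  note <- function(stage, before, after, set_missing = 0L) {
    stages <<- c(stages, stage)
    s_in <<- c(s_in, n_sites(before))
    s_rm <<- c(s_rm, n_sites(before) - n_sites(after))
    g_na <<- c(g_na, as.integer(set_missing))
  }

  if (config$drop_indels || (config$require_mask && !is.null(mask))) {
    y <- drop_indels_and_masked(
      x, if (config$require_mask) mask else NULL)
    if (!config$drop_indels) {  # mask only
      keep <- if (is.null(mask)) rep(TRUE, n_sites(x)) else
        mask_contains(mask, x$positions)
      y <- subset_sites(x, keep)
    }
    note("mask_indel", x, y); x <- y
  }
  if (!is.null(x$depths) && config$min_depth > 0L) {
    before_na <- sum(is.na(x$calls))
    y <- apply_depth_filter(x, config$min_depth)
    note("depth", x, y, sum(is.na(y$calls)) - before_na); x <- y
  }
  if (config$max_missingness < 1) {
    y <- apply_missingness_filter(x, config$max_missingness)
    note("missingness", x, y); x <- y
  }
  if (config$drop_monomorphic) {
    y <- drop_monomorphic(x)
    note("monomorphic", x, y); x <- y
  }
  report <- data.frame(stage = stages, sites_in = s_in,
                       sites_removed = s_rm, genotypes_set_missing = g_na)
  list(matrix = x, report = report)
}
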