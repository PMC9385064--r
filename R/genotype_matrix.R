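#' Haploid genotype matrix
#'
#' The central container for multi-sample haploid SNV calls: a samples x
#' sites matrix of calls (`0` = reference allele, `1` = alternate allele,
#' `NA` = missing), together with 1-based genomic positions, the two alleles
#' per site, optional per-genotype read depths and a per-site indel flag.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param positions Integer vector of 1-based positions, strictly increasing.
#' @param ref Character vector of reference alleles (one per site).
#' @param alt Character vector of alternate alleles (one per site).
#' @param calls Integer matrix, samples x sites, values in \{0, 1, NA\}.
#' @param depths Optional integer matrix of per-genotype read depths
#'   (same shape as `calls`), or `NULL` when depth is unknown.
#' @param is_indel Logical vector flagging indel sites; defaults to all
#'   `FALSE` (pure SNV matrix).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, positions, ref, alt, calls,
                            depths = NULL, is_indel = NULL) {
  sample_ids <- as.character(sample_ids)
  positions <- as.integer(positions)
  n <- length(sample_ids)
  m <- length(positions)
  if (n == 0L) stop("genotype_matrix requires at least one sample")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (m > 1L && any(diff(positions) <= 0L)) {
    stop("positions must be strictly increasing (no duplicates)")
  }
  if (length(ref) != m || length(alt) != m) {
    stop("ref/alt must have one allele per site")
  }
  if (any(ref == alt)) stop("ref and alt alleles must differ at every site")
  calls <- matrix(as.integer(calls), nrow = n, ncol = m)
  if (!all(calls %in% c(0L, 1L, NA_integer_))) {
    stop("calls must be 0 (REF), 1 (ALT) or NA (missing)")
  }
  if (!is.null(depths)) {
    depths <- matrix(as.integer(depths), nrow = n, ncol = m)
    if (any(depths < 0L, na.rm = TRUE)) stop("depths must be non-negative")
    dimnames(depths) <- list(sample_ids, positions)
  }
  if (is.null(is_indel)) is_indel <- rep(FALSE, m)
  dimnames(calls) <- list(sample_ids, positions)
  structure(
    list(sample_ids = sample_ids, positions = positions,
         ref = as.character(ref), alt = as.character(alt),
         calls = calls, depths = depths, is_indel = as.logical(is_indel)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites\n",
              length(x$sample_ids), length(x$positions)))
  cat(sprintf("  missing calls: %d; depths: %s; indel sites: %d\n",
              sum(is.na(x$calls)),
              if (is.null(x$depths)) "absent" else "present",
              sum(x$is_indel)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) {
  c(length(x$sample_ids), length(x$positions))
}

#' Number of sites in a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Integer site count.
#' @export
n_sites <- function(x) length(x$positions)

#' Number of samples in a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) length(x$sample_ids)

# Keep a subset of sites (logical or integer index), preserving all slots.
subset_sites <- function(x, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  genotype_matrix(
    sample_ids = x$sample_ids,
    positions = x$positions[idx],
    ref = x$ref[idx], alt = x$alt[idx],
    calls = x$calls[, idx, drop = FALSE],
    depths = if (is.null(x$depths)) NULL else x$depths[, idx, drop = FALSE],
    is_indel = x$is_indel[idx])
}
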