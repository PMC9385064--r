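#' Partition variants relative to a clade
#'
#' Classifies every polarized site with at least one derived carrier by its
#' relation to a sample set (the clade under study):
#' \describe{
#'   \item{defining}{derived in all non-missing clade members, ancestral in
#'     all non-missing outsiders, with at least one non-missing call on
#'     each side (the quorum); defining SNPs of a clade are mutually
#'     equivalent — they sit on the clade's stem branch.}
#'   \item{internal}{derived in a proper non-empty subset of the clade and
#'     in no outsider — sub-lineage structure within the clade.}
#'   \item{private}{the subset of internal with exactly one carrier.}
#'   \item{excluded}{derived in at least one sample outside the clade.}
#'   \item{unresolved}{would be defining by the non-missing calls but fails
#'     the quorum (no informative call on one side).}
#' }
#' A missing call neither confirms nor denies carrier status.
#'
#' @param bm A `binary_matrix`.
#' @param clade_samples Non-empty character vector of sample ids, a subset
#'   of the matrix samples.
#' @return A `clade_partition`: list with the clade, a per-site data frame
#'   (`position`, `class`, `n_carriers_in`, `carriers`) and position
#'   vectors `defining`, `internal`, `private`, `excluded`, `unresolved`.
#' @export
clade_variant_partition <- function(bm, clade_samples) {
  if (!length(clade_samples)) stop("empty clade")
  idx_in <- match(clade_samples, bm$sample_ids)
  if (any(is.na(idx_in))) {
    stop("clade samples absent from matrix: ",
         paste(clade_samples[is.na(idx_in)], collapse = ", "))
  }
  idx_out <- setdiff(seq_along(bm$sample_ids), idx_in)
  m <- length(bm$positions)
  cls <- character(m); ncar <- integer(m); carriers <- character(m)
  for (j in seq_len(m)) {
    s_in <- bm$states[idx_in, j]
    s_out <- bm$states[idx_out, j]
    der_in <- sum(s_in == 1L, na.rm = TRUE)
    der_out <- sum(s_out == 1L, na.rm = TRUE)
    obs_in <- sum(!is.na(s_in)); obs_out <- sum(!is.na(s_out))
    ncar[j] <- der_in
    carriers[j] <- paste(bm$sample_ids[c(idx_in, idx_out)[
      which(c(s_in, s_out) == 1L)]], collapse = ",")
    cls[j] <- if (der_out > 0L) "excluded"
    else if (der_in == 0L) "no_derived_in_clade"
    else if (obs_in > 0L && der_in == obs_in) {
      if (obs_out > 0L) "defining" else "unresolved"
    } else if (der_in == 1L) "private"
    else "internal"
  }
  per_site <- data.frame(position = bm$positions, class = cls,
                         n_carriers_in = ncar, carriers = carriers)
  structure(list(
    clade_samples = clade_samples,
    sites = per_site,
    defining = bm$positions[cls == "defining"],
    internal = bm$positions[cls %in% c("internal", "private")],
    private = bm$positions[cls == "private"],
    excluded = bm$positions[cls == "excluded"],
    unresolved = bm$positions[cls == "unresolved"]),
    class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf(
    "clade_partition: %d samples; %d defining, %d internal (%d private), %d excluded, %d unresolved\n",
    length(x$clade_samples), length(x$defining), length(x$internal),
    length(x$private), length(x$excluded), length(x$unresolved)))
  invisible(x)
}

#' Group a partition's positions into branch equivalence classes
#'
#' Two positions are equivalent when the phylogeny assigns them to the same
#' branch: they separate the same samples and cannot be ordered in time.
#' The defining SNPs of a true tree clade form one class on its stem.
#'
#' @param partition A `clade_partition` (or any vector of positions).
#' @param st An `snp_tree` whose events cover the positions.
#' @return Named list: one element per branch (`edge_<row>`), each a sorted
#'   vector of positions.
#' @export
equivalence_classes <- function(partition, st) {
  pos <- if (inherits(partition, "clade_partition")) {
    c(partition$defining, partition$internal)
  } else as.integer(partition)
  ev <- st$events[st$events$position %in% pos, ]
  if (!nrow(ev)) return(list())
  sp <- split(ev$position, ev$edge)
  stats::setNames(lapply(sp, function(p) sort(unique(p))),
                  paste0("edge_", names(sp)))
}

#' Check positions against a catalog of known SNPs
#'
#' A position is novel iff absent from the catalog; known positions are
#' reported with their catalog names.
#'
#' @param partition A `clade_partition`, or a vector of positions.
#' @param catalog An `snp_catalog` from [read_snp_catalog()] (may have zero
#'   rows).
#' @return A `novel_snp_set`: list with `novel` (positions), `known`
#'   (data frame `position`, `name`) and empty `names` to be filled by
#'   [name_novel()].
#' @export
novelty_check <- function(partition, catalog) {
  pos <- if (inherits(partition, "clade_partition")) {
    sort(unique(c(partition$defining, partition$internal)))
  } else sort(unique(as.integer(partition)))
  hit <- match(pos, catalog$pos)
  structure(list(
    novel = pos[is.na(hit)],
    known = data.frame(position = pos[!is.na(hit)],
                       name = catalog$name[hit[!is.na(hit)]]),
    names = character(0)),
    class = "novel_snp_set")
}

#' Assign sequential names to novel SNPs
#'
#' Names are `prefix` plus an increasing index, ordered by genomic
#' position from `start_index` — deterministic for a given input.
#'
#' @param novel A `novel_snp_set` from [novelty_check()].
#' @param prefix Name stem (e.g. `"GMP"`).
#' @param start_index First index used (default 1).
#' @return The set with `names` filled (named by position).
#' @export
name_novel <- function(novel, prefix = "GMP", start_index = 1L) {
  pos <- sort(novel$novel)
  if (!length(pos)) {
    novel$names <- character(0)
    return(novel)
  }
  idx <- seq.int(start_index, length.out = length(pos))
  novel$names <- stats::setNames(paste0(prefix, idx), pos)
  novel
}
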