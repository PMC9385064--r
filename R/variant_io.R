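#' Read a multi-sample haploid VCF into a genotype matrix
#'
#' Genotypes are interpreted haploid: `0` is the reference allele, `1` the
#' alternate, `.` missing.  Diploid-coded homozygous calls (`0/0`, `1/1`)
#' are collapsed to their haploid state; heterozygous calls, which cannot
#' occur on the haploid Y and indicate calling artefacts, are set missing
#' and counted in the QC attribute.  Multi-allelic records are split into
#' biallelic sites; where splitting would duplicate a position, the
#' alternate allele with the most carriers is retained and the discarded
#' alternatives counted.  Per-genotype read depth is taken from the `DP`
#' FORMAT field when present.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param mask Optional [region_mask()]; records outside it are excluded.
#' @return A [genotype_matrix()] with a `qc` attribute listing
#'   `het_set_missing`, `multiallelic_dropped` and `masked_out` counts.
#' @export
read_haploid_vcf <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) stop("VCF contains zero samples")
  sample_ids <- colnames(gt_raw)[-1]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- if (any(grepl("DP", gt_raw[, 1]))) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else NULL

  n_het <- 0L
  n_multi_dropped <- 0L

  # expand records: one row per (record, alt allele)
  rec_list <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    g <- gt[i, ]
    # collapse diploid homozygotes; flag heterozygotes
    parts <- strsplit(ifelse(is.na(g), ".", g), "[/|]")
    hap <- vapply(parts, function(p) {
      p <- p[p != ""]
      if (!length(p) || all(p == ".")) return(NA_character_)
      u <- unique(p[p != "."])
      if (length(u) == 1L) u else "HET"
    }, character(1))
    n_het <- n_het + sum(hap == "HET", na.rm = TRUE)
    hap[hap == "HET"] <- NA_character_
    per_alt <- lapply(seq_along(alts), function(k) {
      calls <- ifelse(is.na(hap), NA_integer_,
                      ifelse(hap == "0", 0L,
                             ifelse(hap == as.character(k), 1L, NA_integer_)))
      list(pos = pos[i], ref = ref[i], alt = alts[k], calls = calls,
           depth = if (is.null(dp)) NULL else dp[i, ],
           carriers = sum(calls == 1L, na.rm = TRUE))
    })
    if (length(per_alt) > 1L) {
      keep <- which.max(vapply(per_alt, `[[`, numeric(1), "carriers"))
      n_multi_dropped <- n_multi_dropped + length(per_alt) - 1L
      per_alt <- per_alt[keep]
    }
    rec_list[[i]] <- per_alt[[1]]
  }

  pos_all <- vapply(rec_list, `[[`, numeric(1), "pos")
  n_masked <- 0L
  keep <- rep(TRUE, length(rec_list))
  if (!is.null(mask)) {
    keep <- mask_contains(mask, pos_all)
    n_masked <- sum(!keep)
  }
  # duplicate positions after splitting cannot be represented; keep first
  keep <- keep & !duplicated(pos_all)
  rec_list <- rec_list[keep]
  if (!length(rec_list)) stop("no usable sites after mask/duplicate handling")
  ord <- order(vapply(rec_list, `[[`, numeric(1), "pos"))
  rec_list <- rec_list[ord]

  calls <- vapply(rec_list, `[[`, integer(length(sample_ids)), "calls")
  calls <- matrix(calls, nrow = length(sample_ids))
  depths <- if (is.null(dp)) NULL else {
    d <- vapply(rec_list, function(r) as.integer(r$depth),
                integer(length(sample_ids)))
    matrix(d, nrow = length(sample_ids))
  }
  refs <- vapply(rec_list, `[[`, character(1), "ref")
  alts <- vapply(rec_list, `[[`, character(1), "alt")
  gm <- genotype_matrix(
    sample_ids = sample_ids,
    positions = vapply(rec_list, `[[`, numeric(1), "pos"),
    ref = refs, alt = alts, calls = calls, depths = depths,
    is_indel = nchar(refs) > 1L | nchar(alts) > 1L)
  attr(gm, "qc") <- list(het_set_missing = n_het,
                         multiallelic_dropped = n_multi_dropped,
                         masked_out = n_masked)
  gm
}

#' Write a genotype matrix as a haploid VCF
#'
#' The inverse of [read_haploid_vcf()]: emits one biallelic record per site
#' with haploid `GT` (and `DP` when depths are present).
#'
#' @param x A [genotype_matrix()].
#' @param path Output path.
#' @param seqname CHROM value for all records.
#' @return `path`, invisibly.
#' @export
write_haploid_vcf <- function(x, path, seqname = "chrY") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", seqname),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x$sample_ids), collapse = "\t"), con)
  has_dp <- !is.null(x$depths)
  fmt <- if (has_dp) "GT:DP" else "GT"
  for (j in seq_along(x$positions)) {
    g <- ifelse(is.na(x$calls[, j]), ".", as.character(x$calls[, j]))
    if (has_dp) {
      d <- ifelse(is.na(x$depths[, j]), ".", as.character(x$depths[, j]))
      g <- paste(g, d, sep = ":")
    }
    writeLines(paste(c(seqname, x$positions[j], ".", x$ref[j], x$alt[j],
                       ".", "PASS", ".", fmt, g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the variable sites of a genotype matrix as FASTA
#'
#' Emits one record per sample whose sequence holds only the variable
#' (non-monomorphic) sites, REF/ALT as their nucleotides and missing calls
#' as `missing_char` — the variable-site alignment consumed by tree search
#' programs.
#'
#' @param x A [genotype_matrix()] with at least one site.
#' @param path Output path.
#' @param missing_char Character emitted for missing calls (default `"N"`).
#' @return Invisibly, the number of variable sites written.
#' @export
write_variable_sites_fasta <- function(x, path, missing_char = "N") {
  if (n_sites(x) == 0L) stop("empty matrix")
  variable <- vapply(seq_len(n_sites(x)), function(j) {
    u <- unique(x$calls[, j])
    length(u[!is.na(u)]) > 1L
  }, logical(1))
  idx <- which(variable)
  seqs <- matrix(missing_char, nrow = n_samples(x), ncol = length(idx),
                 dimnames = list(x$sample_ids, NULL))
  for (k in seq_along(idx)) {
    j <- idx[k]
    seqs[x$calls[, j] %in% 0L, k] <- x$ref[j]
    seqs[x$calls[, j] %in% 1L, k] <- x$alt[j]
  }
  ape::write.dna(seqs, path, format = "fasta", colsep = "", colw = 10000L)
  invisible(length(idx))
}

#' Read a SNP catalog (ISOGG-style TSV)
#'
#' Columns `name`, `pos`, `anc`, `der`: the named, already-known SNPs
#' against which novelty is assessed.
#'
#' @param path Path to a tab-separated catalog.
#' @return A data frame of class `snp_catalog`.
#' @export
read_snp_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer",
                                         "character", "character"))
  need <- c("name", "pos", "anc", "der")
  if (!all(need %in% names(df))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$pos)) stop("duplicate catalog positions")
  if (any(nchar(df$anc) != 1L) || any(nchar(df$der) != 1L)) {
    stop("catalog alleles must be single nucleotides")
  }
  class(df) <- c("snp_catalog", "data.frame")
  df
}

#' Read sample metadata (TSV)
#'
#' Columns `sample`, `population`, `high_coverage`; the `high_coverage`
#' flag marks complete sequences eligible for node dating.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A data frame with one row per sample.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "logical"))
  need <- c("sample", "population", "high_coverage")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in metadata")
  df
}

#' Check that metadata covers every matrix sample
#' @param x A [genotype_matrix()].
#' @param meta Metadata data frame from [read_sample_meta()].
#' @return `TRUE` invisibly; errors if a sample lacks metadata.
#' @export
validate_sample_meta <- function(x, meta) {
  missing <- setdiff(x$sample_ids, meta$sample)
  if (length(missing)) {
    stop("metadata missing for samples: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a rooted Newick tree
#' @param path Path to a Newick file.
#' @return An `ape` `phylo` object (polytomies preserved).
#' @export
read_tree_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("cannot parse Newick file: ", path)
  if (any(is.na(tr$tip.label)) || any(tr$tip.label == "")) {
    stop("Newick tree has unlabeled tips")
  }
  tr
}

#' Write a tree as Newick
#' @param tree An `ape` `phylo` object or an `snp_tree` (its topology is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  if (inherits(tree, "snp_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
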