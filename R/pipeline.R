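#' Pipeline configuration
#'
#' Bundles the inputs and parameters of an end-to-end run: the joint
#' haploid VCF, the callable-region BED, sample metadata, an optional SNP
#' catalog, an optional externally estimated rooted Newick topology (when
#' absent the perfect-phylogeny builder is used), the outgroup id, filter
#' and rate settings, and the clades to partition.
#'
#' @param vcf Path to the multi-sample haploid VCF.
#' @param mask_bed Path to the callable-region BED (or `NULL`).
#' @param meta_tsv Path to sample metadata TSV.
#' @param catalog_tsv Optional path to a known-SNP catalog TSV.
#' @param newick Optional path to a rooted Newick topology.
#' @param outgroup_id Outgroup sample id (must be in the VCF).
#' @param filter A [filter_config()].
#' @param rate A [mutation_rate()].
#' @param clades Named list of sample-id vectors, or `"tree"` to partition
#'   every internal clade of the estimated tree.
#' @param out_dir Output directory for the report TSVs.
#' @param high_coverage_only Restrict dating to high-coverage tips.
#' @param seed Integer seed recorded in the run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, mask_bed = NULL, meta_tsv, catalog_tsv = NULL,
                            newick = NULL, outgroup_id,
                            filter = filter_config(),
                            rate = mutation_rate(), clades = "tree",
                            out_dir, high_coverage_only = TRUE, seed = 1L) {
  for (p in c(vcf, mask_bed, meta_tsv, catalog_tsv, newick)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(vcf = vcf, mask_bed = mask_bed, meta_tsv = meta_tsv,
                 catalog_tsv = catalog_tsv, newick = newick,
                 outgroup_id = outgroup_id, filter = filter, rate = rate,
                 clades = clades, out_dir = out_dir,
                 high_coverage_only = high_coverage_only,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Read -> filter -> polarize -> tree (build or load) -> branch assignment
#' -> dating -> clade partition -> novelty, writing one TSV per report to
#' `out_dir` (`filter_report.tsv`, `branch_snps.tsv`, `dating.tsv`,
#' `clade_partition.tsv`, `run_log.tsv`).  Identical config and seed give
#' byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` bundle: the intermediate objects and the
#'   report data frames, invisibly printable via [summarize_run()].
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  mask <- stage("mask", if (is.null(config$mask_bed)) NULL else
    read_region_mask(config$mask_bed))
  gm <- stage("read_vcf", read_haploid_vcf(config$vcf, mask = NULL))
  meta <- stage("metadata", {
    m <- read_sample_meta(config$meta_tsv)
    validate_sample_meta(gm, m)
    m
  })
  filt <- stage("filter", run_filter_cascade(gm, mask, config$filter))
  bm <- stage("polarize", polarize(filt$matrix, config$outgroup_id))
  st <- stage("tree", {
    if (is.null(config$newick)) build_tree(bm)
    else assign_snps_to_branches(read_tree_newick(config$newick), bm)
  })
  L <- if (is.null(mask)) stop("a region mask is required to supply L") else
    mask$effective_length_bp
  dating <- stage("dating", date_all_nodes(
    st, meta, mask, config$rate,
    high_coverage_only = config$high_coverage_only))
  clade_sets <- if (identical(config$clades, "tree")) {
    cl <- tree_clades(st$tree)
    stats::setNames(cl, vapply(cl, function(s)
      paste0("clade_", paste(substr(s, 1, 8), collapse = "+")), character(1)))
  } else config$clades
  catalog <- if (is.null(config$catalog_tsv)) {
    structure(data.frame(name = character(0), pos = integer(0),
                         anc = character(0), der = character(0)),
              class = c("snp_catalog", "data.frame"))
  } else stage("catalog", read_snp_catalog(config$catalog_tsv))
  partitions <- stage("clades", lapply(clade_sets, function(s) {
    part <- clade_variant_partition(bm, s)
    nov <- name_novel(novelty_check(part, catalog))
    list(partition = part, novel = nov)
  }))

  # ---- reports -----------------------------------------------------
  branch_tbl <- branch_snp_table(st)
  part_tbl <- do.call(rbind, lapply(names(partitions), function(nm) {
    p <- partitions[[nm]]$partition
    nv <- partitions[[nm]]$novel
    df <- p$sites[p$sites$class != "no_derived_in_clade", ]
    if (!nrow(df)) return(NULL)
    df$clade <- nm
    df$catalog_name <- NA_character_
    hit <- match(df$position, nv$known$position)
    df$catalog_name[!is.na(hit)] <- nv$known$name[hit[!is.na(hit)]]
    df$assigned_name <- unname(nv$names[as.character(df$position)])
    df[, c("clade", "position", "class", "n_carriers_in", "carriers",
           "catalog_name", "assigned_name")]
  }))
  run_log <- data.frame(
    key = c("seed", "n_samples", "n_sites_raw", "n_sites_filtered",
            "outgroup", "callable_bp", "rate_central", "rate_ci_low",
            "rate_ci_high", "tree_source", "r_version"),
    value = c(config$seed, n_samples(gm), n_sites(gm), n_sites(filt$matrix),
              config$outgroup_id, L, config$rate$central,
              config$rate$ci_low, config$rate$ci_high,
              if (is.null(config$newick)) "built" else "external",
              as.character(getRversion())))
  wt <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(filt$report, "filter_report.tsv")
  wt(branch_tbl, "branch_snps.tsv")
  wt(dating, "dating.tsv")
  if (!is.null(part_tbl)) wt(part_tbl, "clade_partition.tsv")
  wt(run_log, "run_log.tsv")

  structure(list(matrix = gm, filtered = filt, binary = bm, tree = st,
                 dating = dating, partitions = partitions,
                 branch_table = branch_tbl, partition_table = part_tbl,
                 run_log = run_log, config = config),
            class = "pipeline_result")
}

#' Human-readable per-clade summary of a run
#'
#' One line per clade — sample count, defining and novel SNP counts, and
#' the clade's date with its interval, formatted at printing precision
#' (one decimal at >= 1 kya, two below).  Every number is read from the
#' run's tables; nothing is recomputed.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @return Character vector of summary lines (header first), invisibly
#'   printed.
#' @export
summarize_run <- function(result) {
  lines <- sprintf("pipeline run: %d samples, %d filtered sites, %d clades",
                   n_samples(result$matrix), n_sites(result$filtered$matrix),
                   length(result$partitions))
  dating <- result$dating
  for (nm in names(result$partitions)) {
    p <- result$partitions[[nm]]$partition
    nv <- result$partitions[[nm]]$novel
    # locate the clade's MRCA row in the dating table, if the clade maps
    # to a tree node with a date
    phy <- result$tree$tree
    tipn <- match(p$clade_samples, phy$tip.label)
    date_txt <- "undated"
    if (!any(is.na(tipn)) && length(tipn) >= 2) {
      mrca <- ape::getMRCA(phy, tipn)
      row <- dating[dating$node_id == mrca & dating$dated, ]
      if (nrow(row) == 1L) {
        date_txt <- format_kya(row$t_kya, row$t_low_kya, row$t_high_kya)
      }
    }
    lines <- c(lines, sprintf(
      "  %s: n=%d, defining=%d, private=%d, novel=%d, T=%s",
      nm, length(p$clade_samples), length(p$defining), length(p$private),
      length(nv$novel), date_txt))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
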