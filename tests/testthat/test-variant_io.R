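test_that("haploid VCF ingestion maps records, missing and diploid calls", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrY>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT",
            "S1","S2","S3"), collapse = "\t"),
    "chrY\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0:30\t1:25\t.:0",
    "chrY\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP\t1:10\t0:12\t0:9",
    "chrY\t300\t.\tG\tA\t.\tPASS\t.\tGT:DP\t0/0:20\t1/1:21\t0/1:22",
    "chrY\t400\t.\tT\tC\t.\tPASS\t.\tGT:DP\t1:5\t1:6\t0:7",
    "chrY\t500\t.\tA\tC\t.\tPASS\t.\tGT:DP\t0:8\t0:9\t1:10"), vcf)
  gm <- read_haploid_vcf(vcf)
  expect_equal(dim(gm), c(3L, 5L))
  expect_equal(gm$sample_ids, c("S1", "S2", "S3"))
  expect_equal(gm$positions, c(100L, 200L, 300L, 400L, 500L))
  # genotype "." -> missing; diploid homozygotes collapse; het -> missing
  expect_true(is.na(gm$calls["S3", "100"]))
  expect_equal(unname(gm$calls["S1", "300"]), 0L)
  expect_equal(unname(gm$calls["S2", "300"]), 1L)
  expect_true(is.na(gm$calls["S3", "300"]))
  expect_equal(attr(gm, "qc")$het_set_missing, 1L)
  expect_equal(unname(gm$depths["S2", "100"]), 25L)

  # mask covering only 3 of the 5 positions, checked by brute-force scan
  mask <- region_mask(start = c(90, 390), end = c(210, 510))
  expect_equal(brute_in_mask(c(100, 200, 300, 400, 500),
                             c(90, 390), c(210, 510)),
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
  gm_m <- read_haploid_vcf(vcf, mask = mask)
  expect_equal(gm_m$positions, c(100L, 200L, 400L, 500L))

  # VCF with no sample columns errors
  nov <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO"),
                     collapse = "\t"),
               "chrY\t100\t.\tA\tG\t.\tPASS\t."), nov)
  expect_error(read_haploid_vcf(nov), "zero samples")
  expect_error(read_haploid_vcf(tempfile()), "cannot read")
})

test_that("VCF round-trip preserves order, alleles, calls and depths", {
  sim <- simulate_dataset(sim_config(n_tips = 6, root_age_years = 5000,
                                     seed = 11, missingness_rate = 0.05))
  vcf <- tempfile(fileext = ".vcf")
  write_haploid_vcf(sim$matrix, vcf)
  back <- read_haploid_vcf(vcf)
  expect_equal(back$sample_ids, sim$matrix$sample_ids)
  expect_equal(back$positions, sim$matrix$positions)
  expect_equal(back$ref, sim$matrix$ref)
  expect_equal(back$alt, sim$matrix$alt)
  expect_equal(unname(back$calls), unname(sim$matrix$calls))
  expect_equal(unname(back$depths), unname(sim$matrix$depths))
})

test_that("region mask merges intervals and reports effective length", {
  expect_equal(region_mask(c(0, 100), c(100, 200))$effective_length_bp, 200)
  m <- region_mask(c(0, 50), c(100, 150))     # overlap -> union by sweep
  expect_equal(m$start, 0); expect_equal(m$end, 150)
  expect_equal(m$effective_length_bp, 150)
  expect_error(region_mask(10, 10), "end > start")

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrY\t0\t100", "chrY\t50\t150", "chrY\t300\t400"), bed)
  mb <- read_region_mask(bed)
  expect_equal(mb$effective_length_bp, 250)
  empty <- tempfile(fileext = ".bed"); file.create(empty)
  expect_equal(read_region_mask(empty)$effective_length_bp, 0)

  # union length equals brute-force count of covered bases (<= 10 kb)
  set.seed(42)
  for (i in 1:5) {
    s <- sort(sample(0:9000, 8)); e <- s + sample(50:900, 8, replace = TRUE)
    m2 <- region_mask(s, e)
    covered <- unique(unlist(mapply(function(a, b) seq(a, b - 1), s, e)))
    expect_equal(m2$effective_length_bp, length(covered))
  }
})

test_that("variable-sites FASTA has one column per variable site", {
  samples <- c("S1", "S2", "S3")
  calls <- rbind(c(0, 1, 0, NA), c(1, 1, 0, 1), c(0, 1, 0, 0))
  gm <- genotype_matrix(samples, c(10, 20, 30, 40),
                        ref = c("A", "C", "G", "T"),
                        alt = c("G", "T", "A", "C"), calls = calls)
  fa <- tempfile(fileext = ".fa")
  nvar <- write_variable_sites_fasta(gm, fa)
  # brute-force recount: sites 20 (all ALT) and 30 (all REF) are invariant
  expect_equal(nvar, 2L)
  aln <- ape::read.dna(fa, format = "fasta", as.character = TRUE)
  expect_equal(dim(aln), c(3L, 2L))
  expect_equal(toupper(aln["S1", ]), c("A", "N"))   # missing emitted as N
  expect_equal(toupper(aln["S2", ]), c("G", "C"))
  expect_error(write_variable_sites_fasta(
    genotype_matrix("S1", integer(0), character(0), character(0),
                    matrix(integer(0), 1, 0)), fa), "empty")
})

test_that("catalog/metadata readers validate schemas; Newick round-trips", {
  cat_tsv <- tempfile(fileext = ".tsv")
  writeLines(c("name\tpos\tanc\tder", "M3\t100\tA\tG", "Z780\t250\tC\tT"),
             cat_tsv)
  cat <- read_snp_catalog(cat_tsv)
  expect_equal(nrow(cat), 2L)
  writeLines(c("name\tpos\tanc\tder", "M3\t100\tA\tG", "DUP\t100\tC\tT"),
             cat_tsv)
  expect_error(read_snp_catalog(cat_tsv), "duplicate")

  meta_tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\thigh_coverage",
               "S1\tPE\tTRUE", "S2\tAR\tFALSE"), meta_tsv)
  meta <- read_sample_meta(meta_tsv)
  expect_equal(meta$high_coverage, c(TRUE, FALSE))
  gm <- genotype_matrix(c("S1", "S2", "S3"), 10, "A", "G",
                        matrix(c(0L, 1L, 0L), 3, 1))
  expect_error(validate_sample_meta(gm, meta), "S3")

  # 5-tip tree with a polytomy survives a write/read round trip
  nwk <- tempfile(fileext = ".nwk")
  tr <- ape::read.tree(text = "((A,B,C),(D,E));")
  write_tree_newick(tr, nwk)
  tr2 <- read_tree_newick(nwk)
  expect_equal(tr2$Nnode, tr$Nnode)
  expect_setequal(sapply(tree_clades(tr2), paste, collapse = ","),
                  sapply(tree_clades(tr), paste, collapse = ","))
})
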