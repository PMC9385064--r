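#!/usr/bin/env Rscript
# Partition variants for the largest non-trivial clade of the SNP tree:
# defining / internal / private / excluded classes, branch equivalence
# classes, novelty against a small catalog, and sequential naming of the
# novel defining/internal SNPs.  Writes results/clade_partition.tsv.

library(ylineage)

gm <- read_haploid_vcf("results/filtered.vcf")
bm <- polarize(gm, "OUTGROUP")
st <- build_tree(bm)

clades <- tree_clades(st)
clade <- clades[[which.max(lengths(clades))]]
part <- clade_variant_partition(bm, clade)
print(part)

# catalog containing a third of the defining/internal positions: the rest
# are reported novel and named sequentially by genomic position
known_pos <- sort(c(part$defining, part$internal))
known_pos <- known_pos[seq_along(known_pos) %% 3 == 0]
catalog_path <- "results/catalog.tsv"
writeLines(c("name\tpos\tanc\tder",
             sprintf("KN%d\t%d\tA\tG", seq_along(known_pos), known_pos)),
           catalog_path)
nov <- name_novel(novelty_check(part, read_snp_catalog(catalog_path)),
                  prefix = "GMP", start_index = 1)

tab <- part$sites
tab$assigned_name <- unname(nov$names[as.character(tab$position)])
write.table(tab, "results/clade_partition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

eq <- equivalence_classes(part, st)
cat(sprintf("clade of %d samples: %d defining SNPs in %d branch classes, %d novel (named %s..%s)\n",
            length(clade), length(part$defining), length(eq),
            length(nov$novel),
            if (length(nov$names)) nov$names[1] else "-",
            if (length(nov$names)) nov$names[length(nov$names)] else "-"))
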