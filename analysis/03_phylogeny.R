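#!/usr/bin/env Rscript
# Polarize the filtered calls against the outgroroup, build the SNP tree and
# assign every site to a branch by parsimony, flagging recurrent sites.
# Writes results/branch_snps.tsv, results/snp_tree.nwk and a variable-site
# FASTA (the alignment an external ML search would consume).

library(ylineage)

gm <- read_haploid_vcf("results/filtered.vcf")
bm <- polarize(gm, "OUTGROUP")
st <- build_tree(bm)

write.table(branch_snp_table(st), "results/branch_snps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_tree_newick(st, "results/snp_tree.nwk")
write_variable_sites_fasta(gm, "results/variable_sites.fasta")

inc <- check_pairwise_compatibility(bm)
cat(sprintf("polarized %d sites (%d dropped), %d incompatible pairs\n",
            length(bm$positions), sum(bm$dropped$n_sites), nrow(inc)))
print(st)
cat(sprintf("recurrent positions: %s\n",
            if (length(st$recurrent_positions))
              paste(st$recurrent_positions, collapse = ", ") else "none"))
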