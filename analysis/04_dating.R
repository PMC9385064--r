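#!/usr/bin/env Rscript
# Date every internal node of the SNP tree with the rho statistic and the
# mutation-rate interval (0.76e-9, 95% CI 0.67e-9-0.86e-9 /site/year), then
# compare estimates with the simulation's true node ages.
# Writes results/dating.tsv.

library(ylineage)

gm <- read_haploid_vcf("results/filtered.vcf")
mask <- read_region_mask("results/simdata/mask.bed")
meta <- read_sample_meta("results/simdata/sample_meta.tsv")
bm <- polarize(gm, "OUTGROUP")
st <- build_tree(bm)

d <- date_all_nodes(st, meta, mask, mutation_rate())
ages <- read.table("results/simdata/node_ages.tsv", header = TRUE, sep = "\t")
truth_tree <- read_tree_newick("results/simdata/tree.nwk")
d$t_true_years <- vapply(seq_len(nrow(d)), function(k) {
  labs <- st$tree$tip.label[ylineage:::node_descendant_tips(st$tree,
                                                            d$node_id[k])]
  ages$age_years[ape::getMRCA(truth_tree, labs)]
}, numeric(1))
write.table(d, "results/dating.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

dated <- d[d$dated, ]
cat(sprintf("dated %d of %d internal nodes\n", nrow(dated), nrow(d)))
root <- dated[which.max(dated$n_tips), ][1, ]
cat(sprintf("root TMRCA: %s  (truth %.1f kya)\n",
            format_kya(root$t_kya, root$t_low_kya, root$t_high_kya),
            root$t_true_years / 1000))
# per-node relative error is Poisson-noisy for very young nodes in a
# single replicate, so summarise with the median
cat(sprintf("median relative error vs truth: %+.1f%%\n",
            100 * median((dated$t_years - dated$t_true_years) /
                           dated$t_true_years)))
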