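#!/usr/bin/env Rscript
# Generate the reference simulated dataset used by the downstream analysis
# steps: a 20-tip clock tree with MRCA at 20 kya, Poisson mutations at
# 0.76e-9 /site/year over a 10.45 Mb callable mask, plus a corrupted copy
# (10% missingness, 5% low-depth calls) to exercise the filters.
# Writes results/simdata/ (VCF, Newick, truth TSVs, mask BED, metadata).

library(ylineage)

out <- "results/simdata"
cfg <- sim_config(n_tips = 20, root_age_years = 20000, seed = 1001,
                  missingness_rate = 0.1, low_depth_rate = 0.05)

phy <- simulate_tree(cfg)
truth <- drop_mutations(phy, cfg)
paths <- emit_dataset(truth, out)
write_region_mask(cfg$mask, file.path(out, "mask.bed"))

# corrupted genotype matrix for the filtering step
sim <- simulate_dataset(cfg)
write_haploid_vcf(sim$matrix, file.path(out, "sim_corrupted.vcf"))

cat(sprintf("simulated %d tips, %d mutations (%d recurrent), root age %d years\n",
            length(phy$tip.label), nrow(truth$mutations),
            sum(truth$mutations$recurrent), cfg$root_age_years))
cat("outputs in", out, "\n")
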