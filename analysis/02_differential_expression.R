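#!/usr/bin/env Rscript
# Negative-binomial Wald differential expression of NEPC against each
# comparator group, from the simulated cohort of 01_simulate_cohort.R.
# Writes the top of each comparison's result table to results/.

library(surfnom)

cohort <- simulate_cohort(sim_config(seed = 101))
sf <- estimate_size_factors(cohort$counts)
disp <- estimate_dispersions(cohort$counts, sf, cohort$design)

for (grp in c("benign", "pca", "crpc")) {
  de <- nb_wald_test(cohort$counts, sf, disp, cohort$design, "nepc", grp)
  de <- de[order(de$padj, de$wald_p), ]
  n_sig <- sum(de$padj < 0.05 & de$log2fc >= 1)
  cat(sprintf("NEPC vs %-6s: %d features at padj<0.05 & FC>=2\n",
              grp, n_sig))
  write_tsv(utils::head(de, 25),
            sprintf("results/02_de_nepc_vs_%s_top25.tsv", grp))
}
cat("Top DE tables -> results/02_de_nepc_vs_*_top25.tsv\n")
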