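#!/usr/bin/env Rscript
# Build the synthetic study cohort: a scaled-down NEPC/CRPC/PCa/benign
# RNA-seq cohort (20/20/20/12 samples, 2,000 genes) with planted
# NEPC-specific surface targets and one decoy class per cascade stage,
# plus GTEx-style tissue medians and surface-annotation files.
# Full matrices go to scratch/cohort/ (regenerable from the seed);
# a small design summary goes to results/.

library(surfnom)

cfg <- sim_config(seed = 101)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "scratch/cohort")

cat("Cohort:", nrow(cohort$counts), "genes x", ncol(cohort$counts),
    "samples;", length(catalog_genes(cohort$catalog)),
    "genes in the surface catalog\n")
print(table(cohort$design))
print(table(cohort$truth$class))

dir.create("results", showWarnings = FALSE)
class_summary <- as.data.frame(table(class = cohort$truth$class,
                                     expected = cohort$truth$expected_outcome))
class_summary <- class_summary[class_summary$Freq > 0, ]
write_tsv(class_summary, "results/01_planted_classes.tsv",
          meta = run_metadata(unclass(cfg), seed = cfg$seed))
cat("Planted-class table -> results/01_planted_classes.tsv\n")
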