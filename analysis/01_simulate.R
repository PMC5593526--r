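#!/usr/bin/env Rscript
# Step 1: generate the full synthetic input bundle.
#
# Emits the five input modalities (microarray time course, multi-tissue
# RNA-seq, tumor cohort, qPCR Ct tables, TSS/peak annotations) with a
# 28-gene planted repressed module, as plain text under results/data/.
suppressPackageStartupMessages(library(p53repress))

seed <- 1
cfg <- sim_config(seed = seed)
bundle <- simulate_bundle(cfg)
dir <- "results/data"
write_bundle(bundle, dir)

cat("Simulated input bundle (seed ", seed, ") written to ", dir, "\n", sep = "")
cat("  gene universe: ", cfg$n_genes, " genes; planted module: ",
    length(bundle$truth$true_repressed), " genes\n", sep = "")
cat("  microarray: ", nrow(bundle$microarray$expr), " probes x ",
    ncol(bundle$microarray$expr), " arrays\n", sep = "")
cat("  RNA-seq: ", nrow(bundle$rnaseq$expr), " genes x ",
    ncol(bundle$rnaseq$expr), " samples over ",
    length(unique(bundle$rnaseq$design$tissue)), " tissues\n", sep = "")
cat("  cohort: ", ncol(bundle$cohort$cohort$expr), " patients (",
    sum(bundle$cohort$cohort$patients$p53_status == "wt"), " wt / ",
    sum(bundle$cohort$cohort$patients$p53_status == "mut"), " mut p53)\n",
    sep = "")
cat("  qPCR: ", nrow(bundle$qpcr$ct), " Ct measurements across ",
    nrow(bundle$qpcr$lines), " cell lines\n", sep = "")
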