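#!/usr/bin/env Rscript
# Step 2: the three candidate screens and their intersection.
#
# Reads the bundle written by 01_simulate.R, applies the microarray
# median/min ratio screen, the mouse RNA-seq pseudocount ratio screen
# (mammary gland) and the cohort t-test screen, then intersects the
# candidate sets through the ortholog map.
suppressPackageStartupMessages(library(p53repress))

dir <- "results/data"
if (!file.exists(file.path(dir, "microarray_expr.tsv"))) {
  stop("run analysis/01_simulate.R first")
}

micro_expr <- read_expression_table(file.path(dir, "microarray_expr.tsv"), "probe")
micro_design <- read_design_table(file.path(dir, "microarray_design.tsv"))
probe_map <- read.delim(file.path(dir, "probe_map.tsv"))
rna_expr <- read_expression_table(file.path(dir, "rnaseq_fpkm.tsv"), "gene")
rna_design <- read_design_table(file.path(dir, "rnaseq_design.tsv"))
coh_expr <- read_expression_table(file.path(dir, "cohort_expr.tsv"), "gene")
coh_pat <- read.delim(file.path(dir, "cohort_patients.tsv"))
cohort <- cohort_table(coh_expr, coh_pat)
orthologs <- read.delim(file.path(dir, "orthologs.tsv"))

scr_micro <- screen_microarray(micro_expr, micro_design, probe_map)
scr_rna <- screen_rnaseq(rna_expr, rna_design)
scr_coh <- screen_cohort(cohort)
inter <- intersect_candidates(list(microarray = scr_micro, cohort = scr_coh),
                              scr_rna, orthologs)

for (scr in list(scr_micro, scr_rna, scr_coh)) {
  write.table(scr$gene_stats,
              sprintf("results/screen_%s.tsv", scr$screen),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write_gene_set(inter$genes, "results/candidates.txt")
jsonlite::write_json(as.list(inter$venn), "results/venn_counts.json",
                     auto_unbox = TRUE)

cat("Candidates per screen: microarray ",
    length(screen_candidates(scr_micro)), ", RNA-seq (mammary gland) ",
    length(screen_candidates(scr_rna)), ", cohort ",
    length(screen_candidates(scr_coh)), "\n", sep = "")
cat("Three-way intersection: ", length(inter$genes),
    " candidate p53-repressed genes (results/candidates.txt)\n", sep = "")
if (length(inter$unmapped)) {
  cat("Mouse symbols without orthologs: ", length(inter$unmapped), "\n", sep = "")
}
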