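#!/usr/bin/env Rscript
# Step 5: prognosis of the repressed module.
#
# Median-split Kaplan-Meier / log-rank screen of every module gene in the
# simulated tumor cohort, plus the Fisher test of p53 mutation status
# against the High/Low split for each prognostic gene.
suppressPackageStartupMessages(library(p53repress))

dir <- "results/data"
coh_expr <- read_expression_table(file.path(dir, "cohort_expr.tsv"), "gene")
coh_pat <- read.delim(file.path(dir, "cohort_patients.tsv"))
cohort <- cohort_table(coh_expr, coh_pat)
module <- read_gene_set("results/module.txt")

prog <- prognosis_screen(cohort, module)
hits <- prog$gene[prog$significant]
assoc <- vapply(hits, function(g) mutation_association(cohort, g)$p_value,
                numeric(1))
prog$mutation_assoc_p <- assoc[match(prog$gene, names(assoc))]
write.table(prog, "results/prognosis.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(length(hits), "of", nrow(prog),
    "module genes correlate with survival at nominal p < 0.05\n")
if (length(hits)) {
  cat("  directions:", paste(unique(prog$direction[prog$significant]),
                             collapse = ", "), "\n")
  cat("  p53-mutation association p-values (Fisher, High/Low split):\n")
  for (g in hits) {
    cat(sprintf("    %s: %.3g\n", g, assoc[[g]]))
  }
}
cat("Wrote results/prognosis.tsv\n")
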