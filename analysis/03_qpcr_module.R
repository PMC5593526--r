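#!/usr/bin/env Rscript
# Step 3: delta-delta-Ct quantification and the module call.
#
# For the intersected candidates: log2 fold changes after ADR across the
# seven-line panel (stage 1), p53-knockdown dependence (stage 2) and
# repression by exogenous p53 in a mutant line (stage 3). A candidate
# joins the module only if it passes all three stages.
suppressPackageStartupMessages(library(p53repress))

dir <- "results/data"
candidates <- read_gene_set("results/candidates.txt")
ct <- read.delim(file.path(dir, "qpcr_ct.tsv"))
lines <- read.delim(file.path(dir, "qpcr_lines.tsv"))

adr_fc <- panel_log2fc(ct, candidates, "ADR", "untreated",
                       cell_lines = lines$cell_line)
adr <- classify_adr_repressed(adr_fc, lines)
kd_line <- lines$cell_line[lines$p53_status == "wt"][1]
kd <- validate_knockdown(
  panel_log2fc(ct, candidates, "siEGFP_ADR", "mock", cell_lines = kd_line),
  panel_log2fc(ct, candidates, "sip53_ADR", "mock", cell_lines = kd_line))
ad_line <- lines$cell_line[lines$p53_status == "mut"][1]
exo <- validate_exogenous_p53(
  panel_log2fc(ct, candidates, "Adp53", "control", cell_lines = ad_line),
  panel_log2fc(ct, candidates, "AdLacZ", "control", cell_lines = ad_line))
call <- call_module(candidates, adr, kd, exo)

write.table(adr_fc, "results/qpcr_panel_log2fc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(call$audit, "results/module_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gene_set(call$module, "results/module.txt")

cat("Stage 1 (ADR panel, log2FC <= -2 in >= 2 wt, 0 mut lines): ",
    sum(adr$pass), " of ", length(candidates), " candidates\n", sep = "")
cat("Stage 2 (knockdown abrogation): ", sum(kd$pass), " pass\n", sep = "")
cat("Stage 3 (exogenous p53): ", sum(exo$pass), " pass\n", sep = "")
cat("Called p53-repressed gene module: ", length(call$module),
    " genes (results/module.txt)\n", sep = "")
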