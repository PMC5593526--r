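# Seeded generators for the five input modalities, each with planted ground
# truth. Every generator draws from its own RNG stream derived from the
# master seed by a stable label, so adding a generator never perturbs the
# draws of another.

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: a 28-gene planted
#' repressed module, four wild-type and three p53-mutant cell lines, a
#' 795/298 wild-type/mutant tumor cohort, fourfold repression (planted
#' treated/baseline ratio 0.25 against the 0.5 screen cutoff), a planted
#' qPCR effect of -3 log2 units against the -2 cutoff, and promoter-peak
#' probabilities matching the observed 42.6% vs 3.7% proportions.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_true_repressed number of planted module genes.
#' @param repression_fold fold reduction of planted genes under p53-active
#'   stress (> 1; planted ratio is `1/repression_fold`).
#' @param noise_sd_log sd of multiplicative log-normal expression noise
#'   (natural-log scale).
#' @param ct_noise_sd sd (cycles) of qPCR Ct measurement noise.
#' @param qpcr_effect_log2 planted log2 fold change in responsive wild-type
#'   lines (negative).
#' @param n_wt_lines,n_mut_lines cell-line panel composition.
#' @param peak_enrichment_prob length-2 probability of a promoter peak for
#'   (induced, module) genes.
#' @param cohort_n named length-2 count of (wt, mut) patients.
#' @param hazard_ratio_high hazard multiplier for the high-risk half of the
#'   cohort.
#' @param cohort_effect_log2 planted log2 reduction of module-gene
#'   expression in wild-type-p53 tumors.
#' @param n_prognostic number of planted module genes tied to the latent
#'   risk factor driving survival.
#' @param prognostic_loading log-scale loading of prognostic genes on the
#'   latent risk factor.
#' @param n_induced size of the simulated p53-induced reference gene set.
#' @param seed master seed; all generator streams derive from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       n_true_repressed = 28,
                       repression_fold = 4,
                       noise_sd_log = 0.2,
                       ct_noise_sd = 0.15,
                       qpcr_effect_log2 = -3,
                       n_wt_lines = 4,
                       n_mut_lines = 3,
                       peak_enrichment_prob = c(induced = 0.426, module = 0.037),
                       cohort_n = c(wt = 795, mut = 298),
                       hazard_ratio_high = 3,
                       cohort_effect_log2 = 1,
                       n_prognostic = min(9, n_true_repressed),
                       prognostic_loading = 0.3,
                       n_induced = 183,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_true_repressed = n_true_repressed,
              repression_fold = repression_fold, noise_sd_log = noise_sd_log,
              ct_noise_sd = ct_noise_sd, qpcr_effect_log2 = qpcr_effect_log2,
              n_wt_lines = n_wt_lines, n_mut_lines = n_mut_lines,
              peak_enrichment_prob = peak_enrichment_prob,
              cohort_n = cohort_n, hazard_ratio_high = hazard_ratio_high,
              cohort_effect_log2 = cohort_effect_log2,
              n_prognostic = n_prognostic,
              prognostic_loading = prognostic_loading,
              n_induced = n_induced, seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0, cfg$n_true_repressed >= 0,
            cfg$n_true_repressed <= cfg$n_genes,
            cfg$repression_fold > 1, cfg$noise_sd_log >= 0,
            cfg$ct_noise_sd >= 0, cfg$n_wt_lines > 0, cfg$n_mut_lines >= 0,
            all(cfg$peak_enrichment_prob >= 0),
            all(cfg$peak_enrichment_prob <= 1),
            all(cfg$cohort_n > 0), cfg$hazard_ratio_high > 0,
            cfg$n_prognostic <= cfg$n_true_repressed)
  class(cfg) <- "sim_config"
  cfg
}

# Stable per-generator stream: a small deterministic hash of the label mixed
# with the master seed, kept inside 32-bit integer range.
stream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_len(nchar(label)) * 131L)) %% 100003L
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

gene_universe <- function(cfg) sprintf("GENE%04d", seq_len(cfg$n_genes))

# The planted module is a deterministic function of the seed (drawn on its
# own stream so all generators agree on it).
planted_module <- function(cfg) {
  set.seed(stream_seed(cfg$seed, "truth"))
  sort(sample(gene_universe(cfg), cfg$n_true_repressed))
}

#' Simulate the microarray ADR time course
#'
#' Emulates a p53 wild-type vs p53-null cell time course after a 2-hour ADR
#' pulse (conditions W0/W12/W24/W48 and K0/K12/K24/K48, one array each).
#' Planted module genes have their W12/W24/W48 expression divided by
#' `repression_fold` relative to W0 and all K samples; each gene is measured
#' by 1-3 probes around a shared log-normal baseline.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (probe x sample matrix), `design`, `probe_map`
#'   (probe_id, gene) and `truth` (planted gene set and effect).
#' @export
simulate_microarray <- function(config) {
  genes <- gene_universe(config)
  truth <- planted_module(config)
  set.seed(stream_seed(config$seed, "microarray"))
  n_probes <- sample(1:3, config$n_genes, replace = TRUE)
  probe_gene <- rep(genes, n_probes)
  probes <- sprintf("P%06d", seq_along(probe_gene))
  conds <- c("W0", "W12", "W24", "W48", "K0", "K12", "K24", "K48")
  base <- exp(rnorm(length(probes), log(100), 1))
  fold <- matrix(1, length(probes), length(conds),
                 dimnames = list(probes, conds))
  fold[probe_gene %in% truth, c("W12", "W24", "W48")] <- 1 / config$repression_fold
  noise <- matrix(exp(rnorm(length(fold), 0, config$noise_sd_log)),
                  nrow = nrow(fold))
  expr <- base * fold * noise
  dimnames(expr) <- dimnames(fold)
  expr <- validate_expression_matrix(expr, "probe")
  design <- make_design(
    sample_id = conds,
    genotype = rep(c("p53_wt", "p53_null"), each = 4),
    treatment = "ADR",
    timepoint = rep(c(0, 12, 24, 48), 2)
  )
  list(expr = expr,
       design = design,
       probe_map = data.frame(probe_id = probes, gene = probe_gene,
                              stringsAsFactors = FALSE),
       truth = list(true_repressed = truth,
                    effect_ratio = 1 / config$repression_fold))
}

#' Simulate the multi-tissue mouse irradiation RNA-seq design
#'
#' FPKM values for p53 wild-type / knockout mice, irradiated or not
#' (W/WX/K/KX per tissue), n = 3 replicates per arm except n = 2 for
#' mammary gland and ovary. Repression is planted only in
#' `repressed_tissues`; a fraction of genes is silent (all-zero FPKM) to
#' exercise the pseudocount.
#'
#' @param config a [sim_config()].
#' @param tissues tissue labels.
#' @param repressed_tissues tissues in which the planted module responds.
#' @param zero_fraction fraction of genes with all-zero FPKM.
#' @return list with `expr` (gene x sample), `design`, `truth`.
#' @export
simulate_rnaseq_tissues <- function(config,
                                    tissues = c("mammary_gland", "ovary",
                                                "uterus", "thymus",
                                                "spleen", "lung"),
                                    repressed_tissues = c("mammary_gland",
                                                          "uterus", "thymus"),
                                    zero_fraction = 0.05) {
  stopifnot(all(repressed_tissues %in% tissues))
  genes <- normalize_symbols(gene_universe(config), "mouse")
  truth <- normalize_symbols(planted_module(config), "mouse")
  set.seed(stream_seed(config$seed, "rnaseq"))
  base <- exp(rnorm(config$n_genes, log(20), 1))
  silent <- runif(config$n_genes) < zero_fraction
  # planted effects require expression: module genes are never silent and
  # sit above the detectability floor the pseudocount imposes on the
  # screen ratio (a fourfold drop below ~2 FPKM is invisible after +1)
  silent[genes %in% truth] <- FALSE
  base[genes %in% truth] <- pmax(base[genes %in% truth], 5)
  base[silent] <- 0

  design <- do.call(rbind, lapply(tissues, function(ti) {
    n_rep <- if (ti %in% c("mammary_gland", "ovary")) 2L else 3L
    expand <- expand.grid(rep = seq_len(n_rep),
                          geno = c("p53_wt", "p53_null"),
                          irr = c(FALSE, TRUE), stringsAsFactors = FALSE)
    data.frame(
      sample_id = sprintf("%s_%s%s_r%d", ti,
                          ifelse(expand$geno == "p53_wt", "W", "K"),
                          ifelse(expand$irr, "X", ""), expand$rep),
      genotype = expand$geno,
      treatment = ifelse(expand$irr, "irradiation", "none"),
      tissue = ti, stringsAsFactors = FALSE
    )
  }))
  design <- make_design(design$sample_id, design$genotype, design$treatment,
                        NA, design$tissue)

  repressed_col <- design$condition_code == "WX" &
    design$tissue %in% repressed_tissues
  fold <- matrix(1, config$n_genes, nrow(design),
                 dimnames = list(genes, design$sample_id))
  fold[truth, repressed_col] <- 1 / config$repression_fold
  noise <- matrix(exp(rnorm(length(fold), 0, config$noise_sd_log)),
                  nrow = nrow(fold))
  expr <- base * fold * noise
  dimnames(expr) <- dimnames(fold)
  expr <- validate_expression_matrix(expr, "gene")
  list(expr = expr, design = design,
       truth = list(true_repressed = truth,
                    repressed_tissues = repressed_tissues,
                    silent_genes = genes[silent]))
}

#' Simulate a tumor cohort with expression, p53 status and survival
#'
#' Planted module genes are expressed lower in wild-type-p53 tumors by
#' `cohort_effect_log2` log2 units. A latent per-patient risk factor loads
#' on `n_prognostic` of the module genes; event times are exponential with
#' the hazard multiplied by `hazard_ratio_high` for patients in the upper
#' half of the latent risk, with independent uniform censoring.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a [cohort_table()]) and `truth` (planted
#'   module, prognostic genes, latent risk group).
#' @export
simulate_cohort <- function(config) {
  genes <- gene_universe(config)
  truth <- planted_module(config)
  set.seed(stream_seed(config$seed, "cohort"))
  n <- sum(config$cohort_n)
  status <- rep(c("wt", "mut"), times = config$cohort_n)
  patients <- sprintf("PT%04d", seq_len(n))
  prognostic <- sort(sample(truth, config$n_prognostic))

  base_log <- rnorm(config$n_genes, log(500), 0.8)
  shift <- matrix(0, config$n_genes, n, dimnames = list(genes, patients))
  shift[truth, status == "wt"] <- -config$cohort_effect_log2 * log(2)
  z <- rnorm(n)
  shift[prognostic, ] <- shift[prognostic, ] +
    rep(config$prognostic_loading * z, each = length(prognostic))
  noise <- matrix(rnorm(config$n_genes * n, 0, config$noise_sd_log),
                  config$n_genes, n)
  expr <- exp(base_log + shift + noise)
  dimnames(expr) <- list(genes, patients)

  high_risk <- z > stats::median(z)
  rate <- log(2) / 2000 * ifelse(high_risk, config$hazard_ratio_high, 1)
  event_time <- stats::rexp(n, rate)
  censor_time <- stats::runif(n, 0, 4000)
  time <- pmin(event_time, censor_time)
  event <- event_time <= censor_time

  cohort <- cohort_table(expr, data.frame(
    patient_id = patients, p53_status = status,
    time = time, event = event, stringsAsFactors = FALSE))
  list(cohort = cohort,
       truth = list(true_repressed = truth, prognostic = prognostic,
                    high_risk = stats::setNames(high_risk, patients)))
}

#' Simulate qPCR Ct tables for the panel, knockdown and exogenous-p53 designs
#'
#' Ct values are simulated at the cycle level so the delta-delta-Ct
#' arithmetic is genuinely exercised: the reference gene (beta-actin role)
#' sits at 20 cycles nominal, targets near 24, and every measurement gets
#' independent Gaussian noise of `ct_noise_sd` cycles. Planted genes shift
#' their Ct up by `-qpcr_effect_log2` cycles under ADR in wild-type lines
#' only; the p53-knockdown arm cancels the shift and the exogenous-p53 arm
#' reproduces it in a mutant line.
#'
#' @param config a [sim_config()].
#' @param genes genes to assay.
#' @param planted subset of `genes` carrying the p53-dependent effect.
#' @param n_replicates replicates per condition.
#' @return list with `ct` (long table: gene, cell_line, condition,
#'   replicate, ct), `lines` (cell_line, p53_status), `reference_gene`,
#'   `truth`.
#' @export
simulate_qpcr <- function(config, genes, planted = character(),
                          n_replicates = 3) {
  stopifnot(all(planted %in% genes))
  set.seed(stream_seed(config$seed, "qpcr"))
  ref <- "ACTB"
  wt_lines <- sprintf("WT%d", seq_len(config$n_wt_lines))
  mut_lines <- sprintf("MUT%d", seq_len(config$n_mut_lines))
  lines <- data.frame(
    cell_line = c(wt_lines, mut_lines),
    p53_status = rep(c("wt", "mut"), c(config$n_wt_lines, config$n_mut_lines)),
    stringsAsFactors = FALSE)

  # design blocks: ADR panel on every line; siRNA arm on the first wt line;
  # adenovirus arm on the first mutant line
  blocks <- rbind(
    expand.grid(cell_line = lines$cell_line,
                condition = c("untreated", "ADR"),
                stringsAsFactors = FALSE),
    data.frame(cell_line = wt_lines[1L],
               condition = c("mock", "siEGFP_ADR", "sip53_ADR")),
    data.frame(cell_line = mut_lines[1L],
               condition = c("control", "AdLacZ", "Adp53"))
  )
  all_genes <- c(ref, genes)
  base_ct <- stats::setNames(c(20, stats::runif(length(genes), 23, 26)),
                             all_genes)

  grid <- merge(merge(blocks, data.frame(gene = all_genes)),
                data.frame(replicate = seq_len(n_replicates)))
  status <- lines$p53_status[match(grid$cell_line, lines$cell_line)]
  shift_cycles <- -config$qpcr_effect_log2  # repression raises Ct
  shifted <- grid$gene %in% planted & (
    (grid$condition %in% c("ADR", "siEGFP_ADR") & status == "wt") |
      (grid$condition == "Adp53")
  )
  ct <- base_ct[grid$gene] + ifelse(shifted, shift_cycles, 0) +
    stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  out <- data.frame(gene = grid$gene, cell_line = grid$cell_line,
                    condition = grid$condition, replicate = grid$replicate,
                    ct = ct, stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$cell_line, out$condition, out$replicate), ]
  rownames(out) <- NULL
  list(ct = out, lines = lines, reference_gene = ref,
       truth = list(planted = planted,
                    effect_log2 = config$qpcr_effect_log2))
}

#' Simulate TSS annotations for a gene universe
#'
#' Genes are spread 1 Mb apart over 19 autosome labels with random strand,
#' so simulated peaks never straddle two genes' windows.
#'
#' @param config a [sim_config()].
#' @param genes gene symbols to annotate.
#' @return TSS data.frame (gene, chrom, tss_position, strand).
#' @export
simulate_tss <- function(config, genes) {
  set.seed(stream_seed(config$seed, "tss"))
  data.frame(
    gene = genes,
    chrom = paste0("chr", sample(1:19, length(genes), replace = TRUE)),
    tss_position = 1e6L * seq_along(genes) +
      sample.int(1000L, length(genes), replace = TRUE),
    strand = sample(c("+", "-"), length(genes), replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate ChIP-seq peak intervals around gene TSSs
#'
#' Each gene in the induced set gets a promoter peak (placed fully inside
#' the +/-2 kb window) with probability `prob[1]`, each module gene with
#' probability `prob[2]`; otherwise a distal peak is placed beyond 10 kb
#' from the TSS. Genes outside both sets receive no peak.
#'
#' @param config a [sim_config()].
#' @param induced,module gene sets.
#' @param tss TSS annotation covering both sets.
#' @param peak_width interval width in bp.
#' @param prob length-2 promoter-peak probabilities (induced, module);
#'   defaults to `config$peak_enrichment_prob`.
#' @return list with `peaks` (BED-like data.frame) and `truth`
#'   (per-gene promoter-peak indicator).
#' @export
simulate_peaks <- function(config, induced, module, tss,
                           peak_width = 200,
                           prob = config$peak_enrichment_prob) {
  set.seed(stream_seed(config$seed, "peaks"))
  genes <- c(induced, setdiff(module, induced))
  grp_prob <- ifelse(genes %in% induced, prob[[1L]], prob[[2L]])
  idx <- match(genes, tss$gene)
  if (anyNA(idx)) stop("genes missing from TSS annotation: ",
                       paste(genes[is.na(idx)][1:5], collapse = ", "))
  promoter <- stats::runif(length(genes)) < grp_prob
  # promoter peaks sit fully inside +/-2 kb; distal peaks start 15 kb out
  offset <- ifelse(promoter,
                   round(stats::runif(length(genes), -2000 + peak_width, 2000 - peak_width)),
                   15000 + round(stats::runif(length(genes), 0, 5000)))
  center <- tss$tss_position[idx] + offset
  peaks <- validate_peaks(data.frame(
    chrom = tss$chrom[idx],
    start = as.integer(center - peak_width / 2),
    end = as.integer(center + peak_width / 2),
    stringsAsFactors = FALSE))
  list(peaks = peaks,
       truth = stats::setNames(promoter, genes))
}

#' Simulate the full input bundle
#'
#' Runs every generator under its own stream of the master seed and returns
#' all five modalities plus the shared planted ground truth, an ortholog map
#' and a simulated p53-induced reference gene set for the enrichment stage.
#'
#' @param config a [sim_config()].
#' @return named list: `microarray`, `rnaseq`, `cohort`, `qpcr`, `tss`,
#'   `peaks`, `induced`, `orthologs`, `truth`.
#' @export
simulate_bundle <- function(config) {
  genes <- gene_universe(config)
  truth <- planted_module(config)
  micro <- simulate_microarray(config)
  rna <- simulate_rnaseq_tissues(config)
  coh <- simulate_cohort(config)
  qp <- simulate_qpcr(config, genes, planted = truth)
  set.seed(stream_seed(config$seed, "induced"))
  non_module <- setdiff(genes, truth)
  induced <- sort(sample(non_module, min(config$n_induced, length(non_module))))
  tss <- simulate_tss(config, genes)
  pk <- simulate_peaks(config, induced, truth, tss)
  orthologs <- data.frame(human = genes,
                          mouse = normalize_symbols(genes, "mouse"),
                          stringsAsFactors = FALSE)
  list(microarray = micro, rnaseq = rna, cohort = coh, qpcr = qp,
       tss = tss, peaks = pk$peaks, induced = induced,
       orthologs = orthologs,
       truth = list(true_repressed = truth,
                    prognostic = coh$truth$prognostic,
                    promoter_peak = pk$truth))
}

#' Write a simulated bundle to a directory in the standard text formats
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_expression_table(bundle$microarray$expr, p("microarray_expr.tsv"),
                         feature_col = "probe_id")
  write_design_table(bundle$microarray$design, p("microarray_design.tsv"))
  utils::write.table(bundle$microarray$probe_map, p("probe_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_table(bundle$rnaseq$expr, p("rnaseq_fpkm.tsv"),
                         feature_col = "gene")
  write_design_table(bundle$rnaseq$design, p("rnaseq_design.tsv"))
  write_expression_table(bundle$cohort$cohort$expr, p("cohort_expr.tsv"),
                         feature_col = "gene")
  utils::write.table(bundle$cohort$cohort$patients, p("cohort_patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$qpcr$ct, p("qpcr_ct.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$qpcr$lines, p("qpcr_lines.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tss_table(bundle$tss, p("tss.tsv"))
  write_bed_intervals(bundle$peaks, p("peaks.bed"))
  write_gene_set(bundle$induced, p("induced_genes.txt"))
  utils::write.table(bundle$orthologs, p("orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_set(bundle$truth$true_repressed, p("ground_truth_module.txt"))
  invisible(dir)
}
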