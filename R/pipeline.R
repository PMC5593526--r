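# End-to-end orchestration: screens -> intersection -> qPCR module call ->
# TSS-window enrichment -> prognosis, with a self-describing report.

#' Pipeline parameters
#'
#' Aggregates every stage's parameter block; the defaults are the
#' pipeline's canonical settings (ratio cutoff 0.5, pseudocount 1,
#' alpha 0.05, log2fc cutoff -2 with the 2-of-4 wild-type / 0-of-3 mutant
#' rule, 2 kb and 10 kb TSS windows, median survival split).
#'
#' @param microarray a [microarray_params()].
#' @param rnaseq an [rnaseq_params()].
#' @param cohort a [cohort_params()].
#' @param module a [module_params()].
#' @param windows TSS window half-widths (bp) for the enrichment stage.
#' @param prognosis_alpha significance level of the prognosis screen.
#' @param run_enrichment,run_prognosis stage toggles.
#' @return parameter list.
#' @export
pipeline_params <- function(microarray = microarray_params(),
                            rnaseq = rnaseq_params(),
                            cohort = cohort_params(),
                            module = module_params(),
                            windows = c(promoter = 2000, extended = 10000),
                            prognosis_alpha = 0.05,
                            run_enrichment = TRUE,
                            run_prognosis = TRUE) {
  list(microarray = microarray, rnaseq = rnaseq, cohort = cohort,
       module = module, windows = windows,
       prognosis_alpha = prognosis_alpha,
       run_enrichment = run_enrichment, run_prognosis = run_prognosis)
}

#' Run the full discovery-and-validation pipeline on an input bundle
#'
#' Stages: the three candidate screens, ortholog-mapped intersection, the
#' three-stage qPCR module call restricted to the intersection, TSS-window
#' peak enrichment of the induced set against the called module, and the
#' per-gene prognosis screen. The report echoes all thresholds and every
#' intermediate gene set, and is deterministic: no randomness is consumed
#' (the generators own all RNG).
#'
#' @param bundle input bundle as produced by [simulate_bundle()] (or
#'   assembled from files with the same structure).
#' @param params a [pipeline_params()].
#' @param quiet suppress per-stage progress messages.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(bundle, params = pipeline_params(), quiet = TRUE) {
  say <- function(...) if (!quiet) message("[p53repress] ", ...)
  need <- c("microarray", "rnaseq", "cohort", "qpcr", "orthologs")
  miss <- setdiff(need, names(bundle))
  if (length(miss)) stop("bundle missing inputs: ", paste(miss, collapse = ", "))
  if (params$module$require_knockdown_abrogation && is.null(bundle$qpcr)) {
    stop("knockdown validation required but no qPCR data supplied")
  }

  say("screen: microarray")
  scr_micro <- screen_microarray(bundle$microarray$expr,
                                 bundle$microarray$design,
                                 bundle$microarray$probe_map,
                                 params$microarray)
  say("screen: rnaseq")
  scr_rna <- screen_rnaseq(bundle$rnaseq$expr, bundle$rnaseq$design,
                           params$rnaseq)
  say("screen: cohort")
  scr_coh <- screen_cohort(bundle$cohort$cohort, params$cohort)

  say("intersect candidate sets")
  inter <- intersect_candidates(
    list(microarray = scr_micro, cohort = scr_coh),
    scr_rna, bundle$orthologs)
  candidates <- inter$genes

  say("qPCR module call on ", length(candidates), " candidates")
  qp <- bundle$qpcr
  if (!length(candidates)) {
    module_call <- list(module = character(0),
                        audit = data.frame(gene = character(0)))
    adr <- kd <- exo <- NULL
  } else {
  adr_fc <- panel_log2fc(qp$ct, candidates, "ADR", "untreated",
                         cell_lines = qp$lines$cell_line,
                         reference_gene = qp$reference_gene)
  adr <- classify_adr_repressed(adr_fc, qp$lines, params$module)
  kd_line <- qp$lines$cell_line[qp$lines$p53_status == "wt"][1L]
  kd_ctrl <- panel_log2fc(qp$ct, candidates, "siEGFP_ADR", "mock",
                          cell_lines = kd_line,
                          reference_gene = qp$reference_gene)
  kd_p53 <- panel_log2fc(qp$ct, candidates, "sip53_ADR", "mock",
                         cell_lines = kd_line,
                         reference_gene = qp$reference_gene)
  kd <- validate_knockdown(kd_ctrl, kd_p53, params$module)
  ad_line <- qp$lines$cell_line[qp$lines$p53_status == "mut"][1L]
  fc_adp53 <- panel_log2fc(qp$ct, candidates, "Adp53", "control",
                           cell_lines = ad_line,
                           reference_gene = qp$reference_gene)
  fc_adlacz <- panel_log2fc(qp$ct, candidates, "AdLacZ", "control",
                            cell_lines = ad_line,
                            reference_gene = qp$reference_gene)
  exo <- validate_exogenous_p53(fc_adp53, fc_adlacz, params$module)
  module_call <- call_module(candidates, adr, kd, exo, params$module)
  }

  enrich <- NULL
  if (params$run_enrichment && !is.null(bundle$tss) &&
      !is.null(bundle$peaks) && !is.null(bundle$induced)) {
    say("enrichment over ", length(params$windows), " windows")
    enrich <- enrichment_report(bundle$induced, module_call$module,
                                bundle$tss, list(peaks = bundle$peaks),
                                windows = params$windows)
  }

  prognosis <- NULL
  if (params$run_prognosis) {
    say("prognosis screen")
    prognosis <- prognosis_screen(bundle$cohort$cohort, module_call$module,
                                  alpha = params$prognosis_alpha)
  }

  structure(list(
    schema_version = "1.0",
    params = params,
    screens = list(microarray = scr_micro, rnaseq = scr_rna,
                   cohort = scr_coh),
    candidate_sets = inter$sets,
    venn = inter$venn,
    unmapped_mouse = inter$unmapped,
    candidates = candidates,
    qpcr = list(adr = adr, knockdown = kd, exogenous = exo),
    module = module_call$module,
    audit = module_call$audit,
    enrichment = enrich,
    prognosis = prognosis
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("p53-repressed module pipeline report (schema ", x$schema_version,
      ")\n", sep = "")
  cat("  candidates by screen:",
      paste(sprintf("%s=%d", names(x$candidate_sets),
                    lengths(x$candidate_sets)), collapse = ", "), "\n")
  cat("  intersection:", length(x$candidates), "genes\n")
  cat("  called module:", length(x$module), "genes\n")
  if (!is.null(x$prognosis)) {
    cat("  prognostic genes (nominal):",
        sum(x$prognosis$significant, na.rm = TRUE), "of",
        nrow(x$prognosis), "\n")
  }
  invisible(x)
}

#' Score recovery of a planted module
#'
#' @param called called gene set.
#' @param truth planted gene set.
#' @param universe full gene universe (for specificity).
#' @return named vector: sensitivity, specificity, n_called, n_true.
#' @export
recovery_score <- function(called, truth, universe) {
  nulls <- setdiff(universe, truth)
  c(sensitivity = length(intersect(called, truth)) / length(truth),
    specificity = 1 - length(intersect(called, nulls)) / length(nulls),
    n_called = length(called), n_true = length(truth))
}
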