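# Delta-delta-Ct quantification and the three-stage module-membership
# classifier: ADR repression across the cell-line panel, p53-knockdown
# dependence, and repression by exogenous p53.

#' Module-call parameters
#'
#' @param log2fc_cutoff a gene counts as repressed in a contrast iff its
#'   log2 fold change is `<=` this cutoff (inclusive; default -2).
#' @param min_wt_lines minimum number of wild-type lines repressed under
#'   ADR.
#' @param max_mut_lines maximum number of mutant lines allowed to be
#'   repressed under ADR ("but not in the mutant lines" read strictly as 0).
#' @param require_knockdown_abrogation require the p53-knockdown stage.
#' @param require_adp53_repression require the exogenous-p53 stage.
#' @param require_lacz_control require the Ad-LacZ control itself to stay
#'   above the cutoff for an exogenous-p53 pass.
#' @return parameter list.
#' @export
module_params <- function(log2fc_cutoff = -2, min_wt_lines = 2,
                          max_mut_lines = 0,
                          require_knockdown_abrogation = TRUE,
                          require_adp53_repression = TRUE,
                          require_lacz_control = TRUE) {
  stopifnot(log2fc_cutoff < 0, min_wt_lines >= 1, max_mut_lines >= 0)
  list(log2fc_cutoff = log2fc_cutoff, min_wt_lines = min_wt_lines,
       max_mut_lines = max_mut_lines,
       require_knockdown_abrogation = require_knockdown_abrogation,
       require_adp53_repression = require_adp53_repression,
       require_lacz_control = require_lacz_control)
}

# Per-replicate delta Ct (target minus reference, matched on cell line,
# condition and replicate). Errors if the reference gene is missing for any
# replicate of the requested conditions.
delta_ct <- function(ct, gene, cell_line, condition, reference_gene) {
  g <- ct[ct$gene == gene & ct$cell_line == cell_line &
            ct$condition == condition, ]
  r <- ct[ct$gene == reference_gene & ct$cell_line == cell_line &
            ct$condition == condition, ]
  if (!nrow(g)) stop("no Ct records for gene ", gene, " in ", cell_line,
                     "/", condition)
  idx <- match(g$replicate, r$replicate)
  if (anyNA(idx)) stop("reference gene ", reference_gene,
                       " missing for some replicates of ", cell_line, "/",
                       condition)
  g$ct - r$ct[idx]
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per replicate, delta Ct = Ct(target) - Ct(reference); then
#' delta-delta-Ct = mean(delta Ct, case) - mean(delta Ct, control),
#' log2 fold change = -delta-delta-Ct and fold = 2^(-delta-delta-Ct).
#' Replicates are not paired across conditions (group means). The reported
#' p-value is a two-tailed t test of the case vs control delta-Ct groups;
#' with a single replicate in either group, sd and p are `NA`.
#'
#' @param ct long Ct table (columns gene, cell_line, condition, replicate,
#'   ct).
#' @param gene target gene.
#' @param cell_line cell line.
#' @param case_condition,control_condition condition labels contrasted.
#' @param reference_gene reference (beta-actin role).
#' @return one-row data.frame of class `fold_change` with delta-delta-Ct,
#'   log2fc, fold, per-group sd and the t-test p-value.
#' @export
compute_ddct <- function(ct, gene, cell_line, case_condition,
                         control_condition, reference_gene = "ACTB") {
  dc_case <- delta_ct(ct, gene, cell_line, case_condition, reference_gene)
  dc_ctrl <- delta_ct(ct, gene, cell_line, control_condition, reference_gene)
  ddct <- mean(dc_case) - mean(dc_ctrl)
  p <- sd_case <- sd_ctrl <- NA_real_
  if (length(dc_case) > 1L) sd_case <- stats::sd(dc_case)
  if (length(dc_ctrl) > 1L) sd_ctrl <- stats::sd(dc_ctrl)
  if (length(dc_case) > 1L && length(dc_ctrl) > 1L &&
      (stats::sd(dc_case) > 0 || stats::sd(dc_ctrl) > 0)) {
    p <- stats::t.test(dc_case, dc_ctrl)$p.value
  }
  out <- data.frame(gene = gene, cell_line = cell_line,
                    case = case_condition, control = control_condition,
                    delta_delta_ct = ddct, log2fc = -ddct, fold = 2^(-ddct),
                    sd_case = sd_case, sd_control = sd_ctrl, p_value = p,
                    n_case = length(dc_case), n_control = length(dc_ctrl),
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_change", "data.frame")
  out
}

#' Delta-delta-Ct fold changes for a panel of genes and cell lines
#'
#' Vectorized driver over [compute_ddct()] for one contrast.
#'
#' @param ct long Ct table.
#' @param genes target genes.
#' @param cell_lines cell lines (default: all lines in `ct`).
#' @inheritParams compute_ddct
#' @return data.frame with one row per gene x cell line.
#' @export
panel_log2fc <- function(ct, genes, case_condition, control_condition,
                         cell_lines = NULL, reference_gene = "ACTB") {
  if (is.null(cell_lines)) {
    cell_lines <- unique(ct$cell_line[ct$condition %in%
                                        c(case_condition, control_condition)])
  }
  grid <- expand.grid(gene = genes, cell_line = cell_lines,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    compute_ddct(ct, grid$gene[i], grid$cell_line[i], case_condition,
                 control_condition, reference_gene)
  }))
  rownames(out) <- NULL
  out
}

#' Stage 1: ADR repression across the cell-line panel
#'
#' A gene passes iff it is repressed (log2fc <= cutoff, inclusive) in at
#' least `min_wt_lines` wild-type lines and at most `max_mut_lines` mutant
#' lines.
#'
#' @param fc output of [panel_log2fc()] for the ADR-vs-untreated contrast.
#' @param statuses data.frame with columns `cell_line`, `p53_status`.
#' @param params a [module_params()].
#' @return data.frame per gene: wt/mut repressed-line counts and `pass`.
#' @export
classify_adr_repressed <- function(fc, statuses, params = module_params()) {
  status <- statuses$p53_status[match(fc$cell_line, statuses$cell_line)]
  if (anyNA(status)) stop("cell line missing from status table")
  if (sum(statuses$p53_status == "wt") < params$min_wt_lines) {
    stop("panel has fewer wild-type lines than min_wt_lines")
  }
  rep_flag <- fc$log2fc <= params$log2fc_cutoff
  n_wt <- tapply(rep_flag & status == "wt", fc$gene, sum)
  n_mut <- tapply(rep_flag & status == "mut", fc$gene, sum)
  data.frame(gene = names(n_wt),
             n_wt_repressed = as.integer(n_wt),
             n_mut_repressed = as.integer(n_mut),
             pass = as.integer(n_wt) >= params$min_wt_lines &
               as.integer(n_mut) <= params$max_mut_lines,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stage 2: p53-knockdown dependence
#'
#' A gene is p53-dependent iff it is repressed under the control siRNA with
#' ADR (log2fc <= cutoff) and the repression is abrogated under si-p53 with
#' ADR (log2fc > cutoff). Genes never suppressed under the control arm are
#' flagged as vacuous rather than merely failed.
#'
#' @param fc_control_si,fc_p53_si data.frames with columns `gene`,
#'   `log2fc` for the control-siRNA and si-p53 arms.
#' @param params a [module_params()].
#' @return data.frame per gene: `pass` and `vacuous`.
#' @export
validate_knockdown <- function(fc_control_si, fc_p53_si,
                               params = module_params()) {
  idx <- match(fc_control_si$gene, fc_p53_si$gene)
  if (anyNA(idx)) stop("si-p53 arm missing genes")
  ctrl <- fc_control_si$log2fc
  kd <- fc_p53_si$log2fc[idx]
  data.frame(gene = fc_control_si$gene,
             log2fc_control_si = ctrl, log2fc_sip53 = kd,
             pass = ctrl <= params$log2fc_cutoff & kd > params$log2fc_cutoff,
             vacuous = ctrl > params$log2fc_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stage 3: repression by exogenous p53
#'
#' A gene passes iff log2fc under Ad-p53 (vs untransduced control) is
#' <= cutoff while the Ad-LacZ control stays strictly above the cutoff
#' (so the repression is attributable to p53, not to transduction).
#'
#' @param fc_adp53,fc_adlacz data.frames with columns `gene`, `log2fc`.
#' @param params a [module_params()].
#' @return data.frame per gene with `pass`.
#' @export
validate_exogenous_p53 <- function(fc_adp53, fc_adlacz,
                                   params = module_params()) {
  idx <- match(fc_adp53$gene, fc_adlacz$gene)
  if (anyNA(idx)) stop("Ad-LacZ arm missing genes")
  p53 <- fc_adp53$log2fc
  lacz <- fc_adlacz$log2fc[idx]
  pass <- p53 <= params$log2fc_cutoff
  if (params$require_lacz_control) pass <- pass & lacz > params$log2fc_cutoff
  data.frame(gene = fc_adp53$gene,
             log2fc_adp53 = p53, log2fc_adlacz = lacz, pass = pass,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Final module call with per-gene audit trail
#'
#' A candidate is a module member iff it passes the ADR-panel stage and,
#' where required, the knockdown and exogenous-p53 stages. The audit trail
#' records the first stage that excluded each non-member.
#'
#' @param candidates candidate gene set.
#' @param adr stage-1 table from [classify_adr_repressed()].
#' @param knockdown stage-2 table from [validate_knockdown()] (or `NULL`).
#' @param exogenous stage-3 table from [validate_exogenous_p53()] (or
#'   `NULL`).
#' @param params a [module_params()].
#' @return list with `module` (member gene set) and `audit` (per-gene stage
#'   booleans and exclusion reason).
#' @export
call_module <- function(candidates, adr, knockdown = NULL, exogenous = NULL,
                        params = module_params()) {
  candidates <- sort(unique(candidates))
  get_pass <- function(tab, stage) {
    if (is.null(tab)) {
      if (stage == "knockdown" && params$require_knockdown_abrogation ||
          stage == "exogenous_p53" && params$require_adp53_repression) {
        stop("stage '", stage, "' is required but no results were supplied")
      }
      return(rep(TRUE, length(candidates)))
    }
    p <- tab$pass[match(candidates, tab$gene)]
    if (anyNA(p)) stop("stage '", stage, "' missing candidates: ",
                       paste(candidates[is.na(p)][1:5], collapse = ", "))
    p
  }
  adr_pass <- get_pass(adr, "adr_panel")
  kd_pass <- get_pass(if (params$require_knockdown_abrogation) knockdown, "knockdown")
  exo_pass <- get_pass(if (params$require_adp53_repression) exogenous, "exogenous_p53")
  member <- adr_pass & kd_pass & exo_pass
  excluded_by <- rep(NA_character_, length(candidates))
  excluded_by[!exo_pass] <- "exogenous_p53"
  excluded_by[!kd_pass] <- "knockdown"
  excluded_by[!adr_pass] <- "adr_panel"
  list(module = candidates[member],
       audit = data.frame(gene = candidates, adr_pass = adr_pass,
                          knockdown_pass = kd_pass, exogenous_pass = exo_pass,
                          member = member, excluded_by = excluded_by,
                          stringsAsFactors = FALSE, row.names = NULL))
}
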