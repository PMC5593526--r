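# The three candidate screens, their cross-dataset intersection, and the
# multi-tissue irradiation-response profile.

#' Microarray screen parameters
#'
#' The screen statistic is A/B where A is the per-probe median over the
#' ADR-treated wild-type timepoints and B the minimum over the untreated
#' wild-type baseline and every p53-null sample; a probe passes iff
#' A/B < `ratio_threshold` (strict).
#'
#' @param treated_codes condition codes entering the median (A).
#' @param baseline_codes condition codes entering the minimum (B).
#' @param ratio_threshold strict upper bound on A/B.
#' @param probe_collapse `"any_probe"` (gene passes if any probe passes) or
#'   `"median_probe"` (gene statistic is the median probe ratio).
#' @return parameter list.
#' @export
microarray_params <- function(treated_codes = c("W12", "W24", "W48"),
                              baseline_codes = c("W0", "K0", "K12", "K24", "K48"),
                              ratio_threshold = 0.5,
                              probe_collapse = c("any_probe", "median_probe")) {
  stopifnot(ratio_threshold > 0,
            !length(intersect(treated_codes, baseline_codes)))
  list(treated_codes = treated_codes, baseline_codes = baseline_codes,
       ratio_threshold = ratio_threshold,
       probe_collapse = match.arg(probe_collapse))
}

#' RNA-seq screen parameters
#'
#' @param pseudocount constant added to every FPKM before averaging.
#' @param ratio_threshold strict upper bound on A/B.
#' @param screen_tissue tissue used for candidate selection.
#' @return parameter list.
#' @export
rnaseq_params <- function(pseudocount = 1, ratio_threshold = 0.5,
                          screen_tissue = "mammary_gland") {
  stopifnot(pseudocount >= 0, ratio_threshold > 0)
  list(pseudocount = pseudocount, ratio_threshold = ratio_threshold,
       screen_tissue = screen_tissue)
}

#' Cohort screen parameters
#'
#' @param alpha per-gene significance level (no multiple-testing
#'   correction is applied).
#' @param variance_rule `"f_test_gate"` (an F test at 0.05 chooses pooled
#'   vs Welch) or `"welch_always"`.
#' @return parameter list.
#' @export
cohort_params <- function(alpha = 0.05,
                          variance_rule = c("f_test_gate", "welch_always")) {
  stopifnot(alpha > 0, alpha < 1)
  list(alpha = alpha, variance_rule = match.arg(variance_rule))
}

new_screen_result <- function(gene_stats, screen, params, extra = list()) {
  structure(c(list(gene_stats = gene_stats, screen = screen, params = params),
              extra),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result [", x$screen, "]: ", nrow(x$gene_stats), " genes, ",
      sum(x$gene_stats$candidate), " candidates\n", sep = "")
  invisible(x)
}

#' Extract the candidate gene set from a screen result
#'
#' @param x a `screen_result`.
#' @return sorted character vector of candidate genes.
#' @export
screen_candidates <- function(x) {
  stopifnot(inherits(x, "screen_result"))
  sort(x$gene_stats$gene[x$gene_stats$candidate])
}

sample_cols <- function(expr, design, codes) {
  ids <- design$sample_id[design$condition_code %in% codes]
  miss <- setdiff(codes, design$condition_code)
  if (length(miss)) stop("condition codes absent from design: ",
                         paste(miss, collapse = ", "))
  expr[, ids, drop = FALSE]
}

#' Microarray candidate screen
#'
#' Per probe, A = median expression over the treated wild-type codes and
#' B = minimum over the baseline codes; the probe is a hit iff
#' A/B < threshold (strict). Probes with B = 0 are non-evaluable and are
#' excluded with a logged count rather than an error. Probe hits are
#' collapsed to genes by the `probe_collapse` rule.
#'
#' @param expr probe-level expression matrix.
#' @param design sample design (all eight condition codes present).
#' @param probe_map data.frame with columns `probe_id`, `gene`.
#' @param params a [microarray_params()].
#' @return `screen_result` with per-gene and per-probe statistics.
#' @export
screen_microarray <- function(expr, design, probe_map,
                              params = microarray_params()) {
  stopifnot(all(rownames(expr) %in% probe_map$probe_id))
  treated <- sample_cols(expr, design, params$treated_codes)
  baseline <- sample_cols(expr, design, params$baseline_codes)
  A <- apply(treated, 1L, stats::median)
  B <- apply(baseline, 1L, min)
  evaluable <- B > 0
  ratio <- ifelse(evaluable, A / B, NA_real_)
  hit <- evaluable & ratio < params$ratio_threshold
  gene <- probe_map$gene[match(rownames(expr), probe_map$probe_id)]
  probe_stats <- data.frame(probe_id = rownames(expr), gene = gene,
                            A = A, B = B, ratio = ratio,
                            evaluable = evaluable, hit = hit,
                            stringsAsFactors = FALSE, row.names = NULL)
  keep <- probe_stats[probe_stats$evaluable, ]
  if (params$probe_collapse == "any_probe") {
    stat <- tapply(keep$ratio, keep$gene, min)
  } else {
    stat <- tapply(keep$ratio, keep$gene, stats::median)
  }
  gene_stats <- data.frame(gene = names(stat), statistic = as.numeric(stat),
                           candidate = as.numeric(stat) < params$ratio_threshold,
                           stringsAsFactors = FALSE, row.names = NULL)
  new_screen_result(gene_stats, "microarray", params,
                    list(probe_stats = probe_stats,
                         n_non_evaluable = sum(!evaluable)))
}

#' RNA-seq candidate screen
#'
#' Within the screen tissue, the pseudocount is added to every FPKM value
#' before averaging; then A = mean(WX) and B = min(mean W, mean KX, mean K)
#' per gene, candidate iff A/B < threshold (strict).
#'
#' @param expr gene-level FPKM matrix.
#' @param design sample design with tissue labels and W/WX/K/KX codes.
#' @param params an [rnaseq_params()].
#' @return `screen_result` with components A, B and the group means.
#' @export
screen_rnaseq <- function(expr, design, params = rnaseq_params()) {
  design <- design[design$tissue == params$screen_tissue, , drop = FALSE]
  if (!nrow(design)) stop("no samples for tissue ", params$screen_tissue)
  need <- c("W", "WX", "K", "KX")
  miss <- setdiff(need, design$condition_code)
  if (length(miss)) stop("missing condition group(s) in tissue ",
                         params$screen_tissue, ": ",
                         paste(miss, collapse = ", "))
  grp_mean <- sapply(need, function(code) {
    rowMeans(expr[, design$sample_id[design$condition_code == code],
                  drop = FALSE] + params$pseudocount)
  })
  A <- grp_mean[, "WX"]
  B <- pmin(grp_mean[, "W"], grp_mean[, "KX"], grp_mean[, "K"])
  ratio <- A / B
  gene_stats <- data.frame(gene = rownames(expr), statistic = ratio,
                           A = A, B = B,
                           mean_W = grp_mean[, "W"], mean_WX = A,
                           mean_K = grp_mean[, "K"], mean_KX = grp_mean[, "KX"],
                           candidate = ratio < params$ratio_threshold,
                           stringsAsFactors = FALSE, row.names = NULL)
  new_screen_result(gene_stats, "rnaseq", params)
}

# Two-sample t-test with the F-test variance gate and a defined value for
# degenerate (zero-variance) inputs: equal constants give p = 1, unequal
# constants give p = 0.
gated_t_p <- function(x, y, variance_rule) {
  vx <- stats::var(x); vy <- stats::var(y)
  if ((is.na(vx) || vx == 0) && (is.na(vy) || vy == 0)) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  var_equal <- if (variance_rule == "welch_always") FALSE else {
    stats::var.test(x, y)$p.value >= 0.05
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Tumor-cohort candidate screen
#'
#' Per gene, a two-tailed two-sample t test of wild-type-p53 vs mutant-p53
#' tumors (pooled vs Welch chosen by an F test at 0.05 under the default
#' gate); the gene is a candidate iff p < alpha and the wild-type mean is
#' lower. Nominal p-values, no multiplicity correction.
#'
#' @param cohort a [cohort_table()].
#' @param params a [cohort_params()].
#' @return `screen_result` with per-gene p-values and group means.
#' @export
screen_cohort <- function(cohort, params = cohort_params()) {
  stopifnot(inherits(cohort, "cohort_table"))
  wt <- cohort$patients$p53_status == "wt"
  mut <- cohort$patients$p53_status == "mut"
  if (!any(wt) || !any(mut)) stop("both p53 genotype groups must be non-empty")
  ewt <- cohort$expr[, wt, drop = FALSE]
  emut <- cohort$expr[, mut, drop = FALSE]
  p <- vapply(seq_len(nrow(ewt)), function(i) {
    gated_t_p(ewt[i, ], emut[i, ], params$variance_rule)
  }, numeric(1))
  mean_wt <- rowMeans(ewt); mean_mut <- rowMeans(emut)
  gene_stats <- data.frame(gene = rownames(cohort$expr), statistic = p,
                           mean_wt = mean_wt, mean_mut = mean_mut,
                           candidate = p < params$alpha & mean_wt < mean_mut,
                           stringsAsFactors = FALSE, row.names = NULL)
  new_screen_result(gene_stats, "cohort", params)
}

as_gene_set <- function(x) {
  if (inherits(x, "screen_result")) screen_candidates(x) else sort(unique(x))
}

#' Intersect candidate sets across datasets
#'
#' Mouse candidates are translated to human symbols through the ortholog
#' map before intersecting; mouse symbols with no ortholog are counted and
#' reported, never silently dropped. All pairwise intersection sizes are
#' returned for the Venn diagram.
#'
#' @param human_sets list of `screen_result`s or character vectors
#'   (human symbols).
#' @param mouse_set `screen_result` or character vector of mouse symbols.
#' @param orthologs data.frame with columns `human`, `mouse`.
#' @return list with `genes` (the intersection), `sets` (all translated
#'   sets), `venn` (named pairwise and total intersection sizes) and
#'   `unmapped` mouse symbols.
#' @export
intersect_candidates <- function(human_sets, mouse_set, orthologs) {
  sets <- lapply(human_sets, as_gene_set)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("human", seq_along(sets))
  }
  mapped <- map_orthologs(as_gene_set(mouse_set), orthologs)
  sets$mouse <- sort(mapped$human)
  inter <- Reduce(intersect, sets)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2L, simplify = FALSE)
  venn <- c(
    stats::setNames(lengths(sets), paste0("n_", nm)),
    stats::setNames(
      vapply(pairs, function(p) length(intersect(sets[[p[1]]], sets[[p[2]]])),
             integer(1)),
      vapply(pairs, function(p) paste0("n_", p[1], "_", p[2]), character(1))),
    n_all = length(inter)
  )
  list(genes = sort(inter), sets = sets, venn = venn,
       unmapped = mapped$unmapped)
}

#' Per-tissue irradiation-response profile
#'
#' For each gene and tissue, the log2 ratio of mean irradiated to mean
#' non-irradiated expression within one genotype, with the pseudocount
#' applied per sample before averaging as in [screen_rnaseq()]. Tissues
#' lacking either arm are omitted with a warning.
#'
#' @param expr gene-level FPKM matrix.
#' @param design sample design.
#' @param genes genes to profile.
#' @param genotype `"p53_wt"` or `"p53_null"`.
#' @param pseudocount constant added per sample.
#' @return genes x tissues matrix of log2 ratios.
#' @export
tissue_profile <- function(expr, design, genes, genotype = c("p53_wt", "p53_null"),
                           pseudocount = 1) {
  genotype <- match.arg(genotype)
  design <- design[design$genotype == genotype, , drop = FALSE]
  irr_code <- if (genotype == "p53_wt") "WX" else "KX"
  ctl_code <- if (genotype == "p53_wt") "W" else "K"
  genes <- intersect(genes, rownames(expr))
  tissues <- unique(design$tissue)
  cols <- lapply(tissues, function(ti) {
    d <- design[design$tissue == ti, ]
    irr <- d$sample_id[d$condition_code == irr_code]
    ctl <- d$sample_id[d$condition_code == ctl_code]
    if (!length(irr) || !length(ctl)) {
      warning("tissue ", ti, " lacks one arm; omitted")
      return(NULL)
    }
    log2(rowMeans(expr[genes, irr, drop = FALSE] + pseudocount) /
           rowMeans(expr[genes, ctl, drop = FALSE] + pseudocount))
  })
  names(cols) <- tissues
  cols <- cols[!vapply(cols, is.null, logical(1))]
  do.call(cbind, cols)
}
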