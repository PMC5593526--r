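# Strand-aware TSS-window peak annotation and exact 2x2 enrichment testing
# between gene sets (p53-induced genes vs the repressed module).

#' Annotate genes for peak overlap within a TSS window
#'
#' A gene is positive iff any peak interval intersects the closed window of
#' `window_bp` on either side of its TSS base — implemented on 0-based
#' half-open intervals as `[tss - window_bp, tss + window_bp + 1)`. The
#' window is symmetric, so strand affects only the upstream choice of the
#' TSS base, not the window itself. Genes on chromosomes absent from the
#' peak set are negative, with a logged count.
#'
#' @param tss TSS annotation (gene, chrom, tss_position, strand).
#' @param peaks BED-like interval data.frame (chrom, start, end).
#' @param window_bp window half-width in bp (2000 for the promoter window,
#'   10000 for the extended window).
#' @return named logical vector over `tss$gene`, with attribute
#'   `n_missing_chrom`.
#' @export
annotate_tss_overlap <- function(tss, peaks, window_bp = 2000) {
  stopifnot(window_bp > 0)
  win_start <- tss$tss_position - window_bp
  win_end <- tss$tss_position + window_bp + 1  # half-open
  out <- logical(nrow(tss))
  present <- tss$chrom %in% unique(peaks$chrom)
  for (chr in unique(tss$chrom[present])) {
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    gi <- which(tss$chrom == chr)
    out[gi] <- vapply(gi, function(i) {
      any(p$start < win_end[i] & p$end > win_start[i])
    }, logical(1))
  }
  structure(stats::setNames(out, tss$gene),
            n_missing_chrom = sum(!present))
}

#' Build the 2x2 contingency table for two gene sets
#'
#' Rows are the two gene sets, columns the with/without-feature counts.
#' Genes missing from the overlap annotation are excluded from the
#' denominators and reported via the `excluded` attribute.
#'
#' @param group1,group2 gene sets.
#' @param overlaps named logical vector (from [annotate_tss_overlap()]).
#' @return 2x2 integer matrix with attribute `excluded` (per-group counts
#'   of unannotated genes).
#' @export
count_enrichment <- function(group1, group2, overlaps) {
  tab_row <- function(g) {
    known <- g[g %in% names(overlaps)]
    c(sum(overlaps[known]), length(known) - sum(overlaps[known]),
      length(g) - length(known))
  }
  r1 <- tab_row(unique(group1)); r2 <- tab_row(unique(group2))
  if (r2[1] + r2[2] == 0) stop("group2 has no annotated genes")
  if (r1[1] + r1[2] == 0) stop("group1 has no annotated genes")
  m <- matrix(as.integer(c(r1[1:2], r2[1:2])), nrow = 2, byrow = TRUE,
              dimnames = list(c("group1", "group2"),
                              c("with_peak", "without_peak")))
  attr(m, "excluded") <- c(group1 = r1[3], group2 = r2[3])
  m
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value under the hypergeometric null with all margins fixed,
#' using the standard two-sided definition: the sum of the probabilities of
#' every table (with the same margins) whose probability does not exceed
#' that of the observed table (up to a 1 + 1e-7 relative tie tolerance).
#' Probabilities are computed in log space via `lchoose` for numerical
#' safety. A zero margin gives p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows = groups, columns = with/without feature).
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  m <- as.matrix(table)
  stopifnot(identical(dim(m), c(2L, 2L)))
  if (any(m < 0) || any(m != floor(m))) {
    stop("counts must be non-negative integers")
  }
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  k <- sum(m[, 1]); n <- sum(m)
  if (n == 0) stop("empty table")
  if (r1 == 0 || r2 == 0 || k == 0 || k == n) return(1)
  support <- max(0, k - r2):min(k, r1)
  logp <- lchoose(r1, support) + lchoose(r2, k - support) - lchoose(n, k)
  log_obs <- logp[match(a, support)]
  p <- sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
  min(p, 1)
}

#' Counts, percentages and Fisher p for one enrichment configuration
#'
#' Convenience constructor from positive counts and group sizes; used both
#' by [enrichment_report()] and to re-analyze published contingency counts.
#' Note that a percentage denominator and a test denominator can legally
#' differ when a group member lacks annotation in one accounting: the
#' function takes the counts as given.
#'
#' @param k1,n1 positives and size of group 1.
#' @param k2,n2 positives and size of group 2.
#' @return list with the 2x2 `table`, `percent` (one decimal place, per
#'   group) and the two-sided Fisher `p_value`.
#' @export
enrichment_from_counts <- function(k1, n1, k2, n2) {
  stopifnot(k1 <= n1, k2 <= n2)
  tab <- matrix(as.integer(c(k1, n1 - k1, k2, n2 - k2)), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("group1", "group2"),
                                c("with_peak", "without_peak")))
  list(table = tab,
       percent = round(c(group1 = 100 * k1 / n1, group2 = 100 * k2 / n2), 1),
       p_value = fisher_exact_two_sided(tab))
}

#' Full enrichment report over windows and peak sources
#'
#' For each window, per-gene overlaps are computed for every peak source
#' and combined (`"any"`: a peak in at least one source counts; `"all"`:
#' consensus across sources); counts, percentages (one decimal place) and
#' the two-sided Fisher p are emitted for the combined call and per source.
#'
#' @param induced,module gene sets (group 1 and group 2).
#' @param tss TSS annotation.
#' @param peak_sources named list of peak data.frames.
#' @param windows named numeric vector of window half-widths.
#' @param combine `"any"` or `"all"`.
#' @return nested list: per window, `combined` and `per_source` entries,
#'   each with `table`, `percent`, `p_value`.
#' @export
enrichment_report <- function(induced, module, tss, peak_sources,
                              windows = c(promoter = 2000, extended = 10000),
                              combine = c("any", "all")) {
  combine <- match.arg(combine)
  if (!is.list(peak_sources)) peak_sources <- list(peaks = peak_sources)
  lapply(windows, function(w) {
    ov_src <- lapply(peak_sources, annotate_tss_overlap, tss = tss,
                     window_bp = w)
    comb <- Reduce(if (combine == "any") `|` else `&`, ov_src)
    one <- function(ov) {
      tab <- count_enrichment(induced, module, ov)
      list(table = tab,
           percent = round(100 * tab[, 1] / rowSums(tab), 1),
           p_value = fisher_exact_two_sided(tab),
           excluded = attr(tab, "excluded"))
    }
    list(combined = one(comb), per_source = lapply(ov_src, one))
  })
}
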