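# Median-split Kaplan-Meier analysis, log-rank testing and the
# mutation-association test over the repressed module.

#' Split a cohort at the per-gene median expression
#'
#' Patients with expression strictly greater than the median are assigned
#' to the High group, all others (including values tied at the median) to
#' Low. A constant expression vector cannot be split and is an error.
#'
#' @param cohort a [cohort_table()], or a numeric vector of expression
#'   values.
#' @param gene gene symbol (when `cohort` is a cohort_table).
#' @return factor with levels `Low`, `High` and attribute `cutoff`.
#' @export
median_split <- function(cohort, gene = NULL) {
  x <- if (inherits(cohort, "cohort_table")) {
    if (!gene %in% rownames(cohort$expr)) stop("gene not in cohort: ", gene)
    cohort$expr[gene, ]
  } else as.numeric(cohort)
  if (length(unique(x)) == 1L) {
    stop("degenerate split: all expression values identical")
  }
  med <- stats::median(x)
  g <- factor(ifelse(x > med, "High", "Low"), levels = c("Low", "High"))
  if (!all(c("Low", "High") %in% g)) {
    stop("degenerate split: one group is empty")
  }
  attr(g, "cutoff") <- med
  g
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the estimate as a
#' plain structure with the package's invariants (survival starts at 1, is
#' non-increasing, lies in [0, 1]).
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (TRUE = death observed).
#' @return list of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "distinct times,",
      sum(x$n_event), "events\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (observed minus expected events over the
#' hypergeometric variance, summed across distinct event times, with the
#' simultaneous-event tie convention), referred to chi-square on 1 df.
#' Wraps [survival::survdiff()].
#'
#' @param groups two-level grouping factor.
#' @param times follow-up times.
#' @param events event indicators.
#' @return list: `statistic`, `p_value`, `df`, `observed`, `expected`.
#' @export
logrank_test <- function(groups, times, events) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2L) {
    stop("log-rank test requires exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ groups)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       df = 1L, observed = sd$obs, expected = sd$exp)
}

#' Association between p53 status and the expression split
#'
#' Builds the 2x2 table of p53 status (wt/mut) against the High/Low median
#' split for a gene and applies the exact two-sided Fisher test.
#'
#' @param cohort a [cohort_table()].
#' @param gene gene symbol.
#' @param split optional precomputed split factor (defaults to
#'   [median_split()]).
#' @return list: `table` (2x2), `p_value`.
#' @export
mutation_association <- function(cohort, gene, split = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(split)) split <- median_split(cohort, gene)
  status <- factor(cohort$patients$p53_status, levels = c("wt", "mut"))
  if (!all(levels(status) %in% status)) {
    stop("both p53 genotype groups must be non-empty")
  }
  tab <- table(status, split)
  m <- matrix(as.integer(tab), nrow = 2, dimnames = dimnames(tab))
  list(table = m, p_value = fisher_exact_two_sided(m))
}

# Restricted-mean survival per group, used only to report which group has
# the worse outcome.
restricted_means <- function(groups, times, events) {
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ groups)
  tab <- summary(fit, rmean = max(times))$table
  stats::setNames(tab[, "rmean"], sub("^groups=", "", rownames(tab)))
}

#' Per-gene prognosis screen over a gene module
#'
#' For each gene: median split, two-group log-rank test at `alpha`
#' (nominal p-values; a Benjamini-Hochberg-adjusted column is added when
#' `adjust = TRUE` but does not drive the `significant` flag by default),
#' and the direction of the effect by comparing restricted mean survival.
#' Genes with a degenerate split are reported with `NA` p-values.
#'
#' @param cohort a [cohort_table()].
#' @param module gene set to screen.
#' @param alpha significance level.
#' @param adjust also report Benjamini-Hochberg adjusted p-values.
#' @return data.frame per gene: `p_value`, `direction`
#'   (`"high_worse"`/`"low_worse"`), `significant`.
#' @export
prognosis_screen <- function(cohort, module, alpha = 0.05, adjust = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  module <- intersect(module, rownames(cohort$expr))
  rows <- lapply(module, function(g) {
    split <- tryCatch(median_split(cohort, g), error = function(e) NULL)
    if (is.null(split)) {
      return(data.frame(gene = g, p_value = NA_real_,
                        direction = NA_character_, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    lr <- logrank_test(split, cohort$patients$time, cohort$patients$event)
    rm <- restricted_means(split, cohort$patients$time,
                           cohort$patients$event)
    data.frame(gene = g, p_value = lr$p_value,
               direction = if (rm[["High"]] < rm[["Low"]]) "high_worse" else "low_worse",
               significant = lr$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
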