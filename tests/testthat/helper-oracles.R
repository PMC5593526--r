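# Independent oracles used across the suite. They recompute each criterion
# directly from first principles (different code paths from the package:
# choose() products instead of log-space lchoose, explicit per-gene loops
# instead of vectorized screens).

# Two-sided Fisher p by explicit enumeration of every table with the
# observed margins; probabilities as ratios of binomial coefficients.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; k <- a + c_; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || k == 0 || k == n) return(1)
  support <- max(0, k - r2):min(k, r1)
  prob <- choose(r1, support) * choose(r2, k - support) / choose(n, k)
  p_obs <- prob[match(a, support)]
  min(sum(prob[prob <= p_obs * (1 + 1e-7)]), 1)
}

# Direct recomputation of the microarray criterion: per probe, median of
# treated samples over minimum of baseline samples, strict < threshold;
# probes with zero baseline minimum are dropped; a gene passes if any of
# its evaluable probes passes.
microarray_oracle <- function(expr, design, probe_map, threshold = 0.5) {
  treated <- design$sample_id[design$condition_code %in% c("W12", "W24", "W48")]
  baseline <- design$sample_id[design$condition_code %in%
                                 c("W0", "K0", "K12", "K24", "K48")]
  genes <- unique(probe_map$gene)
  hits <- vapply(genes, function(g) {
    probes <- probe_map$probe_id[probe_map$gene == g]
    pass <- FALSE
    for (p in probes) {
      A <- median(expr[p, treated])
      B <- min(expr[p, baseline])
      if (B > 0 && A / B < threshold) pass <- TRUE
    }
    pass
  }, logical(1))
  sort(genes[hits])
}

# Direct recomputation of the RNA-seq criterion in one tissue.
rnaseq_oracle <- function(expr, design, tissue = "mammary_gland",
                          pseudocount = 1, threshold = 0.5) {
  d <- design[design$tissue == tissue, ]
  grp <- function(code) d$sample_id[d$condition_code == code]
  hits <- vapply(rownames(expr), function(g) {
    A <- mean(expr[g, grp("WX")] + pseudocount)
    B <- min(mean(expr[g, grp("W")] + pseudocount),
             mean(expr[g, grp("KX")] + pseudocount),
             mean(expr[g, grp("K")] + pseudocount))
    A / B < threshold
  }, logical(1))
  sort(rownames(expr)[hits])
}

# Direct recomputation of the cohort criterion with the F-test gate.
cohort_oracle <- function(cohort, alpha = 0.05) {
  wt <- cohort$patients$p53_status == "wt"
  hits <- vapply(rownames(cohort$expr), function(g) {
    x <- cohort$expr[g, wt]; y <- cohort$expr[g, !wt]
    if (var(x) == 0 && var(y) == 0) {
      p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else {
      eq <- var.test(x, y)$p.value >= 0.05
      p <- t.test(x, y, var.equal = eq)$p.value
    }
    p < alpha && mean(x) < mean(y)
  }, logical(1))
  sort(rownames(cohort$expr)[hits])
}

# Hand-rolled product-limit estimate at the distinct event times.
km_oracle <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- as.logical(events)[ord]
  ev_times <- sort(unique(times[events]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, surv = surv)
}
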