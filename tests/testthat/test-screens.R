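# Fixture: a small probe-level matrix over the eight time-course conditions
# with hand-chosen values.
micro_fixture <- function(values_by_probe) {
  conds <- c("W0", "W12", "W24", "W48", "K0", "K12", "K24", "K48")
  expr <- do.call(rbind, values_by_probe)
  dimnames(expr) <- list(names(values_by_probe), conds)
  design <- make_design(conds, rep(c("p53_wt", "p53_null"), each = 4),
                        "ADR", rep(c(0, 12, 24, 48), 2))
  list(expr = expr, design = design)
}

test_that("microarray screen applies the median/min ratio with strict threshold", {
  fx <- micro_fixture(list(
    p1 = c(30, 10, 10, 10, 30, 30, 30, 30),   # ratio 1/3 -> candidate
    p2 = c(30, 15, 15, 15, 30, 30, 30, 30),   # ratio exactly 0.5 -> not
    p3 = c(30, 40, 10, 40, 30, 30, 30, 30)))  # median 40 -> ratio > 1
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene = c("GA", "GB", "GC"))
  scr <- screen_microarray(fx$expr, fx$design, map)
  expect_equal(screen_candidates(scr), "GA")
  stats <- scr$gene_stats
  expect_equal(stats$statistic[stats$gene == "GA"], 1 / 3)
  expect_equal(stats$statistic[stats$gene == "GB"], 0.5)
  expect_false(stats$candidate[stats$gene == "GB"])
})

test_that("zero-baseline probes are excluded, not errors, and any_probe collapses per gene", {
  fx <- micro_fixture(list(
    p1 = c(0, 10, 10, 10, 30, 30, 30, 30),    # B = 0 -> non-evaluable
    p2 = c(30, 10, 10, 10, 30, 30, 30, 30)))  # hit
  map <- data.frame(probe_id = c("p1", "p2"), gene = c("GA", "GA"))
  scr <- screen_microarray(fx$expr, fx$design, map)
  expect_equal(scr$n_non_evaluable, 1L)
  expect_equal(screen_candidates(scr), "GA")
})

test_that("RNA-seq screen arithmetic follows pseudocount-then-average order", {
  conds <- c("W", "WX", "K", "KX")
  expr <- matrix(c(9, 1, 9, 9,   # -> A = 2, B = 10, ratio 0.2
                   0, 0, 0, 0),  # all-zero -> ratio 1
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("Ga", "Gb"), paste0("s_", conds)))
  design <- make_design(paste0("s_", conds),
                        rep(c("p53_wt", "p53_null"), each = 2),
                        rep(c("none", "irradiation"), 2), NA, "mammary_gland")
  scr <- screen_rnaseq(expr, design)
  stats <- scr$gene_stats
  expect_equal(stats$A[stats$gene == "Ga"], 2)
  expect_equal(stats$B[stats$gene == "Ga"], 10)
  expect_equal(stats$statistic, c(0.2, 1))
  expect_equal(screen_candidates(scr), "Ga")
  expect_error(screen_rnaseq(expr, design, rnaseq_params(screen_tissue = "liver")),
               "no samples")
})

test_that("cohort screen requires both significance and the wt-lower direction", {
  set.seed(1)
  n <- c(30, 20)
  expr <- rbind(
    LOWER  = c(rnorm(n[1], 5, 1), rnorm(n[2], 9, 1)),   # wt << mut: candidate
    HIGHER = c(rnorm(n[1], 9, 1), rnorm(n[2], 5, 1)),   # wrong direction
    SAME   = rnorm(sum(n), 7, 1))                        # no signal
  expr <- expr - min(expr) + 0.1
  colnames(expr) <- sprintf("p%02d", seq_len(sum(n)))
  coh <- cohort_table(expr, data.frame(
    patient_id = colnames(expr),
    p53_status = rep(c("wt", "mut"), n),
    time = 100, event = FALSE))
  scr <- screen_cohort(coh)
  stats <- scr$gene_stats
  expect_equal(screen_candidates(scr), "LOWER")
  expect_lt(stats$statistic[stats$gene == "HIGHER"], 0.05)  # significant...
  expect_false(stats$candidate[stats$gene == "HIGHER"])     # ...but filtered
})

test_that("each screen agrees gene-for-gene with its brute-force oracle", {
  cfg <- sim_config(n_genes = 20, n_true_repressed = 4,
                    cohort_n = c(wt = 40, mut = 25), seed = 13)
  m <- simulate_microarray(cfg)
  expect_identical(
    screen_candidates(screen_microarray(m$expr, m$design, m$probe_map)),
    microarray_oracle(m$expr, m$design, m$probe_map))
  r <- simulate_rnaseq_tissues(cfg)
  expect_identical(screen_candidates(screen_rnaseq(r$expr, r$design)),
                   rnaseq_oracle(r$expr, r$design))
  coh <- simulate_cohort(cfg)$cohort
  expect_identical(screen_candidates(screen_cohort(coh)),
                   cohort_oracle(coh))
})

test_that("microarray candidacy is scale-invariant and monotone in treated values", {
  cfg <- sim_config(n_genes = 30, n_true_repressed = 6, seed = 21)
  m <- simulate_microarray(cfg)
  base <- screen_candidates(screen_microarray(m$expr, m$design, m$probe_map))
  # multiplying all samples of some probes by c > 0 changes nothing
  scaled <- m$expr
  scaled[seq(1, nrow(scaled), by = 2), ] <- scaled[seq(1, nrow(scaled), by = 2), ] * 37.5
  expect_identical(
    screen_candidates(screen_microarray(scaled, m$design, m$probe_map)), base)
  # decreasing treated-condition values never removes a candidate
  treated <- m$design$sample_id[m$design$condition_code %in% c("W12", "W24", "W48")]
  lowered <- m$expr
  lowered[, treated] <- lowered[, treated] * 0.5
  expect_true(all(base %in% screen_candidates(
    screen_microarray(lowered, m$design, m$probe_map))))
})

test_that("candidate intersection maps orthologs and reports the Venn counts", {
  orth <- data.frame(human = c("A", "B", "C"), mouse = c("a", "b", "c"))
  res <- intersect_candidates(list(s1 = c("A", "B", "C"), s2 = c("B", "C")),
                              c("c", "d"), orth)
  expect_equal(res$genes, "C")
  expect_equal(res$unmapped, "D")  # mouse-normalized unmapped symbol
  expect_equal(unname(res$venn["n_all"]), 1L)
  expect_equal(unname(res$venn["n_s1_s2"]), 2L)
  # disjoint sets give the empty set
  expect_length(intersect_candidates(list(c("A"), c("B")), character(0),
                                     orth)$genes, 0L)
})

test_that("tissue profiles are log2 ratios with pseudocount, omitting one-armed tissues", {
  cfg <- sim_config(n_genes = 10, n_true_repressed = 2,
                    noise_sd_log = 0, seed = 2)
  r <- simulate_rnaseq_tissues(cfg)
  prof <- tissue_profile(r$expr, r$design, rownames(r$expr), "p53_wt")
  # unplanted tissue, noise-free: equal means -> log2 ratio exactly 0
  expect_equal(unname(prof[, "spleen"]), rep(0, 10))
  # knockouts show no response anywhere
  prof_k <- tissue_profile(r$expr, r$design, rownames(r$expr), "p53_null")
  expect_equal(max(abs(prof_k)), 0)
  # dropping one arm triggers the warning path
  design_cut <- r$design[!(r$design$tissue == "lung" &
                             r$design$condition_code == "WX"), ]
  expect_warning(tissue_profile(r$expr, design_cut, rownames(r$expr), "p53_wt"),
                 "lung")
})
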