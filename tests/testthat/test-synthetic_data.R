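noise_free <- sim_config(n_genes = 200, n_true_repressed = 10,
                         noise_sd_log = 0, ct_noise_sd = 0, seed = 42)

test_that("generators are deterministic given config and seed", {
  cfg <- sim_config(n_genes = 100, n_true_repressed = 8, seed = 11)
  expect_identical(simulate_microarray(cfg), simulate_microarray(cfg))
  expect_identical(simulate_cohort(cfg)$cohort, simulate_cohort(cfg)$cohort)
  expect_identical(simulate_qpcr(cfg, c("GENE0001", "GENE0002")),
                   simulate_qpcr(cfg, c("GENE0001", "GENE0002")))
  expect_identical(simulate_bundle(cfg)$peaks, simulate_bundle(cfg)$peaks)
})

test_that("noise-free microarray plants the exact repression ratio", {
  m <- simulate_microarray(noise_free)
  scr <- screen_microarray(m$expr, m$design, m$probe_map)
  truth <- m$truth$true_repressed
  stats <- scr$gene_stats
  expect_equal(unique(stats$statistic[stats$gene %in% truth]), 0.25)
  expect_equal(unique(stats$statistic[!stats$gene %in% truth]), 1)
})

test_that("noise-free RNA-seq responds only in the planted tissues", {
  r <- simulate_rnaseq_tissues(noise_free)
  truth <- r$truth$true_repressed
  # all-zero genes give ratio exactly 1 after the pseudocount
  silent <- r$truth$silent_genes
  scr <- screen_rnaseq(r$expr, r$design)
  expect_true(length(silent) > 0)
  expect_equal(unique(scr$gene_stats$statistic[scr$gene_stats$gene %in% silent]), 1)
  expect_setequal(screen_candidates(scr), truth)
  # profile: suppressed only in configured tissues
  prof <- tissue_profile(r$expr, r$design, truth, "p53_wt")
  expect_true(all(prof[, r$truth$repressed_tissues] < -1))
  other <- setdiff(colnames(prof), r$truth$repressed_tissues)
  expect_equal(max(abs(prof[, other])), 0)
})

test_that("noise-free qPCR recovers the planted effect exactly and only where planted", {
  q <- simulate_qpcr(noise_free, c("GENE0001", "GENE0002"),
                     planted = "GENE0001")
  fc <- compute_ddct(q$ct, "GENE0001", "WT2", "ADR", "untreated")
  expect_equal(fc$log2fc, -3)
  expect_equal(fc$fold, 0.125)
  # mutant line: no effect
  expect_equal(compute_ddct(q$ct, "GENE0001", "MUT2", "ADR", "untreated")$log2fc, 0)
  # si-p53 cancels the shift
  expect_equal(compute_ddct(q$ct, "GENE0001", "WT1", "sip53_ADR", "mock")$log2fc, 0)
  # exogenous p53 reproduces it in the mutant line; LacZ does not
  expect_equal(compute_ddct(q$ct, "GENE0001", "MUT1", "Adp53", "control")$log2fc, -3)
  expect_equal(compute_ddct(q$ct, "GENE0001", "MUT1", "AdLacZ", "control")$log2fc, 0)
  # unplanted gene: flat everywhere
  expect_equal(compute_ddct(q$ct, "GENE0002", "WT1", "ADR", "untreated")$log2fc, 0)
})

test_that("peak placement follows the group probabilities", {
  genes <- sprintf("GENE%04d", 1:200)
  cfg <- sim_config(n_genes = 200, n_true_repressed = 20, seed = 5)
  tss <- simulate_tss(cfg, genes)
  induced <- genes[1:100]; module <- genes[101:130]
  # degenerate probabilities give exact overlap calls
  pk <- simulate_peaks(cfg, induced, module, tss, prob = c(1, 0))
  ov <- annotate_tss_overlap(tss, pk$peaks, 2000)
  expect_setequal(names(ov)[ov], induced)
  pk0 <- simulate_peaks(cfg, induced, module, tss, prob = c(0, 0))
  expect_false(any(annotate_tss_overlap(tss, pk0$peaks, 2000)))
  # stochastic placement matches the binomial expectation across seeds
  hits <- sapply(1:40, function(s) {
    cfg_s <- sim_config(n_genes = 200, n_true_repressed = 20, seed = s)
    pk <- simulate_peaks(cfg_s, induced, module, tss,
                         prob = c(0.426, 0.037))
    ov <- annotate_tss_overlap(tss, pk$peaks, 2000)
    c(mean(ov[induced]), mean(ov[module]))
  })
  se <- sqrt(c(0.426 * 0.574 / (100 * 40), 0.037 * 0.963 / (30 * 40)))
  expect_lt(abs(mean(hits[1, ]) - 0.426), 4 * se[1])
  expect_lt(abs(mean(hits[2, ]) - 0.037), 4 * se[2])
})

test_that("null cohort candidate rate matches the analytic type-I rate", {
  # two-sided test at alpha = 0.05 plus the one-sided direction filter
  # gives an expected null candidate fraction of about 0.025
  cfg <- sim_config(n_genes = 4000, n_true_repressed = 0, n_prognostic = 0,
                    cohort_n = c(wt = 60, mut = 40), seed = 9)
  coh <- simulate_cohort(cfg)
  frac <- mean(screen_cohort(coh$cohort)$gene_stats$candidate)
  se <- sqrt(0.025 * 0.975 / 4000)
  expect_lt(abs(frac - 0.025), 4 * se)
})
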