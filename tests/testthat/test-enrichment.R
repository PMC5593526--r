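test_that("TSS-window overlap uses half-open boundary arithmetic", {
  tss <- data.frame(gene = "G", chrom = "chr1", tss_position = 10000,
                    strand = "+")
  ov <- function(start, end, w = 2000) {
    unname(annotate_tss_overlap(tss, data.frame(chrom = "chr1",
                                                start = start, end = end), w)["G"])
  }
  expect_true(ov(11999, 12100))    # window end 12001, half-open
  expect_false(ov(12001, 12100))   # just past the window
  expect_true(ov(9999, 10001))     # peak covering the TSS base itself
  expect_true(ov(9999, 10001, w = 1))
  expect_false(ov(7999, 8000))     # window start 8000, [7999,8000) misses
  expect_true(ov(7999, 8001))
  # gene on a chromosome absent from the peak set is negative, logged
  res <- annotate_tss_overlap(tss, data.frame(chrom = "chr9", start = 1,
                                              end = 10), 2000)
  expect_false(res[["G"]])
  expect_equal(attr(res, "n_missing_chrom"), 1L)
})

test_that("window enlargement never turns a positive gene negative", {
  cfg <- sim_config(n_genes = 100, n_true_repressed = 10, seed = 17)
  genes <- sprintf("GENE%04d", 1:100)
  tss <- simulate_tss(cfg, genes)
  pk <- simulate_peaks(cfg, genes[1:50], genes[51:70], tss, prob = c(.5, .5))
  ov2 <- annotate_tss_overlap(tss, pk$peaks, 2000)
  ov10 <- annotate_tss_overlap(tss, pk$peaks, 10000)
  expect_true(all(ov10[ov2]))
})

test_that("contingency counts follow group bookkeeping and report exclusions", {
  g1 <- sprintf("I%03d", 1:183); g2 <- sprintf("M%02d", 1:27)
  ov <- setNames(rep(FALSE, 210), c(g1, g2))
  ov[g1[1:78]] <- TRUE; ov[g2[1]] <- TRUE
  tab <- count_enrichment(g1, g2, ov)
  expect_equal(unname(tab), matrix(c(78L, 105L, 1L, 26L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  # unannotated genes leave the denominators and are reported
  tab2 <- count_enrichment(c(g1, "NOVEL"), g2, ov)
  expect_equal(unname(attr(tab2, "excluded")["group1"]), 1L)
  expect_equal(sum(tab2[1, ]), 183L)
  expect_error(count_enrichment(g1, "UNSEEN", ov), "group2")
  # all genes positive
  tab3 <- count_enrichment(g1[1:5], g2[1], setNames(rep(TRUE, 210), c(g1, g2)))
  expect_equal(unname(tab3[, 2]), c(0L, 0L))
})

test_that("exact two-sided Fisher p matches closed forms and symmetries", {
  expect_equal(fisher_exact_two_sided(matrix(c(1, 1, 1, 1), 2)), 1)
  # margins (5,5,5,5): only the two extreme tables are as improbable
  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / choose(10, 5), tolerance = 1e-12)
  # zero margin
  expect_equal(fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  # invariance under transpose and simultaneous row/column swap
  set.seed(3)
  for (i in 1:25) {
    m <- matrix(rpois(4, 8), 2)
    p <- fisher_exact_two_sided(m)
    expect_equal(fisher_exact_two_sided(t(m)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(m[2:1, 2:1]), p, tolerance = 1e-12)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("implementation agrees with enumeration oracle and stats::fisher.test", {
  set.seed(5)
  for (i in 1:200) {
    m <- matrix(rpois(4, sample(1:12, 1)), 2)
    if (sum(m) == 0) m[1, 1] <- 1L
    p <- fisher_exact_two_sided(m)
    expect_equal(p, fisher_oracle(m), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("enrichment reports emit counts, one-decimal percentages and p-values", {
  cfg <- sim_config(n_genes = 80, n_true_repressed = 10, seed = 23)
  genes <- sprintf("GENE%04d", 1:80)
  tss <- simulate_tss(cfg, genes)
  induced <- genes[1:40]; module <- genes[41:60]
  pk <- simulate_peaks(cfg, induced, module, tss, prob = c(1, 0))
  rep <- enrichment_report(induced, module, tss, list(chip = pk$peaks))
  prom <- rep$promoter$combined
  expect_equal(unname(prom$percent), c(100, 0))
  # fully separated groups achieve the minimal attainable p for the margins
  expect_equal(prom$p_value, fisher_oracle(prom$table), tolerance = 1e-12)
  expect_equal(prom$p_value,
               min(sapply(20:40, function(a) {
                 fisher_oracle(matrix(c(a, 40 - a, 40 - a, a - 20), 2,
                                      byrow = TRUE))
               })))
  # zero-peak input: all percentages 0 and p = 1
  far <- data.frame(chrom = "chrZ", start = 1L, end = 2L)
  rep0 <- enrichment_report(induced, module, tss, list(chip = far))
  expect_equal(unname(rep0$promoter$combined$percent), c(0, 0))
  expect_equal(rep0$promoter$combined$p_value, 1)
})
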