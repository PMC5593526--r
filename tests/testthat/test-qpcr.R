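# Minimal long-format Ct table builder.
ct_rows <- function(gene, cell_line, condition, ct) {
  data.frame(gene = gene, cell_line = cell_line, condition = condition,
             replicate = seq_along(ct), ct = ct, stringsAsFactors = FALSE)
}

test_that("delta-delta-Ct arithmetic matches the defining formula", {
  ct <- rbind(ct_rows("G", "L", "ADR", c(25, 25, 25)),
              ct_rows("ACTB", "L", "ADR", c(20, 20, 20)),
              ct_rows("G", "L", "untreated", c(22, 22, 22)),
              ct_rows("ACTB", "L", "untreated", c(20, 20, 20)))
  fc <- compute_ddct(ct, "G", "L", "ADR", "untreated")
  expect_equal(fc$delta_delta_ct, 3)
  expect_equal(fc$log2fc, -3)
  expect_equal(fc$fold, 0.125)
  # case identical to control
  fc0 <- compute_ddct(ct, "G", "L", "ADR", "ADR")
  expect_equal(fc0$log2fc, 0)
  expect_equal(fc0$fold, 1)
  # missing reference gene is an error
  expect_error(compute_ddct(ct[ct$gene != "ACTB", ], "G", "L", "ADR",
                            "untreated"), "reference")
})

test_that("log2fc is antisymmetric and invariant to per-sample Ct offsets", {
  set.seed(8)
  ct <- rbind(ct_rows("G", "L", "case", rnorm(3, 26, 0.3)),
              ct_rows("ACTB", "L", "case", rnorm(3, 20, 0.3)),
              ct_rows("G", "L", "ctrl", rnorm(3, 24, 0.3)),
              ct_rows("ACTB", "L", "ctrl", rnorm(3, 20, 0.3)))
  fwd <- compute_ddct(ct, "G", "L", "case", "ctrl")
  rev <- compute_ddct(ct, "G", "L", "ctrl", "case")
  expect_equal(fwd$log2fc, -rev$log2fc)
  # adding a constant to every Ct of one (line, condition, replicate) --
  # including the reference -- models input-amount variation and must
  # cancel in the reference normalization
  shifted <- ct
  bump <- shifted$condition == "case" & shifted$replicate == 2
  shifted$ct[bump] <- shifted$ct[bump] + 1.7
  expect_equal(compute_ddct(shifted, "G", "L", "case", "ctrl")$log2fc,
               fwd$log2fc)
})

test_that("single replicates yield a fold change but no sd or p", {
  ct <- rbind(ct_rows("G", "L", "case", 25), ct_rows("ACTB", "L", "case", 20),
              ct_rows("G", "L", "ctrl", 22), ct_rows("ACTB", "L", "ctrl", 20))
  fc <- compute_ddct(ct, "G", "L", "case", "ctrl")
  expect_equal(fc$log2fc, -3)
  expect_true(is.na(fc$sd_case) && is.na(fc$p_value))
})

test_that("ADR-panel classification counts lines at the inclusive cutoff", {
  statuses <- data.frame(cell_line = c("W1", "W2", "W3", "W4", "M1", "M2", "M3"),
                         p53_status = rep(c("wt", "mut"), c(4, 3)))
  fc <- function(l2fc) data.frame(gene = "G", cell_line = statuses$cell_line,
                                  log2fc = l2fc)
  # exactly -2 in two wt lines counts (inclusive <=), zero mut lines: pass
  expect_true(classify_adr_repressed(fc(c(-2, -2, 0, 0, 0, 0, 0)),
                                     statuses)$pass)
  # repressed in 2 wt but also 1 mut line: fail under max_mut_lines = 0
  expect_false(classify_adr_repressed(fc(c(-3, -3, 0, 0, -2.5, 0, 0)),
                                      statuses)$pass)
  # repressed in all wt, no mut: pass
  expect_true(classify_adr_repressed(fc(rep(c(-4, 0), c(4, 3))),
                                     statuses)$pass)
  # just above the cutoff does not count
  expect_false(classify_adr_repressed(fc(c(-1.99, -2, 0, 0, 0, 0, 0)),
                                      statuses)$pass)
})

test_that("knockdown validation requires suppression and its abrogation", {
  fc2 <- function(ctrl, kd) list(
    data.frame(gene = "G", log2fc = ctrl),
    data.frame(gene = "G", log2fc = kd))
  f <- fc2(-3, -0.2)
  expect_true(validate_knockdown(f[[1]], f[[2]])$pass)
  f <- fc2(-3, -2.5)   # still repressed under si-p53: not abrogated
  expect_false(validate_knockdown(f[[1]], f[[2]])$pass)
  f <- fc2(-1, 0)      # never suppressed: vacuous, flagged separately
  res <- validate_knockdown(f[[1]], f[[2]])
  expect_false(res$pass)
  expect_true(res$vacuous)
})

test_that("exogenous-p53 validation also gates on the LacZ control", {
  fc2 <- function(p53, lacz) list(
    data.frame(gene = "G", log2fc = p53),
    data.frame(gene = "G", log2fc = lacz))
  f <- fc2(-4, -0.3)
  expect_true(validate_exogenous_p53(f[[1]], f[[2]])$pass)
  f <- fc2(-4, -2.5)   # control itself repressed: attribution fails
  expect_false(validate_exogenous_p53(f[[1]], f[[2]])$pass)
  f <- fc2(-1.9, 0)    # strictly above the cutoff
  expect_false(validate_exogenous_p53(f[[1]], f[[2]])$pass)
  # the control gate is a toggle
  f <- fc2(-4, -2.5)
  expect_true(validate_exogenous_p53(
    f[[1]], f[[2]], module_params(require_lacz_control = FALSE))$pass)
})

test_that("module call combines stages with a per-gene audit trail", {
  genes <- c("PASS", "FAIL_ADR", "FAIL_KD", "FAIL_EXO")
  adr <- data.frame(gene = genes, pass = c(TRUE, FALSE, TRUE, TRUE))
  kd <- data.frame(gene = genes, pass = c(TRUE, TRUE, FALSE, TRUE))
  exo <- data.frame(gene = genes, pass = c(TRUE, TRUE, TRUE, FALSE))
  res <- call_module(genes, adr, kd, exo)
  expect_equal(res$module, "PASS")
  audit <- res$audit
  expect_equal(audit$excluded_by[audit$gene == "FAIL_EXO"], "exogenous_p53")
  expect_equal(audit$excluded_by[audit$gene == "FAIL_KD"], "knockdown")
  expect_equal(audit$excluded_by[audit$gene == "FAIL_ADR"], "adr_panel")
  expect_true(is.na(audit$excluded_by[audit$gene == "PASS"]))
  # a required stage with no data is a configuration error
  expect_error(call_module(genes, adr, NULL, exo), "knockdown")
})

test_that("loosening the cutoff can only grow the module", {
  cfg <- sim_config(n_genes = 60, n_true_repressed = 10, seed = 31)
  genes <- sprintf("GENE%04d", 1:60)
  q <- simulate_qpcr(cfg, genes, planted = genes[1:10])
  adr_fc <- panel_log2fc(q$ct, genes, "ADR", "untreated",
                         cell_lines = q$lines$cell_line)
  modules <- lapply(c(-3, -2, -1), function(cut) {
    p <- module_params(log2fc_cutoff = cut,
                       require_knockdown_abrogation = FALSE,
                       require_adp53_repression = FALSE)
    call_module(genes, classify_adr_repressed(adr_fc, q$lines, p),
                params = p)$module
  })
  expect_true(all(modules[[1]] %in% modules[[2]]))
  expect_true(all(modules[[2]] %in% modules[[3]]))
})
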