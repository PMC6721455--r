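meas <- function(mir_f, mir_r, ctl_f, ctl_r) {
  n <- length(mir_f)
  tibble::tibble(construct_id = "c1",
                 condition = rep(c("mir", "control"), each = n),
                 replicate = rep(seq_len(n), 2L),
                 firefly = c(mir_f, ctl_f), renilla = c(mir_r, ctl_r))
}

test_that("R0 is the paired ratio of firefly/Renilla ratios", {
  same <- meas(c(100, 200, 300), c(10, 20, 30), c(100, 200, 300), c(10, 20, 30))
  expect_equal(compute_r0(same)$r0_replicates, c(1, 1, 1))
  expect_equal(compute_r0(same)$r0_mean, 1)
  expect_equal(compute_r0(meas(50, 100, 100, 100))$r0_mean, 0.5)
  mixed <- meas(c(40, 50, 60), c(100, 100, 100), c(100, 100, 100),
                c(100, 100, 100))
  expect_equal(compute_r0(mixed)$r0_replicates, c(0.4, 0.5, 0.6))
  expect_equal(compute_r0(mixed)$r0_mean, 0.5)
  # unpaired mode: ratio of condition means
  expect_equal(compute_r0(mixed, paired = FALSE)$r0_mean, 0.5)
  bad <- meas(c(50, 60), c(100, 100), c(100, 100), c(100, 100))
  bad$replicate[4] <- 5L
  expect_error(compute_r0(bad), "unmatched replicate")
  neg <- meas(-1, 100, 100, 100)
  expect_error(compute_r0(neg), "positive")
})

test_that("confirmation requires mean R0 below 1 at two-sided p < alpha", {
  null <- call_target(c(1, 1, 1))
  expect_false(null$confirmed)
  expect_equal(null$p_value, 1)
  flat <- call_target(c(0.5, 0.5, 0.5))
  expect_true(flat$confirmed)
  expect_equal(flat$p_value, 0)
  # t = (0.95 - 1) / (0.05 / sqrt(3)) = -1.732, df = 2, two-sided p ~ 0.225
  mild <- call_target(c(0.90, 0.95, 1.00))
  expect_equal(mild$p_value, 2 * pt(-sqrt(3) * 0.05 / 0.05, df = 2),
               tolerance = 1e-10)
  expect_equal(mild$p_value, 0.2254033, tolerance = 1e-6)
  expect_false(mild$confirmed)
  few <- call_target(c(0.5, 0.6))
  expect_false(few$callable)
  expect_true(is.na(few$confirmed))
})

test_that("confirmation is monotone under uniformly lowered R0", {
  set.seed(5)
  for (k in 1:50) {
    r0 <- exp(rnorm(3, 0, 0.1)) * runif(1, 0.5, 1)
    a <- call_target(r0)
    b <- call_target(r0 - 0.1)  # lower every replicate, variance unchanged
    if (isTRUE(a$confirmed)) expect_true(b$confirmed)
  }
})

test_that("R1 rescales by the batch positive control", {
  expect_equal(compute_r1(0.6, 0.15), 4)
  expect_equal(compute_r1(0.15, 0.15), 1)
  expect_error(compute_r1(0.6, NA), "positive control")
  set.seed(9)
  r1 <- compute_r1(runif(1, 0.5, 0.95), runif(1, 0.1, 0.2))
  expect_gt(r1, 1)
})

test_that("R1 is invariant to rescaling a batch's firefly readings", {
  set.seed(77)
  cfg <- scenario_config(rng_seed = 77, n_targets = 12, batch_size = 6)
  truth <- assign_true_r0(rep("8mer", 12), cfg)
  assay <- gen_assay(truth, cfg)
  rec1 <- call_reporters(assay$measurements, assay$batches)
  m2 <- assay$measurements
  m2$firefly <- m2$firefly * 3.7
  rec2 <- call_reporters(m2, assay$batches)
  expect_equal(rec1$r1, rec2$r1)
})

test_that("percentages round half-up to one decimal", {
  expect_equal(confirmation_ratio(162, 196), 82.7)
  expect_equal(confirmation_ratio(140, 165), 84.8)
  expect_equal(confirmation_ratio(52, 64), 81.3)   # 81.25 rounds up
  expect_equal(confirmation_ratio(0, 10), 0.0)
  expect_true(is.na(confirmation_ratio(0, 0)))
})

test_that("summary categories partition the cohort", {
  set.seed(13)
  truth <- tibble::tibble(construct_id = sprintf("g%03d", 1:80),
                          true_r0 = runif(80, 0.5, 1))
  ann <- gen_annotations(truth)
  rec <- tibble::tibble(construct_id = truth$construct_id,
                        confirmed = runif(80) < 0.8,
                        programs = ann$programs,
                        mirtarbase = ann$mirtarbase,
                        n_mres = ann$n_mres)
  s <- summarize_confirmation(rec)
  g <- function(cat, col) s[[col]][s$category == cat]
  expect_identical(g("Total", "selected"), 80L)
  expect_identical(g("Single MRE", "selected") + g("Multiple MREs", "selected"),
                   g("Total", "selected"))
  expect_identical(g("Single MRE", "confirmed") + g("Multiple MREs", "confirmed"),
                   g("Total", "confirmed"))
  expect_lte(g("TargetScan only", "selected"), g("TargetScan", "selected"))
  expect_lte(g("All three", "selected"), min(g("TargetScan", "selected"),
                                             g("miRanda", "selected"),
                                             g("PicTar", "selected")))
  expect_equal(s$ratio, confirmation_ratio(s$confirmed, s$selected))
})

test_that("records without annotation land in a diagnostics row", {
  rec <- tibble::tibble(construct_id = c("a", "b"), confirmed = c(TRUE, TRUE),
                        programs = c("TargetScan", NA),
                        mirtarbase = c(FALSE, NA), n_mres = c(1L, NA))
  s <- summarize_confirmation(rec)
  expect_true("diagnostics: unannotated" %in% s$category)
  expect_identical(s$selected[s$category == "diagnostics: unannotated"], 1L)
  expect_identical(s$selected[s$category == "Total"], 1L)
})

test_that("cohorts reconstructed from category counts re-tabulate exactly", {
  reg <- table1_regions[["miR-1"]]
  rec <- cohort_from_counts(reg$selected, reg$confirmed, reg$mirtarbase,
                            reg$multi_mre)
  s <- summarize_confirmation(rec)
  printed <- table1_printed[["miR-1"]]
  expect_identical(s$selected[match(printed$category, s$category)],
                   as.integer(printed$selected))
  expect_identical(s$confirmed[match(printed$category, s$category)],
                   as.integer(printed$confirmed))
})
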