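test_that("Pearson correlation matches hand-computed and degenerate cases", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  res <- pearson(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8)
  expect_identical(res$n, 5L)
  # p from the t transform, df = n - 2
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-tstat, df = 3), tolerance = 1e-12)
  const <- pearson(x, rep(1, 10))
  expect_true(is.na(const$r))
  expect_identical(const$reason, "zero variance")
  # missing pairs dropped listwise, n reported after deletion
  res2 <- pearson(c(1, 2, NA, 4, 5), c(2, 1, 4, NA, 5))
  expect_identical(res2$n, 3L)
})

test_that("Pearson p agrees with a permutation p within Monte Carlo error", {
  set.seed(31)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12)
  obs <- pearson(x, y)
  perms <- replicate(4000, abs(cor(x, sample(y))))
  p_perm <- mean(perms >= abs(obs$r))
  expect_lt(abs(obs$p - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.01)
})

test_that("one-sided K-S statistic is the sup over ECDF jump points", {
  expect_equal(ks_one_sided(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_one_sided(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ks_one_sided(c(1, 3, 5), c(2, 4, 6))$D, 1 / 3)
  set.seed(32)
  for (k in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), 0.5)
    ours <- ks_one_sided(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, alternative = "greater",
                                           exact = FALSE))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  expect_true(ks_one_sided(c(1, 2), c(3, 4))$low_reliability)
})

test_that("seed-type analysis recovers a planted repression hierarchy", {
  set.seed(33)
  rec <- gen_r1_cohort(c("8mer" = 3, "7mer-m8" = 4, "7mer-A1" = 5,
                         "6mer" = 6), sd = 1, n = 40)
  res <- seed_type_analysis(rec)
  expect_identical(res$groups$seed_type, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  expect_true(all(diff(res$groups$mean_r1) > 0))
  top <- res$comparisons[res$comparisons$stronger == "8mer" &
                           res$comparisons$weaker == "6mer", ]
  expect_lt(top$p, 0.05)
  # absent groups are skipped with notice, not an error
  expect_true(any(grepl("else", attr(res$comparisons, "skipped"))))
  # non-confirmed and multi-MRE records are excluded
  rec2 <- rbind(rec, tibble::tibble(construct_id = "x", gene_id = "x",
                                    seed_type = "8mer", r1 = 100,
                                    confirmed = FALSE, n_mres = 1L))
  res2 <- seed_type_analysis(rec2)
  expect_equal(res2$groups$mean_r1[1], res$groups$mean_r1[1])
})

test_that("two identical groups are rarely called different at alpha 0.05", {
  set.seed(34)
  hits <- 0
  for (k in 1:200) {
    a <- rnorm(40); b <- rnorm(40)
    if (ks_one_sided(a, b)$p < 0.05) hits <- hits + 1
  }
  expect_lte(hits / 200, 0.10)  # conservative one-sided null
})

test_that("expression correlation joins, filters and recovers construction", {
  set.seed(35)
  r1 <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                       r1 = runif(100, 2, 8))
  # monotone construction -> positive correlation
  expr <- tibble::tibble(gene_id = r1$gene_id, abundance = exp(r1$r1 / 2))
  expect_gt(correlate_with_expression(r1, expr)$r, 0.99)
  # genes under the detection threshold are dropped and n reflects it
  expr2 <- expr
  expr2$abundance[1:20] <- 0.001
  res <- correlate_with_expression(r1, expr2)
  expect_identical(res$n, 80L)
  # genes absent from the table are dropped
  res2 <- correlate_with_expression(r1, expr[1:50, ])
  expect_identical(res2$n, 50L)
  expect_error(correlate_with_expression(r1[1:2, ], expr[1:2, ]),
               "n = 2")
})

test_that("fold-change analysis handles degenerate and missing input", {
  r1 <- tibble::tibble(gene_id = sprintf("g%03d", 1:60), r1 = runif(60, 2, 8))
  expr <- tibble::tibble(gene_id = r1$gene_id, abundance = exp(rnorm(60, 2)))
  same <- fold_change_analysis(r1, expr, expr)
  expect_true(all(same$fold_changes$fc == 1))
  expect_identical(same$correlation$reason, "zero variance")
  # FC coupled to R1 -> positive correlation
  set.seed(36)
  mirv <- expr
  mirv$abundance <- expr$abundance * exp(0.1 * scale(r1$r1)[, 1] +
                                           rnorm(60, 0, 0.05))
  res <- fold_change_analysis(r1, mirv, expr)
  expect_gt(res$correlation$r, 0.5)
  # gene missing in the control table is excluded
  res2 <- fold_change_analysis(r1, mirv, expr[-1, ])
  expect_identical(res2$correlation$n, 59L)
})

test_that("score correlations run per program and flag constants", {
  r1 <- tibble::tibble(gene_id = sprintf("g%03d", 1:50), r1 = runif(50, 2, 8))
  ann <- tibble::tibble(gene_id = r1$gene_id,
                        score_TargetScan = r1$r1,
                        score_PicTar = rep(1, 50))
  res <- score_correlations(r1, ann)
  expect_equal(res$r[res$label == "score_TargetScan"], 1)
  expect_identical(res$reason[res$label == "score_PicTar"], "zero variance")
})

test_that("confirmation t-test p-values are calibrated under the null", {
  set.seed(37)
  p <- replicate(800, call_target(exp(rnorm(3, 0, 0.1)))$p_value)
  frac <- mean(p < 0.05)
  # two-sided test: fraction with p < alpha is ~alpha (binomial 99% band)
  expect_lt(abs(frac - 0.05), 2.58 * sqrt(0.05 * 0.95 / 800) + 0.01)
})
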