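test_that("generators are deterministic given a seed", {
  set.seed(50); m1 <- gen_mirna()
  set.seed(50); m2 <- gen_mirna()
  expect_identical(m1$sequence, m2$sequence)
  expect_identical(nchar(m1$sequence), 22L)
  cfg <- scenario_config(rng_seed = 99, n_targets = 15)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$sequences, b$sequences)
  expect_equal(a$records, b$records)
  expect_equal(a$expr_corr, b$expr_corr)
})

test_that("random miRNAs have near-uniform base composition", {
  set.seed(51)
  bases <- unlist(strsplit(vapply(1:200, function(i) gen_mirna()$sequence,
                                  character(1)), ""))
  tab <- table(factor(bases, levels = c("A", "C", "G", "U")))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("planted UTRs round-trip through the scanner", {
  set.seed(52)
  m <- mir122()
  for (type in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    g <- gen_utr_with_sites(m, type, utr_len = 600)
    expect_identical(g$sites$seed_type, type)
    expect_equal(find_seed_sites(g$utr, m), g$sites)
  }
  none <- gen_utr_with_sites(m, character(0), utr_len = 600)
  expect_identical(nrow(find_seed_sites(none$utr, m)), 0L)
  # sites 150 nt apart fall into a single cluster
  two <- gen_utr_with_sites(m, c("8mer", "8mer"), positions = c(300, 450))
  expect_length(cluster_sites(two$sites), 1L)
  expect_error(gen_utr_with_sites(m, rep("8mer", 100), utr_len = 500),
               "fit")
})

test_that("noiseless assays recover the planted R0 exactly", {
  cfg <- scenario_config(rng_seed = 53, n_targets = 10, noise_cv = 0)
  set.seed(53)
  truth <- assign_true_r0(rep(c("8mer", "else"), 5), cfg)
  assay <- gen_assay(truth, cfg)
  rec <- call_reporters(assay$measurements, assay$batches)
  rec <- rec[match(truth$construct_id, rec$construct_id), ]
  expect_equal(rec$r0_mean, truth$true_r0, tolerance = 1e-12)
})

test_that("assay noise follows the planted lognormal law", {
  cfg <- scenario_config(rng_seed = 54, n_targets = 400, replicates = 3)
  set.seed(54)
  truth <- assign_true_r0(rep("8mer", 400), cfg)
  truth$true_r0 <- 0.6
  assay <- gen_assay(truth, cfg)
  rec <- call_reporters(assay$measurements, assay$batches)
  rec <- rec[rec$construct_id %in% truth$construct_id, ]
  r0 <- rec$r0_mean
  expect_equal(mean(r0), 0.6 * exp(0.005), tolerance = 0.01)
  # strong planted repression is almost always confirmed
  expect_gte(mean(rec$confirmed), 0.95)
})

test_that("expression generator plants the requested correlation", {
  set.seed(55)
  r1 <- tibble::tibble(gene_id = sprintf("g%04d", 1:500),
                       r1 = rnorm(500, 5, 1.5))
  strong <- gen_expression(r1, target_r = 0.99, frac_undetected = 0)
  expect_gt(cor(r1$r1, log(strong$abundance)), 0.9)
  nullr <- gen_expression(r1, target_r = 0, frac_undetected = 0)
  expect_lt(abs(cor(r1$r1, log(nullr$abundance))), 0.15)
  # undetected fraction sits below the threshold
  some <- gen_expression(r1, target_r = 0.3, frac_undetected = 0.2)
  expect_gt(mean(some$abundance < 0.004), 0.1)
  pair <- gen_expression_pair(r1, target_r = 0.4, frac_undetected = 0)
  lfc <- log(pair$expr_mir$abundance / pair$expr_control$abundance)
  expect_gt(cor(r1$r1, lfc), 0.25)
})

test_that("true R0 assignment respects ranges and the seed hierarchy", {
  cfg <- scenario_config(rng_seed = 56)
  set.seed(56)
  types <- sample(names(cfg$seed_type_mix), 600, TRUE, prob = cfg$seed_type_mix)
  truth <- assign_true_r0(types, cfg)
  tg <- truth[truth$is_target, ]
  expect_true(all(tg$true_r0 >= cfg$target_r0_range[1] &
                    tg$true_r0 <= cfg$target_r0_range[2]))
  expect_true(all(truth$true_r0[!truth$is_target] == 1))
  m8 <- mean(tg$true_r0[tg$seed_type == "8mer"])
  m6 <- mean(tg$true_r0[tg$seed_type == "6mer"])
  expect_lt(m8, m6)
})

test_that("an end-to-end scenario reproduces its planted confirmation structure", {
  cfg <- scenario_config(rng_seed = 57, n_targets = 150)
  res <- simulate_scenario(cfg)
  rec <- res$records[!res$records$is_positive_control, ]
  # planted non-targets are confirmed at roughly the directional error rate
  fp <- mean(rec$confirmed[!rec$is_target])
  expect_lt(fp, 0.15)
  # strongly repressed classes are mostly confirmed
  strong <- rec$is_target & rec$seed_type %in% c("8mer", "7mer-m8")
  expect_gt(mean(rec$confirmed[strong]), 0.8)
  # most confirmed targets fall in the typical R1 band
  conf <- rec[rec$confirmed %in% TRUE & rec$is_target, ]
  expect_gt(mean(conf$r1 >= 2 & conf$r1 <= 10), 0.8)
})
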