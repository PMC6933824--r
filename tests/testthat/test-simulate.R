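test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_proteins = 80, de_fraction = 0.2, seed = 99)
  a <- simulate_spectral_counts(cfg)
  b <- simulate_spectral_counts(cfg)
  expect_identical(a, b)
  ea <- simulate_expression_tables(a$truth, cfg)
  eb <- simulate_expression_tables(b$truth, cfg)
  expect_identical(ea, eb)
  # a different seed gives different data
  c2 <- simulate_spectral_counts(sim_config(n_proteins = 80,
                                            de_fraction = 0.2, seed = 100))
  expect_false(identical(a$counts, c2$counts))
})

test_that("null configuration plants no effects", {
  sim <- simulate_spectral_counts(sim_config(n_proteins = 60,
                                             de_fraction = 0, seed = 3))
  expect_false(any(sim$truth$is_de))
  expect_true(all(sim$truth$true_fold_change == 1))
  expect_true(all(sim$truth$true_direction == "unchanged"))
})

test_that("planted fold changes are recovered in the simulated counts", {
  cfg <- sim_config(n_proteins = 1000, de_fraction = 0.2, fold_change = 4,
                    de_balance = 1, depth = c(50000, 50000), seed = 17)
  sim <- simulate_spectral_counts(cfg)
  de <- sim$truth$is_de
  expect_true(all(sim$truth$true_fold_change[de] == 4))
  expect_true(all(sim$truth$true_fold_change[!de] == 1))
  # pooled count ratio among DE proteins concentrates at the planted fold
  pooled <- sum(sim$counts$count_group1[de]) / sum(sim$counts$count_group2[de])
  expect_equal(pooled, 4, tolerance = 0.05)
  # and the null proteins stay balanced
  pooled0 <- sum(sim$counts$count_group1[!de]) / sum(sim$counts$count_group2[!de])
  expect_equal(pooled0, 1, tolerance = 0.05)
})

test_that("replicate structure matches the configuration", {
  cfg <- sim_config(n_proteins = 40, n_replicates = 5, seed = 8)
  sim <- simulate_spectral_counts(cfg)
  reps <- attr(sim$counts, "replicates")
  expect_equal(dim(reps$group1), c(40, 5))
  expect_equal(rowMeans(reps$group1), sim$counts$count_group1)
  expect_equal(rowMeans(reps$group2), sim$counts$count_group2)
  # expected run total equals the configured depth under the null
  cfg0 <- sim_config(n_proteins = 400, de_fraction = 0, depth = c(8000, 2000),
                     seed = 21)
  sim0 <- simulate_spectral_counts(cfg0)
  expect_equal(mean(colSums(attr(sim0$counts, "replicates")$group1)), 8000,
               tolerance = 0.05)
  expect_equal(mean(colSums(attr(sim0$counts, "replicates")$group2)), 2000,
               tolerance = 0.05)
})

test_that("transcript tables share the protein effect sign at the configured rate", {
  cfg1 <- sim_config(n_proteins = 500, de_fraction = 0.4, fold_change = 4,
                     concordance_prob = 1, seed = 31)
  sim <- simulate_spectral_counts(cfg1)
  expr <- simulate_expression_tables(sim$truth, cfg1)
  res <- data.frame(gene = sim$truth$gene,
                    direction = sim$truth$true_direction,
                    stringsAsFactors = FALSE)
  rec <- match_directions(res, expr, pseudocount = 0)
  de_rec <- rec[rec$gene %in% sim$truth$gene[sim$truth$is_de], ]
  expect_true(all(de_rec$concordant))

  cfg5 <- sim_config(n_proteins = 500, de_fraction = 0.4, fold_change = 4,
                     concordance_prob = 0.5, seed = 32)
  sim5 <- simulate_spectral_counts(cfg5)
  expr5 <- simulate_expression_tables(sim5$truth, cfg5)
  res5 <- data.frame(gene = sim5$truth$gene,
                     direction = sim5$truth$true_direction,
                     stringsAsFactors = FALSE)
  rec5 <- match_directions(res5, expr5, pseudocount = 0)
  de5 <- rec5[rec5$gene %in% sim5$truth$gene[sim5$truth$is_de], ]
  frac <- mean(de5$concordant)
  se <- sqrt(0.5 * 0.5 / nrow(de5))
  expect_lt(abs(frac - 0.5), 3 * se)

  expect_equal(nrow(simulate_expression_tables(sim$truth[0, ], cfg1)), 0)
})

test_that("overdispersed counts show inflated variance", {
  base <- sim_config(n_proteins = 2000, de_fraction = 0, seed = 44,
                     abundance_log_sd = 0)  # equal rates isolate noise
  od <- base; od$overdispersion <- 0.5
  v0 <- var(as.vector(attr(simulate_spectral_counts(base)$counts,
                           "replicates")$group1))
  v1 <- var(as.vector(attr(simulate_spectral_counts(od)$counts,
                           "replicates")$group1))
  expect_gt(v1, 2 * v0)
})

test_that("simulation files round-trip through the readers", {
  cfg <- sim_config(n_proteins = 25, de_fraction = 0.2, seed = 12)
  sim <- simulate_spectral_counts(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir, cfg)
  cols <- count_columns(group_cols = c(group1 = "count_group1",
                                       group2 = "count_group2"))
  back <- read_peptide_counts(paths[["counts"]], cols)
  expect_equal(back$count_group1, sim$counts$count_group1)
  tpm <- read_expression_table(paths[["tpm_first_trimester"]],
                               "first_trimester")
  expect_equal(nrow(tpm), 25)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(0), "positive")
  expect_error(sim_config(10, de_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(10, depth = -5), "positive")
  expect_error(sim_config(10, fold_change = 0.5), ">= 1")
  expect_error(sim_config(10, fold_change_range = c(4, 2)), "increasing")
  expect_error(simulate_spectral_counts(list()), "sim_config")
})
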