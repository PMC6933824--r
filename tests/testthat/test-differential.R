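test_that("pseudocount ratio reproduces published count arithmetic", {
  expect_equal(pseudocount_ratio(232, 136, 1), 1.70073, tolerance = 1e-5)
  expect_equal(pseudocount_ratio(7, 0, 1), 8)
  expect_equal(pseudocount_ratio(0.171777, 0.036219, 0), 4.74273091,
               tolerance = 1e-6)
  # symmetry at equal counts, any pseudocount
  for (x in c(0, 1, 7, 232.5)) for (k in c(0.5, 1, 2))
    expect_equal(pseudocount_ratio(x, x, k), 1)
  expect_error(pseudocount_ratio(3, 0, 0), "undefined")
  expect_error(pseudocount_ratio(-1, 2, 1), "non-negative")
})

test_that("ratio obeys reciprocal symmetry and strict monotonicity", {
  set.seed(41)
  for (i in 1:50) {
    c0 <- runif(1, 0, 300); s0 <- runif(1, 0, 300); k <- runif(1, 0, 2)
    expect_equal(pseudocount_ratio(c0, s0, k) * pseudocount_ratio(s0, c0, k), 1)
    expect_equal(log2_fold_change(pseudocount_ratio(c0, s0, k)),
                 -log2_fold_change(pseudocount_ratio(s0, c0, k)))
    expect_gt(pseudocount_ratio(c0 + 1, s0, k), pseudocount_ratio(c0, s0, k))
    expect_lt(pseudocount_ratio(c0, s0 + 1, k), pseudocount_ratio(c0, s0, k))
  }
})

test_that("log2 fold change matches published values and rejects bad input", {
  expect_equal(log2_fold_change(8), 3)
  expect_equal(log2_fold_change(1), 0)
  expect_equal(log2_fold_change(1.70073), 0.766154, tolerance = 1e-5)
  expect_error(log2_fold_change(0), "positive")
  expect_error(log2_fold_change(-2), "positive")
})

test_that("direction classification respects the tolerance band", {
  expect_equal(classify_direction(c(1.70073, 1, 0.723077)),
               c("higher_group1", "unchanged", "higher_group2"))
  # dead band is symmetric on the ratio scale
  expect_equal(classify_direction(1.05, tolerance = 0.1), "unchanged")
  expect_equal(classify_direction(1 / 1.05, tolerance = 0.1), "unchanged")
  expect_equal(classify_direction(1.2, tolerance = 0.1), "higher_group1")
  expect_equal(classify_direction(1 / 1.2, tolerance = 0.1), "higher_group2")
})

test_that("fit reproduces all 29 published ratios and fold changes", {
  fit <- fit_fixture()
  ref <- printed_counts()
  expect_equal(fit$results$ratio, ref$ratio_printed, tolerance = 1e-5)
  expect_equal(fit$results$log2fc, ref$log2fc_printed, tolerance = 1e-5)
  expect_equal(fit$results$protein_id, ref$protein_id)
  expect_equal(unname(fit$background$totals), c(1993, 1461))
})

test_that("minimum unique-peptide filter applies to the maximum across groups", {
  cnt <- data.frame(protein_id = c("A", "B", "C"), gene = c("GA", "GB", "GC"),
                    count_group1 = c(2, 7, 1), count_group2 = c(2, 0, 5),
                    stringsAsFactors = FALSE)
  fit <- spectral_da(cnt, control = da_control())
  # (2,2) filtered out; (7,0) and (1,5) retained
  expect_equal(fit$results$protein_id, c("B", "C"))
  expect_equal(fit$dropped$protein_id, "A")
  expect_equal(fit$dropped$reason, "below_min_unique_peptides")

  lone <- cnt[1, ]
  expect_warning(empty <- spectral_da(lone, control = da_control()),
                 "no proteins retained")
  expect_equal(nrow(empty$results), 0)
})

test_that("explicit background totals are honoured and validated", {
  cnt <- decoy_counts()
  ann <- load_annotation_fixture()
  ctl <- da_control(background_mode = "explicit",
                    background_totals = c(5000, 3500))
  fit <- spectral_da(cnt, ann, ctl)
  expect_equal(unname(fit$background$totals), c(5000, 3500))
  i <- which(fit$results$gene == "ATP5B")
  expect_equal(fit$results$p_value[i],
               fisher_background_test(232, 136, 5000, 3500))
  expect_error(spectral_da(cnt, ann,
                           da_control(background_mode = "explicit",
                                      background_totals = c(100, 3500))),
               "smaller than")
})

test_that("averaged counts are rounded half-up before testing", {
  cnt <- data.frame(protein_id = c("A", "B"), gene = c("GA", "GB"),
                    count_group1 = c(10.5, 20), count_group2 = c(3.5, 30),
                    stringsAsFactors = FALSE)
  fit <- spectral_da(cnt, control = da_control())
  # totals use 11 + 20 and 4 + 30
  expect_equal(unname(fit$background$totals), c(31, 34))
  expect_equal(fit$results$p_value[1], fisher_background_test(11, 4, 31, 34))
})

test_that("direction summary counts the published 24/0/5 split and is order-invariant", {
  fit <- fit_fixture()
  expect_equal(summarize_directions(fit),
               c(higher_group1 = 24L, unchanged = 0L, higher_group2 = 5L))
  expect_equal(sum(summarize_directions(fit)), nrow(fit$results))
  expect_equal(summarize_directions(character(0)),
               c(higher_group1 = 0L, unchanged = 0L, higher_group2 = 0L))
  set.seed(7)
  shuffled <- fit$results[sample.int(29), ]
  expect_equal(summarize_directions(shuffled), summarize_directions(fit))
})

test_that("pathway grouping counts match the published category sizes", {
  fit <- fit_fixture()
  blocks <- assign_pathways(fit, read_pathway_map(fixture_path("pathways_table_blocks.tsv")))
  expect_equal(unname(blocks["Carbohydrate metabolism"]), 3L)
  expect_equal(unname(blocks["Fatty acid metabolism"]), 2L)
  expect_equal(unname(blocks["Mitochondrial complex subunits"]), 4L)
  expect_equal(sum(blocks), 29L)

  txt <- assign_pathways(fit, read_pathway_map(fixture_path("pathways_results_text.tsv")))
  expect_equal(unname(txt["Pyruvate metabolism"]), 3L)
  expect_equal(unname(txt["Amino acid metabolism"]), 9L)
  expect_equal(unname(txt["Heat shock proteins"]), 6L)
  expect_equal(sum(txt), 29L)

  # unmapped genes are collected, totals still add up
  partial <- c(ATP5B = "x")
  p <- assign_pathways(fit, partial)
  expect_equal(unname(p["unassigned"]), 28L)
  expect_equal(sum(p), 29L)
  expect_equal(length(assign_pathways(fit$results[0, ], partial)), 0L)
})

test_that("optional BH adjustment reports q-values without changing the significance call", {
  fit <- fit_fixture(adjust = "BH")
  expect_true("q_value" %in% names(fit$results))
  expect_equal(fit$results$q_value,
               p.adjust(fit$results$p_value, method = "BH"))
  expect_equal(fit$results$significant,
               fit$results$p_value <= fit$control$alpha)
})
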