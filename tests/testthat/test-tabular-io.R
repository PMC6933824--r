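test_that("peptide count reader reproduces fixture rows in order", {
  cnt <- load_count_fixture()
  expect_equal(nrow(cnt), 29)
  expect_equal(attr(cnt, "group_labels"), c("Cyto", "Syncytio"))
  atp5b <- cnt[cnt$gene == "ATP5B", ]
  expect_equal(atp5b$protein_id, "P06576")
  expect_equal(atp5b$count_group1, 232)
  expect_equal(atp5b$count_group2, 136)
  # row order preserved, nothing dropped
  raw <- printed_counts()
  expect_equal(cnt$protein_id, raw$protein_id)
})

test_that("count reader averages replicate columns and handles empty files", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(protein_id = "P1", gene = "G1",
                       c_r1 = 3, c_r2 = 5, c_r3 = 4,
                       s_r1 = 1, s_r2 = 2, s_r3 = 0), tmp)
  cols <- count_columns(replicate_cols = list(Cyto = c("c_r1", "c_r2", "c_r3"),
                                              Syncytio = c("s_r1", "s_r2", "s_r3")))
  cnt <- read_peptide_counts(tmp, cols)
  expect_equal(cnt$count_group1, 4)
  expect_equal(cnt$count_group2, 1)
  expect_equal(dim(attr(cnt, "replicates")$Cyto), c(1, 3))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("protein_id", "gene", "avg_unique_peptides_cyto",
                   "avg_unique_peptides_syncytio", sep = "\t"), empty)
  expect_equal(nrow(read_peptide_counts(empty)), 0)
})

test_that("count reader rejects bad input with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(protein_id = "P1", gene = "G1", wrong = 1), tmp)
  expect_error(read_peptide_counts(tmp), "avg_unique_peptides_cyto")

  bad <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(protein_id = c("P1", "P2"), gene = c("G1", "G2"),
                       avg_unique_peptides_cyto = c(5, -1),
                       avg_unique_peptides_syncytio = c(1, 2)), bad)
  expect_error(read_peptide_counts(bad), "row 2")

  dup <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(protein_id = c("P1", "P1"), gene = c("G1", "G2"),
                       avg_unique_peptides_cyto = c(5, 6),
                       avg_unique_peptides_syncytio = c(1, 2)), dup)
  expect_error(read_peptide_counts(dup), "duplicate protein_id")

  expect_error(read_peptide_counts("no/such/file.tsv"), "not found")
})

test_that("expression reader parses TPM fixtures and validates input", {
  tpm3 <- read_expression_table(fixture_path("tpm_third_trimester.tsv"),
                                "third_trimester")
  pc <- tpm3[tpm3$gene == "PC", ]
  expect_equal(pc$tpm_group1, 3.229057)
  expect_equal(pc$tpm_group2, 0)
  tpm1 <- read_expression_table(fixture_path("tpm_first_trimester.tsv"),
                                "first_trimester")
  a <- tpm1[tpm1$gene == "ATP5A1", ]
  expect_equal(a$tpm_group1, 10.85863)
  expect_equal(a$tpm_group2, 6.709574)

  hdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\ttpm_cyt\ttpm_syn", hdr)
  expect_equal(nrow(read_expression_table(hdr, "first_trimester")), 0)

  neg <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene = "G1", tpm_cyt = -1, tpm_syn = 2), neg)
  expect_error(read_expression_table(neg, "first_trimester"), "non-negative")

  dup <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene = c("G1", "g1"), tpm_cyt = c(1, 2),
                       tpm_syn = c(2, 1)), dup)
  expect_error(read_expression_table(dup, "first_trimester"), "duplicate gene")
})

test_that("result tables survive a write/read round trip", {
  fit <- fit_fixture()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(fit, tmp)
  back <- read_results_table(tmp)
  expect_equal(nrow(back), 29)
  expect_equal(back$protein_id, fit$results$protein_id)
  expect_equal(back$ratio, fit$results$ratio, tolerance = 1e-5)
  expect_equal(back$log2fc, fit$results$log2fc, tolerance = 1e-5)
  expect_equal(back$p_value, fit$results$p_value, tolerance = 1e-5)
  expect_equal(back$direction, fit$results$direction)
  expect_equal(back$significant, fit$results$significant)
  expect_equal(attr(back, "group_labels"), c("Cyto", "Syncytio"))
  # the published ratio prints at 6 significant figures
  lines <- readLines(tmp)
  expect_match(lines[2], "1.70073", fixed = TRUE)

  # empty result set -> header-only file
  empty_fit <- fit
  empty_fit$results <- fit$results[0, ]
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(empty_fit, tmp2)
  expect_length(readLines(tmp2), 1)
  expect_equal(nrow(read_results_table(tmp2)), 0)

  expect_error(write_results_table(fit, file.path(tempdir(), "no", "dir", "x.tsv")),
               "cannot write")
})

test_that("pathway map reader validates uniqueness", {
  pm <- read_pathway_map(fixture_path("pathways_table_blocks.tsv"))
  expect_equal(unname(pm["PCK2"]), "Carbohydrate metabolism")
  expect_equal(length(pm), 29)
  dup <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene = c("A", "A"), pathway = c("x", "y")), dup)
  expect_error(read_pathway_map(dup), "more than once")
})
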