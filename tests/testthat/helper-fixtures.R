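# shared fixtures and independent oracles

fixture_path <- function(name) {
  system.file("extdata", name, package = "mitodiff", mustWork = TRUE)
}

load_count_fixture <- function() {
  read_peptide_counts(fixture_path("trophoblast_mito_counts.tsv"))
}

load_annotation_fixture <- function() {
  read_annotation(fixture_path("mitocarta_symbols.tsv"))
}

load_tpm_fixture <- function(stages = c("first_trimester", "third_trimester")) {
  do.call(rbind, lapply(stages, function(st)
    read_expression_table(fixture_path(sprintf("tpm_%s.tsv", st)), st)))
}

fit_fixture <- function(...) {
  spectral_da(load_count_fixture(), load_annotation_fixture(),
              da_control(...))
}

# printed reference columns of the packaged tables, read raw
printed_counts <- function() {
  utils::read.delim(fixture_path("trophoblast_mito_counts.tsv"))
}

printed_tpm <- function(stage) {
  utils::read.delim(fixture_path(sprintf("tpm_%s.tsv", stage)))
}

# independent two-sided Fisher oracle: exhaustive enumeration of all tables
# with the observed margins via binomial coefficients (no dhyper)
fisher_oracle <- function(c, s, C_tot, S_tot) {
  r <- c + s
  k <- max(0, r - S_tot):min(r, C_tot)
  p <- exp(lchoose(C_tot, k) + lchoose(S_tot, r - k) - lchoose(C_tot + S_tot, r))
  p_obs <- p[k == c]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# small synthetic count table with non-mitochondrial decoys, built in code
decoy_counts <- function() {
  out <- data.frame(
    protein_id = c("P06576", "P60709", "P04406", "Q16822"),
    gene = c("ATP5B", "ACTB", "GAPDH", "PCK2"),
    count_group1 = c(232, 50, 40, 7),
    count_group2 = c(136, 48, 41, 0),
    stringsAsFactors = FALSE)
  attr(out, "group_labels") <- c("Cyto", "Syncytio")
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
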