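#' Configuration of a synthetic spectral-count experiment
#'
#' Parameterizes the ground-truth generator emulating a triplicate label-free
#' experiment: per-protein baseline abundances are log-normal, planted
#' differential effects multiply one group's rate, and per-run counts are
#' Poisson (optionally gamma-Poisson). Paired TPM tables with controllable
#' direction concordance can be generated from the same truth.
#'
#' @param n_proteins Number of proteins.
#' @param n_replicates Runs per group (default 3, matching triplicate runs).
#' @param abundance_log_mean,abundance_log_sd Meanlog/sdlog of the
#'   log-normal baseline abundances (defaults `log(10)` and 1, giving the
#'   order-of-magnitude spread of unique-peptide counts seen in organellar
#'   spectral-count tables).
#' @param depth Expected total unique-peptide count per run, one value per
#'   group (default 5000 each).
#' @param de_fraction Fraction of proteins with a planted effect.
#' @param fold_change Planted fold-change magnitude (> 1), used when
#'   `fold_change_range` is `NULL`.
#' @param fold_change_range Optional length-2 range; planted magnitudes are
#'   drawn log-uniformly from it.
#' @param de_balance Probability a planted effect is higher in group 1
#'   (default 0.5).
#' @param concordance_prob Probability a planted transcript effect shares
#'   the protein effect's sign (default 0.9).
#' @param overdispersion Gamma-Poisson overdispersion; 0 (default) gives
#'   pure Poisson counts, values > 0 give variance
#'   `mu + overdispersion * mu^2`.
#' @param seed Integer seed; the whole simulated experiment is reproducible
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins,
                       n_replicates = 3,
                       abundance_log_mean = log(10),
                       abundance_log_sd = 1,
                       depth = c(5000, 5000),
                       de_fraction = 0.1,
                       fold_change = 4,
                       fold_change_range = NULL,
                       de_balance = 0.5,
                       concordance_prob = 0.9,
                       overdispersion = 0,
                       seed = 1L) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1L || n_proteins < 1)
    stop_input("'n_proteins' must be a positive integer")
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L || n_replicates < 1)
    stop_input("'n_replicates' must be >= 1")
  if (length(depth) == 1L) depth <- rep(depth, 2L)
  if (length(depth) != 2L || any(!is.finite(depth)) || any(depth <= 0))
    stop_input("'depth' must be one or two positive numbers")
  for (p in c(de_fraction, de_balance, concordance_prob))
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
      stop_input("probabilities must lie in [0, 1]")
  if (is.null(fold_change_range)) {
    if (!is.numeric(fold_change) || length(fold_change) != 1L || fold_change < 1)
      stop_input("'fold_change' must be a single number >= 1")
  } else if (length(fold_change_range) != 2L || any(fold_change_range < 1) ||
             fold_change_range[1] > fold_change_range[2]) {
    stop_input("'fold_change_range' must be an increasing pair of numbers >= 1")
  }
  if (!is.numeric(overdispersion) || length(overdispersion) != 1L ||
      overdispersion < 0)
    stop_input("'overdispersion' must be a single non-negative number")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_input("'seed' must be a single integer")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 abundance_log_mean = abundance_log_mean,
                 abundance_log_sd = abundance_log_sd,
                 depth = as.numeric(depth),
                 de_fraction = de_fraction,
                 fold_change = fold_change,
                 fold_change_range = fold_change_range,
                 de_balance = de_balance,
                 concordance_prob = concordance_prob,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rcounts <- function(n, mu, overdispersion) {
  if (overdispersion > 0)
    stats::rnbinom(n, size = 1 / overdispersion, mu = mu)
  else
    stats::rpois(n, mu)
}

#' Simulate a two-group spectral-count experiment with known truth
#'
#' Per protein, a baseline abundance is drawn log-normal; proteins selected
#' as differentially abundant get a planted fold change applied to one
#' group's rate. Both groups' rates are scaled by the common baseline
#' normalization (total baseline abundance), so planted fold changes are
#' exactly recovered in expected-rate ratios and each group's expected run
#' total equals its configured depth when no effects are planted
#' (approximately otherwise). Per-run counts are Poisson (or gamma-Poisson)
#' draws; reported group counts are the replicate means.
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#'   * `counts`: data frame in the canonical count layout (`protein_id`,
#'     `gene`, `count_group1`, `count_group2` = replicate means), with the
#'     per-run counts in columns `<group>_run<k>` and in attribute
#'     `replicates`.
#'   * `truth`: data frame with `protein_id`, `gene`, `is_de`,
#'     `true_fold_change` (expected group-1 / group-2 rate ratio; 1 for
#'     non-DE proteins) and `true_direction`.
#' @examples
#' sim <- simulate_spectral_counts(sim_config(n_proteins = 50, seed = 7))
#' head(sim$truth)
#' @export
simulate_spectral_counts <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_input("'config' must come from sim_config()")
  with_seed(config$seed, {
    n <- config$n_proteins
    lambda <- stats::rlnorm(n, config$abundance_log_mean,
                            config$abundance_log_sd)
    w <- lambda / sum(lambda)
    is_de <- stats::runif(n) < config$de_fraction
    mag <- rep(1, n)
    n_de <- sum(is_de)
    if (n_de > 0) {
      mag[is_de] <- if (is.null(config$fold_change_range)) {
        rep(config$fold_change, n_de)
      } else {
        exp(stats::runif(n_de, log(config$fold_change_range[1]),
                         log(config$fold_change_range[2])))
      }
    }
    up1 <- stats::runif(n) < config$de_balance
    # fold applied to the favored group's rate; ratio orientation is
    # group1 / group2 like the reported count ratios
    fold <- ifelse(is_de & up1, mag, ifelse(is_de, 1 / mag, 1))
    rate1 <- config$depth[1] * w * ifelse(fold > 1, fold, 1)
    rate2 <- config$depth[2] * w * ifelse(fold < 1, 1 / fold, 1)
    R <- config$n_replicates
    m1 <- matrix(rcounts(n * R, rep(rate1, R), config$overdispersion),
                 nrow = n,
                 dimnames = list(NULL, paste0("group1_run", seq_len(R))))
    m2 <- matrix(rcounts(n * R, rep(rate2, R), config$overdispersion),
                 nrow = n,
                 dimnames = list(NULL, paste0("group2_run", seq_len(R))))
    id <- sprintf("SIMP%05d", seq_len(n))
    gene <- sprintf("SIMG%05d", seq_len(n))
    counts <- data.frame(protein_id = id, gene = gene,
                         count_group1 = rowMeans(m1),
                         count_group2 = rowMeans(m2),
                         stringsAsFactors = FALSE)
    counts <- cbind(counts, as.data.frame(m1), as.data.frame(m2))
    attr(counts, "group_labels") <- c("group1", "group2")
    attr(counts, "replicates") <- list(group1 = m1, group2 = m2)
    truth <- data.frame(protein_id = id, gene = gene, is_de = is_de,
                        true_fold_change = fold,
                        true_direction = classify_direction(ifelse(fold == 1,
                                                                   1, fold)),
                        stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

#' Simulate paired TPM tables from a simulated truth
#'
#' For every gene and gestational stage, draws a baseline TPM (log-normal)
#' and applies the truth's fold-change magnitude with the protein effect's
#' sign with probability `concordance_prob` (flipped otherwise), each stage
#' independently. Genes without a planted protein effect get equal TPM in
#' both cell types.
#'
#' @param truth Truth data frame from [simulate_spectral_counts()].
#' @param config The same [sim_config()]; `concordance_prob` and the
#'   abundance parameters are reused for the transcript layer. Stage
#'   draws use a seed offset so counts and expression are independently
#'   reproducible.
#' @param stages Character vector of stage labels to generate.
#' @return Data frame in the layout of [read_expression_table()] output
#'   (`gene`, `stage`, `tpm_group1`, `tpm_group2`), all stages row-bound.
#' @export
simulate_expression_tables <- function(truth, config,
                                       stages = c("first_trimester",
                                                  "third_trimester")) {
  if (!inherits(config, "sim_config"))
    stop_input("'config' must come from sim_config()")
  need <- c("gene", "is_de", "true_fold_change")
  if (!is.data.frame(truth) || !all(need %in% names(truth)))
    stop_input("'truth' must come from simulate_spectral_counts()")
  if (nrow(truth) == 0L)
    return(data.frame(gene = character(0), stage = character(0),
                      tpm_group1 = numeric(0), tpm_group2 = numeric(0),
                      stringsAsFactors = FALSE))
  with_seed(config$seed + 1000003L, {
    out <- lapply(stages, function(st) {
      n <- nrow(truth)
      base <- stats::rlnorm(n, config$abundance_log_mean,
                            config$abundance_log_sd)
      keep_sign <- stats::runif(n) < config$concordance_prob
      fold <- ifelse(truth$is_de,
                     ifelse(keep_sign, truth$true_fold_change,
                            1 / truth$true_fold_change),
                     1)
      data.frame(gene = truth$gene, stage = st,
                 tpm_group1 = base * fold, tpm_group2 = base,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Write a simulated experiment to TSV files
#'
#' Writes the simulated count table (with replicate columns), the paired
#' TPM tables, and the ground truth in the same tab-separated dialects the
#' package's readers consume.
#'
#' @param sim Output of [simulate_spectral_counts()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used; required to also write TPM tables.
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "simulated_counts.tsv"),
             truth = file.path(dir, "simulated_truth.tsv"))
  utils::write.table(sim$counts, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(config)) {
    expr <- simulate_expression_tables(sim$truth, config)
    for (st in unique(expr$stage)) {
      p <- file.path(dir, sprintf("simulated_tpm_%s.tsv", st))
      sub <- expr[expr$stage == st, c("gene", "tpm_group1", "tpm_group2")]
      names(sub) <- c("gene", "tpm_cyt", "tpm_syn")
      utils::write.table(sub, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[paste0("tpm_", st)] <- p
    }
  }
  invisible(paths)
}
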