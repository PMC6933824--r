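# Pipeline orchestration: annotate -> filter -> test -> summarize ->
# concordance, with a machine-readable summary and a run manifest.

default_pipeline_config <- function() {
  list(
    group_labels = c("Cyto", "Syncytio"),
    pseudocount = 1,
    alpha = 0.05,
    min_unique_peptides = 3,
    unchanged_tolerance = 0,
    background_mode = "column_totals",
    background_totals = NULL,
    adjust = "none",
    stage_pseudocounts = list(first_trimester = 0, third_trimester = 1),
    columns = list(protein_id = "protein_id", gene = "gene",
                   counts = list(Cyto = "avg_unique_peptides_cyto",
                                 Syncytio = "avg_unique_peptides_syncytio"),
                   replicates = NULL),
    expression_columns = list(gene = "gene",
                              tpm = list(CYT = "tpm_cyt", SYN = "tpm_syn")))
}

read_pipeline_config <- function(config_path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  if (!is.null(config_path)) {
    if (!file.exists(config_path))
      stop_input("config file not found: %s", config_path)
    user <- yaml::read_yaml(config_path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop_input("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  cfg
}

config_to_control <- function(cfg) {
  da_control(pseudocount = cfg$pseudocount,
             alpha = cfg$alpha,
             min_unique_peptides = cfg$min_unique_peptides,
             unchanged_tolerance = cfg$unchanged_tolerance,
             background_mode = cfg$background_mode,
             background_totals = cfg$background_totals,
             adjust = cfg$adjust,
             group_labels = unlist(cfg$group_labels))
}

config_to_columns <- function(cfg) {
  cc <- cfg$columns
  count_columns(protein_id = cc$protein_id, gene = cc$gene,
                group_cols = unlist(cc$counts),
                replicate_cols = cc$replicates)
}

#' Run the full differential-abundance pipeline
#'
#' Orchestrates annotate -> filter -> test -> summarize (-> concordance)
#' as one reproducible run. Writes, under `out_dir`: `differential.tsv`
#' (the result report), `concordance.tsv` (when expression tables are
#' given), `summary.json` (direction triple, significant count, optional
#' pathway counts, per-stage concordance and the conserved-gene list, at
#' full precision), and `manifest.json` (configuration snapshot, input
#' paths with MD5 digests recorded before processing, package version,
#' seed, output paths, status). The manifest is written even when a later
#' stage fails.
#'
#' Rerunning with identical inputs and configuration yields byte-identical
#' TSV/JSON outputs apart from the manifest's timestamp field.
#'
#' @param count_path Path to the unique-peptide count TSV.
#' @param annotation_path Path to the mitochondrial gene list.
#' @param expression_paths Optional named character vector mapping stage
#'   labels (`first_trimester`, `third_trimester`) to TPM TSV paths.
#' @param config_path Optional YAML file overriding the defaults (keys:
#'   `group_labels`, `pseudocount`, `alpha`, `min_unique_peptides`,
#'   `unchanged_tolerance`, `background_mode`, `background_totals`,
#'   `adjust`, `stage_pseudocounts`, `columns`, `expression_columns`).
#' @param out_dir Output directory (created if needed).
#' @param pathway_path Optional gene-to-pathway TSV; adds pathway counts of
#'   the significant hits to the summary.
#' @param seed Optional integer seed recorded in the manifest and set
#'   before processing (the core pipeline is deterministic; the seed
#'   matters only for user configs that add randomness downstream).
#' @param overrides Named list of config keys overriding both defaults and
#'   file values.
#' @return Invisibly, a list with `fit` (the [spectral_da()] object),
#'   `concordance` (or `NULL`), `summary` (the JSON payload as a list) and
#'   `paths` (the files written).
#' @export
run_pipeline <- function(count_path, annotation_path,
                         expression_paths = NULL,
                         config_path = NULL,
                         out_dir = ".",
                         pathway_path = NULL,
                         seed = NULL,
                         overrides = list()) {
  cfg <- read_pipeline_config(config_path, overrides)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(counts = count_path, annotation = annotation_path,
              expression_paths,
              if (!is.null(pathway_path)) c(pathways = pathway_path),
              if (!is.null(config_path)) c(config = config_path))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop_input("input file(s) not found: %s", paste(missing, collapse = ", "))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package = "mitodiff",
    package_version = as.character(utils::packageVersion("mitodiff")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg,
    inputs = lapply(stats::setNames(nm = names(inputs)), function(nm)
      list(path = unname(inputs[[nm]]),
           md5 = unname(tools::md5sum(inputs[[nm]])))),
    outputs = character(0),
    status = "running")
  write_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  write_manifest()
  on.exit(if (manifest$status == "running") {
    manifest$status <- "failed"
    write_manifest()
  }, add = TRUE)
  if (!is.null(seed)) set.seed(seed)

  control <- config_to_control(cfg)
  counts <- read_peptide_counts(count_path, config_to_columns(cfg))
  annotation <- read_annotation(annotation_path)
  fit <- spectral_da(counts, annotation, control)

  diff_path <- file.path(out_dir, "differential.tsv")
  write_results_table(fit, diff_path)
  paths <- c(differential = diff_path)

  pathways <- if (!is.null(pathway_path)) read_pathway_map(pathway_path)
  smry <- summary(fit, pathways = pathways)

  conc <- NULL
  if (!is.null(expression_paths) && length(expression_paths)) {
    if (is.null(names(expression_paths)))
      stop_input("'expression_paths' must be named by stage")
    ec <- cfg$expression_columns
    expr <- do.call(rbind, lapply(names(expression_paths), function(st)
      read_expression_table(expression_paths[[st]], st,
                            gene_col = ec$gene, tpm_cols = unlist(ec$tpm))))
    conc <- direction_concordance(
      fit$results, expr,
      pseudocount = unlist(cfg$stage_pseudocounts),
      tolerance = cfg$unchanged_tolerance)
    conc_path <- file.path(out_dir, "concordance.tsv")
    write_concordance_table(conc, conc_path)
    paths["concordance"] <- conc_path
  }

  summary_json <- list(
    group_labels = fit$group_labels,
    n = as.list(fit$n),
    background = list(mode = fit$background$mode,
                      totals = as.list(fit$background$totals)),
    directions_tested = as.list(smry$directions_tested),
    n_significant = smry$n_significant,
    directions_significant = as.list(smry$directions_significant),
    pathway_counts = if (!is.null(smry$pathway_counts))
      as.list(smry$pathway_counts),
    concordance = if (!is.null(conc)) {
      s <- conc$summary
      list(per_stage = lapply(stats::setNames(nm = names(s$n_tested)),
                              function(st) list(
                                n_tested = unname(s$n_tested[[st]]),
                                matches = unname(s$per_stage_matches[[st]]),
                                fraction = unname(s$fraction_concordant[[st]]))),
           conserved_genes = s$conserved_genes,
           n_conserved = length(s$conserved_genes),
           n_distinct_concordant_genes = s$n_distinct_genes)
    })
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_json, summary_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  paths["summary"] <- summary_path

  manifest$outputs <- as.list(paths)
  manifest$status <- "ok"
  write_manifest()
  paths["manifest"] <- manifest_path

  invisible(list(fit = fit, concordance = conc, summary = summary_json,
                 paths = paths))
}
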