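# Tabular I/O: every file the pipeline reads or writes is tab-separated
# UTF-8 with one header row. Column names are never hard-coded to one
# search engine's export; a column mapping adapts other layouts.

#' Column mapping for a peptide-count table
#'
#' Describes which columns of a tab-separated count export hold the protein
#' accession, the gene symbol, and the per-group counts. Counts may be given
#' either as pre-averaged columns (`group_cols`) or as per-run replicate
#' columns (`replicate_cols`), in which case the group value is the
#' arithmetic mean over runs.
#'
#' @param protein_id Name of the protein accession column.
#' @param gene Name of the gene-symbol column.
#' @param group_cols Named character vector of length 2 mapping the two
#'   group labels to their pre-averaged count columns. Ignored when
#'   `replicate_cols` is given.
#' @param replicate_cols Optional named list of length 2 mapping each group
#'   label to a character vector of per-run count columns.
#' @return A list of class `count_columns`.
#' @export
count_columns <- function(protein_id = "protein_id",
                          gene = "gene",
                          group_cols = c(Cyto = "avg_unique_peptides_cyto",
                                         Syncytio = "avg_unique_peptides_syncytio"),
                          replicate_cols = NULL) {
  if (!is.null(replicate_cols)) {
    if (!is.list(replicate_cols) || length(replicate_cols) != 2L ||
        is.null(names(replicate_cols)) || any(!nzchar(names(replicate_cols))))
      stop_input("'replicate_cols' must be a named list of two character vectors")
  } else if (length(group_cols) != 2L || is.null(names(group_cols)) ||
             any(!nzchar(names(group_cols)))) {
    stop_input("'group_cols' must be a named character vector of length 2")
  }
  structure(list(protein_id = protein_id, gene = gene,
                 group_cols = group_cols, replicate_cols = replicate_cols),
            class = "count_columns")
}

check_columns <- function(header, wanted, path) {
  missing <- setdiff(wanted, header)
  if (length(missing))
    stop_input("file %s lacks configured column(s): %s", path,
               paste(missing, collapse = ", "))
}

parse_counts_col <- function(x, col, path) {
  val <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(val) | !is.finite(val) | val < 0)
  if (length(bad))
    stop_input("file %s column '%s': negative or non-numeric count at data row %d",
               path, col, bad[1])
  val
}

#' Read a protein-level unique-peptide count table
#'
#' Ingests a tab-separated protein-level export (e.g. derived from a
#' MaxQuant proteinGroups table) into the package's canonical count layout.
#' When replicate columns are configured, per-group values are the
#' arithmetic mean over runs; otherwise the pre-averaged columns are taken
#' as-is. Row order is preserved and no row is ever silently dropped.
#'
#' @param path Path to the TSV file.
#' @param columns A [count_columns()] mapping.
#' @return A data frame with columns `protein_id`, `gene`, `count_group1`,
#'   `count_group2`, carrying the group labels in attribute `group_labels`.
#'   With replicate columns configured, the per-run counts are kept in
#'   attribute `replicates` (a named list of matrices, proteins x runs).
#' @examples
#' cnt <- read_peptide_counts(system.file("extdata",
#'   "trophoblast_mito_counts.tsv", package = "mitodiff"))
#' cnt[cnt$gene == "ATP5B", ]
#' @export
read_peptide_counts <- function(path, columns = count_columns()) {
  if (!file.exists(path))
    stop_input("count file not found: %s", path)
  if (!inherits(columns, "count_columns"))
    stop_input("'columns' must come from count_columns()")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  labels <- if (is.null(columns$replicate_cols)) names(columns$group_cols)
            else names(columns$replicate_cols)
  wanted <- c(columns$protein_id, columns$gene,
              if (is.null(columns$replicate_cols)) unname(columns$group_cols)
              else unlist(columns$replicate_cols, use.names = FALSE))
  # a header-only file parses to zero columns unless the header is present;
  # read.delim keeps the header, so validate against it
  header <- names(tab)
  check_columns(header, wanted, path)
  n <- nrow(tab)
  protein_id <- tab[[columns$protein_id]]
  if (anyDuplicated(protein_id))
    stop_input("file %s: duplicate protein_id '%s'", path,
               protein_id[duplicated(protein_id)][1])
  replicates <- NULL
  if (is.null(columns$replicate_cols)) {
    g1 <- parse_counts_col(tab[[columns$group_cols[[1]]]],
                           columns$group_cols[[1]], path)
    g2 <- parse_counts_col(tab[[columns$group_cols[[2]]]],
                           columns$group_cols[[2]], path)
  } else {
    mats <- lapply(labels, function(lb) {
      cols <- columns$replicate_cols[[lb]]
      m <- vapply(cols, function(cl) parse_counts_col(tab[[cl]], cl, path),
                  numeric(n))
      matrix(m, nrow = n, dimnames = list(NULL, cols))
    })
    names(mats) <- labels
    g1 <- rowMeans(mats[[1]])
    g2 <- rowMeans(mats[[2]])
    replicates <- mats
  }
  out <- data.frame(protein_id = protein_id,
                    gene = tab[[columns$gene]],
                    count_group1 = as.numeric(g1),
                    count_group2 = as.numeric(g2),
                    stringsAsFactors = FALSE)
  attr(out, "group_labels") <- labels
  if (!is.null(replicates)) attr(out, "replicates") <- replicates
  out
}

# validate/canonicalize a count data frame built by a reader, a simulator
# or by hand
validate_counts <- function(counts) {
  need <- c("protein_id", "gene", "count_group1", "count_group2")
  if (!is.data.frame(counts) || !all(need %in% names(counts)))
    stop_input("count table must have columns %s", paste(need, collapse = ", "))
  if (!is_count_like(counts$count_group1) || !is_count_like(counts$count_group2))
    stop_input("counts must be finite and non-negative")
  if (anyDuplicated(counts$protein_id))
    stop_input("duplicate protein_id values in count table")
  if (is.null(attr(counts, "group_labels")))
    attr(counts, "group_labels") <- c("group1", "group2")
  counts
}

#' Read a single-cell expression (TPM) table for one gestational stage
#'
#' Reads a tab-separated table of average transcripts-per-million per cell
#' type, one row per gene, for a single gestational stage. Gene symbols are
#' normalized via [normalize_gene_symbol()].
#'
#' @param path Path to the TSV file with a gene column and one TPM column
#'   per cell type.
#' @param stage Stage label, `"first_trimester"` or `"third_trimester"`.
#' @param gene_col Name of the gene column.
#' @param tpm_cols Named character vector of length 2 mapping the two
#'   cell-type labels to their TPM columns.
#' @return Data frame with columns `gene`, `stage`, `tpm_group1`,
#'   `tpm_group2`; cell-type labels kept in attribute `cell_labels`.
#' @examples
#' tpm3 <- read_expression_table(system.file("extdata",
#'   "tpm_third_trimester.tsv", package = "mitodiff"), "third_trimester")
#' tpm3[tpm3$gene == "TRAP1", ]
#' @export
read_expression_table <- function(path,
                                  stage = c("first_trimester", "third_trimester"),
                                  gene_col = "gene",
                                  tpm_cols = c(CYT = "tpm_cyt", SYN = "tpm_syn")) {
  stage <- match.arg(stage)
  if (!file.exists(path))
    stop_input("expression file not found: %s", path)
  if (length(tpm_cols) != 2L || is.null(names(tpm_cols)))
    stop_input("'tpm_cols' must be a named character vector of length 2")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  check_columns(names(tab), c(gene_col, unname(tpm_cols)), path)
  if (nrow(tab) == 0L) {
    out <- data.frame(gene = character(0), stage = character(0),
                      tpm_group1 = numeric(0), tpm_group2 = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "cell_labels") <- names(tpm_cols)
    return(out)
  }
  gene <- normalize_gene_symbol(tab[[gene_col]])
  if (anyDuplicated(gene))
    stop_input("file %s: duplicate gene '%s' within stage %s", path,
               gene[duplicated(gene)][1], stage)
  t1 <- suppressWarnings(as.numeric(tab[[tpm_cols[[1]]]]))
  t2 <- suppressWarnings(as.numeric(tab[[tpm_cols[[2]]]]))
  if (any(is.na(t1)) || any(is.na(t2)) || any(t1 < 0) || any(t2 < 0))
    stop_input("file %s: TPM values must be numeric and non-negative", path)
  out <- data.frame(gene = gene, stage = stage,
                    tpm_group1 = t1, tpm_group2 = t2,
                    stringsAsFactors = FALSE)
  attr(out, "cell_labels") <- names(tpm_cols)
  out
}

#' Read a pathway map
#'
#' Tab-separated two-column file mapping each gene symbol to exactly one
#' pathway label.
#'
#' @param path Path to a TSV with columns `gene` and `pathway`.
#' @return Named character vector: normalized gene symbol -> pathway label.
#' @export
read_pathway_map <- function(path) {
  if (!file.exists(path))
    stop_input("pathway map not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  check_columns(names(tab), c("gene", "pathway"), path)
  gene <- normalize_gene_symbol(tab$gene)
  if (anyDuplicated(gene))
    stop_input("pathway map %s assigns gene '%s' more than once", path,
               gene[duplicated(gene)][1])
  stats::setNames(tab$pathway, gene)
}

#' Write a differential-abundance result table
#'
#' Tab-separated report mirroring the layout of the published tables:
#' accession, gene, per-group counts, ratio, log2 fold change, p-value,
#' direction, significance flag. Numbers are printed at `digits`
#' significant figures (default 6, matching the published precision);
#' writing then reading back reproduces ratio, log2 fold change and
#' p-value to well within 1e-5 for values on the scale of count ratios.
#'
#' @param results A `spectral_da` fit or its `results` data frame.
#' @param path Output file path.
#' @param digits Significant figures for numeric columns.
#' @return `path`, invisibly.
#' @seealso [read_results_table()]
#' @export
write_results_table <- function(results, path, digits = 6) {
  if (inherits(results, "spectral_da")) {
    labels <- results$group_labels
    results <- results$results
  } else {
    labels <- attr(results, "group_labels") %||% c("group1", "group2")
  }
  need <- c("protein_id", "gene", "count_group1", "count_group2",
            "ratio", "log2fc", "p_value", "direction", "significant")
  if (!is.data.frame(results) || !all(need %in% names(results)))
    stop_input("'results' must contain columns %s", paste(need, collapse = ", "))
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  out <- data.frame(protein_id = results$protein_id,
                    gene = results$gene,
                    c1 = fmt(results$count_group1),
                    c2 = fmt(results$count_group2),
                    ratio = fmt(results$ratio),
                    log2fc = fmt(results$log2fc),
                    p_value = fmt(results$p_value),
                    direction = results$direction,
                    significant = results$significant,
                    stringsAsFactors = FALSE)
  names(out)[3:4] <- paste0("count_", labels)
  ok <- tryCatch({
    suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_input("cannot write results table to %s: %s", path,
               conditionMessage(ok))
  invisible(path)
}

#' Read back a differential result table written by [write_results_table()]
#'
#' @param path Path to the TSV report.
#' @return Data frame in the same layout as the `results` component of a
#'   [spectral_da()] fit.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path))
    stop_input("results file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cnt <- grep("^count_", names(tab), value = TRUE)
  if (length(cnt) != 2L)
    stop_input("file %s is not a mitodiff results table", path)
  out <- data.frame(protein_id = as.character(tab$protein_id),
                    gene = as.character(tab$gene),
                    count_group1 = as.numeric(tab[[cnt[1]]]),
                    count_group2 = as.numeric(tab[[cnt[2]]]),
                    ratio = as.numeric(tab$ratio),
                    log2fc = as.numeric(tab$log2fc),
                    p_value = as.numeric(tab$p_value),
                    direction = as.character(tab$direction),
                    significant = as.logical(tab$significant),
                    stringsAsFactors = FALSE)
  attr(out, "group_labels") <- sub("^count_", "", cnt)
  out
}
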