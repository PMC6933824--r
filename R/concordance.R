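#' Fold change of a transcript between cell types
#'
#' Applies the same pseudocount ratio / log2 fold change machinery used for
#' spectral counts to a pair of TPM values (cytotrophoblast vs
#' syncytiotrophoblast). TPM values of exactly 0 in one cell type go through
#' the pseudocount path like any other value.
#'
#' @param tpm_group1,tpm_group2 Non-negative TPM values (vectors allowed).
#' @param pseudocount Non-negative pseudocount; the published first- and
#'   third-trimester tables use 0 and 1 respectively.
#' @return A list with components `ratio` and `log2fc`.
#' @examples
#' expression_fold_change(3.229057, 0, pseudocount = 1)    # ratio 4.229057
#' expression_fold_change(10.85863, 6.709574, pseudocount = 0)
#' @export
expression_fold_change <- function(tpm_group1, tpm_group2, pseudocount = 1) {
  ratio <- pseudocount_ratio(tpm_group1, tpm_group2, pseudocount)
  list(ratio = ratio, log2fc = log2_fold_change(ratio))
}

#' Match proteomic and transcriptomic directions gene by gene
#'
#' For every (gene, stage) pair present in both the proteomic results and
#' the expression table, computes the transcript fold change with the
#' stage-specific pseudocount, classifies its direction, and flags
#' concordance: a record is concordant when protein and transcript change
#' in the same direction and neither is unchanged. Genes present on only
#' one side are skipped (and reported via a message).
#'
#' @param results A `spectral_da` fit or its results data frame (columns
#'   `gene`, `direction`).
#' @param expression Expression records from [read_expression_table()],
#'   possibly several stages row-bound together.
#' @param pseudocount Named numeric vector giving the pseudocount per stage
#'   (default `c(first_trimester = 0, third_trimester = 1)`, the dialects of
#'   the published table), or a single number used for every stage.
#' @param tolerance Direction dead band, as in [classify_direction()].
#' @return Data frame with one row per (gene, stage): `gene`, `stage`,
#'   `tpm_group1`, `tpm_group2`, `tpm_ratio`, `tpm_log2fc`,
#'   `protein_direction`, `transcript_direction`, `concordant`.
#' @export
match_directions <- function(results, expression,
                             pseudocount = c(first_trimester = 0,
                                             third_trimester = 1),
                             tolerance = 0) {
  if (inherits(results, "spectral_da")) results <- results$results
  if (!is.data.frame(results) || !all(c("gene", "direction") %in% names(results)))
    stop_input("'results' must contain columns gene and direction")
  need <- c("gene", "stage", "tpm_group1", "tpm_group2")
  if (!is.data.frame(expression) || !all(need %in% names(expression)))
    stop_input("'expression' must contain columns %s",
               paste(need, collapse = ", "))
  stage_kappa <- function(stage) {
    if (length(pseudocount) == 1L && is.null(names(pseudocount)))
      return(as.numeric(pseudocount))
    if (!stage %in% names(pseudocount))
      stop_input("no pseudocount configured for stage '%s'", stage)
    as.numeric(pseudocount[[stage]])
  }
  prot_gene <- normalize_gene_symbol(results$gene)
  prot_dir <- stats::setNames(results$direction, prot_gene)
  expr_gene <- normalize_gene_symbol(expression$gene)
  shared <- expr_gene %in% prot_gene
  only_expr <- unique(expr_gene[!shared])
  only_prot <- setdiff(prot_gene, expr_gene)
  if (length(only_expr) || length(only_prot))
    message(sprintf("skipping genes absent from one side (%d expression-only, %d protein-only)",
                    length(only_expr), length(only_prot)))
  expr <- expression[shared, , drop = FALSE]
  expr_gene <- expr_gene[shared]
  if (nrow(expr) == 0L) {
    return(data.frame(gene = character(0), stage = character(0),
                      tpm_group1 = numeric(0), tpm_group2 = numeric(0),
                      tpm_ratio = numeric(0), tpm_log2fc = numeric(0),
                      protein_direction = character(0),
                      transcript_direction = character(0),
                      concordant = logical(0), stringsAsFactors = FALSE))
  }
  kappa <- vapply(expr$stage, stage_kappa, numeric(1), USE.NAMES = FALSE)
  ratio <- mapply(pseudocount_ratio, expr$tpm_group1, expr$tpm_group2, kappa)
  tdir <- classify_direction(ratio, tolerance)
  pdir <- unname(prot_dir[expr_gene])
  out <- data.frame(gene = expr_gene,
                    stage = expr$stage,
                    tpm_group1 = expr$tpm_group1,
                    tpm_group2 = expr$tpm_group2,
                    tpm_ratio = ratio,
                    tpm_log2fc = log2_fold_change(ratio),
                    protein_direction = pdir,
                    transcript_direction = tdir,
                    stringsAsFactors = FALSE)
  out$concordant <- out$protein_direction == out$transcript_direction &
    out$protein_direction != "unchanged"
  rownames(out) <- NULL
  out
}

#' Summarize direction concordance across gestational stages
#'
#' @param records Concordance records from [match_directions()].
#' @return A list: `per_stage_matches` (concordant genes per stage),
#'   `n_tested` (genes compared per stage), `fraction_concordant`,
#'   `conserved_genes` (genes concordant in every stage present, i.e. the
#'   intersection of the per-stage concordant sets), and
#'   `n_distinct_genes` (distinct concordant genes over all stages).
#' @export
summarize_concordance <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("gene", "stage", "concordant") %in% names(records)))
    stop_input("'records' must come from match_directions()")
  stages <- unique(records$stage)
  per_stage <- lapply(stages, function(st) {
    sub <- records[records$stage == st, , drop = FALSE]
    list(tested = nrow(sub), genes = sub$gene[sub$concordant])
  })
  names(per_stage) <- stages
  matches <- vapply(per_stage, function(x) length(x$genes), integer(1))
  tested <- vapply(per_stage, function(x) x$tested, integer(1))
  conserved <- if (length(stages) == 0L) character(0) else
    sort(Reduce(intersect, lapply(per_stage, `[[`, "genes")))
  list(per_stage_matches = matches,
       n_tested = tested,
       fraction_concordant = ifelse(tested > 0, matches / tested, NA_real_),
       conserved_genes = conserved,
       n_distinct_genes = length(unique(unlist(lapply(per_stage, `[[`,
                                                      "genes")))))
}

#' Cross-validate proteomic directions against transcriptome TPM tables
#'
#' Convenience wrapper: [match_directions()] followed by
#' [summarize_concordance()], returned as a classed object with `print` and
#' `plot` methods.
#'
#' @inheritParams match_directions
#' @return An object of class `direction_concordance` with components
#'   `records`, `summary`, `pseudocount` and `tolerance`.
#' @examples
#' counts <- read_peptide_counts(system.file("extdata",
#'   "trophoblast_mito_counts.tsv", package = "mitodiff"))
#' ann <- read_annotation(system.file("extdata", "mitocarta_symbols.tsv",
#'   package = "mitodiff"))
#' fit <- spectral_da(counts, ann)
#' tpm <- rbind(
#'   read_expression_table(system.file("extdata", "tpm_first_trimester.tsv",
#'     package = "mitodiff"), "first_trimester"),
#'   read_expression_table(system.file("extdata", "tpm_third_trimester.tsv",
#'     package = "mitodiff"), "third_trimester"))
#' direction_concordance(fit, tpm)
#' @export
direction_concordance <- function(results, expression,
                                  pseudocount = c(first_trimester = 0,
                                                  third_trimester = 1),
                                  tolerance = 0) {
  records <- match_directions(results, expression, pseudocount, tolerance)
  structure(list(records = records,
                 summary = summarize_concordance(records),
                 pseudocount = pseudocount,
                 tolerance = tolerance),
            class = "direction_concordance")
}

#' @export
print.direction_concordance <- function(x, ...) {
  s <- x$summary
  cat("Proteome-transcriptome direction concordance\n")
  if (length(s$n_tested) == 0L) {
    cat("  no (gene, stage) pairs compared\n")
    return(invisible(x))
  }
  for (st in names(s$n_tested))
    cat(sprintf("  %s: %d of %d genes concordant (%.1f%%)\n", st,
                s$per_stage_matches[[st]], s$n_tested[[st]],
                100 * s$fraction_concordant[[st]]))
  cat(sprintf("  conserved across stages: %d gene(s)\n",
              length(s$conserved_genes)))
  if (length(s$conserved_genes))
    cat("   ", paste(s$conserved_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Scatter plot of transcript versus protein fold-change direction
#'
#' @param x A `direction_concordance` object.
#' @param results Optional `spectral_da` fit supplying protein log2 fold
#'   changes for the x axis; without it, protein direction is shown as
#'   sign only.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.direction_concordance <- function(x, results = NULL, ...) {
  rec <- x$records
  if (nrow(rec) == 0L) {
    warning("nothing to plot: no matched records", call. = FALSE)
    return(invisible(x))
  }
  xval <- if (!is.null(results)) {
    res <- if (inherits(results, "spectral_da")) results$results else results
    lfc <- stats::setNames(res$log2fc, normalize_gene_symbol(res$gene))
    unname(lfc[rec$gene])
  } else {
    ifelse(rec$protein_direction == "higher_group1", 1,
           ifelse(rec$protein_direction == "higher_group2", -1, 0))
  }
  col <- ifelse(rec$concordant, "forestgreen", "grey50")
  pch <- ifelse(rec$stage == rec$stage[1], 19, 17)
  graphics::plot(xval, rec$tpm_log2fc, col = col, pch = pch,
                 xlab = "protein log2 fold change",
                 ylab = "transcript log2 fold change", ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey40")
  invisible(x)
}

#' Write a concordance report table
#'
#' Tab-separated report in the layout of the published validation table,
#' one row per (gene, stage).
#'
#' @param x A `direction_concordance` object or a records data frame from
#'   [match_directions()].
#' @param path Output file path.
#' @param digits Significant figures for numeric columns (default 7; the
#'   published TPM tables print up to 7 significant figures).
#' @return `path`, invisibly.
#' @export
write_concordance_table <- function(x, path, digits = 7) {
  rec <- if (inherits(x, "direction_concordance")) x$records else x
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  out <- data.frame(gene = rec$gene, stage = rec$stage,
                    tpm_cyt = fmt(rec$tpm_group1),
                    tpm_syn = fmt(rec$tpm_group2),
                    tpm_ratio = fmt(rec$tpm_ratio),
                    tpm_log2fc = fmt(rec$tpm_log2fc),
                    protein_direction = rec$protein_direction,
                    transcript_direction = rec$transcript_direction,
                    concordant = rec$concordant, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
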