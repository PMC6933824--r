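#' Control parameters for the differential-abundance fit
#'
#' @param pseudocount Non-negative number added to both group counts before
#'   forming the ratio (default 1, the convention that reproduces the
#'   published count-table arithmetic; use 0 for the plain ratio).
#' @param alpha Significance level in (0, 1) for Fisher's exact test
#'   (default 0.05).
#' @param min_unique_peptides Minimum unique-peptide count a protein must
#'   reach in at least one group to be tested (default 3). The filter is on
#'   the maximum across groups, so a protein confidently detected in only
#'   one group (e.g. 7 vs 0) is retained.
#' @param unchanged_tolerance Dead band around ratio 1 for the direction
#'   call; see [classify_direction()].
#' @param background_mode `"column_totals"` (default) builds the background
#'   from the rounded column sums of the tested set; `"explicit"` uses
#'   `background_totals`.
#' @param background_totals Length-2 positive integer vector of explicit
#'   background totals (group 1, group 2); required for `"explicit"` mode,
#'   and each total must be at least the corresponding per-protein counts.
#' @param adjust `"none"` (default; raw Fisher p-values decide significance)
#'   or `"BH"` to additionally report Benjamini-Hochberg q-values in a
#'   `q_value` column. The q-values are reported only; the significance
#'   flag always uses the raw p-value, matching the original procedure.
#' @param group_labels Character vector of length 2 naming the groups
#'   (numerator first).
#' @return A list of class `da_control`.
#' @export
da_control <- function(pseudocount = 1,
                       alpha = 0.05,
                       min_unique_peptides = 3,
                       unchanged_tolerance = 0,
                       background_mode = c("column_totals", "explicit"),
                       background_totals = NULL,
                       adjust = c("none", "BH"),
                       group_labels = c("Cyto", "Syncytio")) {
  background_mode <- match.arg(background_mode)
  adjust <- match.arg(adjust)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop_input("'pseudocount' must be a single non-negative number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_input("'alpha' must lie strictly between 0 and 1")
  if (!is.numeric(min_unique_peptides) || length(min_unique_peptides) != 1L ||
      min_unique_peptides < 0)
    stop_input("'min_unique_peptides' must be a single non-negative number")
  if (!is.numeric(unchanged_tolerance) || length(unchanged_tolerance) != 1L ||
      unchanged_tolerance < 0)
    stop_input("'unchanged_tolerance' must be a single non-negative number")
  if (background_mode == "explicit") {
    if (is.null(background_totals) || length(background_totals) != 2L ||
        !is_count_like(background_totals) || any(background_totals < 1) ||
        !is_whole(background_totals))
      stop_input("'background_totals' must be two positive integers in explicit mode")
  }
  if (length(group_labels) != 2L || anyDuplicated(group_labels))
    stop_input("'group_labels' must be two distinct labels")
  structure(list(pseudocount = pseudocount, alpha = alpha,
                 min_unique_peptides = min_unique_peptides,
                 unchanged_tolerance = unchanged_tolerance,
                 background_mode = background_mode,
                 background_totals = background_totals,
                 adjust = adjust,
                 group_labels = as.character(group_labels)),
            class = "da_control")
}

#' Differential abundance of mitochondrial proteins from spectral counts
#'
#' Fits the spectral-count differential-abundance model to a two-group
#' unique-peptide count table: (1) restrict to proteins annotated as
#' mitochondrial; (2) drop proteins whose maximum group count falls below
#' `min_unique_peptides`; (3) form the background totals (rounded column
#' sums of the tested set, or explicit totals); (4) per protein compute the
#' pseudocount ratio, log2 fold change, direction class, and a two-sided
#' Fisher's exact p-value of the protein's rounded counts against the
#' background. Input order is preserved in the output.
#'
#' @param counts Count table from [read_peptide_counts()] or
#'   [simulate_spectral_counts()] (columns `protein_id`, `gene`,
#'   `count_group1`, `count_group2`).
#' @param annotation Optional `mito_annotation` from [read_annotation()].
#'   If omitted and `counts` carries no `is_mitochondrial` column, every
#'   protein is treated as mitochondrial (useful for simulated data).
#' @param control A [da_control()] object.
#' @return An object of class `spectral_da`: a list with components
#'   `results` (data frame: `protein_id`, `gene`, `count_group1`,
#'   `count_group2`, `ratio`, `log2fc`, `p_value`, optional `q_value`,
#'   `direction`, `significant`), `background` (totals and mode), `n`
#'   (input / mitochondrial / tested counts), `dropped` (excluded proteins
#'   with reasons), `control`, `group_labels` and `call`. Methods:
#'   `print`, `summary`, `coef` (named log2 fold changes), `plot`
#'   (volcano), `as.data.frame`.
#' @examples
#' counts <- read_peptide_counts(system.file("extdata",
#'   "trophoblast_mito_counts.tsv", package = "mitodiff"))
#' ann <- read_annotation(system.file("extdata", "mitocarta_symbols.tsv",
#'   package = "mitodiff"))
#' fit <- spectral_da(counts, ann)
#' summary(fit)
#' @export
spectral_da <- function(counts, annotation = NULL, control = da_control()) {
  cl <- match.call()
  counts <- validate_counts(counts)
  if (!inherits(control, "da_control"))
    stop_input("'control' must come from da_control()")
  if (!is.null(annotation)) {
    counts <- annotate_mitochondrial(counts, annotation)
  } else if (!"is_mitochondrial" %in% names(counts)) {
    counts$is_mitochondrial <- TRUE
    counts$matched_symbol <- normalize_gene_symbol(counts$gene)
  }
  n_input <- nrow(counts)
  mito <- counts[counts$is_mitochondrial, , drop = FALSE]
  keep <- pmax(mito$count_group1, mito$count_group2) >=
    control$min_unique_peptides
  tested <- mito[keep, , drop = FALSE]
  not_mito <- counts$protein_id[!counts$is_mitochondrial]
  low_count <- mito$protein_id[!keep]
  dropped <- data.frame(
    protein_id = c(not_mito, low_count),
    reason = c(rep("not_mitochondrial", length(not_mito)),
               rep("below_min_unique_peptides", length(low_count))),
    stringsAsFactors = FALSE)
  empty <- data.frame(protein_id = character(0), gene = character(0),
                      count_group1 = numeric(0), count_group2 = numeric(0),
                      ratio = numeric(0), log2fc = numeric(0),
                      p_value = numeric(0), direction = character(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (nrow(tested) == 0L) {
    warning("no proteins retained after annotation and count filtering",
            call. = FALSE)
    res <- empty
    totals <- c(NA_real_, NA_real_)
  } else {
    c_int <- round_half_up(tested$count_group1)
    s_int <- round_half_up(tested$count_group2)
    if (control$background_mode == "column_totals") {
      totals <- c(sum(c_int), sum(s_int))
      if (any(totals < 1))
        stop_input("background column total is zero; supply explicit totals")
    } else {
      totals <- as.numeric(control$background_totals)
      if (any(c_int > totals[1]) || any(s_int > totals[2]))
        stop_input("explicit background totals are smaller than a per-protein count")
    }
    ratio <- pseudocount_ratio(tested$count_group1, tested$count_group2,
                               control$pseudocount)
    res <- data.frame(protein_id = tested$protein_id,
                      gene = tested$gene,
                      count_group1 = tested$count_group1,
                      count_group2 = tested$count_group2,
                      ratio = ratio,
                      log2fc = log2_fold_change(ratio),
                      p_value = fisher_background_test(c_int, s_int,
                                                      totals[1], totals[2]),
                      direction = classify_direction(ratio,
                                                     control$unchanged_tolerance),
                      stringsAsFactors = FALSE)
    res$significant <- res$p_value <= control$alpha
    if (control$adjust == "BH")
      res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    rownames(res) <- NULL
  }
  structure(list(results = res,
                 background = list(mode = control$background_mode,
                                   totals = stats::setNames(totals,
                                                            control$group_labels)),
                 n = c(input = n_input, mitochondrial = nrow(mito),
                       tested = nrow(tested)),
                 dropped = dropped,
                 control = control,
                 group_labels = control$group_labels,
                 call = cl),
            class = "spectral_da")
}

#' @export
print.spectral_da <- function(x, ...) {
  lb <- x$group_labels
  cat("Spectral-count differential abundance (", lb[1], " vs ", lb[2], ")\n",
      sep = "")
  cat(sprintf("  proteins: %d input, %d mitochondrial, %d tested\n",
              x$n["input"], x$n["mitochondrial"], x$n["tested"]))
  if (x$n["tested"] > 0)
    cat(sprintf("  background totals: %s = %d, %s = %d (%s)\n",
                lb[1], as.integer(x$background$totals[1]),
                lb[2], as.integer(x$background$totals[2]),
                x$background$mode))
  cat(sprintf("  significant at alpha = %g: %d\n", x$control$alpha,
              sum(x$results$significant)))
  invisible(x)
}

#' Summarize a spectral-count differential-abundance fit
#'
#' @param object A `spectral_da` fit.
#' @param pathways Optional pathway map (named vector from
#'   [read_pathway_map()]); when given, significant hits are also grouped
#'   by pathway.
#' @param ... Unused.
#' @return A `summary.spectral_da` list: direction triples over all tested
#'   and over significant proteins, significant count, background totals,
#'   and optional pathway counts.
#' @export
summary.spectral_da <- function(object, pathways = NULL, ...) {
  res <- object$results
  sig <- res[res$significant, , drop = FALSE]
  out <- list(group_labels = object$group_labels,
              n = object$n,
              background = object$background,
              alpha = object$control$alpha,
              directions_tested = summarize_directions(res),
              directions_significant = summarize_directions(sig),
              n_significant = nrow(sig),
              pathway_counts = if (!is.null(pathways))
                assign_pathways(sig, pathways))
  class(out) <- "summary.spectral_da"
  out
}

#' @export
print.summary.spectral_da <- function(x, ...) {
  lb <- x$group_labels
  cat("Spectral-count differential abundance (", lb[1], " vs ", lb[2], ")\n",
      sep = "")
  cat(sprintf("  proteins tested: %d (of %d input)\n",
              x$n["tested"], x$n["input"]))
  d <- x$directions_tested
  cat(sprintf("  directions (tested): %d higher in %s, %d unchanged, %d higher in %s\n",
              d["higher_group1"], lb[1], d["unchanged"],
              d["higher_group2"], lb[2]))
  d <- x$directions_significant
  cat(sprintf("  significant at alpha = %g: %d (%d higher in %s, %d higher in %s)\n",
              x$alpha, x$n_significant,
              d["higher_group1"], lb[1], d["higher_group2"], lb[2]))
  if (!is.null(x$pathway_counts)) {
    cat("  significant hits by pathway:\n")
    pc <- x$pathway_counts
    for (nm in names(pc))
      cat(sprintf("    %-38s %d\n", nm, pc[[nm]]))
  }
  invisible(x)
}

#' @export
coef.spectral_da <- function(object, ...) {
  stats::setNames(object$results$log2fc, object$results$protein_id)
}

#' @export
as.data.frame.spectral_da <- function(x, ...) {
  out <- x$results
  attr(out, "group_labels") <- x$group_labels
  out
}

#' Volcano plot of a differential-abundance fit
#'
#' @param x A `spectral_da` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spectral_da <- function(x, ...) {
  res <- x$results
  if (nrow(res) == 0L) {
    warning("nothing to plot: empty result set", call. = FALSE)
    return(invisible(x))
  }
  col <- ifelse(!res$significant, "grey60",
                ifelse(res$direction == "higher_group1", "firebrick",
                       "steelblue"))
  graphics::plot(res$log2fc, -log10(res$p_value), col = col, pch = 19,
                 xlab = sprintf("log2 fold change (%s / %s)",
                                x$group_labels[1], x$group_labels[2]),
                 ylab = "-log10 Fisher p", ...)
  graphics::abline(h = -log10(x$control$alpha), lty = 2, col = "grey40")
  graphics::abline(v = 0, lty = 3, col = "grey40")
  invisible(x)
}

#' Count proteins per direction class
#'
#' @param x A `spectral_da` fit, a results data frame with a `direction`
#'   column, or a character vector of direction labels.
#' @return Named integer vector `c(higher_group1, unchanged, higher_group2)`;
#'   the three entries always sum to the number of records.
#' @examples
#' summarize_directions(c("higher_group1", "higher_group2", "higher_group1"))
#' @export
summarize_directions <- function(x) {
  dir <- if (inherits(x, "spectral_da")) x$results$direction
         else if (is.data.frame(x)) x$direction
         else x
  if (is.null(dir)) dir <- character(0)
  if (!all(dir %in% direction_levels))
    stop_input("unknown direction label(s): %s",
               paste(setdiff(dir, direction_levels), collapse = ", "))
  counts <- table(factor(dir, levels = direction_levels))
  stats::setNames(as.integer(counts), direction_levels)
}

#' Group results by pathway
#'
#' Counts result proteins per pathway label using a gene-to-pathway map;
#' genes absent from the map are collected under `"unassigned"`. Counts
#' (including `"unassigned"`) always sum to the number of input results.
#'
#' @param results A `spectral_da` fit or a results data frame with a `gene`
#'   column.
#' @param pathways Named character vector from [read_pathway_map()].
#' @return Named integer vector of per-pathway counts (empty for empty
#'   input; `"unassigned"` present only when needed).
#' @export
assign_pathways <- function(results, pathways) {
  if (inherits(results, "spectral_da")) results <- results$results
  if (!is.character(pathways) || is.null(names(pathways)))
    stop_input("'pathways' must be a named character vector (gene -> label)")
  if (nrow(results) == 0L) return(stats::setNames(integer(0), character(0)))
  genes <- normalize_gene_symbol(results$gene)
  label <- unname(pathways[genes])
  label[is.na(label)] <- "unassigned"
  counts <- table(label)
  # stable order: pathway-map order first, then unassigned
  ord <- c(intersect(unique(unname(pathways)), names(counts)),
           intersect("unassigned", names(counts)))
  stats::setNames(as.integer(counts[ord]), ord)
}
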