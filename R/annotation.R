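#' Normalize a gene symbol
#'
#' Canonical form used for every symbol comparison in the package:
#' uppercase, surrounding whitespace stripped, internal whitespace removed.
#' Gene symbols are the join key across the proteomic and transcriptomic
#' layers, so both sides are normalized the same way.
#'
#' @param symbol Character vector of gene symbols; no element may be empty
#'   or all-whitespace.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_gene_symbol(c("Atp5b ", "chchd3"))
#' @export
normalize_gene_symbol <- function(symbol) {
  if (!is.character(symbol))
    stop_input("'symbol' must be a character vector")
  if (length(symbol) == 0L) return(character(0))
  out <- toupper(gsub("[[:space:]]+", "", symbol))
  if (any(is.na(out)) || any(!nzchar(out)))
    stop_input("gene symbols must be non-empty, non-blank strings")
  out
}

#' Read a mitochondrial gene annotation list
#'
#' Reads a MitoCarta-style inventory of mitochondrial genes: a tab-separated
#' file with a `symbol` column and an optional `synonyms` column holding
#' comma-separated alternative symbols. Symbols are normalized via
#' [normalize_gene_symbol()] and must be unique after normalization.
#'
#' @param path Path to the annotation file.
#' @return A data frame of class `mito_annotation` with columns `symbol`
#'   (normalized primary symbol) and `synonyms` (list column of normalized
#'   synonym vectors).
#' @examples
#' ann <- read_annotation(system.file("extdata", "mitocarta_symbols.tsv",
#'                                    package = "mitodiff"))
#' head(ann$symbol)
#' @export
read_annotation <- function(path) {
  if (!file.exists(path))
    stop_input("annotation file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"symbol" %in% names(tab))
    stop_input("annotation file %s lacks required column 'symbol'", path)
  symbol <- normalize_gene_symbol(tab$symbol)
  if (anyDuplicated(symbol))
    stop_input("duplicate annotation symbols after normalization: %s",
               paste(unique(symbol[duplicated(symbol)]), collapse = ", "))
  synonyms <- rep(list(character(0)), length(symbol))
  if ("synonyms" %in% names(tab)) {
    synonyms <- lapply(tab$synonyms, function(x) {
      parts <- strsplit(x %||% "", ",", fixed = TRUE)[[1]]
      parts <- trimws(parts)
      parts <- parts[nzchar(parts)]
      if (length(parts)) normalize_gene_symbol(parts) else character(0)
    })
  }
  out <- data.frame(symbol = symbol, stringsAsFactors = FALSE)
  out$synonyms <- synonyms
  class(out) <- c("mito_annotation", "data.frame")
  out
}

# build a lookup environment: normalized symbol/synonym -> primary symbol.
# primary symbols always win over synonyms; a synonym shared by several
# entries resolves to the first entry in file order.
annotation_lookup <- function(annotation) {
  primary <- annotation$symbol
  map <- new.env(parent = emptyenv(), size = 2L * length(primary))
  dup_syn <- character(0)
  for (i in seq_along(primary)) {
    for (syn in annotation$synonyms[[i]]) {
      if (is.null(map[[syn]])) {
        map[[syn]] <- primary[i]
      } else if (map[[syn]] != primary[i]) {
        dup_syn <- c(dup_syn, syn)
      }
    }
  }
  # primaries override any synonym of the same name
  for (p in primary) map[[p]] <- p
  list(map = map, dup_syn = unique(dup_syn))
}

#' Flag mitochondrial proteins by gene-symbol cross-reference
#'
#' Cross-references each protein's gene symbol against a mitochondrial gene
#' list to identify "true" mitochondrial proteins. Matching is by normalized
#' primary symbol first, then by synonyms; matched records report the
#' annotation's primary symbol so downstream joins are deterministic.
#' Non-matching proteins are retained and flagged `FALSE` (no match is a
#' valid outcome, not an error).
#'
#' @param records A peptide-count data frame as returned by
#'   [read_peptide_counts()] (columns `protein_id`, `gene`, `count_group1`,
#'   `count_group2`).
#' @param annotation A `mito_annotation` object from [read_annotation()].
#' @return `records` with two added columns: `is_mitochondrial` (logical)
#'   and `matched_symbol` (the annotation's primary symbol, `NA` when
#'   unmatched). Row order is preserved; re-annotating is idempotent.
#' @export
annotate_mitochondrial <- function(records, annotation) {
  records <- validate_counts(records)
  if (!inherits(annotation, "mito_annotation"))
    stop_input("'annotation' must come from read_annotation()")
  if (nrow(annotation) == 0L)
    stop_input("annotation table is empty")
  lk <- annotation_lookup(annotation)
  genes <- normalize_gene_symbol(records$gene)
  matched <- vapply(genes, function(g) {
    hit <- lk$map[[g]]
    if (is.null(hit)) NA_character_ else hit
  }, character(1), USE.NAMES = FALSE)
  hit_dup <- intersect(genes, lk$dup_syn)
  if (length(hit_dup))
    warning(sprintf(
      "symbol(s) %s match a synonym of multiple annotation entries; %s",
      paste(hit_dup, collapse = ", "),
      "resolved to the first entry in file order"), call. = FALSE)
  records$is_mitochondrial <- !is.na(matched)
  records$matched_symbol <- matched
  records
}
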