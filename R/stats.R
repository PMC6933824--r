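#' Pseudocount ratio of two spectral counts
#'
#' Forms the abundance ratio `(c + kappa) / (s + kappa)` between the two
#' groups, where the pseudocount `kappa` keeps ratios finite when a protein
#' was not detected in one group (e.g. PCK2, detected with 7 average unique
#' peptides in cytotrophoblast mitochondria and 0 in syncytiotrophoblast
#' mitochondria, has ratio 8 at `kappa = 1`). With `kappa = 0` this is the
#' plain ratio used for already-continuous quantities such as TPM values.
#'
#' @param c Non-negative numeric vector, group-1 counts (numerator group).
#' @param s Non-negative numeric vector, group-2 counts (denominator group).
#' @param pseudocount Single non-negative number added to both counts.
#' @return Numeric vector of positive ratios.
#' @examples
#' pseudocount_ratio(232, 136, 1)  # 1.70073
#' pseudocount_ratio(7, 0, 1)      # 8
#' @seealso [log2_fold_change()], [classify_direction()]
#' @export
pseudocount_ratio <- function(c, s, pseudocount = 1) {
  if (!is_count_like(c) || !is_count_like(s))
    stop_input("counts must be finite, non-negative numbers")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount < 0)
    stop_input("'pseudocount' must be a single non-negative number")
  if (length(c) != length(s))
    stop_input("'c' and 's' must have the same length")
  den <- s + pseudocount
  if (any(den == 0))
    stop_input("ratio undefined: denominator count plus pseudocount is zero")
  (c + pseudocount) / den
}

#' Log2 fold change of a ratio
#'
#' @param ratio Positive numeric vector.
#' @return `log2(ratio)`; positive values mean higher abundance in group 1.
#' @examples
#' log2_fold_change(8)  # 3
#' @export
log2_fold_change <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
    stop_input("'ratio' must be positive and finite")
  log2(ratio)
}

#' Classify the direction of a fold change
#'
#' Maps a (pseudocount) ratio to one of `"higher_group1"`, `"unchanged"`,
#' `"higher_group2"`. The tolerance defines a symmetric dead band around 1:
#' a ratio counts as changed only if it exceeds `1 + tolerance` or falls
#' below `1 / (1 + tolerance)`. The default tolerance 0 treats only exact
#' ties as unchanged.
#'
#' @param ratio Positive numeric vector.
#' @param tolerance Single non-negative number.
#' @return Character vector of direction labels.
#' @examples
#' classify_direction(c(1.7, 1, 0.72))
#' @export
classify_direction <- function(ratio, tolerance = 0) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
    stop_input("'ratio' must be positive and finite")
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop_input("'tolerance' must be a single non-negative number")
  out <- rep("unchanged", length(ratio))
  out[ratio > 1 + tolerance] <- "higher_group1"
  out[ratio < 1 / (1 + tolerance)] <- "higher_group2"
  out
}

direction_levels <- c("higher_group1", "unchanged", "higher_group2")

#' Fisher's exact test of a protein against the background counts
#'
#' Tests whether a protein's unique-peptide counts `(c, s)` in the two
#' groups depart from the background count distribution, via the 2x2 table
#' `[[c, s], [C_tot - c, S_tot - s]]` where `C_tot`/`S_tot` are the total
#' counts per group. The two-sided p-value is the conventional
#' minimum-likelihood definition: the sum of hypergeometric point
#' probabilities of all tables (with the same margins) no more probable
#' than the observed one, ties included up to a 1e-7 relative tolerance.
#'
#' Counts must be whole numbers; averaged counts should be rounded
#' (half-up) before testing, as [spectral_da()] does.
#'
#' @param c,s Non-negative integer counts for the protein in groups 1 and 2
#'   (vectors are accepted and recycled against each other).
#' @param C_tot,S_tot Positive integer background totals per group;
#'   `c <= C_tot` and `s <= S_tot` are required.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' fisher_background_test(1, 1, 2, 2)      # 1: perfectly balanced
#' fisher_background_test(232, 136, 1993, 1461)
#' @export
fisher_background_test <- function(c, s, C_tot, S_tot) {
  if (!is_count_like(c) || !is_count_like(s))
    stop_input("'c' and 's' must be finite, non-negative numbers")
  if (!is_whole(c) || !is_whole(s))
    stop_input("'c' and 's' must be whole numbers; round averaged counts first")
  if (!is.numeric(C_tot) || length(C_tot) != 1L || !is.finite(C_tot) ||
      C_tot < 1 || !is_whole(C_tot))
    stop_input("'C_tot' must be a single positive integer")
  if (!is.numeric(S_tot) || length(S_tot) != 1L || !is.finite(S_tot) ||
      S_tot < 1 || !is_whole(S_tot))
    stop_input("'S_tot' must be a single positive integer")
  n <- max(length(c), length(s))
  c <- rep_len(round(c), n)
  s <- rep_len(round(s), n)
  if (any(c > C_tot))
    stop_input("count c exceeds background total C_tot")
  if (any(s > S_tot))
    stop_input("count s exceeds background total S_tot")
  vapply(seq_len(n), function(i) {
    fisher_two_sided(c[i], s[i], C_tot, S_tot)
  }, numeric(1))
}

# scalar two-sided Fisher p by minimum-likelihood summation
fisher_two_sided <- function(c, s, C_tot, S_tot) {
  r <- c + s
  lo <- max(0L, r - S_tot)
  hi <- min(r, C_tot)
  k <- lo:hi
  prob <- stats::dhyper(k, C_tot, S_tot, r)
  p_obs <- prob[c - lo + 1L]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}
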