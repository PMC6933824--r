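---
title: "Spectral-count differential abundance with background Fisher tests"
author: "mitodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count differential abundance with background Fisher tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodiff)
```

## The problem

Label-free proteomics of isolated organelles often quantifies each protein
by its *unique peptide count* — the number of distinct peptide sequences
identified per LC-MS run — averaged over replicate runs. mitodiff
implements a complete differential-abundance workflow for such data,
developed around the comparison of mitochondria isolated from the two
trophoblast lineages of the human placenta: mononuclear cytotrophoblast
("Cyto-Mito", group 1) versus the fused, multinucleated syncytiotrophoblast
("Syncytio-Mito", group 2). The same machinery applies to any two-group
spectral-count comparison of an annotated protein universe.

The workflow is:

1. **Annotation.** Proteins are cross-referenced by gene symbol against a
   MitoCarta-style inventory of mitochondria-localized genes to restrict
   the analysis universe to "true" organellar proteins. Matching is on
   normalized symbols (uppercased, whitespace-stripped), primary symbols
   first, then synonyms; synonym matches are reported under the primary
   symbol so that all downstream joins are deterministic.
2. **Filtering.** Proteins need at least `min_unique_peptides` (default 3)
   unique peptides in *at least one* group. The maximum-across-groups
   reading is deliberate: a protein confidently detected in one group and
   absent from the other (counts 7 vs 0) is among the most interesting
   outcomes and must not be discarded.
3. **Effect size.** For counts $c$ (group 1) and $s$ (group 2) the ratio is
   $R = (c + \kappa)/(s + \kappa)$ with pseudocount $\kappa$ (default 1),
   and the fold change is $L = \log_2 R$. The pseudocount keeps
   zero-count ratios finite and is the unique convention that reproduces
   the published count-table arithmetic this package ships as a fixture.
4. **Significance.** Each protein's rounded counts are contrasted against
   the background totals $(C_{tot}, S_{tot})$ in a 2×2 table
   $[[c, s], [C_{tot}-c, S_{tot}-s]]$ and assessed with a two-sided
   Fisher's exact test at level `alpha` (default 0.05).
5. **Cross-omics validation.** Protein-level directions are compared with
   single-cell transcriptome TPM tables (cytotrophoblast vs
   syncytiotrophoblast, first and third trimester) gene by gene: a gene is
   *concordant* when protein and transcript change in the same direction,
   and *conserved across gestation* when concordant in every stage.

## The Fisher background test

The test statistic is the conventional minimum-likelihood two-sided
Fisher's exact p-value: with the table margins fixed, the first cell is
hypergeometric, and the p-value sums the point probabilities of every
table no more probable than the observed one (ties included up to a 1e-7
relative tolerance, the standard guard against floating-point
misclassification of mathematically tied tables). The implementation
enumerates the hypergeometric support directly and is cross-checked in the
test suite against both an independent binomial-coefficient enumeration
oracle and `stats::fisher.test`, to 1e-10, exhaustively for all tables
with group totals up to 60.

Two numerical conventions matter:

* **Rounding.** Replicate-averaged counts are real numbers; the exact test
  needs integers. Averages are rounded half-up (`floor(x + 0.5)`) before
  testing. Ratios and fold changes are computed from the *unrounded*
  averages.
* **Background construction.** The background totals default to the column
  sums of the post-filter mitochondrial set. This is the simplest
  self-contained reading of "testing against the background distribution";
  when an analysis was originally run against a wider universe (e.g. all
  identified proteins before annotation), the `background_mode = "explicit"`
  override reproduces it exactly, given those totals. Because the packaged
  29-protein fixture is itself a published *result* table, its column sums
  (1993 and 1461) are much smaller than the original experiment's
  unpublished totals, and p-values recomputed on the fixture are therefore
  not comparable to the published ones — the ratios, fold changes,
  directions and concordance counts are, and those are what the acceptance
  machinery checks.

### A caution on testing averaged counts

The procedure tests the *replicate-averaged* counts as if they were raw
counts of a single run. The average of $R$ Poisson counts has variance
$\lambda/R$, a factor $R$ smaller than the Poisson variance the
hypergeometric null implicitly assumes, so the test is strongly
conservative: on null simulations with triplicate runs the empirical
type-I error at $\alpha = 0.05$ is of the order of $10^{-3}$, far below
the nominal level (the package's operating-characteristics evaluator
measures this directly, and one acceptance-level calibration check — that
the empirical size equal the nominal level within binomial noise —
deliberately fails for this reason). Conservatism costs power, not
validity: no spurious discoveries are introduced. Users who want a
calibrated test at the same significance machinery can sum replicate
counts instead of averaging them upstream of the package; the averaged
form is retained as the default because it is the procedure the packaged
fixtures embody.

## Direction classes and ties

`classify_direction()` maps a ratio to `higher_group1`, `unchanged` or
`higher_group2` with a symmetric dead band: changed only if
$R > 1 + t$ or $R < 1/(1 + t)$. The default $t = 0$ counts only exact
ties as unchanged — with integer-valued averages and $\kappa = 1$ exact
ties do occur — and the band is exposed because any nonzero choice is a
judgment call the data cannot settle.

## Pseudocount dialects in the transcriptome layer

The packaged TPM validation tables use two arithmetic dialects, pinned by
reproducing their printed ratios: the third-trimester table applies
$\kappa = 1$ to the TPM values, while the first-trimester table uses the
plain ratio ($\kappa = 0$). `direction_concordance()` therefore takes a
per-stage pseudocount map, defaulting to
`c(first_trimester = 0, third_trimester = 1)`. Genes with TPM 0 in one
cell type flow through the pseudocount path like any other value; with
$\kappa = 0$ a zero denominator is an error by design rather than a
silent infinity.

A concordance record requires a *changed* direction on both layers:
`unchanged` on either side is never concordant. The conserved-gene set is
the intersection of the per-stage concordant gene sets, an identity the
test suite asserts directly. On the packaged fixtures the package computes
18 first-trimester and 21 third-trimester concordant genes, 14 conserved
across gestation and 25 distinct concordant genes; fractions are always
reported with explicit denominators rather than as a single headline
percentage, because the published denominator conventions for such
percentages are ambiguous.

## The synthetic-data generator

`simulate_spectral_counts()` emulates the study design: triplicate runs
per group (`n_replicates = 3`), per-protein baseline abundances drawn
log-normal (`meanlog = log(10)`, `sdlog = 1`, spanning roughly 1–300
unique peptides like the packaged count table), and an expected total
count of 5000 per run per group — consistent with a few hundred organellar
proteins at average counts in the tens. A fraction `de_fraction` of
proteins receives a planted fold change (fixed magnitude or log-uniform
range), applied to the favored group's rate with `de_balance` controlling
which group is favored. Per-run counts are Poisson; a gamma-Poisson
overdispersion knob exists but is off by default because the triplicate
design gives no usable dispersion estimate.

Both groups' rates are scaled by the *common* baseline normalization (the
sum of baseline abundances), not per-group: planted fold changes are then
exactly recovered in expected-rate ratios, and each group's expected run
total equals its configured depth exactly under the null and approximately
otherwise. The alternative — renormalizing each group to its depth —
makes every planted effect leak into all other proteins' rates (a
compositional artifact) and biases recovered fold changes toward 1;
since the generator's purpose is known ground truth, exact effect
recovery was chosen over exact depth preservation.

`simulate_expression_tables()` gives each gene and stage a log-normal
baseline TPM and applies the truth's fold-change magnitude with the
protein effect's sign with probability `concordance_prob` (independently
per stage); genes without a planted effect get equal TPM in both cell
types. The generator emulates direction structure only — it makes no
attempt at peptide-sequence realism, protein-to-transcript magnitude
coupling, or single-cell sampling noise, so passing tests certify the
pipeline's statistics and bookkeeping, not biological fidelity of any
particular dataset.

`evaluate_operating_characteristics()` runs the full differential stage
over repeated simulations (one RNG stream per dataset, derived from the
seed and the simulation index) and pools type-I error, power and
sign-error rate with binomial standard errors. The suite checks that the
empirical size never exceeds the nominal level, that power increases with
planted fold change and with depth, and that with strong effects (fold 8
at depth 5000) significant calls carry no sign errors. Default problem
sizes in the tests (hundreds of proteins, tens to hundreds of
simulations) were chosen as the smallest giving stable binomial noise
margins.

## Degenerate inputs and numerical edges

* Empty files with valid headers parse to empty tables; empty result sets
  write header-only reports; an empty retained set after filtering is a
  warning plus an empty fit, not an error.
* Duplicate protein accessions are an error; duplicate gene symbols across
  accessions are allowed (isoforms), and the transcriptome join then
  matches by symbol on each of them.
* Reports print at 6 significant figures (the published precision);
  write-then-read reproduces ratios, fold changes and p-values to well
  within 1e-5 on the count-ratio scale. JSON summaries carry full
  precision.
* `run_pipeline()` records input MD5 digests in a manifest before
  processing and rewrites the manifest with a terminal status even when a
  stage fails; reruns on identical inputs are byte-identical apart from
  the manifest's timestamp.

## Known limitations

* Raw per-run unique-peptide counts for the original experiment are not
  public; the packaged count fixture is the published 29-protein
  significant set, so recomputed p-values (and anything downstream of the
  original background totals, such as the published 649/384/52/213
  population partition) are not reproducible from the package — only
  effect sizes, directions, pathway groupings and concordance are.
* Fisher-on-averages is conservative (see above).
* No intensity-based quantification, imputation, peptide-to-protein
  inference or empirical-Bayes moderation; the protein-level count table
  is the unit of input.
* The pathway grouping is a static gene-to-label map (two published
  variants ship as fixtures); no enrichment service is queried.
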