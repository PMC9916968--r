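---
title: "Systematic vetting of tumor-associated antigens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systematic vetting of tumor-associated antigens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taavet)
```

## The problem

Targeted T cell therapies (TCR-engineered adoptive transfer,
vaccination, TCR-based engagers) stand or fall with the choice of the
tumor-associated antigen (TAA). A usable TAA for epithelial ovarian
cancer (EOC) must be a shared self-antigen — neoantigens are patient
specific, and EOC has no oncovirus association — expressed strongly and
homogeneously by tumor cells, near-silent in healthy tissue (on-target /
off-tumor toxicity), immunogenic, and ideally tied to the malignant
phenotype so that antigen-negative escape is costly for the tumor.
`taavet` encodes a systematic vetting procedure for this decision as a
tested pipeline: expression-based triage, weighted-rubric scoring,
immunohistochemical (IHC) validation statistics, clinical association
tests, and molecular-subtype differential expression.

## The filter cascade

Candidates enter as a roster of gene-symbol-like ids with an antigen
class (`self`, `neoantigen`, `viral`). Three stages follow, each
emitting counts that satisfy `n_in = n_excluded + n_out` and chain into
the next stage:

1. **Class exclusion.** Only self-antigens pass.
2. **Healthy-tissue tiering.** For each gene, the maximum of its
   per-tissue median TPM across the healthy-tissue panel is compared to
   two cutoffs: below 40 TPM in *every* tissue is `low`, below 400 TPM
   is `medium`, anything else is excluded. "Below a cutoff in all
   tissues" is equivalent to a strict comparison on the per-gene
   maximum, which is how it is implemented; a gene sitting exactly on a
   cutoff lands in the *next* (more expressed) tier, following the
   strict `<` in the rule's statement. Candidates missing from the
   healthy table are a hard error — tiering is not optional.
3. **Tumor-expression gate.** A candidate counts as expressed in the
   tumor cohort when its median FPKM strictly exceeds the tier's median
   cutoff *or* its mean FPKM strictly exceeds the tier's mean cutoff:
   0.5 / 1 for the low tier (a detection threshold), 5 / 10 for the
   medium tier. Medium-tier candidates already show background
   expression in healthy tissue, so only robust tumor expression
   justifies their higher off-tumor risk. The published description of
   the medium-tier rule is grammatically ambiguous between an OR and an
   AND reading; we implement the OR-of-strict-`>` structure, parallel to
   the low-tier rule with raised cutoffs, and expose all four numbers as
   `pipeline_config()` arguments so the choice is overridable.
   Candidates absent from the tumor table are softly excluded with
   reason `no_tumor_data` (missing measurement, not evidence of
   absence).

All cutoffs (40 / 400 TPM; 0.5 / 1 and 5 / 10 FPKM) are defaults, not
constants.

## The scoring rubric

The rubric adapts the Cheever antigen-prioritization criteria for
TCR-based therapy in a specific entity: the *cellular location*
criterion is dropped (TCRs see processed peptides on MHC, not surface
protein), and the *therapeutic function / clinical efficacy* criteria
are dropped to avoid biasing toward clinically established candidates.
The seven remaining criteria are weighted so their maxima sum to
exactly 10: Immunogenicity 2.5, Oncogenicity 2.25, Specificity 2.25,
Level of Expression 1, Tumor Stem Cell Expression 0.8, Patients with
TAA-positive tumors 0.6, Number of Epitopes 0.6. Within each
criterion, ordered subcriteria carry fixed point values
(`default_rubric()` prints them all), the first carrying the criterion
maximum, and an implicit "not applicable" is worth 0 everywhere.

Scoring conventions:

- `unknown` (no literature evidence for a criterion) scores 0 but
  leaves the candidate scored; a candidate whose literature is
  insufficient for any evaluation is flagged `insufficient_data` and is
  listed unranked instead of receiving a misleading 0.
- Totals are reported to two decimals, rounding half away from zero;
  the shipped subcriterion constants are treated as exact.
- Ranking is competition ranking: tied totals share a rank, the next
  distinct total skips the tied positions, and display order within a
  tie is alphabetical.
- `normalize_rubric()` rescales a user-supplied rubric onto a target
  total (default 10) and warns if two-decimal rounding leaves the
  maxima more than 0.05 from the target. The default rubric ships
  already normalized; its own rescaling from the original criterion
  weights is not re-derived.

Three worked annotation patterns (`worked_example_annotations()`) pin
the arithmetic: maximum tiers everywhere except Specificity
("oncofetal AG", 1.22 — the cancer-testis pattern; no real candidate
attains absolute specificity) and Level of Expression ("high, most
cancer cells", 0.37), with the Tumor Stem Cell Expression tier at
0.8 / 0.53 / 0.16 giving totals 8.34, 8.07 and 7.70.

```{r}
sapply(worked_example_annotations(), function(a) score_candidate(a)$total)
```

## IHC quantification

Each tissue-microarray core carries two pathologists' staining
intensities (0 negative, 1 weak, 2 moderate, 3 strong), a consensus
intensity, and the percentage of positive tumor cells as a whole
number. The Q-Score is their product, an integer in 0–300, binned at
exactly 0, 1–149, and ≥ 150. A Q-Score ≥ 150 *implies* intensity ≥ 2
and ≥ 50% positive cells (the converse fails: 2 × 50 = 100), which is
what makes the 150 cut a surrogate for "moderate-to-strong staining in
at least half the tumor" — the test suite asserts this by enumerating
all 4 × 101 input pairs. Inter-rater disagreement is carried as data
(a consensus field plus a discordance count), never averaged:
averaging two intensities produces values outside the ordinal 0–3
scale. Unassessable cores are flagged explicitly and excluded from all
statistics but reported.

## Clinical statistics

The association battery crosses two expression groupings — intensity
dichotomized at moderate (0–1 vs 2–3) and Q-Score ≥ 150 — with the
categorical clinical covariates and with progression-free survival:

- **Fisher's exact test** (2×2): two-sided by the point-probability
  method — the sum of hypergeometric probabilities of all tables, under
  the observed margins, no more probable than the observed one, with a
  `1 + 1e-7` relative tolerance on the comparison (the common
  convention). A zero margin returns p = 1. The implementation is the
  direct `dhyper` sum; `stats::fisher.test` serves as an independent
  cross-check in the tests, as does full `choose()`-based enumeration
  over every table with grand total ≤ 40.
- **Pearson's chi-squared** for larger tables, without continuity
  correction; zero expected counts are refused with a pointer to the
  exact test.
- **Spearman's rho** as the Pearson correlation of midranks; p exact by
  full permutation enumeration for n ≤ 8, t-approximation above.
- **Kaplan–Meier / log-rank** via the `survival` package, with the
  median defined as the smallest event time where the curve reaches
  0.5 or below (undefined if never reached). With no events at all the
  log-rank statistic is 0 and p = 1, with a warning.

The battery applies Fisher to 2×2 tables and chi-squared otherwise
(configurable), and applies **no multiplicity correction by default** —
it is an exploratory screen; a Bonferroni column is available via
`bonferroni = TRUE`.

## Molecular subtypes

Expression-derived EOC clusters c1 (high stromal response), c2 (high
immune signature), c4 (low stromal response) and c5 (mesenchymal) are
the accepted labels; anything else is rejected at load, since only
these represent true malignant neoplasia in the source classification.
The loader takes a pre-normalized probe × sample matrix (e.g.
model-based expression indices); array normalization is out of scope.
When several probe sets measure one gene, the one with the highest mean
expression across all samples represents it (ties break to the
lexicographically smallest probe id, for determinism). Differential
expression uses the tie-corrected Kruskal–Wallis H (chi-squared
approximation on k−1 df; exact enumeration of group assignments for
pooled n ≤ 10), followed by Dunn's z on pooled midranks with two-sided
p-values Bonferroni-corrected by the number of pairs — all six pairs
among four clusters, not only the contrasts against one cluster of
interest, since the analysis is symmetric a priori.

## What the synthetic data emulates — and what it does not

Every input has a generator that plants its ground truth and returns
it alongside the data, so recovery tests consume only (data, pipeline)
and compare afterwards. Defaults reproduce the marginal structure of
the motivating study design: a 237-candidate roster with 70
neoantigens; healthy-tissue tiers 60/47/60 (low/medium/high) with each
gene's maximum planted strictly inside its band; a 373-sample tumor
cohort with 21 low-tier and 17 medium-tier genes planted above their
gate cutoffs and 3 candidates dropped from the table entirely; a
58-core TMA with covariate frequencies matching an advanced serous
cohort (≈90% grade 3, ≈79% FIGO III, ≈88% peritoneal carcinomatosis,
≈26% residual tumor, age ≈ N(60.5, 10), ≈2% unknown platinum
response); and a four-cluster expression matrix with null genes
exchangeable across clusters.

Distributional choices are pragmatic, not estimated from data:
log-normal expression, categorical staining intensity with
percent-positive ≈ 30 × intensity + Gaussian noise (truncated to
1–100, 0 when negative), exponential survival under proportional
hazards (baseline median PFS 15 months in the low-staining group),
logistic platinum response against the Q-bin with a planted odds
ratio. Consequently the generators emulate *marginal structure and
planted effects*, not: between-gene correlation, tumor heterogeneity
within a core, informative censoring, batch effects, probe-level
cross-hybridization, or the mRNA–protein discordance that motivates
doing IHC at all. Passing recovery tests therefore demonstrates that
the pipeline computes its statistics correctly and detects effects it
was told to plant — not that those effects are detectable in real
cohorts of this size.

Determinism: every generator takes an explicit seed, restores the
caller's RNG state, and is byte-reproducible; there is no hidden
global state.

## Numerical conventions and degenerate inputs

- Boundary values in the cascade always land on the side the strict
  inequality dictates (40 TPM → medium; 400 TPM → excluded; median
  exactly 0.5 → not expressed).
- Q-Scores, percentages and intensities are integers; non-integers are
  rejected, not rounded silently.
- Constant input makes Spearman's rho undefined: an error (and a
  warning with an omitted correlation in `staining_summary()`), never
  a fabricated 0.
- Exact-test enumeration sizes: n! permutations for Spearman (n ≤ 8,
  40 320 cases), multinomial assignments for Kruskal–Wallis (pooled
  n ≤ 10, ≤ 4 200 cases); both are exhaustive, not sampled.
- All p-values are clamped to (0, 1].

## Problem sizes in the shipped tests

The test suite runs the cascade at the full 237-candidate scale,
enumerates all 135 751 2×2 tables with grand total ≤ 40 against the
Fisher oracle, and uses 100 seeded replicates of a 200-core TMA for
the log-rank power (hazard ratio 3) and type-I (hazard ratio 1)
simulations; the subtype recovery plants one shifted gene among 50
nulls at 20 samples per cluster. These sizes were chosen so the whole
suite documents the pipeline's statistical behavior while running in
well under a minute of compute for the deterministic parts and a few
tens of seconds for the simulations.

## Known limitations

- Literature curation, epitope-database queries and any external
  downloads are out of scope: annotations, expression tables and TMA
  scores are curated inputs.
- The rubric inherits the subjectivity of its inputs: identical
  evidence can be annotated into different subcriteria by different
  curators; the package makes the arithmetic reproducible, not the
  curation.
- No Cox regression or multivariable modeling is provided; the
  association battery is deliberately the simple exploratory toolkit.
- The Dunn correction factor counts all pairwise comparisons; analyses
  that pre-register a single cluster of interest will find it
  conservative.
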