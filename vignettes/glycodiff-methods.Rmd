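---
title: "glycodiff: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glycodiff: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodiff)
```

`glycodiff` analyses paired tumor / adjacent-normal tissue cohorts
measured by label-free LC-MS at two levels: protein groups and
site-specific N-glycopeptides. This vignette is the package's account of
the statistical machinery, the parameters that matter, and the design
decisions taken where more than one defensible choice existed.

## The glycan model

A glycan composition such as `F1H5N4S1` records residue counts only —
fucose (F), hexose (H), HexNAc (N), sialic acid (S) — with no topology.
Everything the package derives from a composition therefore rests on
standard structural assumptions about mammalian N-glycans:

* every N-glycan carries a chitobiose core of two GlcNAcs and three core
  mannoses;
* in complex and hybrid glycans, each HexNAc beyond the core initiates an
  antenna (`antennae = N - 2`);
* hexoses beyond the three core mannoses are antennal galactoses, capped
  at the antenna count;
* sialic acids cap antennae, again capped at the antenna count.

Classification uses a composition-only rule table (`glycan_rules()`):
`N == 2` with `H >= 5` is high-mannose and with `H <= 4` paucimannose;
`N == 3` with `H >= 5` is hybrid; any other `N >= 3` is complex; `N < 2`
cannot form the core and is unclassified. These are the standard
composition heuristics; since composition cannot distinguish a bisecting
GlcNAc from an antennal one, bisected structures are counted as having one
extra antenna, and core versus antennal fucose cannot be separated, so
fucosylation is the binary "any fucose" indicator per glycopeptide. The
thresholds are deliberately configurable (including from a plain-text
file via `read_glycan_rules()`) because the borderline compositions —
chiefly the paucimannose series around `H3N2`/`H4N2` — are binned
differently across laboratories; with the default table `H3N2` is
paucimannose, not high-mannose.

Glycans without antennae (high-mannose, paucimannose) have *undefined*
sialylation and galactosylation rather than zero: a proportion of
antennae has no meaning without antennae. They are excluded from both the
numerator and the denominator of the overall metrics. Scoring them zero
would instead deflate tissue-level sialylation whenever the high-mannose
share rises, conflating two distinct biological signals.

Overall metrics are abundance-weighted means over glycopeptides. An
alternative reading — averaging over *antennae*, i.e. weighting each
glycopeptide additionally by its antenna count — is available through
`weighted_glycan_metrics(weighting = "antenna")`; the per-glycopeptide
weighting is the default because the fucosylation metric is explicitly
"the proportion of fucosylated N-glycopeptides", making the glycopeptide
the natural unit for all three metrics.

## The glycopeptide pipeline

The cascade is: score filter → merge → presence filter → adaptive test →
BH. Score cutoffs (MS1 ≥ 3.0, MS2 ≥ 5.0) are inclusive, reading "cutoff"
as the minimum acceptable score. Because sub-threshold records can
inflate presence counts, filtering scores *before* counting presence is
the canonical (and stricter) order; the two orders coincide exactly when
every record passes the score filter, and the test suite pins down this
relationship. Both the pre-merge record count and the post-filter feature
count are available (`glyco_counts()` at any stage), since published
"unique glycopeptide" totals can refer to either side of the score
filter.

Merging sums within-sample duplicates (the same glycoform identified in
several charge states or adducts), keeps absence as `NA` — never zero,
which would be a measured quantity — and treats an ambiguous glycosite
(`"197/553"`, where the peptide covers two sequons) as a single feature
under its sorted rendering.

The presence filter (≥ 5 samples in at least one group, at the default
cohort size of 12 + 12) is intentionally one-sided: a glycopeptide
consistently present in tumors and absent from adjacent tissue is exactly
the kind of feature one must keep.

**Adaptive testing.** For each glycopeptide with at least `min_n = 3`
observations per group (the Shapiro–Wilk test is undefined below 3):

1. Shapiro–Wilk in each group on log2 abundances; if either p < 0.05 →
   Wilcoxon rank-sum (exact p for small untied samples, otherwise normal
   approximation with continuity correction).
2. Otherwise Brown–Forsythe — the median-centered Levene variant, the
   robust default when "Levene" is unqualified — on the pooled data:
   p ≥ 0.05 → Student's t, else Welch's t.

The gate level `alpha_pre = 0.05` is the conventional pre-test level and
is configurable, as is mean-centering for the Levene gate and the log2
transform (parametric tests run on log2 abundances by default;
the Wilcoxon branch is invariant to monotone transforms). No imputation
is applied on the glycopeptide side: missingness there mostly reflects
sporadic identification rather than a detection limit, and the adaptive
test runs on observed values only. Fold-changes are ratios of group
means of observed raw abundances with tumor in the numerator, so 1
separates under- from overexpression; group medians were considered and
rejected as the default because with 5–12 observations per group the
median discards too much of the abundance-weighted structure the metrics
rely on.

Degenerate inputs are resolved deterministically: a constant pooled
sample yields Student's t with statistic 0 and p = 1; a constant single
group passes the normality gate (nothing to reject) and is handled by the
t-test.

**Attribution.** The overlay classifies each significant glycopeptide by
comparing its fold-change with its protein's: same direction and a
protein change of at least 1.5-fold → expression-driven; protein within
[1/1.5, 1.5] or moving the opposite way → glycosylation-driven; protein
not quantified → unattributed. The 1.5-fold dead band is the smallest
change conventionally treated as biologically meaningful in label-free
proteomics and is configurable (`null_fold`).

## The proteomics pipeline

After dropping Reverse and Contaminant groups, a protein is kept when
quantified in at least 2/3 of the samples of either group
(`ceiling(2/3 × 12) = 8` at the study size). Remaining missing values are
treated as left-censored and imputed per sample: the observed log2
intensities are modeled as the upper `(1 − f)` quantiles of a normal
distribution (`f` the missing fraction), whose mean and SD come from a
least-squares fit of observed order statistics against the matching
standard-normal quantiles; missing cells are drawn from the fitted
distribution truncated above at its `q_cens = 0.01` quantile. Imputation
is per sample because the detection limit is a property of the run, not
of the protein. Drawing from the extreme left tail keeps imputed values
below essentially everything observed, which is conservative for
differential testing: imputed cells can support but not manufacture a
group difference. `q_cens` is configurable; values up to ~0.05 give less
extreme draws.

**Moderated t.** Pooled per-protein variances `s²` on `d = n₁ + n₂ − 2`
df are shrunk toward a prior `(d₀, s₀²)` estimated by closed-form moment
matching of `log s²` to a scaled log-F distribution: the excess spread of
`log s²` over `trigamma(d/2)` is inverted through the trigamma function
(Newton iteration) to give `d₀`, and the mean gives `s₀²`. Proteins with
`s² = 0` are offset to the smallest positive variance before fitting.
The posterior variance interpolates between `s²` and `s₀²`, and the
moderated t gains `d₀` degrees of freedom. Setting `d0 = 0` recovers the
ordinary pooled t exactly; `d0 = Inf` is complete shrinkage — both limits
are exposed as arguments and exercised in the tests, which also verify
numerical agreement of the full fit with limma's independent
implementation. The intensity data make the moderated-t path the right
empirical-Bayes tool here; count-based models would need counts that
label-free intensities do not provide.

The default significance threshold is q < 0.05 (configurable). The
literature this pipeline descends from quotes both a 1% and a 5% FDR for
the same analysis; 0.05 is taken as the operative value since the
reported discovery counts accompany it.

The design is unpaired two-group by default. Tumor and adjacent sections
from the same individuals would support a paired analysis, but the
pipeline deliberately mirrors the unpaired two-sample description of the
analysis it implements; pairing can be emulated by passing difference
matrices if needed.

**Preranked GSEA.** Genes are ranked by the moderated t-statistic
(descending; ties broken by gene id so results are independent of input
order and seed). For each set, the weighted Kolmogorov–Smirnov running
sum with exponent 1 on |t| gives the ES; sets smaller than 10 after
intersection with the universe, sets covering the whole universe, and
sets with empty intersection are skipped (the last with a warning).
Significance uses gene-label permutations — phenotype permutation is
impossible from a ranking alone — with NES = ES / mean |ES| of
sign-matched permutations and a sign-matched permutation p, BH-adjusted
across scored sets. With the default 1000 permutations the smallest
attainable p is ≈ 1/1001; increase `nperm` for finer resolution.

## The synthetic-data generator

The generator reproduces the statistical structure that the pipeline's
contracts depend on, with defaults matching the cohort the package is
designed around:

* 12 tumor + 12 adjacent samples;
* 365 glycoproteins with 1–3 glycosites and 1–4 glycoforms each (≈ 1600
  glycopeptides), compositions drawn from a curated ~40-entry pool
  spanning high-mannose through sialylated/fucosylated complex types;
* 68% of glycopeptides observed in a single sample (`singleton_inflation`),
  the rest with a Beta(1, 4) per-feature detection probability — the long
  low tail means only a minority survive the presence filter, as in real
  site-specific data;
* log-normal abundances (log2 baselines N(20, 2), residual SD 0.8 for
  glycopeptides; N(25, 2) baselines with inverse-chi-squared residual
  variances, scale 0.4 and 5 df, for proteins — so the variance prior the
  moderated t estimates actually exists);
* left-censored protein missingness below each sample's 15% quantile;
* 10% of glycopeptide records with sub-threshold MS1/MS2 scores;
* planted effects: protein log2 fold-changes of ±2 on 10% of proteins,
  and 4-fold glycopeptide effects split between glycosylation-driven
  (one glycoform shifts, protein flat) and expression-driven (all
  glycoforms of a protein shift with the protein).

Planted glycopeptides are given a high detection probability (0.85) so
they survive the presence filter — they model the reliably measured
features a study would actually report, and effect recovery is only
defined for features the cascade can see.

What the generator does **not** emulate: batch or run-order effects,
retention-time-dependent intensity drift, correlated missingness between
glycoforms of one protein, patient-level pairing, isotope/charge-state
artifacts, and the composition frequencies of any real glycan database.
Passing tests therefore demonstrate that the algorithms are correct under
the stated stochastic model, not that the biological conclusions of any
particular tissue study are reproduced.

## Numerical and testing notes

Tolerances: weighted-metric recomputations agree with naive loops to
1e-12; the d0 = 0 limit agrees with the classical t to 1e-9; ES values
agree with an independent implementation to 1e-10. The trigamma inversion
iterates Newton steps to a relative 1e-10 with safe asymptotic starts.
BH adjustment delegates to `stats::p.adjust` and is property-tested
against a direct step-up enumeration.

The test suite works at deliberately chosen scales: exhaustive
composition enumeration over the full ≤ 26-residue space for the parser
round trip; 10,000 Gaussian null replicates for the adaptive test's
type-I error (within three binomial SEs of 0.05); 2,000-protein null
matrices for p-value uniformity; 20 replicate synthetic studies for FDR
control; and one full study-scale end-to-end run (score filter through
attribution) per property.

## Known limitations

* Composition-only classification cannot resolve hybrid vs complex for
  unusual compositions, bisecting GlcNAc, or fucose placement; the rule
  table makes the convention explicit but cannot add information.
* The adaptive test's pre-test gating is a faithful implementation of a
  common field practice, but conditioning the test choice on the data
  slightly distorts the nominal level (the calibration test bounds the
  damage at the default settings).
* Glycopeptide fold-changes from observed-only values are biased upward
  for features near the detection limit in one group; the overlay's
  attribution is robust to this only insofar as the protein arm is
  complete after imputation.
* The GSEA permutation null is gene-label based; inter-gene correlation
  is not modeled, so q-values are anti-conservative in strongly
  correlated sets.
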