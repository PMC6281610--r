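---
title: "Cross-species master regulator discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species master regulator discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The problem

A master regulator (MR) is a transcriptional or chromatin regulator whose
regulon — its set of positively and negatively regulated targets — collectively
explains a phenotype's expression signature. `mrpipe` implements a
cross-species MR discovery pipeline: differential signatures from two-group
expression cohorts in mouse and human, regulon enrichment to infer each
regulator's differential activity in each species, Stouffer integration of the
two MR lists into a conserved candidate set, and clinical prioritization of
the candidates on a survival cohort. Because the real cohorts such an analysis
runs on are large external datasets, the package carries a first-class
synthetic-data generator with planted ground truth, so that every stage —
and the pipeline end to end — is testable at desk scale.

## Differential signatures

Genes are ranked by the two-sample unequal-variance (Welch) t-statistic
between phenotype groups, signed so that positive means up in the second
group. Groups need at least 5 samples (`min_n`), the smallest size at which
the statistic is usable for ranking. Ties in the ranking are broken
lexicographically by gene id (radix/C-locale order), so a signature is a total
order reproducible across platforms. Genes with zero pooled standard error
cannot carry a finite statistic and are dropped with a warning.

Per-patient signatures, needed for per-sample MR activity, z-score each gene
against the cohort: `z_ij = (x_ij - mean_i) / sd_i` with the (n-1) standard
deviation. The construction of per-sample signatures is a genuine design
choice (median/MAD scaling would also be defensible); the cohort z-score is
the simplest convention consistent with scoring a regulator by the expression
levels of its targets, and is what the package uses throughout.

Mouse signatures are translated to human gene space through a two-column
ortholog map. A human gene hit by several mouse genes inherits the score of
largest absolute value (the most informative ortholog); unmapped genes are
dropped, and both counts are logged.

## Regulon enrichment

The enrichment of a gene set in a ranked signature is the classic GSEA
running sum: walking the ranking, each query gene adds `|score|^w`
(normalized over the query's hits) and each non-query gene subtracts
`1/(N - |S|)`; the enrichment score (ES) is the value of largest magnitude,
first occurrence on ties. `w = 1` is the standard weighted statistic and the
default for signature-level GSEA; `w = 0` gives the unweighted
Kolmogorov-Smirnov form.

Significance uses **gene permutation**: null query sets of the same size are
drawn uniformly from the signature, NES is the permutation z-score
`(ES - mean_null)/sd_null`, and the two-sided p-value uses the add-one rule
`(1 + #{|ES_null| >= |ES_obs|}) / (n_perm + 1)`, so p is floored at
`1/(n_perm + 1)` and never reported as zero. Cross-species signature
comparison is two-tailed: the query signature's top-`top_n` (default 200) and
bottom-`top_n` genes are scored separately against the reference, on the
shared gene universe.

The leading edge is the set of query genes at or before (positive ES) or at
or after (negative ES) the running-sum extremum. Agreement between two
leading edges is reported as `|A ∩ B|` over the smaller set (the union is
available as an option — the choice of denominator is a convention, and the
smaller-set version is the more conservative of the two for nested sets),
with a chi-square test on the 2x2 membership table, continuity correction
off.

## MR activity (MARINa-style)

A regulator with positive targets overexpressed and/or negative targets
underexpressed is *active*; the converse pattern means *repressed*. The
package realizes this two-tailed definition by **mode adjustment**: the
signature scores of a regulon's negative targets are negated, the signature
is re-ranked, and the combined target set is scored by the running-sum
enrichment above. Activity is the permutation NES in that construction;
its sign is the activity direction.

The permutation null preserves the regulon's `(n_pos, n_neg)` split: each
draw picks random genes from the signature, negates a random `n_neg` of them,
and re-ranks, so the null captures the mechanical lift that mode adjustment
itself produces. Null distributions depend only on `(size, n_neg)` and are
cached per signature with sub-seeds derived from those numbers, which makes
results independent of the order in which regulons are scored. On tiny
universes the null can be enumerated exhaustively
(`n_perm = "exhaustive"`), which is how the implementation is validated
against a brute-force oracle.

**Weight exponent for regulons.** Regulon enrichment defaults to `w = 0`
(unweighted), unlike signature-level GSEA. Two reasons. First, regulon
membership — not the magnitude of each target's differential score — is the
evidence for a regulator's activity. Second, a structural one: with `w = 1`
the null ES of a 20-60 gene regulon in a ~2000-gene signature has standard
deviation around 0.28, and since ES is bounded by 1 the permutation z-score
cannot exceed roughly 3.5 no matter how strong the biology; downstream
conserved-MR filtering at `p < 1e-4` needs per-species NES sums above 5.5 and
would be unreachable. The unweighted statistic has a much tighter null and
restores a usable dynamic range. Both exponents remain configurable.

## Cross-species integration

Mouse regulator ids are translated through the ortholog map (largest-|NES|
row wins a collision), and each regulator common to both species is combined
with equal weights: `z_combined = (z_mouse + z_human)/sqrt(2)` with
`z_species` the signed NES, and `p_combined` the two-sided normal tail.
Whether to combine signed NES or signed `-log p` is not fixed by the
pipeline's definition; signed NES is used because the NES *is* the
permutation z-score here, making the Stouffer combination exact rather than a
transformation of a discretized p-value. A *conserved* MR passes
`p_combined < 1e-4`, has the same activity sign in both species
(configurable), and matches the requested direction (activated by default,
since activated MRs are candidates for therapeutic inhibition). No
multiple-testing correction is applied beyond these fixed thresholds — the
procedure screens at fixed cutoffs by design, and the null-calibration tests
check the false discovery behaviour directly. An optional membership filter
restricts the table to a user-supplied annotation list (e.g. epigenetic
regulators).

## Clinical prioritization

Per-patient activity is the regulators x samples matrix of NES values from
each patient's z-score signature. Three stages consume it:

- **Cox screen** — one univariate proportional-hazards fit per regulator
  with continuous activity as the covariate; Wald p reported; non-converged
  or constant-activity fits are flagged, never dropped silently.
- **Stratification** — Euclidean k-means (`k = 2`, best of `n_restarts`
  starts) over patients in the activity space of a candidate MR set; the
  cluster with larger mean activity is "high". The log-rank test compares
  the two arms, and the hazard ratio (high vs low, with 95% CI) comes from a
  proportional-hazards fit on the group indicator.
- **Empirical random-set null** — `n_iter` random MR sets of the same size
  are stratified identically and their log-rank p-values form the null;
  the empirical p is `(1 + #{p_null <= p_obs}) / (n_iter + 1)`, "reached or
  outperformed" being inclusive and add-one-corrected so zero is never
  reported. Degenerate iterations (single-cluster activity) score p = 1,
  conservatively, and are counted.

**Null pool.** By default random sets are drawn from the tested pool
*excluding* the candidate set. This is a deliberate choice: the synthetic
truth plants one latent per-patient activity shared by all planted
regulators, so any random set containing even one planted MR recovers the
same patient partition and ties the observed log-rank p exactly — a full-pool
"empirical p" then converges to the probability of sampling a planted MR
(about 0.14 at the default sizes) regardless of how strong the survival
signal is, which answers the wrong question. Excluding the candidates makes
the null the specificity question one actually wants: *could an equally sized
set of other regulators stratify this cohort as well?* The full-pool variant
remains available (`pool = "all"`).

## The synthetic study

One configuration object defines the whole study; a single integer seed
drives every stage through fixed sub-seeding, so any artifact regenerates
bit-identically in isolation. Defaults, and what they emulate:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | gene universe |
| `n_regulators` | 100 | regulons, 20-60 targets each |
| `frac_positive_targets` | 0.7 | activating fraction of each regulon |
| `n_planted` | 8 | truly active MRs |
| `activity_effect` (delta) | 1.0 | expression shift per unit mode |
| `noise_sd` | 1.0 | Gaussian noise SD |
| `n_per_group` | 8 | samples per phenotype group |
| `n_patients` | 200 | survival cohort size |
| `hazard_beta` | 0.8 | log-hazard per unit latent activity |
| `baseline_rate` | 0.02 | events per time unit at zero activity |
| `censor_time` | 120 | administrative censoring |
| `ortholog_drop_frac` / `dup_frac` | 0.05 / 0.02 | map drop-outs / one-to-many |

The two-group cohort adds `mode * delta` to every planted target in group 2
(summed over planting regulators). The survival cohort gives each patient a
latent activity `a_i ~ N(0,1)` shared by all planted regulators — emulating a
coordinated MR program — scales the planted expression footprint by `a_i`,
and draws event times from an exponential with rate
`baseline_rate * exp(hazard_beta * a_i)`, censored at `censor_time` (with the
defaults, roughly 85% of patients experience the event). The ortholog map
renames mouse ids to human ids with an exact `round(frac * n)` of drop-outs
and duplications. Expression is simulated additively on a normalized scale —
the pipeline consumes normalized values by design, and count-level simulation
(library sizes, overdispersion), batch effects and competing risks are out of
scope. Passing tests on this generator therefore demonstrates the
*statistical machinery* is correct and calibrated; it does not certify
performance on count-derived real data with correlated noise.

## Numerical choices

- Ranking ties: lexicographic gene id, radix order — deterministic across
  locales and platforms.
- Running-sum extremum ties: first occurrence in rank order.
- ES of an all-zero-score query under `w > 0` falls back to equal hit weights.
- Degenerate permutation nulls (zero variance) flag the affected regulon
  rather than crashing the table.
- All p-values from resampling carry the add-one correction; the floor is
  `1/(n_perm + 1)`.
- Sub-seeds derive from the global seed plus a stage tag via a fixed integer
  hash (kept below 2^31), and the RNG state of the caller is always restored.
- k-means stratification refuses an activity matrix in which all patients
  coincide; the high/low orientation follows the larger mean activity.

## Problem sizes used by the test suite

The enrichment and log-rank implementations are checked for exact equality
against brute-force oracles on all instances with up to 8 genes and up to 6
subjects respectively, and MARINa against exhaustive enumeration on a 10-gene
universe. Simulation-based properties run at the study's native scale
(2000 genes, 100 regulators, 1000 permutations, 5 seeds) for cross-species
recovery and its null calibration; survival recovery uses 20 seeds with the
per-sample activity null reduced to 50 permutations, and the nested
empirical-p calibration uses a scaled-down study (500 genes, 25 regulators,
80 patients, 200 null iterations, 50 repetitions) — calibration properties
are size-invariant, so the smaller study is chosen to keep the suite fast.

## Known limitations

- The per-sample signature construction (cohort z-score) is a convention;
  real analyses may prefer rank-based or variance-stabilized versions.
- Regulon edge weights are accepted and validated but not used by the default
  analysis; the weight exponent applies to signature scores.
- The MARINa variant implemented here is the mode-adjusted single-enrichment
  form; shadow and synergy analysis from the original MR literature is not
  implemented.
- Interactomes are inputs: the package does not reverse-engineer regulatory
  networks.
- Stouffer integration assumes the two species' NES values are independent
  z-scores under the null; shared orthologous structure makes this
  approximate in real data.
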