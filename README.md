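# mrpipe

Cross-species discovery of **master regulators (MRs)** — transcriptional and
chromatin regulators whose regulons (signed target sets) collectively explain
a disease-progression expression signature — with clinical prioritization of
the candidates on a survival cohort.

The package is aimed at computational biologists who have (i) two-group
expression cohorts in two species (e.g. a mouse model contrast and a human
tumor contrast), (ii) regulatory networks ("interactomes") for each species,
(iii) an ortholog map between them, and (iv) a clinical cohort with
follow-up. It also ships a synthetic-data generator with planted ground truth
that emulates exactly this study design, so the entire pipeline runs and is
validated without any external data.

## The method

1. **Signatures.** Genes are ranked by the Welch t-statistic between the two
   phenotypes (signed, positive = up in the second group); mouse signatures
   are humanized through the ortholog map.
2. **Regulon enrichment.** A regulator's differential activity is the
   enrichment of its regulon in the signature after *mode adjustment*
   (negative-target scores are negated and the signature re-ranked, so an
   active MR stacks all its targets on top). ES is the weighted
   Kolmogorov–Smirnov running-sum extremum; significance comes from gene
   permutations, with NES the permutation z-score
   (ES − mean_null)/sd_null and two-sided add-one p-values.
3. **Cross-species integration.** Per-regulator species z-scores (signed NES)
   are combined by Stouffer's method, z = (z_m + z_h)/√2; conserved MRs pass
   p < 10⁻⁴ with concordant direction (activated by default).
4. **Clinical prioritization.** Per-patient MR activity (NES of each
   regulon in each patient's cohort z-score signature) feeds a univariate Cox
   screen (Wald p), k-means two-group stratification, Kaplan–Meier/log-rank
   with a hazard ratio, and an empirical null built from 1000 random
   equally-sized MR sets: empirical p = (1 + #{p_null ≤ p_obs})/(n_iter + 1).

See the methods vignette (`vignettes/mr-discovery-methods.Rmd`) for the
statistical details, defaults, and design rationale.

## Worked example

```r
library(mrpipe)

# a full synthetic study: mouse + human cohorts sharing planted truth
cfg <- pipeline_config(synthetic_config(seed = 11),
                       n_perm_sample = 50, null_iterations = 200)
res <- run_pipeline(cfg, outdir = "results_demo")

nrow(res$selected)        # conserved MRs passing p < 1e-4, concordant, activated
#> [1] 8
sort(res$study$planted_human)  # the 8 planted regulators...
all(res$selected$regulator %in% res$study$planted_human)
#> [1] TRUE                # ...are exactly the ones recovered

res$km                    # stratification of the survival cohort
#> Two-group survival stratification (96 high / 104 low, 169 events)
#>   log-rank chi-square = 47.300, p = 6.09e-12
#>   hazard ratio (high vs low) = 2.948 [2.140, 4.063]
```

The printed numbers say: all 8 planted master regulators — and nothing else —
survive the conserved-MR filter, and stratifying the 200-patient survival
cohort by their inferred activity separates a high-activity arm with a ~3x
hazard of the clinical event (log-rank p ≈ 6×10⁻¹²).

Stage-level functions (`welch_t_signature()`, `marina_activity()`,
`stouffer_integrate()`, `cox_screen()`, `kmeans_stratify()`, `km_logrank()`,
`random_set_null()`, ...) are exported individually and read/write plain TSV,
so the pipeline also runs piecewise on user data. A thin command-line wrapper
lives at `inst/cli/mrpipe.R`.

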