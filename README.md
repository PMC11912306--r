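# zfetr

Analysis tools for the zebrafish embryo acute toxicity test (ZFET).

In a ZFET, zebrafish (*Danio rerio*) embryos are exposed to a chemical
dilution series starting at 0 or 24 hours post fertilization (hpf) and
scored under the microscope at fixed times (typically 48, 72, 96, 120 hpf)
for survival and morphological effects. The assay underlies the OECD TG 236
fish-embryo test and is widely used in ecotoxicology, teratogenicity
screening and read-across. Making such data comparable across experiments
requires a controlled effect vocabulary, explicit quality gates for the
control embryos, and a common dose–response and fingerprinting workflow —
which is what this package provides, for anyone analysing per-embryo ZFET
observation tables.

## What it does

* **Controlled vocabulary** — a 52-term tree of morphological effects
  (`zfet_vocabulary()`), each with the developmental window in which it can
  be observed, and category semantics: "coagulated" is the sole lethal
  endpoint, "normal" marks an unaffected embryo, "no embryo" and
  "miscellaneous" are uninformative, "beats per minute" and "hours post
  fertilization" are quantitative.
* **Data model and CSV dialect** — experiments / treatments / observations
  tables with one row per embryo × time × effect, strict referential and
  window validation, byte-stable round trips
  (`zfet_set()`, `read_zfet_experiments()`, `write_zfet_experiments()`).
* **Control quality gate** — experiments with fewer than 15 embryos or a
  single condition are pre-filtered; each remaining experiment's control
  group is tested one-sided against a binomial null
  X ~ Bin(n, p(normal) = 0.936): the experiment is dropped when
  P(X ≤ k) < 0.05 or when fewer than 9 control embryos are available
  (`qc_filter()`, `control_quality_test()`).
* **Dose–response modelling** — grouped binomial maximum likelihood for
  three two-parameter families on concentration c (µmol/L), slope b,
  location e:

  | family | p(c) |
  |---|---|
  | log-logistic LL2 | 1 / (1 + exp(b (ln c − ln e))) |
  | Weibull-1 W12    | exp(−exp(b (ln c − ln e))) |
  | Weibull-2 W22    | 1 − exp(−exp(b (ln c − ln e))) |

  The lowest-AIC family is selected and kept only if (i) its AIC beats a
  flat (slope-0) null, (ii) the EC50 is below the highest tested
  concentration and (iii) SE(EC50) < EC50. ECx/LCx values are closed-form
  inversions with delta-method standard errors
  (`fit_drm()`, `select_drm()`, `effective_concentration()`).
* **Sensitivity ratio** — SR = LC50 / EC50 per substance and exposure
  window; values well above 1 flag sublethal or teratogenic activity far
  below lethal concentrations (`sensitivity_ratios()`).
* **Phenotypic fingerprints** — per-substance effect-prevalence vectors
  among non-normal embryos exposed between the EC5 (cumulative fit) and
  the LC99 (lethal fit), filtered (≥30 embryos, ≥1% mean prevalence),
  clustered with Ward/Euclidean linkage and ranked by PCA contributions
  (`build_fingerprint()`, `cluster_fingerprints()`,
  `pca_effect_importance()`).
* **Effect propagation** — Pearson correlations between per-embryo effect
  indicators at 48 and 96 hpf in well-plate experiments, with two-sided
  t-test p-values and a p < 0.01 significance mask
  (`pair_embryo_observations()`, `effect_correlation_matrix()`).
* **Synthetic studies** — a seeded generator with four substance
  archetypes and full ground truth (true curves, effect profiles, planted
  effect transitions, degraded-control plants), so the entire pipeline is
  testable without any external data (`simulate_study()`).

## Worked example

```r
library(zfetr)

study <- simulate_study(study_config(n_substances = 4), seed = 1)
study$set
#> <zfet_set>
#>   experiments: 4
#>   treatments:  32
#>   observations: 823 rows, 380 embryos

res <- run_zfet_pipeline(study$set)
str(res$manifest$counts)
#> List of 9
#>  $ experiments_in        : int 4
#>  $ prefilter_survivors   : int 4
#>  $ qc_survivors          : int 4
#>  $ drm_designs_fitted    : int 8
#>  $ drm_valid_fits        : int 6
#>  $ sensitivity_ratios    : int 2
#>  $ fingerprint_candidates: int 3
#>  $ fingerprint_substances: int 3
#>  $ propagation_embryos   : int 336

dplyr::select(res$sensitivity_ratios, substance_name, lc50, ec50, sr)
#>           substance_name lc50 ec50    sr
#> 1 no_hatch_heartbeat_002 50.7 5.00 10.14
#> 2         behavioral_004 81.2 8.48  9.58

head(res$effect_importance, 4)
#>   effect              importance  rank
#> 1 coagulated               0.360     1
#> 2 no hatching              0.289     2
#> 3 yolk sac edema           0.231     3
#> 4 decreased heartbeat      0.212     4
```

All four simulated experiments pass the control gate; eight substance ×
endpoint designs are fitted, six pass the validity gates, and the two
archetypes planted with sublethal effects far below lethal concentrations
come out with sensitivity ratios near their true value of 10. The
"no_hatch_heartbeat_002" substance's cumulative EC50 (5.00 µmol/L) recovers
the planted location e = 5 exactly to three digits. `autoplot()` on a fit
or a propagation matrix and `plot_fingerprint_heatmap()` draw the standard
figures.

## Scope

The package analyses exported observation tables. Database backends, web
UIs, chemical-registry lookups, UMAP embeddings and mixture-effect
modelling are out of scope; mixture and environmental-sample experiments
are carried through with their metadata labels but not modelled.
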