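# metabosurv

Prognostic metabolic subtyping of cancer cohorts from untargeted LC-MS
plasma metabolomics.

Head-and-neck squamous cell carcinoma (HNSCC) risk stratification today
rests mainly on HPV status and smoking history. Circulating metabolites
offer a non-invasive complement: clustering patients by their
pre-treatment plasma metabolome can split a cohort into subtypes with
very different survival, even after adjusting for the established risk
factors. `metabosurv` packages that analysis as a tested, reusable R
pipeline for biostatisticians and translational researchers:

1. **Feature processing** (`preprocess_features()`): replicate-CV
   filtering (median CV ≥ 0.75 removed), triplicate median
   summarisation, empirical-Bayes batch correction on log2 intensities,
   missingness filtering (> 20% removed), k-NN imputation, per-metabolite
   Z-scoring *z = (log₂x − μ)/σ*, Level-1 library matching (10 ppm /
   30 s) and pooling of the HILIC⁺ and C18⁻ chromatography modes.
2. **Subtype discovery** (`cluster_subtypes()`): Ward.D/Euclidean
   hierarchical clustering over k = 2…6, model selection by majority
   vote of six validity metrics (BIC, AIC, silhouette, Dunn,
   Calinski–Harabasz, allocation entropy), plus K-means and
   random-forest-proximity sensitivity clusterings.
3. **Differential ranking** (`rank_metabolites()`): per-metabolite
   Wilcoxon rank-sum tests between subtypes, Benjamini–Hochberg
   adjustment, selection at adjusted p < 10⁻⁵.
4. **Pathway enrichment** (`enrich_all()`): for a pathway with *m* of
   the *N* analysed metabolites and *k* of the *T* selected ones, the
   Pearson χ² statistic (no continuity correction) on
   [[k, m−k], [T−k, N−m−T+k]], df = 1.
5. **Survival analysis** (`stratified_analysis()`): Kaplan–Meier +
   log-rank and a three-model Cox ladder (unadjusted → age/sex/HPV →
   fully adjusted, Efron ties) for overall and progression-free
   survival, stratified by smoking and HPV; proportional hazards
   checked with a subtype×time interaction; three-year mortality
   compared across HPV/subtype logistic models by ROC AUC.
6. **Synthetic cohorts** (`simulate_cohort()`): a calibrated generator
   (209 patients, 41%/59% latent subtype split, 186 metabolites in two
   modes, triplicates, batches, intensity-dependent missingness, and an
   exponential survival model with subtype hazard ratio 3 among
   ever-smokers and 1 among never-smokers) so the whole pipeline is
   testable without patient data.

## Worked example

```r
library(metabosurv)

# the enrichment arithmetic for a 6-member pathway with 4 hits among
# 38 selected of 186 analysed metabolites
enrichment_chisq(186, 38, 6, 4)
#> # A tibble: 1 × 6
#>    chi2    df p_value direction expected_hits low_count
#>   <dbl> <int>   <dbl> <chr>             <dbl> <lgl>
#> 1  8.15     1 0.00430 enriched           1.23 FALSE

# full pipeline on a synthetic cohort
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 1)))
res$clustering
#> <subtype_clustering: hierarchical, k = 2>
#>   A   B
#> 102 107

glance(res$survival)[, c("stratum", "n", "surv3_os_a", "surv3_os_b",
                         "logrank_p_os")]
#> # A tibble: 5 × 5
#>   stratum                       n surv3_os_a surv3_os_b logrank_p_os
#> 1 full                        194      0.687      0.929   0.00000184
#> 2 never_smoker                 76      0.853      0.952   0.0596
#> 3 ever_smoker                 118      0.596      0.911   0.0000183
#> 4 ever_smoker_hpv_related      59      0.581      0.964   0.0000520
#> 5 ever_smoker_hpv_unrelated    59      0.611      0.857   0.0382
```

The clustering finds two metabolic subtypes (102 "A", 107 "B"; subtype
A is the metabolically elevated cluster). Among ever-smokers the
three-year overall survival is 59.6% in subtype A versus 91.1% in
subtype B (log-rank p ≈ 2×10⁻⁵), while among never-smokers the subtypes
barely differ — the planted subtype-by-smoking interaction. The Cox
ladder for that stratum:

```r
hr <- tidy(res$survival)
hr[hr$stratum == "ever_smoker" & hr$outcome == "os" &
     grepl("subtype", hr$term) & hr$model == "adjusted", ]
#>   model    term        hr conf_low conf_high   p_value     n n_events
#> 1 adjusted subtypeA  4.02     2.07      7.79 0.0000375   118       49
```

i.e. subtype A carries about four times the mortality hazard of subtype
B among smokers after age/sex/HPV adjustment (the generator's true
hazard ratio is 3; single-cohort estimates scatter around it).

Plot helpers: `plot_cluster_metrics()`, `plot_km()`, `plot_roc()`,
`plot_enrichment()`. Synthetic cohorts round-trip to plain-text files
with `write_cohort()` / `read_feature_table()` / `read_clinical()`, and
`validate_inputs()` schema-checks a directory of inputs.

See `vignettes/methods.Rmd` for the models, parameter defaults and
design decisions, including exactly what the synthetic generator does
and does not emulate.

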