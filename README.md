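# pathconverge

Integrative proteomics pipeline for finding pathway signatures that change
**convergently** across multiple models of insulin resistance — and for
testing whether those pathways track clinical insulin-sensitivity
phenotypes in a human cohort.

The scientific setting: insulin resistance can be induced in adipocytes by
unrelated insults (chronic insulin, dexamethasone, TNF-α in culture; a
high-fat high-sucrose diet in vivo). A pathway altered in *all* models is a
candidate proximal driver rather than a model-specific artefact. Given
per-contrast protein log2-abundance matrices, a gene-set collection (GMT)
and a phenotype table, the pipeline runs:

1. group-wise missing-value filtering (removed only when ≥ 60 % missing in
   every group), KNN imputation (k = 5), and rank-stability reference
   normalisation of cohort intensities;
2. per-contrast empirical-Bayes **moderated t-tests**
   (s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), t on d₀ + d_g df), BH FDR, and
   DE calls at |FC| > 1.5 and 5 % FDR;
3. **direction analysis**: t → z by quantile matching, projection z·d of
   the per-condition z-vector onto a coherent-change direction, and
   up/down/mixed classification at ≥ 2 significant models;
4. per-contrast **mean-rank gene-set enrichment** on log2 fold changes
   (Wilcoxon rank-sum; exact by enumeration for tiny universes);
5. **Fisher integration**: X = −2Σln pᵢ ~ χ²_{2k} per arm, combined
   z = Φ⁻¹(1 − p_comb); pathways with z > 4 in *both* the cell and tissue
   arms are selected as convergent;
6. **cohort screen**: per-sample pathway scores (sums of relative ratios)
   correlated with phenotypes against the analytic threshold
   r\* = t\*/√(t\*² + n − 2) (0.423 at n = 22, α = 0.05), plus tertile
   stratification (top ⌈n/3⌉) with Mann-Whitney comparisons.

A seeded synthetic-study generator (`sim_config()`,
`simulate_proteome_panel()`, `simulate_clinical_cohort()`) plants
pathway-coherent effects and a pathway–phenotype correlation with known
ground truth, so every stage is testable end to end without external data.

## Worked example

```r
library(pathconverge)
res <- run_pipeline(pipeline_config(sim = sim_config(), seed = 1))
print(res)
#> PipelineResult
#>   CI: 2927 features, 12 DE
#>   Dex: 2931 features, 11 DE
#>   TNF: 2928 features, 6 DE
#>   HFHSD_5d: 2928 features, 14 DE
#>   HFHSD_14d: 2929 features, 10 DE
#>   convergent pathways: planted_pathway

head(res$convergence$table, 3)
#>          set_name   z_cell z_tissue    min_z selected
#> 1 planted_pathway 8.200000 8.200000 8.200000     TRUE
#> 2         set_044 1.394083 2.040241 1.394083    FALSE
#> 3         set_153 1.220181 1.250337 1.220181    FALSE

subset(res$cohort_screen, target == "planted_pathway")
#>            target                trait  n           r critical_r significant
#> 1 planted_pathway NEFA_suppression_pct 22  0.48848073  0.4227135        TRUE
#> 2 planted_pathway            age_years 22 -0.04934810  0.4227135       FALSE
#> 3 planted_pathway            BMI_kg_m2 22  0.01641845  0.4227135       FALSE
```

Reading: each of the five condition contrasts retains ~2930 of 3000
proteins after the missingness filter; the planted 20-member pathway
saturates the combined-z clamp (8.2) in both arms and is the only set
selected at z > 4, while the best null set reaches ~1.4. In the 22-subject
cohort its pathway score correlates with the planted
insulin-sensitivity-like trait (r = 0.49, above the 0.423 threshold) and
with neither null trait.

Per-stage functions (`filter_group_missing()`, `knn_impute()`,
`moderated_t_test()`, `t_to_z()`, `direction_analysis()`,
`mean_rank_test()`, `fisher_combine_z()`, `convergence_select()`,
`correlation_screen()`, `tertile_stratify()`, `mann_whitney()`, ...) are
exported individually; `write_fixture_set()` round-trips a study through
TSV/GMT/JSON for use outside R. See the vignette
(`vignettes/convergence-pipeline.Rmd`) for the models, assumptions and
design choices.

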