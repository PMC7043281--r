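# nafldsubtypes

Electronic-medical-record (EMR) phenotyping and unsupervised subtype
discovery for non-alcoholic fatty liver disease (NAFLD), as a tested,
reusable R pipeline.

NAFLD affects roughly a quarter of the adult population and spans a wide
clinical spectrum — from incidental steatosis to cirrhosis,
hepatocellular carcinoma, cardiovascular and kidney disease. This
package is for biostatisticians and clinical informaticians who want to
(1) define a NAFLD cohort from raw multi-table EMR extracts with a
rule-based electronic phenotype, (2) cluster the cohort into data-driven
subtypes, and (3) quantify how the subtypes differ in comorbidity
profiles and time-to-event outcomes under competing risks. Since
hospital EMR data cannot ship with a package, a synthetic EMR generator
with a planted latent subtype structure stands in for real extracts and
gives every stage a ground truth to be tested against.

## The method

* **Electronic phenotype.** A patient is NAFLD-eligible iff
  (persistent ambulatory ALT elevation — two results ≥ 40 IU/mL for men
  or ≥ 31 IU/mL for women, more than 183 days apart — **or** a chronic
  non-alcoholic liver disease code: ICD-9 571.5/571.8/571.9, ICD-10
  K75.81/K76.0/K76.9) **and** no exclusion (viral hepatitis, alcoholic
  or other chronic liver disease codes, positive HBsAg / detectable
  HCV RNA, steatogenic medications) **and** a *positive* steatosis
  mention in imaging, pathology or notes (keyword scan with NegEx-style
  negation and family-history filtering). The NAFLD diagnosis date is
  the earliest day all criteria hold, restricted to 2013-01-01 …
  2019-01-31.
* **Features.** Binary matrix: age bins, sex, race (Hispanic ethnicity
  precedence), phecode-mapped diagnoses and ingredient-mapped persistent
  medications (0.1% prevalence floor), CPT range groups, abnormal labs
  (qualitative terms or values strictly outside the reference range),
  five abnormal-vital flags.
* **Clustering.** Manhattan distance d(i,j) = Σ|x_i − x_j| and
  Ward-criterion agglomeration in the ward.D2 convention
  (Lance–Williams on squared dissimilarities, heights as square roots),
  with deterministic smallest-index tie-breaking; cut at k = 5 subtypes
  labeled by decreasing size.
* **Profiling.** Each subtype vs the rest: Pearson chi-squared (binary),
  ANOVA / Wilcoxon (continuous), Benjamini–Hochberg FDR, significance at
  q < 0.001.
* **Survival.** Death, cirrhosis, HCC, CKD, CVD, MI from the diagnosis
  date; cases within 183 days are prevalent and excluded; Kaplan–Meier
  and Cox (Efron ties) for death; Aalen–Johansen cumulative incidence
  and Fine–Gray subdistribution hazards with death as the competing
  event for the rest; covariates subtype, age, gender, race, FIB-4
  category.
* **Validation.** 10 × 90% subsample reclustering with adjusted-Rand
  agreement and enriched-feature Jaccard overlap after optimal cluster
  matching.

See `vignettes/nafld-subtyping-methods.Rmd` for assumptions, parameter
defaults, numerical conventions and limitations.

## Worked example

```r
library(nafldsubtypes)

sim <- generate_cohort(cohort_config(1000, seed = 42))
dec <- classify_cohort(sim$bundle)
dec
#> NAFLD phenotype decisions: 1000 patients, 739 eligible (73.9%)
#> Failed rules among ineligible patients:
#> steatosis_evidence      liver_disease       not_excluded
#>                146                104                 38

fm <- build_feature_matrix(sim$bundle, dec)
fm
#> <feature_matrix> 739 patients x 68 binary features
#> demographic   diagnosis         lab  medication   procedure       vital
#>          16          21           6          15           5           5

cl <- cluster_subtypes(fm, k = 5)
summary(cl)
#> Ward-criterion clustering (Manhattan distance), k = 5
#>   subtype   n share
#> 1       1 303 0.410
#> 2       2 207 0.280
#> 3       3 161 0.218
#> 4       4  44 0.060
#> 5       5  24 0.032

tte  <- build_outcome_table(sim$bundle, dec)
covs <- build_covariates(sim$bundle, dec, cl$assignment)
fit_outcome_models(tte, covs, outcomes = "death")$death
#> Cox proportional hazards model (flagged: possible non-convergence or separation; 11 events / 739 subjects)
#>      term       HR      95% CI       p
#>  subtype2 7.41e-01 0.0672-8.18 8.1e-01
#>  subtype3 9.39e-01 0.0852-10.4 9.6e-01
#>  subtype4 2.74e+01    5.69-132 3.7e-05
#>  subtype5 1.73e-07       0-Inf 1.0e+00
```

Reading the output: a quarter of the simulated patients fail the
phenotype (no positive steatosis evidence, no qualifying ALT/code
pattern, or an exclusion) — the failed-rule table says why. The five
subtypes are size-ordered, so subtype 1 is the reference group in the
hazard models. Here clustering isolated the generator's small
high-mortality subtype in cluster 4: its death hazard ratio versus
subtype 1 is 27 (95% CI 5.7–132). The `subtype5` row shows a
sparse-data artifact worth recognizing — a small cluster with zero
observed deaths yields an essentially zero HR with an unbounded CI; the
fit carries a separation flag and the diagnostic message in its `notes`
attribute.

The same stages run as one orchestrated pipeline with per-stage
manifests and deterministic stage seeds:

```r
run_nafld_pipeline(pipeline_config(n_patients = 500, master_seed = 1),
                   out_dir = "artifacts")
```

or from a shell via the thin CLI,
`Rscript inst/cli/nafld-pipeline.R run-all --n 500 --seed 1 --out artifacts`.

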