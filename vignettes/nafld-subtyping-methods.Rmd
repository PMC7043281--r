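---
title: "Methods: EMR phenotyping and subtype discovery for NAFLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMR phenotyping and subtype discovery for NAFLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, rules and numerical choices behind
`nafldsubtypes`: a pipeline that defines a non-alcoholic fatty liver
disease (NAFLD) cohort from multi-table electronic medical record (EMR)
extracts, converts the cohort into a binary clinical feature matrix,
discovers patient subtypes by hierarchical clustering, and characterizes
the subtypes with descriptive statistics and competing-risk survival
models. Because hospital EMR databases cannot be redistributed, the
package also ships a synthetic EMR generator with a planted latent
subtype structure; every stage is tested against that generator's hidden
truth.

## The electronic phenotype

A patient enters the NAFLD cohort when all of the following hold:

1. **Liver-disease signal** — either *persistent ALT elevation*
   (two or more ambulatory alanine-aminotransferase results at
   $\geq 40$ IU/mL for men or $\geq 31$ IU/mL for women, strictly more
   than 183 days apart) or a chronic non-specific / non-alcoholic liver
   disease diagnosis code (ICD-9 571.5, 571.8, 571.9; ICD-10 K75.81,
   K76.0, K76.9). The OR combination is the default; an AND variant is a
   configuration switch (`require_both`).
2. **No exclusion** — no viral hepatitis, alcoholic liver disease or
   other chronic liver disease code at any time in the record; no
   positive HBV surface antigen or detectable HCV RNA; no steatogenic
   medication order. The shipped exclusion code and medication lists are
   small synthetic stand-ins for the full published vocabularies and are
   plain CSV files meant to be replaced by site-specific lists.
3. **Steatosis evidence** — at least one *positive* mention of a
   steatosis term in an imaging report, pathology report or clinical
   note.

The *NAFLD diagnosis date* is the earliest day on which all criteria
hold simultaneously, i.e. the latest of the per-criterion
earliest-satisfaction dates. "More than 6 months apart" is implemented
as strictly greater than 183 days, a deterministic and conservative
day-arithmetic reading. The date must fall after 2012-12-31 and on or
before 2019-01-31. Exclusions are evaluated over the entire record
because the clinical intent is to remove competing etiologies wherever
they are documented.

## Keyword search with negation and family filtering

Free-text evidence (steatosis, cirrhosis, death mentions, MELD scores)
is found by a lexicon scan rather than a learned model. Every
case-insensitive, word-bounded occurrence of a synonym is classified:

* **negated** if a negation cue (*no, not, absence of, without,
  negative for, denies, denied, free of, ruled out*) occurs within six
  tokens before the term, inside the same sentence;
* **family_or_false_positive** if a kinship cue (*mother, father,
  siblings, family history, ...*) occurs in the same sentence;
* **positive** otherwise.

Sentence boundaries are periods and newlines. The six-token window and
the cue inventories are implementation choices in the NegEx tradition —
the underlying publications typically show only examples — and both are
configurable. MELD severity scores are *extracted* (first integer in
6–40 following the token "MELD"), never computed from labs, because the
scores in scope were documented in text.

The synthetic note generator emits at least three surface templates per
mention kind, constructed so that a correct scanner classifies them
unambiguously; the polarity-recovery test therefore measures template
alignment between generator and scanner, not clinical NLP accuracy. Real
clinical notes (abbreviations, hedging, section headers, copy-forward)
are far harder; passing these tests shows the rule set is internally
consistent, not that it would reach 99% on hospital text.

## Binary featurization

All features are binary, mirroring common practice for
unsupervised EMR mining:

* **Demographics** — ten mutually exclusive age bins at the diagnosis
  date (18–20, 21–30, ..., 91–100, 101+), sex, and race indicators with
  Hispanic ethnicity taking precedence over the recorded race category.
* **Diagnoses** — ICD-9/10 codes mapped to phecodes; a column is kept
  when at least 0.1% of the cohort carries it (column mean
  $\geq 0.001$, no rounding).
* **Procedures** — CPT codes mapped to second-level numeric range
  groups (e.g. 33010–37799 = cardiovascular surgery).
* **Medications** — drug names mapped to ingredient concepts; an
  ingredient counts only with two or more orders separated by at least
  183 days, discarding acutely used drugs; the 0.1% floor applies.
* **Labs** — one column per test, set when a qualitative result matches
  an abnormal term (*abnormal, low, below average, reactive, ...*) or a
  numeric value falls strictly outside the reference range. A value
  exactly on a bound counts as normal ("outside the range" read
  strictly). Abnormally low and high values share one column by design;
  the shipped reference ranges are a synthetic stand-in table.
* **Vitals** — five fixed flags: temperature > 39 °C (or > 102 °F,
  applied in the recorded unit), SBP > 130 *or* DBP > 80, heart rate
  > 130, respiratory rate > 40, pain score 9–10. One abnormal
  measurement suffices (the repeated-measurement alternative was
  considered and rejected as unstated in the source rules).

The shipped ICD-to-phecode, CPT-group and drug-ingredient tables are
deliberately tiny, synthetic, and user-replaceable CSVs: reproducing the
full PheWAS/CPT/RxNorm vocabularies is out of scope, and the featurizer
is agnostic to the size of the mapping files.

## Clustering

Patient dissimilarity is the Manhattan distance, which on binary data is
the Hamming count of discordant features. Agglomeration uses the Ward
criterion in its "D2" convention: the Lance–Williams recurrence

$$d^2(k, i \cup j) = \frac{(n_i+n_k)\,d^2(k,i) + (n_j+n_k)\,d^2(k,j)
  - n_k\, d^2(i,j)}{n_i+n_j+n_k}$$

applied to *squared* input dissimilarities, with merge heights reported
as square roots. Ward on a non-Euclidean metric is mathematically
heterodox — the variance interpretation only holds for Euclidean input —
but it reproduces the analysis choice this package follows rather than
correcting it.

The linkage is implemented in the package (not delegated) so that ties
are resolved reproducibly: among minimal-cost pairs the one with the
smallest (left, right) cluster-id pair merges first, where a cluster's
id is the smallest member index. Binary Manhattan distances are integers
and tie constantly, so an unspecified tie order would make merge trees
platform- and order-dependent. A consequence worth knowing: under heavy
ties the merge order necessarily depends on row order, so permutation
equivariance of the final partition is only guaranteed where merges are
unambiguous (the separated regime the method is intended to find).
The implementation is verified, merge-by-merge to $10^{-9}$, against a
naive $O(n^3)$ re-scanning implementation, and against the standard
ward.D2 reference on tie-free data.

The default cut is $k = 5$ subtypes, labeled 1..k in decreasing size
order so that subtype 1 is always the largest and serves as the
reference group in regression. $k$ is a configuration choice, not
estimated from data.

## Subtype profiling

Each subtype is compared against all remaining patients: binary features
with the Pearson chi-squared test (no continuity correction), continuous
summaries with the classical one-way F test or the Wilcoxon rank-sum
test (normal approximation with tie correction). Multiplicity is
controlled with the Benjamini–Hochberg step-up procedure across all
tests in the run; a feature is significant at $q < 0.001$. BH was chosen
because "false discovery rate" without a named procedure conventionally
means BH. Constant features are excluded from testing and logged.

## Survival analysis

Outcomes are death, cirrhosis (note mentions), hepatocellular carcinoma
(ICD-9 155.0/155.2, ICD-10 C22.0/C22.7–C22.9), chronic kidney disease
(ICD-9 585–586, ICD-10 N18–N19, dialysis CPT 90935–90999),
cardiovascular disease (ICD-9 410–414, ICD-10 I20–I25) and acute MI
(ICD-9 410, ICD-10 I21–I22). Time runs from the NAFLD diagnosis date to
the earliest evidence of the outcome. For non-death outcomes, evidence
up to 183 days after diagnosis (inclusive) marks the case *prevalent*
and removes it from model fitting; death is the competing event
(code 2); otherwise the row is administratively censored at 2019-01-31
(last-contact censoring is a configuration option left off by default).

Estimators: Kaplan–Meier for overall survival; the Aalen–Johansen
cumulative incidence function for competing outcomes; Cox proportional
hazards with Efron tie handling (Breslow by option) for death; Fine–Gray
subdistribution-hazard regression for non-death outcomes. Confidence
intervals are normal-theory on the log-hazard scale
($\exp(\hat\beta \pm 1.96\,\mathrm{SE})$), matching the conventional
reporting format. The covariates are subtype (reference = subtype 1),
age, gender, race with Hispanic precedence, and FIB-4 category. FIB-4 is
$\mathrm{age}\times\mathrm{AST} / (\mathrm{platelets}\times\sqrt{\mathrm{ALT}})$
with cut-offs $<1.3$ low, $1.3$–$2.67$ indeterminate, $>2.67$ high —
the formula and boundaries come from the standard fibrosis-index
literature because the source rules use the category without defining
it; both are configurable and any missing input yields `missing`.

## Stability validation

Cluster robustness follows a subsampling protocol: draw 90% of patients
without replacement, rerun distances, linkage, the k-cut and the
profiling, and compare to the full-cohort run; repeat 10 times. Two
quantitative surrogates summarize agreement, since the protocol's
published form is qualitative: the adjusted Rand index on the shared
patients, and the Jaccard overlap of each subtype's significant-feature
set after maximum-overlap (optimal assignment) cluster matching.
Matching is exhaustive over permutations, which is exact and cheap for
small $k$.

## The synthetic cohort generator

Each patient draws a latent subtype from the mixing proportions; the
subtype determines Bernoulli prevalences for ~40 clinical concepts
(diagnoses, medications, abnormal labs, vitals, procedures), the
steatosis-note mention profile, demographics, and constant outcome
hazards. Event times are exponential draws administratively censored at
the window end — the simplest model with closed forms for oracle checks
(the observed-event fraction over horizon $h$ at hazard $\lambda$ is
$1-e^{-\lambda h}$). Observed outcomes are written back into the record
as the same artifacts the real pipeline would see: diagnosis codes,
dialysis procedure codes, cirrhosis notes, a death date and a death
note. Dates are generated at day resolution since every rule in the
pipeline is day-computable.

The default five-subtype structure is motivated by the published
cohort's shape: two large lower-risk subtypes holding most patients, a
metabolic/inflammatory subtype, a fibrosis-dominant subtype, and a small
severe multimorbid subtype whose death hazard is two orders of magnitude
above the reference — 0.25 versus 0.002 events per person-year. Where
the literature gives no quantitative value (per-concept prevalences,
hazards for the middle subtypes), values were chosen once to be
clinically plausible and are not tuned. The generator makes no claim of
matching any real cohort's correlation structure: concepts are drawn
independently given the subtype, visit patterns are schematic, and note
language is templated. Tests passing on this generator therefore
establish the pipeline's internal correctness and its ability to recover
structure *when present*, not clinical validity on hospital data.

## Problem sizes and numerical choices

* Oracle-equivalence checks for the linkage run at $n \le 12$ over 50
  random binary datasets (exact merge order, heights to $10^{-9}$).
* Planted-subtype recovery and the stability protocol run at
  $n = 1000$ with five equal subtypes whose prevalence patterns differ
  pairwise on at least 20 concepts (gap 0.9); recovery is required at
  adjusted Rand $\ge 0.9$, and an all-identical-subtype cohort must stay
  below $|ARI| < 0.05$.
* Estimator recovery uses 20 replicates: two-arm exponential data with
  true hazard ratio 2.0 at $n = 2000$ (mean Cox HR within
  [1.85, 2.15]), and the Fine–Gray latent construction
  $F_1(t;x) = 1-(1-p(1-e^{-t}))^{\exp(\beta x)}$ with $p = 0.3$,
  subdistribution HR 1.5 at $n = 3000$ (mean within [1.35, 1.65]).
* The end-to-end demo runs at 500 patients and is byte-identical under
  a fixed master seed; each randomized stage derives its seed
  deterministically from the master seed and the stage name.

## Known limitations

* The negation/family scoper is windowed and lexical; it will misread
  scope-breaking constructions ("no doubt this is steatosis").
* The shipped vocabularies are synthetic miniatures; production use
  requires site mapping files.
* Ward-on-Manhattan has no variance interpretation; it is reproduced as
  the reference analysis choice.
* Under heavily tied distances the merge order (not the typical
  partition) depends on input order.
* The Fine–Gray variance is the sandwich form reported by the fitting
  backend and differs at the percent level from the Cox inverse
  information in the no-competing-events limit.
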