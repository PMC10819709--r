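---
title: "Methods: log-ratio Random-Forest modelling and proximity fusion of VOC profiles"
author: "vocfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: log-ratio Random-Forest modelling and proximity fusion of VOC profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analytical problem

Primary sclerosing cholangitis (PSC) is a progressive bile-duct disease that
develops in a small fraction of inflammatory bowel disease (IBD) patients and
typically stays subclinical until irreversible damage has occurred. Because
gut microbial dysbiosis is believed to participate in its etiology, volatile
organic compounds (VOCs) measured in the headspace above fecal samples — and,
systemically, in exhaled breath — are candidate non-invasive markers for
discriminating PSC (with or without concurrent IBD) from IBD alone.

Headspace GC-MS tables come with three structural nuisances that shape every
stage of this package:

1. **Background contamination.** Some measured compounds originate from the
   sampling device or the instrument, not the feces. Microchamber blanks
   (sampling runs with no sample) calibrate a retention rule.
2. **Size (dilution) effects.** The total amount of captured volatiles
   varies strongly per sample (water content, purge conditions), multiplying
   whole rows of the table. Standard normalisation was not workable for
   these profiles, so the analysis runs on *pairwise log ratios*, which
   cancel any per-sample multiplicative factor exactly.
3. **Duplicates and class imbalance.** Most patients contribute two fecal
   aliquots; a quarter of the cohort is PSC-class. Every resampling step
   therefore operates on patients, never on samples, and subsamples the two
   classes at different rates (83% / 73%).

# Pipeline stages

## Blank retention rule

A feature is kept iff

```
median(biological) > median(mc blanks) + 3 * IQR(mc blanks)
```

with a *strict* inequality, order statistics over observed values only
(missing entries excluded), and quantiles computed with R's default linear
interpolation (type 7) — the convention is recorded in the result object so
tests can pin it. Instrument blanks and QC samples take no part in the rule;
QC samples only monitor instrument performance. A feature missing in every
biological sample is dropped with reason `"all-missing"`. The unsupervised
Random-Forest screen (`unsupervisedRFScreen`) contrasts the real rows with a
column-wise permuted copy (Breiman's synthetic-contrast construction),
embeds the resulting proximities by principal coordinates, and reports the
blank-side silhouette. Biological profiles are internally heterogeneous by
construction, so the mean silhouette over *all* samples is small even with
perfect blank separation; the blank-side mean is the statistic that says
"blanks sit apart from samples", and is the one returned.

## Missing values and log ratios

Missing entries are treated as censoring at the detection limit: each is
redrawn uniformly from `[0.5 m_f, m_f]`, `m_f` the feature's minimum
observed positive value. Because the imputation is random, every procedure
that consumes imputed data is iterated, with one derived sub-seed per
iteration. Log ratios are formed for all unordered pairs in canonical
orientation (numerator index < denominator index); the square
importance-frequency matrix is filled symmetrically at (i, j) and (j, i),
since tree splits are invariant to the sign of `log(a/b)` and the
numerator/denominator arrangement is a presentation device.

## Shadow-feature stability selection

Per iteration: subsample patients class-wise (83% PSC-class, 73% IBD,
duplicates kept as pairs and only one duplicate per patient entering the
importance model), re-impute, expand ratios, append one shadow column per
ratio, fit a Random Forest, and record which columns reach at least 40% of
that iteration's maximum permutation importance (raw mean decrease in
accuracy; "equal to 40%" is read as ">= 40%", since exact equality of a
continuous importance has probability zero). Ratio frequencies not
*strictly* exceeding the maximum shadow frequency are zeroed.

Two design choices deserve emphasis:

* **Shadow permutations are drawn once, at the patient level, and held
  fixed across iterations.** The shadow threshold is a null for selection
  *stability*. A truly uninformative real ratio still carries a fixed,
  cohort-level chance association with the labels, which persists from
  iteration to iteration; a shadow column re-permuted every iteration loses
  its association each time and its selection frequency stays near zero, so
  persistent chance associations would pass the threshold. With one fixed
  permutation per shadow column, each shadow carries a persistent pseudo-
  association of exactly the same kind, and the maximum over all shadow
  columns is an extreme-value threshold for them. Patient-level (rather
  than sample-level) permutation keeps a shadow's pseudo-association stable
  when a different duplicate of a patient is chosen.
* **Feature-set optimisation.** Compounds are ranked by the column sums of
  the thresholded matrix; for each k the surviving ratios *among* the top-k
  compounds form a candidate model, evaluated by duplicate-safe
  internal-validation AUC; the smallest k attaining the maximum mean AUC is
  selected. When no surviving ratio lies fully inside a candidate set
  (degenerate matrices), the ratios connected to the set are used instead.

The final model refits over iterations with both duplicates of each
training patient included, averages each sample's held-out probability,
computes the out-of-bag proximity matrix (co-terminal-leaf frequency over
trees where both samples are out of bag) from an all-data forest, and
embeds `1 - proximity` by principal coordinates, truncating negative
eigenvalues to zero. Operating points are Youden-optimal on the averaged
probabilities: the study reports single sensitivity/specificity pairs
without naming a threshold rule, and the Youden maximum is the standard
choice.

## Proximity stacking

Platform fusion happens at patient grain (breath has one sample per
patient; fecal duplicates are collapsed by averaging their proximity rows
and columns). The fused matrix `w P_fecal + (1 - w) P_breath` is embedded
by principal coordinates, coordinates explaining at least 90% of the
positive eigenvalue mass are retained, and a Random Forest on the
coordinates is evaluated by internal validation; `w` is grid-searched
(default 0 to 1 in steps of 0.05) with paired seeds across the grid, and
exact ties break toward `w = 0.5`.

How the averaged proximities become a final classifier is genuinely open;
embedding-then-forest was chosen because the principal-coordinate plot is
the pipeline's own visualisation device, making it the most faithful
bridge. One behavioural consequence is documented rather than hidden: a
forest is scale-invariant per coordinate, so wherever the informative axes
remain represented in the embedding the internal-validation AUC is nearly
flat in `w` (measured: a plateau within ~0.02 for `w` in [0.3, 1] when one
platform is pure noise, against ~0.45 at `w = 0`). The optimiser therefore
reliably avoids a degenerate platform, but the exact optimum inside the
plateau is decided by validation noise, and with two informative platforms
the chosen weight should be read as "both platforms contribute", not as a
precise mixing proportion.

## Iterated cross-platform correlation

Fecal log ratios (the selected set) and breath compounds are related by
canonical correlation analysis (CCA) on the first variate, iterated over
imputations. Each iteration runs recursive feature elimination — dropping
the feature with the smallest absolute structure loading from whichever
side still has more than two features — until the permutation p-value of
the first canonical correlation reaches 0.05. The same procedure runs on
row-permuted data; features selected significantly more often in the real
runs (chi-square on the 2x2 selected-by-real/permuted table, Yates
correction) are screened in. Final correlations (canonical and univariate
Pearson) are averaged over iterations on the Fisher-z scale; univariate
p-values are Benjamini-Hochberg adjusted within the screened matrix.
Significance of the canonical variate uses permutation rather than Wilks
asymptotics throughout, which stays valid at this cohort's sample size;
rank-deficient inputs (including collinear columns silently dropped by the
QR path) fall back to a ridge-regularised CCA with a warning. Blood-marker
association restricts to the PSC-class population — only there are ALP,
AST, ALT and bilirubin expected to vary meaningfully — and drops constant
blood columns before analysis.

One statistical subtlety: within a single cohort the per-iteration
canonical p-values share the observed data and differ only through
imputation noise, so they are *not* independent draws. "The fraction of
significant iterations matches the nominal level under the null" is a
statement across independent cohorts, and that is how the test suite
measures it (one iteration each over 200 simulated null cohorts).

# The synthetic cohort generator

No public data accompany the study cohort, so the generator is first-class,
tested code that emulates the design: 8 PSC, 16 PSC/IBD and 49 IBD
patients; fecal duplicates at rate 0.92 (67 of 73 patients measured twice);
the 62-compound targeted fecal panel and 20-compound breath panel (packaged
names are used when the feature counts match); group mean fecal water
contents 74.02 / 80.33 / 73.79 percent. Intensities are log-normal;
duplicates share the patient's biological signal and differ only by
measurement noise and dilution; missingness is censoring-like, biased
toward low intensities; blanks sit ~4 natural-log units below the samples
except for a `blank_leak` fraction of features drawn slightly above the
sample level (excluded from the planted markers) so the retention rule
removes exactly those; blood markers are log-linear in the latent breath
marker signal, hence elevated in the positive class and correlated with the
designated breath compounds at `blood_link_strength` (default 0.9,
mirroring the strong breath-blood and weaker feces-blood associations).

Values the study does not state are conventions chosen once: biological
patient-level noise 0.5 and measurement noise 0.25 (log scale), dilution
scale 1.0, missing rate 10%, 8 microchamber and 4 instrument blanks, leak
fraction 10%, water-content spread 5 percentage points. The planted class
effect defaults to 0.8 log units — a moderate effect for which the
selection's AUC-versus-k curve is informative: at much larger effects
internal-validation AUC saturates at 1.0 for a single marker and the
smallest-k tie-break truncates the selected set, while at 0.8 the optimiser
grows the set until it covers the planted markers (measured over repeated
cohorts: 5-6 of 6 markers recovered with held-out AUC 0.97-0.99).

What the generator does *not* emulate: chromatographic peak shapes,
retention-time drift, co-elution, batch effects over time, and the 48-62 h
physiological offset between fecal and breath sampling. Passing tests
demonstrate the pipeline's statistical machinery under the modelled
mechanisms, not performance on real chromatograms.

# Problem sizes used by the tests and the acceptance script

The study-scale procedure (62 compounds, 1891 ratios, 500 stability
iterations, 5000 correlation iterations) is the package default, but the
test suite and `scripts/acceptance.R` run reduced configurations chosen as
the package's own desk-scale study conditions: panels of 10-20 compounds,
40-60 stability iterations, 20-50 model iterations, 40 correlation
iterations with 99 permutations per test, over the full 73-patient design
(or a 24-patient reduction for unit tests). The methods are unchanged;
only the iteration and panel sizes shrink.

# Known limitations

* **Null calibration of the shadow threshold at desk scale.** With no
  planted effect, the fraction of cohorts in which *no* ratio survives the
  shadow threshold is about 0.75-0.85 at the reduced problem sizes, rising
  with iteration count (0.70 at 20 iterations to 0.80 at 60, panel sizes 20
  and 62). The residual survivors are real ratios whose persistent chance
  association happens to exceed the extreme of all shadow persistences — an
  inflation that shrinks as the stability frequencies sharpen toward the
  study-scale 500 iterations. A survivor under the null is almost always a
  handful of ratios with frequencies barely above the shadow maximum, so
  downstream optimisation still returns a small, low-scoring set.
* **Fusion weight identifiability**, as discussed above: the grid optimum
  within the high plateau is noise-driven.
* **Canonical correlations at small n.** With ~10-25 patients per
  population and several features per side, the first canonical correlation
  is strongly inflated (its null value is far from zero); the permutation
  p-value, not the magnitude of r, carries the inference.
* The severity covariate is consumed as a precomputed score; the package
  does not compute it from blood chemistry.
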