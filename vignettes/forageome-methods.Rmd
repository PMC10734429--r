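---
title: "Methods: foraging phenotype and gut-microbiome dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foraging phenotype and gut-microbiome dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forageome)
```

## The problem

Capital-breeding geese finance migration and reproduction from fat laid
down during a short spring staging window. At the staging site individual
birds differ consistently in where they feed — intertidal *marine*
vegetation, managed *terrestrial* grass, or *switching* between the two —
and this foraging phenotype may be coupled to the structure and stability
of the gut microbiome and, through digestion efficiency, to the rate of
body-mass gain. `forageome` implements the full analysis chain for such a
study: from an ASV count table, taxonomy, sample metadata and resighting
records to phenotype assignment, diversity and composition contrasts,
shared-taxa structure, within-individual stability, and body-condition
trajectory models.

## Phenotype assignment

Birds observed at least five times are classified from their resighting
record (the faecal-collection observation counts as one sighting): both
habitats seen at least once → *switcher*, otherwise a specialist on the
single habitat used. Whether "observed five times" means observation days
or observation events is genuinely ambiguous in field protocols; we count
**day-level** sightings — duplicate same-day, same-habitat records are
collapsed — which makes the classifier invariant to record order and to a
paired-observer protocol recording the same visit twice. `prop_marine`,
the fraction of a bird's sightings on marine habitat, is strictly interior
to (0,1) for switchers and exactly 0 or 1 for specialists.

## Filtering

Three steps, in order:

1. **Taxonomy pruning.** Any ASV whose rank strings match
   `{chloroplast, mitochondria, archaea}` case-insensitively is removed.
2. **Contaminant identification.** For each ASV a 2×2 presence table
   (negative controls vs true samples) is tested — chi-square without
   continuity correction, or Fisher's exact test when any expected cell is
   below 5. The p-value serves as the contaminant score: control-enriched
   ASVs score low. An ASV is flagged when its score falls below the
   threshold (default 0.5) *and* its control prevalence exceeds its sample
   prevalence; the orientation rule prevents sample-enriched taxa from
   being discarded. With no negative controls the stage must be skipped
   explicitly — it never guesses.
3. **Depth filtering.** Samples with *fewer than* `min_reads` (default
   5,000) total reads are dropped; a sample with exactly the threshold is
   retained.

## Alpha diversity

Richness is standardized by classical hypergeometric rarefaction,
interpolated to a common depth equal to `min_reads`:

$$E[S_m] = \sum_i \left(1 - \binom{n - n_i}{m}\Big/\binom{n}{m}\right),$$

computed via log-gamma; extrapolation beyond a sample's depth is refused.
Good–Turing coverage
$\hat C = 1 - (f_1/n)\,[(n-1)f_1 / ((n-1)f_1 + 2 f_2)]$ accompanies every
sample so users can verify the depth threshold sits on the coverage
plateau. The common depth is a package choice: the threshold already
defines the analysis-ready sample set, so it is the natural interpolation
point.

Group contrasts must not be driven by unequal group sizes, so group means
are bootstrapped **balanced to the minimum group size** (in birds): per
iteration, each phenotype contributes that many birds and one random
sample per bird. Within an iteration birds are drawn *without* replacement
(a subsample of the group), with fresh randomness across the 1,000
iterations; this is the more conservative reading where the sampling
design is ambiguous, and it is documented as an interpretation. Group
inference on log-richness uses the same random-intercept engine as the
body-condition model (a deliberate substitution of a profile-likelihood
fit for a Bayesian regression; the contrast structure is identical and the
engine is shared, tested code).

## Beta diversity

Counts are mapped to real space by the centred log-ratio transform with an
additive pseudocount of 1 (exposed in `run_config()`); ASVs absent from
every sample are removed first, and every CLR row sums to zero by
construction. Euclidean distance on CLR coordinates (Aitchison distance)
feeds three procedures:

* **PCA** of the centred CLR matrix. PC1's sign is fixed so that the mean
  score of terrestrial-collected samples is negative; this is purely a
  reproducibility convention so that downstream slopes (e.g. per-bird mean
  PC1 against `prop_marine`) have a stable sign.
* **PERMANOVA.** Anderson's partition of the squared distances gives
  pseudo-F; significance comes from label permutation with
  $p = (b+1)/(m+1)$, which can never be exactly zero at finite
  permutations. Permutation is free by default — matching the standard
  treatment of repeat samples as exchangeable — and a `strata` argument
  permits bird-blocked permutation for the longitudinal design, a choice
  we expose because repeat samples of one bird are not truly exchangeable.
  Pairwise contrasts rerun the same machinery per pair with Bonferroni
  adjustment.
* **Dispersion.** Each sample's distance to its group centroid is computed
  in the principal-coordinate embedding of the distance matrix with the
  usual negative-eigenvalue correction (squared distances in the imaginary
  subspace subtract; for CLR-Euclidean input the negative part is
  numerically zero). The omnibus one-way F on these distances gets a
  permutation p; pairwise differences are reported with Tukey HSD
  intervals *and* Bonferroni-adjusted pairwise t-tests, because combining
  "Tukey's post-hoc test with a Bonferroni correction" is ambiguous about
  which error-rate control applies — emitting both lets the reader pick.
  The centroid (not the spatial median) is used, matching the reporting of
  "distance to centroid".

## Shared and unique taxa

Core taxa require presence at ≥ 1e-5 relative abundance in ≥ 70% of
samples. The printed threshold "0.001% relative abundance" is read
literally as the fraction 1e-5, not 0.001 — the ambiguity changes the core
set, so the choice is flagged prominently here and both thresholds are
plain arguments.

The shared/unique partition bootstraps the uneven design away: per
iteration each phenotype contributes the minimum group size of birds drawn
**with replacement** (this routine is the one explicitly described as a
bootstrap), one random sample per bird; pooled presence then classifies
every ASV present that iteration into one of the seven Venn cells
(M, S, T, MS, MT, TS, MTS), and cell counts become percentages of the
ASVs present, which sum to 100 within each iteration. One randomly flagged
iteration is exported as a phenotype–ASV bipartite network (TSV edge list
and GraphML) with phylum and subset attributes.

Pair-level sharing uses the Jaccard index on presence sets (two empty sets
are defined as similarity 1; with a depth filter upstream this is a
documented edge convention, not a data case). Sample pairs are grouped
into *same phenotype* (marine–marine / terrestrial–terrestrial),
*switcher–specialist*, and *different specialists* (marine–terrestrial);
switcher–switcher pairs and within-individual pairs are excluded. Each of
the three category contrasts gets a Welch t statistic and a permutation
p-value. The permutation unit is the **bird**: phenotype labels are
shuffled over birds, all of a bird's samples move together, and pair
categories are re-derived each time. Permuting pairs directly would break
the dependence between pairs that share a sample and inflate the type-I
error; sample-level permutation is available behind a flag for
comparison. Permutations that empty a category are redrawn. Two-sided
tests are the default since directionality is not specified a priori.

Indicator analysis follows Dufrêne–Legendre: specificity
$A_{ij}$ = mean relative abundance of ASV *i* in group *j* divided by the
sum of those means over groups, fidelity $B_{ij}$ = occurrence frequency
in group *j*, IndVal = A·B, reported on the 0–1 scale (with a percentage
convenience column) for the best group, with bird-blocked permutation
p-values.

## Within-individual stability

For every bird with at least two retained samples, each sample's Euclidean
distance to the bird's CLR centroid measures within-individual turnover.
These distances are strictly positive, so a Gaussian random-intercept
model on them is an approximation; the family of the original group test
is not specified beyond "GLMM", and we choose Gaussian with the identity
link for interpretability of the pairwise contrasts (differences in mean
distance), with the choice logged. The omnibus Wald F for phenotype gets a
bird-blocked permutation p-value by refitting under shuffled bird labels.

## Body-condition (API) model

API is treated as Gaussian despite being an ordinal 1–7 index — matching
standard practice for this response; an ordinal extension is out of scope.
Day of year is z-standardized on the analysis subset (sample SD, n−1), and
the transform is stored so predictions are emitted on raw day of year. The
global model is

$$\mathrm{API} \sim \mathrm{phenotype} + \mathrm{sex} + z\mathrm{day} +
z\mathrm{day}^2 + \mathrm{phenotype}{\times}z\mathrm{day} + (1\,|\,\mathrm{bird}).$$

The engine fits Gaussian random-intercept models by profiling the
likelihood over $\lambda = \sigma^2_u/\sigma^2_e$: for fixed λ the GLS
solution is closed-form via per-group sums (Woodbury structure), and λ is
optimized by a bounded scalar search on the log scale with the λ = 0
boundary always evaluated, so the zero-variance case is exact. ML is used
for model selection and likelihood-ratio tests; REML is available for
reporting variance components. Wald SEs come from the GLS information.
The test suite verifies the engine against lme4 to ~1e-5 in log-likelihood,
coefficients and SEs, and against closed-form ANOVA estimators on balanced
designs.

Model selection dredges all subsets of the global fixed terms that respect
marginality (the quadratic requires its main effect, the interaction its
components — 16 candidates for the global model above), ranks by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with **k counting fixed
effects plus two variance parameters** (the convention under which
published AICc tables for mixed models are built — rankings depend on it,
hence the explicit statement), retains models within six AICc units of the
best, and then applies the nesting rule: a retained model whose terms are
a strict superset of a retained model with lower AICc is removed.
Per-phenotype day slopes and their SEs are linear contrasts of the global
fit.

## The synthetic-data generator

`simulate_study()` is first-class, tested code, not a fixture. It emulates:

* ~92 phenotyped birds (phenotype probabilities 0.15/0.31/0.54 for
  marine/switcher/terrestrial), 1–4 faecal samples per bird with
  P(1..4) = (0.35, 0.37, 0.16, 0.12), whose mean is exactly 2.05;
* a May staging window (days 121–151) with ≥ 5 resightings per bird;
* Dirichlet-multinomial counts. Marine and terrestrial base compositions
  share a 45-ASV core and own unique pools; the marine pool is large (320
  ASVs) with a steep abundance distribution, creating the rare marine tail
  that drives both the higher marine richness and the large marine-unique
  share — rare taxa detected once necessarily land in a single group's
  Venn cell. Per-phenotype Dirichlet precision (30/28/70) controls
  dispersion: terrestrial highest precision, hence tightest communities.
* switcher samples mix the two specialist bases with a weight tracking the
  bird's recent habitat record (`switcher_mix_lag = 0.15`: the community
  mostly reflects the diet on the collection day), plus a small
  switcher-own pool — yielding intermediate mean composition and high
  within-individual turnover;
* read depths drawn log-normally (median 15,000) with 18% of samples
  forced below the 5,000-read threshold, mirroring the attrition the
  analysis must tolerate;
* 8 negative controls carrying 8 planted contaminants at 0.9 prevalence
  (0.15 in true samples) plus sparse, abundance-proportional carry-over of
  real ASVs — giving the prevalence classifier a detectable but imperfect
  signal at the 0.5 threshold;
* API generated from the random-intercept linear model with a
  phenotype × day interaction (terrestrial slope largest, switcher
  smallest; female offset +0.45), rounded and clamped onto the 1–7 scale.

The field study reports no effect sizes for compositional differences, so
the generator's defaults are calibrated once for comfortable power at this
design's scale (~190 samples) and then frozen; they are arbitrary in that
specific sense and documented as such. What the generator does **not**
emulate: taxonomic structure beyond placeholder ranks, chimeras or
sequence-level artefacts, flock-size behavioural dynamics, seasonal
turnover of the base compositions, and any phylogenetic signal. Passing
recovery tests on these studies therefore demonstrates that the pipeline
detects the planted population-level patterns at realistic sample sizes —
not that real faecal microbiomes satisfy the Dirichlet-multinomial model.

## Numerical choices and conventions

* Pseudocount 1 before CLR (simplest reproducible convention; exposed).
* Permutation p-values are always $(b+1)/(m+1)$, never zero.
* PC1 sign anchored on terrestrial-collected samples.
* Jaccard of two empty sets = 1.
* λ = 0 boundary always evaluated in the LMM profile; ties at the boundary
  resolve to OLS exactly.
* LRT statistics are clamped at 0 against numerical noise in nested
  optimizations.
* Stage-level seed streams derive from `(random_seed, stage_name)` via a
  32-bit FNV-1a hash, so single-stage reruns reproduce their slice of a
  full run; the default run seed is 17072020, following the convention of
  fixing one seed for the whole analysis.

## Problem sizes used in the test suite

The statistical acceptance tests run at desk scale, chosen so the suite
completes in minutes while keeping binomial acceptance bands meaningful:
exact-enumeration PERMANOVA checks on 50 eight-sample instances; 500 null
replicates (199 permutations each) for the type-I-error calibration of
PERMANOVA, dispersion, the bird-blocked Jaccard tests and the interaction
LRT, judged against the exact binomial 99% band around 0.05; 200
replicates of 100-bird studies for parameter recovery and CI calibration;
and 100 default synthetic studies (100 bootstrap iterations each) for
pattern recovery. The pipeline itself defaults to 999 permutations and
1,000 bootstrap iterations.

## Known limitations

* Distances to centroids are analysed with a Gaussian model although they
  are non-negative; a log-transform option is provided.
* The API model ignores the ordinal, bounded nature of the index.
* PERMANOVA's default free permutation treats repeat samples of one bird
  as exchangeable; use `strata` for the stricter bird-blocked test.
* Rarefaction interpolates only; samples cannot be compared above their
  own depth.
* No phylogenetic diversity measures (no tree input) and no
  differential-abundance testing — both outside this pipeline's scope.
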