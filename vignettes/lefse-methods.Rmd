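---
title: "Biomarker discovery by LDA effect size: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker discovery by LDA effect size: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lefse)
```

## The problem

Comparative metagenomics asks which features of a community profile --
taxa, clades, pathways, gene families -- differentiate two or more
biological conditions. Feature tables are high-dimensional (hundreds to
thousands of features over tens of samples), compositional (per-sample
relative abundances), and rarely close to normal: abundances are skewed,
zero-inflated and often multi-modal across hosts. A biomarker that is
worth following up experimentally should satisfy three requirements at
once:

1. **statistical significance** -- its distribution differs between the
   classes;
2. **biological consistency** -- the difference holds in every known
   within-class grouping (subclass), not just in one stratum that happens
   to dominate the class;
3. **effect relevance** -- the difference is large enough to plausibly
   matter, and candidates can be ranked by that magnitude.

This package implements the linear discriminant analysis effect size
(LEfSe) approach, which addresses the three requirements with three
successive steps, plus the standard visualizations (ranked score barplot,
taxonomic cladogram, per-feature abundance histograms) and a synthetic
benchmark quantifying type I and type II error.

## The three steps

Let $x_{ij}$ be the abundance of feature $i$ in sample $j$, each sample
carrying a class label, optionally a subclass label (defaulting to the
class) and a subject label (defaulting to the sample id). Unless disabled,
each sample column is first rescaled to sum to a fixed total (default 1,
i.e. relative abundances).

**Step 1 -- class-level screen.** Each feature is tested across classes
with the Kruskal-Wallis rank-sum test (midranks, tie correction,
chi-square approximation on $k-1$ degrees of freedom). Features with
$p \ge \alpha_{\text{class}}$ (default 0.05) are not analyzed further.
Non-parametric tests are used deliberately: their only distributional
assumption is identically shaped distributions up to median shifts, which
multi-modal abundance profiles usually satisfy while violating normality.

**Step 2 -- subclass consistency gate.** For each surviving feature and
each pair of classes, every subclass of one class is compared with every
subclass of the other using the unpaired two-sided Wilcoxon rank-sum test
(so two classes with three subclasses each yield nine comparisons). The
feature passes only if *every* comparison rejects at
$\alpha_{\text{subclass}}$ (default 0.05) *and* all median differences
share one non-zero sign. Because all comparisons are required to reject,
no multiple-testing correction is needed -- requiring unanimity is more,
not less, stringent than any correction. Two variants modify the gate:

* *pairing mode*: for stratified designs in which the same stratum is
  observed inside every class (e.g. pre/post treatment within disease
  subtypes), `pairing_mode = "same_name"` compares only identically named
  subclasses across classes instead of all pairs;
* *small subclasses*: rank tests have essentially no power below a handful
  of samples, so when either subclass in a comparison has fewer than
  `min_subclass_size` samples (default 10) the Wilcoxon test is replaced
  by a sign comparison of the two subclass medians, which must agree with
  the common direction.

With more than two classes, the `strict` strategy demands the gate pass
for *every* unordered class pair, while `nonstrict` accepts a feature if
at least one class passes against all others; strict detections are by
construction a subset of nonstrict ones.

**Step 3 -- effect size.** Features passing both gates enter a linear
discriminant model with the class as the dependent variable and the
candidate features plus integer-coded subclass and subject covariates as
independent variables. For a class pair, the per-feature effect averages
two components on the abundance scale: the raw absolute difference of
class means, and the feature's contribution to the separation of class
means along the unit-normalized first discriminant axis (its loading times
the projected mean difference). The average equally weights a feature's
marginal difference and its discriminatory power in the joint model. The
procedure is stabilized by bootstrapping: 30 iterations, each drawing
two-thirds of the samples with replacement (stratified by class), with the
per-pair effects averaged over iterations and each feature taking the
maximum over the class pairs that passed its gate. The reported score is
$\log_{10}$ of the effect mapped into $[1, 10^6]$; features with score at
least `lda_threshold` (default 2.0) are reported, ranked by score.

## Parameters that matter

| parameter | default | units / range | why this default |
|---|---|---|---|
| `alpha_class`, `alpha_subclass` | 0.05 | level of each test | conventional screening level; lower both (e.g. 0.01) for small designs or to prioritize follow-up |
| `lda_threshold` | 2.0 | orders of magnitude | on relative abundances, score 2 corresponds to an effect of $10^{-4}$; below that, differences are rarely biologically actionable |
| `multiclass_strategy` | strict | strict / nonstrict | strict biomarkers separate *all* classes and are the safer claim |
| `pairing_mode` | all_pairs | all_pairs / same_name | all-pairs is correct when subclasses are covariates; same-name when they are strata observed in every class |
| `min_subclass_size` | 10 | samples | below 10 the exact Wilcoxon cannot reach conventional significance levels reliably, so the median-sign fallback is more honest |
| `n_boot`, `boot_fraction` | 30, 2/3 | iterations, fraction | enough averaging to stabilize the discriminant on small designs at modest cost |
| `coeff_influence_orders` | 3 | orders of magnitude | caps the axis component at $10^3$ times the raw difference so near-singular discriminants cannot dominate |
| `rng_seed` | 1 | integer | all stochastic steps (bootstrap, singularity jitter) flow from it; fixed seeds give bit-identical outputs |

## Numerical choices

* **Kruskal-Wallis p-values** use the chi-square approximation with tie
  correction; the exact permutation distribution appears only as a test
  oracle. At the design sizes this package targets (tens of samples per
  class) the approximation is standard; a feature constant across all
  samples is assigned $p = 1$ directly.
* **Wilcoxon p-values** use the exact distribution when both groups have
  at most 25 observations and the data are tie-free, otherwise the normal
  approximation with continuity and tie correction.
* **Direction** is the sign of the difference of group medians; a zero
  median difference counts as inconsistent (the gate requires a non-zero
  common sign).
* **Enriched class** is the class with the highest within-class mean;
  ties break towards the lexicographically smallest class label.
* **Singular discriminants** are routine when nested clades are retained
  together (a parent's column can be nearly collinear with its children).
  The fit is retried after adding a zero-mean perturbation of relative
  magnitude $10^{-10}$ of each column's standard deviation, drawn from the
  run's seeded generator; an iteration whose fit still fails is skipped
  with a warning.
* **Score mapping**: effects are multiplied by $10^6/\text{total}$ and
  floored at 1 before taking $\log_{10}$, so relative-abundance effects
  map to scores in $[0, 6]$ and the ranking is a monotone transform of the
  effect. A consistent difference of 0.1 in relative abundance scores
  about 5.
* **Degenerate LDA covariates**: when no subclass row is supplied the
  subclass equals the class and would enter the model as a copy of the
  response, trivializing the discriminant; it is dropped. A subject label
  that is distinct for every sample (the default) is likewise dropped.
* **All-zero sample columns** are kept (normalization leaves them at zero,
  with a warning surfaced in the run report) rather than silently removed,
  since removal would change the class cardinalities used by every test.

## Design decisions where the procedure was genuinely open

* *Stratification in step 1.* The class-level screen is the plain
  class-factor Kruskal-Wallis test by default. An aligned-rank variant
  (`stratified_kw = TRUE`: values replaced by within-stratum ranks rescaled
  to a common range before pooling) is available for designs whose strata
  cut across classes, where stratum-level offsets would otherwise mask the
  class signal. It is not the default because with subclasses nested
  inside classes each stratum contains a single class and alignment
  destroys, rather than sharpens, the between-class information; the
  subclass structure is instead enforced entirely by step 2.
* *Subclass nesting vs same-name pairing.* Under all-pairs semantics a
  subclass name occurring in two classes is a design error; under
  same-name pairing that repetition is exactly the expected structure (the
  same stratum observed in each class), and comparisons select samples by
  class and subclass jointly.
* *Mean-then-max.* Per-pair effects are averaged over bootstrap
  iterations first, and each feature then takes the maximum over its
  passing class pairs; each component of the effect uses the bootstrap
  draw (not the full data) for its class means.
* *Benjamini-Hochberg on the class screen* is exposed (`kw_fdr = TRUE`)
  but off by default: the published gate design explicitly relies on
  unanimity in step 2 rather than multiplicity correction in step 1.
* *No command beyond the gates for detection.* In the synthetic benchmark
  the LDA step is excluded from detection (it ranks, it does not test), so
  detector comparisons isolate the screening behavior.

## The synthetic benchmark

The generator reproduces the three Gaussian collections used to
characterize detector error. Every dataset has 1,000 features by 100
samples, two classes of 50, each split into two subclasses of 25; half the
features are positive (true biomarkers), half negative. With
$\mu = 10{,}000$:

* **(a)** negatives are $N(\mu, 100)$ everywhere; positives put their two
  class means at $\mu \mp t$ with $t \in \{1, 10, 25, 50, 75, 100, 125,
  150\}$ (subclass structure meaningless);
* **(b)** as (a) with $t = 1000$ and
  $\sigma \in \{1000, 2500, 5000, 7500, 10000\}$;
* **(c)** positives as in (b); negatives are made *inconsistent*: the
  inner two subclasses (one per class) share mean $\mu$ while the outer
  two sit at $\mu \mp 1000$ -- a clear class-level shift that no
  consistent biomarker should show.

False positive and negative rates use the total feature count (1,000) as
denominator, so both lie in $[0, 0.5]$. Negative Gaussian draws are kept
as-is (no truncation, which would distort the null), the tables are
analyzed unnormalized because the features are independent, and with
subclasses of 25 the median-sign fallback is inactive. Ten replicate
datasets per grid point are generated from seeds derived from one master
seed; the acceptance script (`scripts/acceptance.R`) re-runs the full grid
-- 80 datasets for the class-level screen alone and 180 for the two-gate
detector -- in a few minutes on one CPU.

Two regularities are worth knowing when reading benchmark output. On
collections (a) and (b) the class-level screen alone rejects about 5% of
the 500 nulls regardless of $t$ or $\sigma$, i.e. an FPR near 2.5%, while
the two-gate detector stays well below 0.5%; the price is a higher false
negative rate near the detection boundary. On collection (c) the
class-level screen is misled by construction (FPR approaching 50% at low
noise) while the consistency gate rejects the discordant subclasses; the
two-gate FPR exceeds 0.5% only at the lowest noise levels, where the
single null subclass pair is occasionally significant by chance together
with the three truly shifted pairs.

## The demonstration dataset

`synthetic_colitis_table()` (frozen copy:
`inst/extdata/mouse_colitis_synthetic.tsv`) is a synthetic stand-in
emulating the design of a murine ulcerative-colitis 16S comparison: 20
case and 10 control samples, 53 clade-path rows from domain to genus, and
exactly 19 truly differential clades whose directions follow that model
system's biology (Bifidobacteriaceae and *Bifidobacterium* depleted in
cases; Lachnospiraceae and Ruminococcaceae enriched, with *Roseburia* and
*Papillibacter* as depleted member genera; Staphylococcaceae and
Porphyromonadaceae control-enriched). Genus abundances are log-normal with
class-specific means; ancestors are sums of their descendant genera, so
the hierarchy is internally consistent and differential genera propagate
upward exactly as designed. Effect sizes were chosen well above the
detection boundary so that, at $\alpha = 0.01$ and score threshold 2.0,
the pipeline recovers the 19 designed clades stably across bootstrap
seeds.

What passing on this stand-in shows -- and what it does not: it
demonstrates that the pipeline recovers a known ground truth of realistic
shape and scale through the full file-to-report path. It does not
reproduce any real study's numbers: real 16S data add compositional
coupling beyond what sums-of-genera model, sequencing noise, rare-taxon
tails, and between-subject variability that no log-normal toy captures.
The same caveat applies to the Gaussian benchmark: independent normal
features match the assumptions of the rank tests exactly and are
deliberately favorable territory for *all* detectors compared.

## Known limitations

* Subject labels enter only as an LDA covariate; the rank tests treat
  samples as exchangeable, so repeated measures of one subject are not
  modeled (no signed-rank or mixed-model path).
* The consistency gate is binary; a feature failing one of many subclass
  comparisons by a hair is discarded, which is the intended stringency but
  makes borderline calls sensitive to `alpha_subclass`.
* Compositionality is handled only through normalization; strongly
  coupled features (one dominant clade depressing all others) can shift
  nulls systematically, as in any relative-abundance analysis.
* The cladogram layout is a plain radial embedding of the taxonomy with
  unit edges; it does not attempt the published figures' label packing.
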