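---
title: "Quantifying microglial contamination in Patch-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial contamination in Patch-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchglia)
```

## The problem

Patch-seq records a neuron's intrinsic electrophysiology and then harvests
its mRNA through the patch pipette. In acute brain slices the pipette also
collects transcripts from the processes of surrounding cells — microglia in
particular — so a "neuronal" transcriptome is in fact a mixture of the
neuron and its local microenvironment. `patchglia` treats this contamination
as a measurable quantity: it scores it per cell, characterizes its
transcriptional signature, asks which experimental factors explain it, and
estimates how it covaries with the recorded electrophysiology.

## The contamination score

For a Patch-seq cell $c$ of neuron type $N$ and contaminant type $M$
(microglia), with $P_{c_N,M}$ the summed log2 CPM of the $M$ off-marker
panel in cell $c$:

$$\mathrm{CS}_{N,M} = \frac{P_{c_N,M} - d_{N,M}}{d_{M,M} - d_{N,M}}$$

where $d_{N,M}$ is the median of the same sum over dissociated reference
cells of type $N$ (the floor: marker expression a clean cell of that type
shows) and $d_{M,M}$ the median over dissociated microglia (the ceiling).
A negative numerator means no detected contamination and is clipped to 0;
values above the ceiling are clipped to 1, so a score of 1 reads "this cell
expresses microglial markers at the level of dissociated microglia". The
per-type medians always come from the reference, never from the Patch-seq
cells themselves. The even-$n$ median is the midpoint of the central order
statistics. Clipping above at 1 makes the $[0,1]$ invariant testable; it is
a convention of this implementation.

Key parameters and their defaults:

* `pseudocount = 1` on the CPM scale, so zero counts map to exactly 0 on
  the log2 scale — the convention of the reference atlases this score is
  normally used with.
* off-marker panel size `n = 50`, the standard size of the microglial
  off-marker set.
* Marker derivation (`select_markers`): specificity of gene $g$ for type
  $t$ is its mean log2 CPM in $t$ minus the maximum mean over all other
  types; the top $n$ strictly positive scores win, ties broken by gene id.
  Published panels can be supplied as JSON instead; the selection recipe
  here is deliberately simple, deterministic and testable against the
  simulator's designed markers.
* Gene filtering happens before normalization: flagged genes
  (mitochondrial, uncertain function) never enter the CPM totals.

## Signatures of contamination

Cells are ranked by score and split at the empirical 25th/75th percentiles
("quartile" scheme) or 10th/90th ("decile", for datasets where highly
contaminated cells are rarer); ties at a boundary go to the extreme group.
Differential expression between high and low groups uses the two-sided
Wilcoxon rank-sum test — exact by enumeration when both groups have at most
10 cells, tie-corrected normal approximation otherwise — with the fold
change computed on de-logged means,
$\log_2\{(\overline{2^x - pc}_{high} + pc) / (\overline{2^x - pc}_{low} + pc)\}$.
A gene passes at $|\mathrm{log2FC}| > 2.5$ and $p < 0.01$ (unadjusted, as in
the thresholds this mirrors; a BH-adjusted column is included for
reference). Three signatures follow by set algebra: the Patch-seq
contamination signature (up in high-contamination cells), the general
microglia signature (up in dissociated microglia vs pooled reference
neurons, same machinery), and the Patch-seq distinct signature (the first
minus the second) — the component of contamination absent from dissociated
microglia, i.e. the activated-program candidate set. Enrichment of any
signature in user-supplied gene sets (GMT) uses the exact upper-tail
hypergeometric test with the measured, filtered genes as universe (not
genome-wide; collection sets are intersected with the universe before their
sizes are computed) and Benjamini–Hochberg FDRs across the collection.

The clustering check (`cluster_contamination_association`) asks whether
unsupervised structure tracks contamination: top-variance genes, per-gene
z-scaling, PCA (20 components), k-means ($k = 4$). Initial centers are
taken at evenly spaced order statistics of PC1 and component signs are
canonicalized by the dominant gene loading, so the procedure is
deterministic and equivariant under permutation of the cells — the reported
quantity is the one-way $R^2$ of score on cluster labels, not the embedding
itself.

## Variance partitioning

The full model is a Gaussian linear mixed model fit by REML (lme4):

```
score ~ sex + condition + scale(age) + scale(break_in_time) +
        scale(seal_resistance) + scale(soma_depth) + cell_type +
        iba1_bin + gfap_bin + (1 | donor_id)
```

Covariate preparation: break-in time is hours since the donor's first
recorded cell; histology scores are binned low ($\le 1$) / high ($> 1$);
t-type labels collapse to their first two tokens ("Sst Hspe Sema3c" becomes
"Sst Hspe"); types with fewer than 20 cells (10 for sparser designs) are
dropped; continuous covariates are z-scaled.

Marginal and conditional $R^2$ follow Nakagawa: with $\sigma^2_f$ the
variance of the fitted fixed-effect predictions, $\sigma^2_\alpha$ the
summed random-intercept variances and $\sigma^2_\varepsilon$ the residual,
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_\alpha + \sigma^2_\varepsilon)$
and $R^2_c = (\sigma^2_f + \sigma^2_\alpha) / (\sigma^2_f +
\sigma^2_\alpha + \sigma^2_\varepsilon)$. Each fixed factor's share is
$R^2_m(\text{full}) - R^2_m(\text{reduced})$ where the reduced model
replaces that factor with a random intercept; the donor share is
$R^2_c(\text{full}) - R^2_m(\text{full})$.

Two points were genuinely open and decided here:

* *Continuous covariates in reduced models.* "Replace the fixed effect
  with a random intercept" is ill-defined for a continuous covariate; we
  bin it into quintiles and fit a random intercept over the bins, which
  preserves the replace-not-drop scheme while remaining estimable. If a
  covariate has too few distinct values to bin, its share is reported
  missing with a reason.
* *Negative shares.* Differences of $R^2$ can be negative; they are
  clipped to 0 and flagged in the output rather than silently dropped.

REML is used throughout, including every reduced refit. Aliased columns
are dropped by the engine with a message rather than an error;
non-convergence flags the fit and downstream $R^2$ operations refuse
flagged fits.

## Electrophysiology associations

Features tagged `log10` (input resistance, rheobase, AP half-width are the
usual candidates) are log10-transformed, then every feature is z-scaled
with the sample SD ($n - 1$ denominator). The contamination score is
deliberately *not* standardized, keeping effect sizes comparable across
datasets with different score spreads. Each feature is modeled
independently as

```
feature ~ score + scale(soma_depth) + (1 | cell_type) + (1 | donor_id)
```

(the depth term is optional, for datasets without depth measurements). The
contamination coefficient is reported with its SE, a normal-approximation
95% CI ($\beta \pm 1.96\,\mathrm{SE}$) and a two-sided normal p value on
$\beta/\mathrm{SE}$ — a simpler convention than Satterthwaite-type degrees
of freedom; with hundreds of cells per fit the difference is negligible,
and the package's calibration study validates the coverage empirically. No
multiple-testing correction is applied across features, matching the raw
per-feature reporting convention. Univariate companions (Pearson with
t-based p, Kruskal–Wallis across groups, rank-sum for binary bins) come in
one tidy table from `univariate_associations`.

## The synthetic-data generator

The underlying study is observational and states no generative model, so
every distributional choice below is a stand-in, chosen once to carry the
statistical structure the analyses assume:

* **Gene catalog.** Per-type neuron markers, 50 microglia markers (at
  least 8-fold higher in microglia than any neuron type), astrocyte
  markers, an activated-microglia program (zero expectation in *every*
  reference type), mitochondrial-flagged genes and housekeeping genes.
  Expected profiles are scaled to a common library size.
* **Counts.** Negative binomial with a single global dispersion (0.2;
  per-gene dispersion would be a config extension, not the default) and
  log-normal library-size factors with mean 1 — so CPM normalization has
  something to undo. Dispersion below 1e-8 falls back to Poisson.
* **Contamination.** Each Patch-seq cell's expected expression is the
  convex mixture $(1 - f)\,\lambda_N + f\,\lambda_{M^*}$, where
  $\lambda_{M^*}$ is the dissociated-microglia profile plus the activated
  program — mixing at the mean level keeps the oracle analytic and matches
  the score's linear logic. The fraction $f$ is logistic-normal:
  $\mathrm{logit}(f) = \beta_0 + u_{donor} + v_{type} +
  \beta_{bt}\,\text{break-in} + \beta_{depth}\,(\text{depth} - 500) +
  \varepsilon$, directly mirroring the additive donor/cell-type/covariate
  structure the mixed models assume (a Beta regression would not). Donor
  SD (1.0) dominates cell type (0.3), break-in is negative (-0.15/h:
  later-recorded cells are less contaminated) and depth is negative
  (-0.001/um: deeper cells are less contaminated). The intercept (-3.5)
  was calibrated once so the emergent score distribution on the default
  dataset matches the human condition (simulated 0.33 +/- 0.18 against
  the observed 0.34 +/- 0.25); astrocyte contamination is deliberately
  absent, as astrocytes are not a major contamination source in this
  setting.
* **Electrophysiology.** On the analysis scale, $y = \text{baseline} +
  b_{type} + \gamma f + b_{donor} + \varepsilon$; log10-tagged features
  are then exponentiated so the pipeline's log10 step recovers linearity.
  Effect sizes were fixed by an a-priori power analysis under the default
  contamination distribution (sign-error $t \approx \gamma_{std}\,
  \mathrm{sd}(f)\sqrt{n}$): non-null features carry standardized effects
  of 1.7–3 per unit contamination fraction, i.e. roughly 0.5–1 SD at the
  realistic upper end $f \approx 0.3$ — the magnitude reported for real
  neurons — and the sag ratio carries $\gamma = 0$ as a built-in negative
  control. Because features are z-scored with the sample SD before
  modeling, the estimand of the standardized coefficient is $\gamma$
  divided by the realized feature SD; `simulate_ephys` records that
  per-dataset value (attribute `gamma_std`) for calibration checks.

What the generator does *not* emulate: read-level mixing, doublets or
ambient RNA beyond the single microglial source, per-gene dispersion,
dropout beyond what the NB implies, batch effects, raw voltage traces, and
the mapping of cells to a reference taxonomy (type labels are known).
Passing recovery tests on this generator therefore demonstrates that the
pipeline's statistics recover the structure they model — not that real
Patch-seq data satisfies that structure.

## Numerical conventions and degenerate inputs

* Zero-total cells are a hard error naming the cell; an all-flagged gene
  filter is an error (empty matrix).
* `d_{M,M} \le d_{N,M}` is a degenerate-reference error (the score's
  denominator must be positive).
* Identical values in both rank-sum groups give $p = 1$ by convention; the
  exact path doubles the smaller tail and caps at 1.
* Percentile cuts that coincide (all scores equal) are an error rather
  than empty groups.
* Marker-selection ties break lexicographically by gene id; k-means
  initialization and PCA signs are canonicalized as described above.
* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical datasets and byte-identical pipeline outputs.

## Validation problem sizes

The packaged tests exercise the default study conditions (1000 Patch-seq
cells, 50 donors, 5 neuron types, 2000 genes, 700 reference cells) for
score and signature recovery, and reduced designs chosen for statistical
sufficiency elsewhere: 25 donors x 12 cells over 20 seeds for the
variance-partition ordering study, 20 donors x 20 cells with 100 seeds
(CI coverage) and 200 seeds (type-I error of the null feature) for the
electrophysiology calibration, and exhaustive enumeration oracles for the
hypergeometric test (universe up to 12), the exact rank-sum test (groups
up to 6) and the BH step-up. In the calibration study the contamination
covariate is the true simulated fraction rather than the estimated score:
the score is a saturating monotone proxy of the fraction, so confidence
intervals from the scored pathway target a proxy slope, whereas the
calibration question is whether the mixed-model machinery covers the
generative effect at nominal rate.

## Known limitations

* The score is relative to the chosen reference: a reference whose
  microglia differ systematically from the contaminating population (e.g.
  nuclei vs whole cells) shifts both signature content and the ceiling.
* One contaminant per run; composite multi-source scores are out of scope
  (run the scorer separately per contaminant).
* Gaussian mixed models for a [0,1]-bounded response, matching the
  original analysis; no generalized LMM variants.
* The hypergeometric test is enrichment-only (upper tail); depletion is
  not tested.
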