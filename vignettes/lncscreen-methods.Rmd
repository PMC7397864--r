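---
title: "Methods: how lncscreen models and tests an ASO knockdown screen"
author: "lncscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how lncscreen models and tests an ASO knockdown screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscreen)
```

# The experimental design being modelled

`lncscreen` analyses functional screens in which long noncoding RNAs
(lncRNAs) are knocked down one at a time in primary fibroblasts with
RNase-H-recruiting antisense oligonucleotides (ASOs), and each knockdown is
phenotyped twice: *cellularly*, by live-cell imaging of well confluence and
by image-derived morphology features, and *molecularly*, by expression
profiling against plate-matched negative controls. The design elements the
package assumes are:

* several non-overlapping ASOs per lncRNA (five by default), transfected in
  duplicate wells;
* six non-targeting negative-control wells (NC_A) on every plate, which
  anchor both normalization and significance testing;
* per-ASO knockdown efficiency measured by RT-qPCR with three primer pairs;
* expression libraries for knockdown wells plus NC_A libraries from the
  same plate/run.

Because no single ASO is trustworthy on its own (variable efficiency,
isoform-specific targeting, off-target effects), every lncRNA-level claim
in this package is built from *agreement between independent ASOs measured
against an empirical background*, which is the scientific core of the
method.

# Growth phenotype

**Slope estimation.** Early-phase fibroblast growth is close to linear in
% confluence, so each well's growth rate is the ordinary least-squares
slope of confluence on time. To stay inside the near-linear regime, all
wells of a plate are truncated at the first time point where the mean NC_A
confluence of that plate reaches 90% (`truncate_to_control_window()`); if
the controls never get there, the full 48 h series is used. A plate whose
window leaves fewer than three time points is an error rather than a
guess.

**Normalization.** Each ASO's mean slope is divided by the mean slope of
the same plate's six NC_A wells (`normalize_growth_rate()`). Negative
slopes — cells shrinking or detaching — are deliberately *not* rescaled or
floored: a negative normalized rate is a meaningful flag of severe
inhibition.

**Testing.** The two replicate-well slopes are compared with the six
control slopes by an equal-variance pooled two-sample t-test (6 degrees of
freedom), two-sided, with Benjamini–Hochberg adjustment across all ASOs of
the run. The inhibition call requires FDR ≤ 0.05 *and* a normalized rate
below 1, i.e. it is one-directional. The raw (not normalized) slopes feed
the t-test; normalization is reported alongside, since dividing both
groups by the same plate constant would not change the statistic.

**lncRNA-level calling with conditional cutoffs.** With `n` successful
ASOs for a target, how many must be individually significant before the
target is called? `conditional_cutoff()` answers by resampling from the
screen itself: draw `n` significance flags without replacement from the
flags of all successful ASOs targeting *other* lncRNAs, and find the
smallest `k` whose tail probability is below 5%. The tail is computed
exactly (it is a hypergeometric tail; Monte Carlo draws are available via
`n_resample` but are never more accurate). This makes the cutoff adapt to
the screen's own false-positive level: a screen with a noisy growth assay
automatically demands more concordant ASOs. On simulated null screens (no
planted effects) the pooled fraction of targets called hits stays below
5%, which is exactly what the cutoff is calibrated to do.

# Molecular phenotype

**Differential expression.** Expression is scaled to tags per million
(1e6 per library), and each ASO's knockdown libraries are contrasted with
the NC_A libraries of the same plate on `log2(TPM + 1)`. The per-gene
statistic is the mean log2 difference divided by its standard error from a
gene-wise control variance, with a two-sided normal p-value and BH
adjustment across genes.

Two numerical choices matter here:

* the gene-wise variance is pooled across *all* plates' control libraries
  (centered within plate). Six libraries per plate give a 5-df variance
  estimate whose reciprocal is heavy-tailed; plugging it into a normal
  test visibly inflates the null DEG rate, while cross-plate pooling (30+
  df in a typical screen) calibrates it — the package's null simulations
  show a per-gene false DEG rate of about 0.2–0.3%, and this is asserted
  in the test suite. `differential_expression()` used standalone falls
  back to the per-contrast control variance;
* the variance is floored at its 10th percentile across genes so that
  genes with accidentally tiny control variance cannot flood the DEG
  list.

**Experiment-wide Z-score.** Each gene's log2 fold change is standardized
across all ASO experiments (sample SD; genes with zero spread get z = 0).
This penalizes genes that respond to *every* transfection — the common
stress response — and rewards changes specific to a knockdown. A DEG call
therefore needs all three gates: FDR < 0.05, |Z| > 1.645, |log2FC| > 0.5,
with the sign consistent across gates.

**Divergent partners.** For lncRNAs sharing a bidirectional promoter with
a protein-coding gene, `divergent_partner_response()` tabulates the
partner's fold change per ASO and the screen-wide median |log2FC|, with
missing partners excluded rather than imputed.

# Concordance between ASOs

**Global growth concordance.** The statistic is the mean absolute
difference of normalized growth rates over all same-target ASO pairs. The
null shuffles target labels over ASOs, preserving group sizes, and the
p-value uses the plus-one rule so it can never be zero. On instances with
at most 7 ASOs the package enumerates the complete permutation
distribution instead — this is used to verify the sampled version exactly.

**Pairwise molecular concordance.** DEG sets are *signed* (gene plus
direction) before comparison: two ASOs that move the same gene in opposite
directions are not concordant. For each same-target pair, the Jaccard
index of the signed sets is compared against the Jaccard indices of ASO
pairs targeting *different* lncRNAs (up to 10,000 sampled without
replacement), again with a plus-one empirical p. A pair is "reproducible"
when it has at least five common signed DEGs and p ≤ 0.05. Under an
exchangeable null these empirical p-values are approximately uniform, and
the test suite checks this with a Kolmogorov–Smirnov distance bound.

# Motif activities (MARA)

Expression is modelled as promoter/gene intercepts plus sample intercepts
plus site-counts × per-sample motif activities. After double-centering the
log2 expression matrix and column-centering the site counts `N'`, the
activities solve the ridge system `(N'ᵀN' + λI) A = N'ᵀẼ`, with standard
errors from the ridge covariance and per-sample residual variance, and
`z = A/se`. λ defaults to generalized cross-validation over a log-spaced
grid (1e-3 … 1e3); `λ = 0` on a rank-deficient site-count matrix is
refused with a pointer to use a positive penalty. Because the response is
row-centered, each motif's activities sum to zero across samples — they
are *relative* activities; the per-sample sum over motifs is not
constrained. Display clipping of extreme Z-scores is left to the caller;
stored values are never clipped.

# Gene-set enrichment

`enrichment_score()` is the classic weighted running sum: hits add
`|stat|^w / Σ_hits |stat|^w`, misses subtract `1/(N − set size)`, and the
score is the extremum by absolute value (ties at equal magnitude take the
positive branch, a convention pinned by the tests). `preranked_gsea()`
builds its null by gene-label permutation — equivalent to drawing random
sets of the same size — because its input is an already-ranked statistic
vector per ASO, not per-sample phenotypes. The nominal p is the plus-one
tail within the same-sign half of the null, and NES divides the ES by the
mean |null ES| of that sign. The same-sign convention keeps null p-values
approximately uniform, which the acceptance tests verify; the practical
consequence is that the smallest attainable p is ~2/n_perm rather than
1/(n_perm + 1). The per-ASO summary score is `−log10(p) × sign(NES)`,
which is 0 when p = 1 by construction.

# The synthetic-screen generator

`simulate_screen()` generates the full input bundle with planted ground
truth, and its defaults are the *study conditions* assumed throughout the
tests rather than free dials:

* time grid 0–48 h every 3 h; duplicate ASO wells; six NC_A wells per
  plate; five ASOs per target; up to 45 duplicated ASOs per 96-well plate;
* control growth: slope 1.8 %/h from 10% seeding confluence with 2%
  additive well noise and 0.05 %/h well-to-well slope jitter — controls
  cross 90% confluence inside the window, so truncation is exercised;
* true knockdown efficiency per ASO ~ Beta(4.5, 5.5) (median ≈ 0.45,
  matching the screen-scale reality that roughly half of designed ASOs
  fail), measured by three primer pairs with 5% Gaussian noise; the
  success rule (>40% in two primers or >60% in one, strict) then
  classifies ASOs, so the QC path always has genuine failures to handle;
* expression on the log2 scale: log-normal gene baselines, the targeted
  lncRNA reduced by its ASO's efficiency in expectation, a shared
  downstream module (default 30 genes at 1.0 log2 units, common direction)
  for molecular-hit targets applied to their successful ASOs, an
  ASO-specific off-target module (20 genes), and N(0, 0.3) noise; two
  expression libraries per ASO (duplicate transfection) and six control
  libraries per plate. Shared-module and growth effects are applied at
  full magnitude to successful ASOs — the model is that the downstream
  program switches once knockdown succeeds — while the on-target
  reduction itself scales with efficiency;
* optionally, expression gains a site-counts × planted-activities
  component so motif-activity recovery can be benchmarked against truth.

What the generator deliberately does *not* emulate: count noise
(expression noise is Gaussian in log space, not negative-binomial),
isoform structure, sequence-driven off-target prediction, batch/run
effects beyond plate-matched controls, or image-level data. Passing tests
therefore demonstrate that the statistics are correctly calibrated and
powered *under the stated generative assumptions* — they do not certify
performance on real CAGE libraries, where dispersion, correlation between
genes, and batch structure are harsher.

# Problem sizes used by the tests

The packaged checks run at sizes a laptop handles in about a minute:
twenty 50-target null screens for background calibration; 1000 random
instances per oracle comparison (BH step-up, pooled t, Jaccard, running
sum, scalar ridge, hypergeometric cutoff); 2500 pair p-values and 1000
GSEA p-values for the uniformity bounds; 1000 wells for slope recovery;
five 20-target screens for knockdown recall and pair power; and
200 promoters × 20 motifs × 50 samples for motif-activity recovery at
signal-to-noise 3. These sizes are the package's chosen trade-off between
statistical resolution and quick verification, and each is stated in the
corresponding test.

# Known limitations

* The differential-expression model is a calibrated control-anchored
  normal test, not a count model; with raw CAGE tag counts a
  negative-binomial engine is the better tool, and the surrounding
  machinery (Z-gates, signed DEG sets, concordance) is agnostic to that
  swap.
* The conditional-cutoff background pool treats ASOs as exchangeable
  across targets; plate-level confounding of significance flags is not
  modelled.
* Empirical p-values are discrete; at 10,000 permutations the granularity
  is 1e-4, and the reproducible-pair gate at p ≤ 0.05 inherits it.
* `successful_targets()` applies the knockdown rule to per-primer mean
  efficiencies; whether replicate transfections should instead be
  classified separately is not determined by the assay description, and
  the choice is localized in `kd_success_table()`.
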