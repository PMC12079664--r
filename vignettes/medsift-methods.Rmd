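---
title: "Models and methods in medsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in medsift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsift)
```

medsift implements the statistics of a FACS-sorted CRISPR reporter screen and
of mutant differentiation-dynamics phenotyping, together with a synthetic-data
module that generates every input with planted ground truth. This vignette
documents the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic tests do and do not establish about real data.

## Screen scoring

### Model and score

Guide counts per sample are total-count normalized (each sample rescaled to
the mean of the original column totals) and summarised per guide as

$$\mathrm{lfc}_g = \log_2\frac{\text{sorted}_g + 1}{\text{reference}_g + 1},$$

with a symmetric pseudocount of 1 on both columns. Guides are ranked by
descending enrichment, ties broken stably by guide identifier, and converted
to percentiles $u = \mathrm{rank}/N$ over the *whole* library, non-targeting
controls included — controls thereby anchor the null of the percentile scale.

The gene score is alpha-robust rank aggregation. For a gene with ordered
guide percentiles $u_{(1)} \le \dots \le u_{(n)}$, only guides with
$u \le \alpha$ participate, and with
$\beta_k = P\{\mathrm{Beta}(k,\, n-k+1) \le u_{(k)}\}$ (the distribution of
the $k$-th order statistic of $n$ independent uniforms),
$\rho = \min_k \beta_k$ over participating $k$. A gene with no participating
guide scores $\rho = 1$. $\rho$ is monotone (improving any participating
percentile can only decrease it) and invariant to guide order within a gene;
both properties are tested.

`alpha` defaults to 0.25 and is exposed everywhere. A permissive default
keeps power when genes carry only four guides; the tests sweep it. The
pseudocount, tie-break and percentile conventions exist purely to make runs
deterministic and symmetric; none of them affects which genes can rank first.

### Permutation significance

The null distribution of $\rho$ is obtained by drawing gene-sized sets of
percentiles from the observed percentile pool without replacement and
recomputing $\rho$; the p-value uses the positively biased estimator
$p = (1 + \#\{\rho_\text{null} \le \rho_\text{obs}\})/(1 + n_\text{perm})$,
which can never return zero. Genes with the same guide count share one null
sample: the draws are exchangeable across same-size genes, so this is
distributionally identical to per-gene resampling while costing a single
pass. FDR is Benjamini–Hochberg across genes (`stats::p.adjust`). On tiny
libraries the permutation p agrees with exhaustive subset enumeration within
Monte-Carlo error, and under a global null the p-values are uniform; both are
frozen as tests. `n_perm` below 100 is rejected as too unstable in the tail.

### Hit rule

Across sorting conditions (by default the four low gates: 1% and 5% at days
6 and 9), a gene is a hit iff its FDR is at most 0.05 in at least one
condition or at most 0.2 in at least two. Genes absent from a condition
count as FDR 1 there — the conservative reading of a missing entry.

## Signaling footprints

The query delta is the per-gene difference of mean log2 expression between
mutant and wild type after 24 h of differentiation. Against each pathway's
50-gene footprint and its defining-knockout delta vector $\Delta_\text{def}$:

* activity $a_P = \sum_{g \in S_P} \Delta_\text{query}(g) \big/
  \sum_{g \in S_P} \Delta_\text{def}(g)$ — linear in the query, exactly 1
  for the defining knockout itself;
* Spearman correlation of query and defining deltas over $S_P$, with
  average ranks on ties — invariant to monotone transforms of the query.

Batch correction subtracts the batch's wild-type delta from the query before
scoring. "The wild-type conditions are used" admits several readings;
subtraction is the minimal one, it preserves both the linearity of the
activity and the self-footprint identity, and it is what the tests pin down.
Deltas are computed on log2 expression throughout, consistent with treating
"expression fold changes" as log-scale changes in RNA-seq processing. The
activity is reported as the raw ratio, with no per-row rescaling for display.

## Differentiation dynamics

### Delay estimation

The change of the naive marker panel (Prdm14, Tfcp2l1, Klf4, Tbx3, Nanog,
Zfp42, Esrrb) between pluripotency medium and 24 h of differentiation is
compared to reference change vectors $\mathrm{ref}(t) - \mathrm{ref}(0)$ on
a 0.1 h grid, linearly interpolated between sampled reference timepoints.
"Normalized Euclidean distance" is realized as: each marker dimension is
standardized by its standard deviation over the reference course, the
Euclidean norm is divided by $\sqrt{\#\text{markers}}$, and for plotting the
curve is min–max rescaled to $[0,1]$. Each of these is a monotone transform
of the distance profile, so the argmin — the only thing the estimate uses —
is unaffected. Markers that are flat in the reference carry no time
information and are dropped with a warning.

The delay is reported as the signed offset $\delta = t^* - 24\,\mathrm{h}$
(earliest grid point on ties). Note the sign convention: a mutant lagging
6 h matches the reference at $t^* \approx 18$ h and therefore reports
$\delta = -6$ h. On noise-free synthetic input the estimate is exact to the
grid step for any planted lag inside the reference range.

The marker panel follows the seven-gene naive panel ending in *Zfp42*; a
truncated variant of the last name circulates and is treated as a typo.

### Slopes of regulation and ratio modes

Slopes are per-gene ratios $s_g = \Delta_\text{mut}(g)/\Delta_\text{wt}(g)$
of log2 expression changes over differentiation, for the marker panel or the
100 genes with the strongest negative/positive wild-type fold change.
The orientation is mutant over wild type, so a globally attenuated mutant
response yields slopes below one; descriptions of this statistic sometimes
invert the quotient in figure legends while describing slopes smaller than
one in the text, and the attenuation reading is the only self-consistent
one. Genes with $|\Delta_\text{wt}| \le 0.1$ log2 units are excluded from
the denominator and reported in the result's attributes.

Fold-change ratios for target sets (selected at $|\mathrm{lfc}| > 1$,
adjusted $p < 0.05$, split by sign) are computed on the linear scale,
$r_g = 2^{\mathrm{lfc}_\text{mut} - \mathrm{lfc}_\text{wt}}$; this
orientation and scale is the one under which attenuated responses put the
mode of downregulated genes slightly above 1 and of upregulated genes
slightly below 1. The mode is the argmax of a Gaussian-kernel density with
Silverman's bandwidth on a 512-point grid spanning the ratio range; fewer
than 10 genes in a direction is rejected as unstable.

## Fate prediction and genotype gating

Traces are smoothed by a centered 7-frame rolling mean; edges use shrinking
windows rather than invented padding. The fate-predictive feature defaults
to the smoothed-trace maximum — the natural scalar for rise-and-fall
induction dynamics — with the end-of-induction value selectable.

ROC analysis scans all distinct feature values as thresholds (predicting the
positive class strictly above), computes AUC by the trapezoidal rule — which
equals the rank-sum statistic $U/(n_1 n_2)$, an identity the tests verify to
$10^{-12}$ — and picks the threshold maximizing Youden's
$J = \text{sens} + \text{spec} - 1$, lowest threshold on ties.

Genotype gating fits a two-component Gaussian mixture to log10 intensities
(fluorescence is multiplicative) by EM with deterministic initialization at
the 25th/75th percentiles, tolerance $10^{-8}$, at most 500 iterations;
vanishing components or variances abort with diagnostics. Components are
reported in ascending mean order, so input order is irrelevant. Cells are
assigned to their maximum-posterior component only at posterior $\ge$ 0.85;
cells between the populations remain unassigned. On well-separated mixtures
the misassignment among assigned cells matches the truncated Gaussian
overlap integral, which the tests check against a closed-form oracle.

## Image quantification

Colony counting replays the classic particle-analysis pipeline: Gaussian
high-pass background subtraction at a scale much larger than a colony
(10× the square root of the maximum accepted area, capped so the kernel fits
the image), Gaussian blur (default sigma 2 px), Otsu threshold, 8-connected
labelling, and filtering by area and circularity $4\pi A / P^2$. The
perimeter is measured on the 8-connected contour chain with the
Vossepoel–Smeulders step weights (0.948 per axis step, 1.340 per diagonal),
which corrects the staircase bias of raw boundary counts; rasterized disks
then measure within about 10% of circularity 1, and the accepted
circularity interval defaults to (0.5, 1.2) to admit that discretization
error. No claimed defaults exist for the size/circularity cutoffs
themselves; they are explicit parameters.

Cell classification drops nuclei below 40 µm², calls channels against
supplied thresholds (strictly above = positive), maps marker combinations to
classes (Epi = NANOG+SOX17−, PrE = NANOG−SOX17+, otherwise `other`), and
reports per-replicate proportions with s.e.m. `suggest_threshold()`
automates the manual bisection of bimodal marker profiles by the deepest
density minimum between the two highest KDE modes, falling back to a
histogram Otsu threshold (flagged) on unimodal input.

## Single-cell rules

QC removes barcodes with $\le 2500$ detected genes or $\ge 15\%$
mitochondrial counts — the boundary cells are removed, matching the removal
phrasing, so retention is strict inequality on both sides. Mitochondrial
fraction is computed from counts. Normalization is
$\log 1\mathrm{p}(\text{count}/\text{cell total} \times 10^4)$, so
$\sum \mathrm{expm1}$ per cell is exactly $10^4$. Marker testing is a
per-gene rank-sum test restricted to genes with a group-mean log1p
difference of at least 0.5, BH-adjusted.

The differential-expression contract used throughout is deliberately simple:
log2fc as the difference of group means of $\log_2(x+1)$, Welch's t-test on
that scale, BH adjustment. The downstream statistics consume only
(log2fc, padj), so a heavier count model would change nothing they see; the
full negative-binomial machinery is out of scope.

## The synthetic-data module

The generator plants exactly the quantities the estimators must recover:

* **Screen** — each cell's reporter log-intensity is
  $\mathcal{N}(\text{effect}(\text{gene}), \sigma^2)$ (a single Gaussian per
  clone: the simplest model with a closed-form tail-sorting oracle); a gate
  keeps the population tail fraction, the cutoff solved from the
  guide-weighted mixture CDF; counts are multinomial at the stated depth
  from Gamma-dispersed library weights. Defaults: 500 genes × 4 guides,
  1000 controls, depth $10^6$, gates 1% and 5% at days 6 and 9. The realized
  guide distribution of genome-wide libraries is not published; 4 guides per
  gene and ~1000 controls are library-design conventions, not measured
  facts. Day labels are metadata only — the generator does not model effect
  kinetics across days.
* **Bulk expression** — wild-type log2 fold changes over differentiation are
  a Gaussian signature; mutant fold changes are $c \times$ wild-type on the
  log2 scale (a single global attenuation — the one-parameter model that
  produces a unimodal ratio distribution); naive markers follow the
  reference course at $24 - \text{delay}$ h for the mutant; planted pathway
  activities shift the mutant's differentiated expression along the
  defining-knockout delta. At `noise_sd = 0` every downstream estimator is
  exact by construction, and the tests assert it.
* **Reference course** — per-marker sigmoidal decay
  $\text{floor} + (\text{init}-\text{floor})/(1 + (rt)^s)$, so the half-time
  is $1/r$; rate 0 gives a constant profile and negative rates are rejected.
* **Traces** — pulse $A\,(t/t_p)\,e^{1-t/t_p}$ plus frame noise at 10 min
  intervals; fate is PrE iff the noise-free peak strictly exceeds the
  threshold (a peak exactly at the threshold is non-PrE), and both fates are
  always represented by stratifying amplitudes around the threshold.
* **Mixtures and colony images** — two log-normal intensity components with
  retained labels; non-overlapping elliptical colonies (placement by
  rejection sampling with bounded retries, so the planted count is
  well-defined) with analytic area and Ramanujan-perimeter circularity as
  truth.

All generators are bit-reproducible under a fixed seed, and every random
draw flows from the one seed given per call.

What passing these tests shows — and does not. The generators emulate the
*statistical shape* of the real inputs (tail sorting, attenuated signatures,
sigmoidal marker decay, bimodal intensities, disk-like colonies). They do
not emulate read-level sequencing noise, UMI chemistry, guide-efficiency
heterogeneity, batch structure beyond a single wild-type offset, cell-cycle
or density effects in images, or real genome annotation. Recovery on
synthetic truth therefore validates the estimators' correctness and
calibration, not their robustness to every artifact of real experiments.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the screen recovery at 500
genes × 4 guides + 1000 controls at depth $10^6$ over 3 seeds, delay and
attenuation recovery on 7-marker panels with up to 300 background genes over
5 seeds, mixtures of 6000 cells, and 20 colony images of 320×320 px —
sizes chosen so each module is exercised at realistic dimensionality while
a full run completes in well under a minute per module on one CPU. The
acceptance script derives all sub-seeds from its `--seed` argument and
recomputes every reported number from scratch at run time.

## Known limitations

* The permutation null is shared across same-size genes; per-gene nulls
  would differ only by Monte-Carlo noise but would cost a factor of the
  gene count.
* The delay estimator reports the signed grid offset; interpreting its sign
  requires the convention stated above.
* EM gating assumes exactly two log-normal components; strongly skewed or
  three-population intensity distributions violate the model and are only
  caught by the degenerate-fit diagnostics.
* Colony counting assumes colonies are brighter than background after
  high-pass filtering; images whose foreground occupies a negligible area
  push the Otsu threshold into the noise floor, which is why size filters
  should be set from control wells.
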