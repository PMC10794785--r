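---
title: "Modelling autosomal responses to sex chromosome dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling autosomal responses to sex chromosome dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xydosage)
```

## The scientific problem

Human somatic cells carry one active X chromosome (Xa) plus, in most people,
either an inactive X (Xi) or a Y. Individuals with sex chromosome aneuploidy
span a natural dosage series — one to four X chromosomes (zero to three Xi)
and zero to four Y chromosomes — and expression of many genes responds
approximately linearly to each added chromosome. `xydosage` implements the
inferential machinery for asking how Xi and Y dosage modulate *autosomal*
expression: per-gene dosage regression, comparison of the X- and Y-response
catalogs, a meta-analysis that classifies X-linked genes as escaping or
subject to X inactivation, repeat-array copy-number estimation from read
depth (the Yq heterochromatin proxy), karyotype PCA for placing
structural-variant samples, and peak-to-promoter assignment for
transcription-factor target definition. A synthetic-data module generates
every input with known ground truth, so each stage can be validated by
parameter recovery rather than by eyeballing.

## The dosage model

For gene $g$ in sample $j$ with raw count $K_{gj}$, the model is a negative
binomial GLM with log link,

$$K_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g), \qquad
\log \mu_{gj} = \log s_j + \beta_{g0} + \beta_{gX}\, nX_j +
\beta_{gY}\, nY_j + \gamma_{g,b(j)},$$

where $nX_j \in \{1..4\}$ and $nY_j \in \{0..4\}$ are chromosome copy
numbers, $b(j)$ is the library preparation batch, $s_j$ is a
median-of-ratios size factor, and $\alpha_g$ is the gene's dispersion.
Coefficients are reported in log2 units per chromosome copy
($\beta/\ln 2$). The same engine serves the study's other designs — Chr 21
copy number with sex constitution, CRISPRi knockdown with sgRNA target and
cell line, and repeat-depth regression with population and lab — via
`design_spec()`.

Implementation choices, all deliberate:

* **Size factors** (`size_factors()`) use the median-of-ratios estimator
  restricted to genes with no zero counts, rescaled to geometric mean 1.
  When no such gene exists the function fails loudly; no pseudo-reference
  fallback is silently substituted, because the autosome-only
  renormalization control depends on knowing exactly which genes anchored
  normalization.
* **Dispersion** is per-gene method of moments around a Poisson prefit of
  the same design: with fitted means $\hat\mu$,
  $\hat\alpha = \max\{\sum((y-\hat\mu)^2 - \hat\mu) / \sum \hat\mu^2 \cdot
  n/(n-p),\ 10^{-8}\}$. Taking the mean structure out first matters: a
  designless moment estimator folds batch and dosage signal into
  $\hat\alpha$ and wrecks type-I calibration. No shrinkage trend is fitted
  — estimates are transparent, per-gene, and the documented trade-off is
  noisier dispersions for weakly expressed genes.
* **Fitting** is ridge-stabilized IRLS (penalty $10^{-6}$, tolerance
  $10^{-8}$ on coefficients) shared across genes through one design
  matrix; genes that fail to converge are flagged and excluded from the
  multiple-testing denominator. The tiny ridge only matters for separated
  or all-zero genes.
* **Inference** is a Wald test of each coefficient of interest against a
  t reference with residual degrees of freedom ($n - p$). At the full
  design ($n = 106$, $p = 5$) this is numerically the normal reference;
  the distinction matters in down-sampled subsets ($n = 20$), where a
  normal reference is anticonservative enough to make the saturation
  curve non-monotone — false positives at the smallest size would exceed
  the power at the next size up. Benjamini–Hochberg adjustment is applied
  per coefficient across converged genes only.

Two invariance properties are worth stating precisely because one common
phrasing of them is false for count likelihoods. A *global* depth change
is absorbed exactly by the size factors (tested to $10^{-6}$ log2 units
under a Poisson model). Scaling *one* sample's counts, however, genuinely
changes any Poisson/NB fit — the scaled sample carries more Fisher
information — so exact invariance is impossible; under the saturating NB
weights the movement is small (tested below $10^{-2}$, measured around
$10^{-3.6}$ at a 3-fold scaling) and this is the behaviour any
likelihood-based tool shares.

### Controls built around the model

`renormalization_control()` refits with size factors computed from
autosomal genes only, reporting the per-coefficient correlation and
maximum estimate difference between fits — the guard against strong
sex-chromosomal expression distorting genome-wide normalization. With
simulated data free of sex-linked genes the two fits are identical; with
an adversarial half-the-library sex-linked simulation the deltas are
reported, not suppressed.

`saturation_bootstrap()` re-runs the full pipeline (size factors,
dispersion and all) on repeated without-replacement subsets of samples
and counts significant genes per subset size. Index sets are sorted, so
the full-size subset reproduces the full analysis bit for bit. Subsets in
which a coefficient has no variation (e.g. a draw containing only one
karyotype) are recorded as missing rows rather than dropped — power
curves should not silently condition on estimability.

## Shared-response statistics

Catalog comparisons use four tools: upper-tail hypergeometric overlap
tests (`overlap_test()`, $P(X \ge k)$ including the observed count, with
an explicit Bonferroni denominator — the number of comparisons per figure
is an analysis choice and is never inferred); Pearson correlation of
effect estimates (`correlate_effects()`); squared Pearson correlation as
the coefficient of determination with the association sign reported
separately (`variance_explained()` — a knockdown that opposes a dosage
response has $R^2$ near 1 and sign $-1$); and weighted Deming regression.

`weighted_deming()` handles the errors-in-variables problem of comparing
two estimated effect vectors: the slope minimizes
$\sum_i (y_i - a - b x_i)^2 / (\sigma_{y_i}^2 + b^2 \sigma_{x_i}^2)$
with the intercept profiled out, which reduces to classical Deming
regression (variance ratio 1) for constant equal errors. The minimizer is
found by golden-section search with a narrow-interval polish, agreeing
with the closed-form solution to $10^{-8}$; the slope's standard error is
a leave-one-out jackknife with a normal-theory 95% interval. Sending one
error to zero recovers ordinary or inverse regression, a useful sanity
bracket.

## The Xi-escape meta-analysis

Five published evidence dialects are each re-implemented as a caller with
that study's inclusion rule and test (`call_cotton`, `call_tukiainen`,
`call_garieri`, `call_sauteraud`, `call_sanroman`); all work on the
allelic ratio AR = lower/higher allele (Xi/Xa under skewed inactivation),
with `ar_from_xa_fraction()` converting Xa read fractions
($\mathrm{AR} = 1/f - 1$; $f = 0.95$ gives the 0.0526 per-sample
threshold) and `baseline_ar()` giving the skewing floor
$(1-\mathrm{skew})/\mathrm{skew}$.

`synthesize_calls()` combines the per-dataset verdicts. Open points in
the rule text were resolved as follows and are encoded in one place:
"most studies" counts over informative datasets only; the "average AR" is
the unweighted mean of per-dataset mean ARs (not a pooled per-sample
mean); escape clauses are evaluated before subject clauses; the
Xi-hybrid-line fallback (escape at an expression fraction $\ge 0.22$)
applies only to genes with zero informative datasets; an exact 1-of-2
escape split with average AR below 0.1 is a `no_call`. Degenerate t
inputs follow stated conventions — constant positive differences are
certainty (p = 0), constant zero differences are null — and both are
flagged in the output. The test suite walks an exhaustive grid of call
combinations against an independently transcribed decision table.

## Repeat depth, PCA and variant placement

Repeat-array copy number is the ratio of mean depth in repeat windows to
mean depth in a single-copy reference region (`normalized_repeat_depth()`),
after `gc_correct()`: 10 equal-width GC bins are fitted on the
single-copy region and each bin is scaled to the global single-copy
median; repeat windows are corrected with those factors so their own
(amplified) depths never influence the correction. This bin-median scheme
is deliberately simpler than read-resampling GC corrections; on synthetic
profiles it recovers generating factors across the observed polymorphism
range (24–900) within 5% and leaves residual depth–GC correlation below
0.1.

For structural-variant placement, normalized counts go through
`vst_log()` (log2(x+1) — monotone and parameter-free, which is all
clustering needs), `remove_batch()` (batch means out, grand mean back),
and `pca_project()` (centred, sign-fixed so the largest loading is
positive). `centroid_ellipses()` draws the 95% region of each karyotype
centroid as the covariance of the mean scaled by $\chi^2_2(0.95)$ —
one defensible reading of a centroid confidence ellipse; groups under
three samples get none. `classify_variant()` is nearest-centroid in the
first two components with lexicographic, flagged tie-breaking.
Mosaic cultures (e.g. a 46,X,i(Xq) line that is half 45,X) are emulated
in the generator as mixtures, and their expected behaviour — averaging
toward the euploid centroid — is a feature of the data, not the
classifier.

## Peak-to-promoter assignment

All intervals are BED-semantics: 0-based, half-open, intersection
requires one shared base. A gene is bound when any peak intersects
$[\mathrm{TSS} - w, \mathrm{TSS} + w)$ around the strand-aware TSS
(annotated start for `+`, annotated end for `-`); $w$ is 1 kb for
promoter binding and 30 kb for hormone-receptor target definition.
"Within 30 kb" is implemented as any-peak-within-window rather than
closest-peak-then-cutoff; the two are equivalent for the cutoff
criterion. Direct targets are bound AND significantly responsive
(`direct_targets()`); `binding_proportion()` divides binding cell lines
by expressing cell lines, with never-expressed genes missing rather
than zero.

## What the synthetic data does and does not emulate

`generate_truth()` draws per-copy log2 effects from $N(0, 0.2)$ for
responsive genes — so most fold changes per copy are under 1.5×, matching
the modest effects this analysis needs to resolve — and gives shared
genes $\beta_Y = 0.7\,\beta_X + N(0, 0.05)$ (redrawn on the rare sign
flip), so Y effects track X effects but are smaller. Defaults: 18% of
genes X-responsive, 6% Y-responsive, 4% shared (the LCL proportions);
NB dispersion 0.1, a typical bulk RNA-seq value that the source data do
not pin down; three batches with $N(0, 0.1)$ log2 offsets, since batch
is modelled but never quantified in the source; library sizes log-normal
($\sigma = 0.3$) around a desk-scale mean — only relative normalization
matters. Allelic counts are beta-binomial (overdispersion 0.02, depth
100) because the five source studies' noise is unpublished;
`total_reads = Inf` gives the noise-free configuration used for exact
round-trips. Escape genes get Xi expression fractions in 0.1–0.45.

The generator emulates design structure, batch, dispersion and allelic
noise. It does not emulate GC- or length-dependent quantification bias,
correlated genes, cell-type mixtures, mosaicism (except as explicit
mixtures), or mapping artefacts. Passing parameter-recovery tests
therefore demonstrates correctness of the inference under the stated
model, not robustness to everything real RNA-seq can do.

## Problem sizes and numerical conventions

The packaged validation runs at desk scale, chosen to exercise every code
path with comfortable statistical resolution: the full 106-sample LCL
design with 5,000–6,000 genes for parameter recovery and calibration,
1,000 genes for the 100-replicate saturation analysis, 150–400 genes for
round-trip checks. Tolerances: IRLS convergence $10^{-8}$; Deming
closed-form agreement $10^{-8}$; recovery criteria (median absolute error
< 0.05 log2 per copy, null p < 0.05 fraction in [0.04, 0.06], empirical
FDR ≤ 0.07, repeat-factor error < 5%) are the package's acceptance
thresholds and are asserted in `tests/testthat/test-acceptance.R`.

## Known limitations

* No dispersion shrinkage: per-gene moment estimates are noisier than a
  trended-shrunken estimator for small counts; reported log2 fold changes
  are unshrunken MLEs.
* The GC correction is bin-median scaling, not a read-level model; it
  assumes the single-copy region spans the GC range of the repeat
  windows.
* The escape meta-analysis reproduces the synthesis *rules*, not the
  published per-gene calls, which depend on the five studies' own
  supplementary tables.
* `vst_log()` is not a dispersion-based variance-stabilizing transform;
  it is adequate for ordination, not for downstream inference.
* Gene identifiers are opaque strings; no identifier mapping is bundled.
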