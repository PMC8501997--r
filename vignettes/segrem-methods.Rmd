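---
title: "Methods: MDL segmentation and regression refinement of regulatory elements"
author: "segrem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MDL segmentation and regression refinement of regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrem)
```

## The problem

Paired epigenomic and transcriptomic cohorts — the same donors assayed for,
say, DNase1 accessibility and RNA-seq — make it possible to ask which
genomic intervals around a gene carry signal that tracks the gene's
expression across individuals. `segrem` answers that question without a
peak-calling step: it searches the raw per-base signal in an extended gene
window for segments whose class-conditional statistics justify their own
description, links the surviving segments to the gene by regression, and
attaches effect sizes and significance to each regulatory element (REM).
Identification and linkage are one joint problem, not two stages glued
together.

## The segmentation model

For a gene $g$, let $D_g$ be the $m \times n$ matrix of signal (samples by
positions) over the window: the gene body extended 25 kb 5' of the TSS and
25 kb 3' of the TTS by default. Each sample carries a discrete expression
class $c \in C$ obtained by mixture-model discretization (below). A
*segmentation* $S_g$ is an ordered, non-overlapping cover of the $n$
columns. It is scored by a two-part code length

$$L(D_g, S_g) = L(S_g) + L(D_g \mid S_g),$$

minimised over all segmentations with every segment at least $\beta$
columns long. The model part encodes the number of segments under the
universal integer prior $L_\mathbb{N}$ (constant $c_0 = 2.865064$), one
mean per segment and class at data resolution $\tau$ inside the observed
signal range, and the placement of the boundaries:

$$L(S_g) = L_\mathbb{N}(|S_g|) \; + \; |S_g|\,|C| \log_2\!\frac{|\max-\min|}{\tau} \; + \; \log_2 \binom{n-1}{|S_g|-1}.$$

The data part sums, over segments $s$ and classes $k$, a Gaussian code
length for the block of values of class-$k$ samples inside $s$, weighted by
$1/|C_k|$ so that unbalanced classes contribute comparably:

$$L(D_g \mid S_g) = \sum_{s \in S_g} \sum_{k \in C} \frac{1}{|C_k|} \left[ \frac{|s||C_k|}{2}\Big(\tfrac{1}{\ln 2} + \log_2 2\pi\hat\sigma^2_{s,k}\Big) + |s||C_k| \log_2 \tau \right],$$

with $\hat\sigma^2_{s,k}$ the maximum-likelihood (divide-by-count) variance
of the block. The optimum balances boundary count against within-block
variance: splitting pays when it separates regimes, and the model cost
prevents the degenerate one-column-per-segment solution.

### Numerical choices

* **Variance floor.** $\hat\sigma^2 = 0$ (constant blocks) would give an
  infinite code length; the variance is floored at $\tau^2/12$, the
  quantisation-noise variance of data recorded at resolution $\tau$. The
  signal range in the model cost is floored at $\tau$ so its logarithm is
  non-negative.
* **Range convention.** $|\max - \min|$ is computed once over the whole
  matrix, not per segment — the parameter cost prices means against the
  data's global dynamic range.
* **$\tau$ direction.** As the score is written, the data term carries
  $+|s||C_k|\log_2\tau$, so for fixed segmentation the data part *shrinks*
  as $\tau$ decreases while the model part grows; the block-level scaling
  identity $\Delta = |s||C_k|\log_2(\tau_2/\tau_1)$ is asserted in the test
  suite. The default is $\tau = 1$, appropriate for count-like tracks (the
  score only requires $\tau \le 1$).
* **Deterministic tie-breaks.** Cost ties resolve toward fewer segments,
  then toward the earlier last boundary, so runs are reproducible and
  comparable against enumeration.
* **Exactness by construction.** The dynamic program (in C++) evaluates
  block costs with the same floating-point operation order as the exported
  R cost functions — extended-precision accumulators matching R's `sum()`,
  identical expression structure — so its optimum equals an exhaustive
  enumeration built on the R functions *bit for bit*. The test suite
  asserts identity (`expect_identical`) on hundreds of random instances.
* **Complexity.** The DP is $O(n^2 \cdot n/\beta)$ after an $O(mn^2)$ cost
  table. Windows are split into chunks of 5000 columns processed
  independently (segments never span chunk borders; a terminal remainder
  shorter than $\beta$ becomes one short segment). Chunks share no state,
  so callers may parallelise across them and across genes.

### Minimum segment size and binning

$\beta = 10$ columns by default. Two readings of the published parameter
pair "segment-size 5000, resolution 10" are possible; the methods-level
definition fixes $\beta = 10$ and chunk length 5000, which is what this
package implements. A 10-bp *binning* reading is still available through
`build_signal_matrix(bin_size = 10)` for experimentation. A consequence of
$\beta$ worth knowing: structure narrower than $\beta$ — including gaps
*between* elements — cannot be isolated by any admissible segmentation, so
nothing narrower than $\beta$ should be simulated or expected.

## Expression discretization

Each gene's expression vector is discretized into 2 or 3 classes by
univariate Gaussian mixtures on $\log(y+1)$ (unequal variances, fitted with
**mclust**), the two fits compared by BIC. A raw likelihood comparison
cannot choose between nested mixtures — the 3-component fit never loses —
so a penalised criterion is the coherent reading of "higher likelihood".
Components are ordered by mean, labels are MAP assignments, and a component
left empty after MAP labelling triggers a refit with one fewer class (the
$1/|C_k|$ weights require every class non-empty). Essentially constant
expression yields a single-class, non-informative assignment and the gene
is skipped. The established mixture package is used rather than a bespoke
EM: it is deterministic, numerically hardened, and selects exactly the
model the discretization needs.

## Candidate selection

Every segment of the optimum is correlated (Pearson and Spearman; Spearman
decides by default) with the *continuous* expression across samples;
segments with $P \le 0.05$ (two-sided — repressors are wanted) become
candidates. Per-segment signal is the per-sample **sum** over the segment's
columns; within a gene, sum versus mean changes no correlation. No
multiple-testing correction is applied here — correction happens once, at
the model level, across genes. Constant-signal segments (common: most of a
window has no accessibility) are silently non-candidates.

## Regression refinement

Candidate signals $X$ and expression $y$ are log-transformed with a
pseudo-count of 1, centred and scaled; an elastic net is fitted in a
ten-fold outer Monte Carlo cross-validation (random 80/20 splits), with the
penalty strength $\lambda$ and the mixing parameter $\alpha$ (grid 0 to 1,
step 0.01) chosen per split by an inner six-fold cross-validation
minimising mean squared error (the `lambda.min` rule, via **glmnet**).

**Penalty convention.** The package writes the penalty as
$\lambda[\alpha\|\beta\|^2 + (1-\alpha)\|\beta\|_1]$ — $\alpha$ weights the
*ridge* term. glmnet's mixing parameter weights the L1 term, so internally
`alpha_glmnet = 1 - alpha`; glmnet's extra $1/2$ on its ridge term is
absorbed by the tuned $\lambda$ and never observable through the chosen
model. Reported $\alpha$ values are in the package's convention.

Held-out performance is reported as Pearson $r$, Spearman $\rho$ and MSE.
The model p-value sent to the across-gene correction is the Pearson
correlation p-value between held-out predictions and observations
*concatenated over the ten outer folds* (pooling is one of several
defensible choices; per-fold combination was the alternative). Centring and
scaling are estimated on training samples only and applied to the held-out
side — standard leakage hygiene, possibly stricter than the original
formulation, which does not state it.

Across a cohort, model p-values are Benjamini–Yekutieli corrected
(dependence-robust FDR) and models pass at $q \le 0.05$. Because the
correction depends on the gene set, q-values are recomputed whenever the
set changes; single-gene runs report raw p-values. Features with a non-zero
median coefficient across the ten folds ($|\mathrm{median}| > 10^{-12}$)
form $X_{NZ}$, capped at the training-sample count; an ordinary
least-squares fit on $X_{NZ}$ supplies the per-element coefficients and
t-test p-values attached to the final records. OLS coefficients are
comparable across genes (no shrinkage bias); OLS is never used to judge
performance.

## Nested execution and down-sampling

The default protocol selects features on all samples, so its held-out
correlations inherit an optimistic bias: chance-correlated candidates keep
their correlation in folds drawn from the same data. The *nested* mode
removes the circularity — in each of 10 Monte Carlo repetitions,
discretization, segmentation, candidate selection and the elastic-net fit
see only the 80% training side, and the untouched 20% is scored. The
*down-sampling* mode additionally thins the training side to fractions 0.4
through 1.0 before fitting, tracing the method's data appetite. Both are
performance-estimation protocols: they return per-repetition performance
tables, and the element catalogue itself comes from the default mode (the
candidate set differs across nested repetitions, so a single pooled
coefficient table would be ill-defined).

## Validation machinery

For enrichment against external interval evidence, the package builds ten
background sets per element catalogue, matching each gene's elements in
count, length and side relative to the TSS; backgrounds are placed at
distance $d \cdot W$ from the TSS with $d \sim \mathrm{Exp}(7)$ and $W$ the
window span. The published rate has no stated units; modelling distances as
Exp(7) *fractions of the window span* concentrates backgrounds near the TSS
(mean placement $\approx W/7$), which is the stated intent; the rate is a
config knob. Clipping at the chromosome start shifts rather than truncates
intervals, preserving the length multiset exactly. No exclusion of the real
elements is applied. The observed count of elements supported by same-gene
annotations (or by interaction anchors: one anchor on the element, the
other anywhere on the linked gene's body, in either orientation), divided
by the mean background count, is the OE ratio. When annotations are drawn
from the background process itself the ratio is calibrated at 1, which the
test suite checks. For experiment design, `rem_activity_score()` ranks
elements by coefficient × condition-specific signal abundance.

## What the generators emulate — and what they do not

`simulate_locus()` produces exactly the block structure the code length
assumes: class-conditional Gaussian blocks on a noisy background, clipped
at zero. `simulate_regulatory_gene()` adds the generative model of the
refinement: five true elements whose summed signal drives log-expression
linearly ($b = (1, 0.8, 0.6, -0.8, -1)$: activators and repressors), decoy
elements sharing a sample-level "accessibility program" latent but — by
default — independent of expression, and expression emitted as
$\exp(\cdot)-1$ of an affine map of the predictor so the pipeline's
$\log(x+1)$ recovers linearity. Default conditions: $m = 60$ samples,
signal-to-noise ratio 3 on the predictor, peak activity $10 \pm 2$ over
background 0.5 with unit noise (an order-of-magnitude peak-to-background
contrast, as in accessibility data), element length 20 and gap 15 columns
(both above $\beta$, see above), 20 decoys — about 51 scored segments per
locus. Clipping at zero slightly biases means near zero; the tests measure
means after clipping.

Passing tests on this generator show that the score separates
class-conditional regimes of realistic contrast, that the refinement
recovers sparse signed truth under moderate noise, and that the protocols
rank as expected. They do not show robustness to unmodelled features of
real data: mappability artefacts, copy-number variation, correlated
neighbouring elements, batch structure, non-Gaussian heavy tails, or
cross-gene sharing of elements.

## Problem sizes in the shipped tests

The suite runs the enumeration-equivalence check on 200 instances with up
to 11 columns (enumeration is $2^{n-1}$), boundary recovery on 50
two-regime loci ($40 \times 100$), the label-permutation control on 50
matched instances, recovery and precision on 10 seeded loci at the default
conditions, the nested-versus-default comparison paired over 20 seeds and
the down-sampling trend over 10 seeds with fractions
$\{0.4, 0.6, 0.8, 1.0\}$ — with 5 Monte Carlo repetitions per gene and a
coarser $\alpha$ grid (step 0.1–0.2) in the heavy experiments. These are
the package's chosen experiment sizes; the defaults in `reg_config()`
(grid step 0.01, 10 repetitions) remain the method's reference settings.

## Known limitations

* Segments never span chunk boundaries; a boundary falling exactly on a
  multiple of 5000 columns is forced even if the optimum would merge
  across it.
* `lambda.min` mildly over-selects: candidates that passed the marginal
  filter by chance are often retained with small coefficients in the
  default protocol, since their in-sample correlation persists in every
  outer fold. This is the selection-circularity the nested mode exposes
  (its held-out correlations are systematically lower); consumers wanting
  stricter catalogues should filter records on the OLS p-values the
  package reports.
* The BY gate is cohort-relative: adding or removing genes changes every
  q-value.
* Whether the original window extension is strand-aware is not documented;
  this package extends strand-aware (upstream of the TSS along the gene's
  own orientation). On the minus strand the numeric window is mirrored;
  with equal extensions the result is identical.
* Exp(7) background distances are interpreted on the window-span scale —
  a unit choice, exposed as a parameter.
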