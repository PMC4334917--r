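---
title: "Pharmacometabolomic discrimination and pathway impact: models and choices"
author: "MetaboImpact authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacometabolomic discrimination and pathway impact: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboImpact)
```

# The analysis problem

Targeted plasma metabolomics by LC-MS/MS produces a table of integrated
peak areas — here samples from a four-group treatment study (wild-type
and *Fmr1*-knockout mice, each given saline or the purinergic antagonist
suramin) by several hundred metabolites, plus spiked stable-isotope
internal standards.  The scientific questions are: which metabolites
discriminate treated from untreated knockouts, which biochemical
pathways concentrate that discrimination, in which direction each
metabolite moved, and how the affected pathway set compares across
disease models.  MetaboImpact implements this chain as composable,
tested stages with a synthetic-data generator whose ground truth makes
the statistical behaviour of the whole pipeline checkable.

# Preprocessing

**Internal-standard normalization.**  Stable-isotope internal standards
are spiked into every sample at fixed amounts, so their measured signal
tracks per-sample and per-batch measurement scale.  For sample $i$ the
scale factor is

$$ s_i = \frac{\operatorname{median}_k(\text{IS area}_{ik})}{r}, $$

and every non-IS area is divided by $s_i$.  The reference $r$ is the
grand median over samples of the per-sample IS medians (configurable to
$r = 1$).  With the grand-median reference, normalized values keep the
original magnitude scale, which keeps downstream log values
interpretable; the choice cancels out of every between-group statistic.
When a per-sample multiplicative factor applies to all peaks including
the internal standards, normalization removes it exactly, and it is
idempotent once the IS columns are reattached at factor 1 — both are
asserted as test invariants.

**Missing values.**  Empty cells in the peak table are missing
(undetected), not zero; zero is a legal measured value.  Missing cells
are imputed as half the minimum observed positive value of that
metabolite — the small-value replacement conventional in targeted
metabolomics, reflecting that non-detection usually means
below-detection-limit.  Metabolites missing in more than half the
samples are flagged in the provenance record; a metabolite with nothing
to anchor the replacement is an error rather than a silent guess.

**Log transform and autoscaling.**  Values are log-transformed (base 10
by default; the base is recorded and the choice cancels from
SD-standardized statistics) and then mean-centered and unit-variance
scaled per metabolite ("autoscaling").  Centering is mandatory for
partial least squares; unit-variance scaling is the common default for
metabolomics discriminant analysis and can be switched off.
Zero-variance metabolites are centered only and flagged, not dropped.
When a model is fitted on a subset of samples (the two-class contrast),
scaling is performed within that subset.

# PLS-DA and VIP

Discrimination uses partial least squares discriminant analysis: PLS2
regression of the group indicator matrix $Y$ ($n \times g$, one column
per group) on the metabolite matrix $X$, fitted by NIPALS one component
at a time:

$$ w = X^\top u / \lVert X^\top u \rVert, \quad t = Xw, \quad
   q = Y^\top t / t^\top t, \quad u = Yq $$

iterated to convergence, followed by deflation of $X$ by $t p^\top$
(with $p = X^\top t / t^\top t$) and of $Y$ by $t q^\top$.  The
explained class sum-of-squares per component is
$ss^Y_a = (q_a^\top q_a)(t_a^\top t_a)$.  Variable importance in
projection aggregates the squared weights over the $A$ fitted
components:

$$ \mathrm{VIP}_j \;=\; \sqrt{\; p \cdot
   \frac{\sum_{a=1}^{A} ss^Y_a \, w_{ja}^2}{\sum_{a=1}^{A} ss^Y_a}\;} $$

with unit-norm weight columns, so $\tfrac1p\sum_j \mathrm{VIP}_j^2 = 1$
for every fit — a property the test suite asserts on random matrices,
alongside the equivalence of the one-component weight with the dominant
left singular vector of $X^\top Y$ and elementwise agreement with an
independent PLS-DA implementation (mixOmics).

Metabolites with VIP at or above 1.5 are called significant.  The
boundary is inclusive by default (configurable), since a score exactly
at threshold belongs to the reported significant set in the convention
this package follows.  Two fit modes are provided: the two-class
contrast (default KO-Sal vs KO-Sur) that feeds the significance call and
the pathway statistic, and the all-group fit whose first three score
columns give the 3-D class-separation projection.

**Numerical choices.**  NIPALS convergence is declared when the score
vector changes by less than $10^{-10}$ in Euclidean norm, with an
iteration cap of 5000 per component: four-class fits in which two groups
are essentially indistinguishable have nearly degenerate class
directions and legitimately need on the order of a thousand power-like
iterations.  Sign indeterminacy is resolved by making each weight
column's largest-magnitude entry positive, and the latent vector is
initialized from the $Y$ column with the largest residual variance, so
fits are bit-reproducible.  Components beyond the rank of $X$ are
dropped with a warning rather than an error.

# The pathway impact statistic

For every pathway with at least one significant metabolite the impact
table reports: the pathway size $N$ (metabolites measured in it), the
expected proportion $P = N / \text{total measured}$, the expected hits
$P \times n_{\text{sig}}$ under proportional allocation, the observed
hits, the fold enrichment observed/expected, the *impact* — the sum of
VIP scores of the pathway's significant metabolites — the fraction of
the table-wide total impact, and counts of metabolites increased versus
decreased by treatment.  Rows are ordered by impact, ties broken by
pathway name.  No enrichment p-value is attached: the statistic is a
ranking and effect-size device, and none is computed upstream.

Display rounding follows the convention under which the reference
worked example reproduces exactly: $P$ is rounded first (3 decimals, 2
when $P \ge 0.1$), expected hits are computed from the rounded $P$ and
rounded to 2 decimals, and fold enrichment divides observed hits by the
rounded expected value (e.g. $41/673 = 0.061$, $0.061 \times 58 = 3.54$,
$5/3.54 = 1.41$).  Unrounded shadow columns are kept alongside in every
output, and all conservation identities (hits sum to $n_{\text{sig}}$,
impacts to the total, fractions to 1) are checked on construction.

**Replay mode.**  The reference study reports pathway-level summed VIP
scores but not per-metabolite values, and deposits no raw data.  For
arithmetic verification independent of any stochastic fit,
`replayVipTable()` builds a *synthetic* VIP ranking consistent with the
published pathway summary: each pathway's summed VIP is split equally
across its observed hits.  The published per-row impacts sum to 136.2
while the published total is 136.0, and no single rounding rule
reconciles every printed fraction with either total; the reconstruction
therefore lowers five single-hit/low-rank rows by 0.04 (within their
printing precision), which restores a consistent table: every
reconstructed sum still rounds to its printed impact and reproduces its
printed fraction, and the total is exactly 136.0.  This reconstruction
is a labelled synthetic stand-in, not recovered data.

# z-score effects, colors, and the network

The per-metabolite effect metric is
$z = (\bar{x}_{\text{treat}} - \bar{x}_{\text{ctrl}}) / s_{\text{ctrl}}$
with the sample ($n-1$) SD of the *control* group in the denominator,
computed by default on the normalized concentration scale (matching the
"mean concentration" wording of the source convention) with a
`scale = "log"` switch.  Because the denominator follows the control
group, swapping the two groups negates $z$ exactly only when the groups
share their dispersion; in general the sign always flips while the
magnitude follows the new control SD.  Metabolites with zero control SD
are excluded and reported, not silently given infinite scores.

Colors interpolate linearly from white at $z = 0$ to red at $z = +2$
and green at $z = -2$, clamped beyond $\pm 2$ (so $z = +1$ is exactly
`#FF8080`).  The network is a star topology — one hub node per pathway
annotated with its impact and fraction, one leaf per metabolite
annotated with $z$, color, VIP and significance — because within-pathway
biochemical wiring is presentation, not data, in this analysis.  Export
formats are SIF plus a node-attribute TSV, or GraphML; the GraphML round
trip is isomorphic with identical leaf attributes.

# Cross-model pathway overlap

Pathway names appear under variant spellings across reports ("NAD+
metabolism" vs "Vitamin B3 (Niacin, NAD+) metabolism"; "bile acids" vs
"Bile salt metabolism").  Canonicalization is table-driven and
case-insensitive, with set-valued expansion for combined names
("sphingolipids/gangliosides" contributes both pathways).  Three sets
ship with the package: the 20 affected pathways of the Fragile X
suramin contrast, the 17 of them reported in human ASD, and the 11
shared with the maternal immune activation model.  The MIA list is the
published shared subset — its full pathway list is not enumerated in the
source — so the MIA-only Venn region is structurally empty in the
packaged data.  `intersectPathwaySets()` reports all pairwise and
higher-order intersections and exclusive Venn regions, which always sum
to the union size.

# The synthetic-data generator

`studyLikeSpec()` emulates the reference design: 673 metabolites across
60 pathways (the 20 named pathways at their published sizes, summing to
532, plus 141 metabolites over 40 unnamed filler pathways of size 3-4),
four groups of 11/10/11/9 animals (within the reported 9-11 per group),
35 internal standards (a commercial stable-isotope cocktail's worth),
and 58 planted treatment effects on the KO-Sur group, distributed per
the published observed-hits column with 33 positive and 25 negative
signs.

The generative model: per-metabolite log10 baselines
$\mu_m \sim N(5, 1)$ (areas centred near $10^5$ detector units),
within-group SDs $\sigma_m \sim U(0.05, 0.3)$ on the log10 scale,
per-sample scale factors $s_i \sim \text{LogNormal}(0, 0.2)$, log10
concentrations $N(\mu_m + \delta_{mg}\sigma_m, \sigma_m^2)$, areas
$10^{\text{conc}} \times s_i$, and IS areas exactly
$\text{base}_k \times s_i$, so dividing by the true $s_i$ recovers the
pre-scaling matrix exactly and median-IS normalization recovers $s_i$
up to the reference constant.  Non-IS cells are masked missing at rate
0.02 (IS cells are never masked — normalization requires a usable IS
signal in every sample, and a generator emitting unusable datasets
would test nothing).  Effects are expressed in within-group SD units on
the log scale so the expected log-scale z-score of a planted effect
equals its $\delta$ — which is why the recovery checks evaluate
$\hat{z}$ with `scale = "log"`; on the raw concentration scale the same
effect inflates with $\sigma_m$ (to $\approx 3$–$4$ at the upper end of
the $\sigma$ range) and is no longer calibrated against $\delta$.

**What the generator does and does not emulate.**  It reproduces the
design geometry, lognormal abundances, batch-like scale factors,
missingness, and planted effect structure; it does not simulate
chromatographic drift, detection-limit-dependent (non-random)
missingness, correlated metabolite blocks within pathways, or the real
study's unpublished effect sizes.  Passing recovery tests therefore
demonstrates that the pipeline's statistics behave correctly under the
stated model, not that the original biological effect sizes are
re-derivable.

# Problem sizes used by the checks

The test suite fits PLS-DA on random matrices of 8-20 samples and 4-15
variables for the algebraic invariants (100 fits each for the VIP-norm
and SVD-oracle checks), compares the impact table against a
first-principles recomputation on 200 random instances of up to 10
pathways and 30 metabolites, and runs parameter recovery on study-like
data (673 metabolites, 10 animals per group, $|\delta| = 2$) over 20
replicate seeds, asserting a median VIP-ranking AUROC above 0.90 for
planted versus null metabolites and a median planted $\hat{z}$ inside
$[1, 3]$.  These sizes were chosen so the whole suite runs in about a
minute while keeping the Monte-Carlo envelopes comfortably away from
their thresholds.

# Known limitations

Exact VIP values of the reference study are not reproducible: the raw
data are not deposited and the original web-tool's scaling options are
unrecorded, so numerical agreement is claimed only for the arithmetic
replay and the statistical-behaviour checks.  The impact statistic
carries no inferential error control.  Batch handling is limited to
IS scaling (no injection-order drift correction; a per-batch reference
is configurable but defaults to global).  The pathway map requires
exactly one pathway per metabolite — multi-pathway membership would
need a weighting convention the source statistic does not define.
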