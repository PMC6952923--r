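---
title: "Hydrogen-bond-site scoring of miRNA sequences on a torus: methods and design"
author: "miRTorus authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond-site scoring of miRNA sequences on a torus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRTorus)
```

## The representation

RNA–RNA interactions are mediated by hydrogen bonds, and each nucleobase
offers three donor/acceptor sites. miRTorus encodes a base as the triple of
partial charges at those sites (elementary-charge units, used as
dimensionless numbers):

```{r}
chargeTable()
```

These four triples are fixed constants of the method — the package never
re-derives them from quantum chemistry, and the averaging of the two
amino-group hydrogens at a First site is already folded into the printed
values. The First site of A carries its amino group, so A's weakly bonding
Third site (a ring C–H) is kept anyway: all four bases then share one
representation, and the field-based scores need a charge at every site.
U's Third site is kept because of the G·U wobble pair. Whether
down-weighting A's Third site would change downstream results is untested
here; the encoding treats all twelve charges uniformly.

A sequence of length $n$ becomes the site-major *ternary vector*
$(e_{11},\dots,e_{1n},\,e_{21},\dots,e_{2n},\,e_{31},\dots,e_{3n})$, where
$e_{ij}$ is the charge of the $j$-th base at the $i$-th site. "Ternary"
refers to the three sites, not to three dimensions.

## The torus geometry

Two of the four scores need coordinates. The sequence is laid on a circle —
a torus in the topological sense, motivated by circular and clover-shaped
RNAs being topologically toric and by a circle being a tractable
approximation between "no structure" (a string) and "too much structure"
(a real tertiary fold). The conventions, with their rationale where the
underlying constants leave freedom:

* **Anchor spacing, 12.9 Å.** Treated as *arc* length: the circle radius is
  $R = n \cdot 12.9 / (2\pi)$ and base $j$ sits at angle $2\pi(j-1)/n$.
  Arc (rather than chord) keeps inter-base spacing exactly uniform for
  every $n$; for mature-miRNA lengths the two readings differ by under 1%
  in $R$.
* **Site offsets 1.915 / 4.300 / 6.685 Å.** The base segment is 8.6 Å long
  but the three sites span only $2 \times 2.385 = 4.77$ Å, leaving their
  placement on the segment free; centering the site span on the segment
  midpoint (4.3 Å) is the symmetric choice.
* **Site order.** The First site is placed innermost (nearest the backbone
  circle), Third outermost. The published figures do not fully pin this
  down, so it is configurable (`firstSiteInnermost = FALSE` reverses it).
* **Orientation.** The base segment is the outward radial direction tilted
  toward +z by 0° (Structure A, in-plane), 90° (Structure B,
  perpendicular) or 45° (Structure C). `buildStructure()` exposes the tilt
  as a continuous `angle`, which the tests use to verify that C converges
  to A and B at the limits.
* **Gauge.** Base 1 is anchored on the +x axis and the origin is the circle
  centre. Field *norms* are invariant under this rotational gauge; field
  *components* are not, so component-level comparisons between
  implementations with a different phase convention can disagree while all
  norms, duplicate counts and slope comparisons agree. A sequence of
  length 1 defines no circle and is rejected.

## The four scores

* **VS** $_i = \sqrt{\sum_j e_{ij}^2}$ and **Sum** $_i = \sum_j e_{ij}$ are
  structure-free and permutation-invariant: they see composition, not
  order.
* **EV_C** is the point-charge field
  $\sum q\,\mathbf{r}/|\mathbf{r}|^3$ of all $3n$ sites evaluated at the
  torus centre.
* **EV_S** sums that field over an $11^3$ lattice: each axis of the
  bounding box of the sites is divided into 10 equal parts (11 values,
  indices $-5..5$), giving 1331 points.

Both field scores are *proportional* forms: the physical prefactor
($1/4\pi\varepsilon_0$, elementary charge, Å scaling) is dropped, so EV
values are arbitrary units and only ratios and comparisons are meaningful.

Numerical choices:

* For Structure A the z coordinate is set to exactly 0, so the z component
  of both field scores is exactly zero — this is what produces the `NA`
  axis pairs (y–z, z–x) in regression and discrimination tables for
  EV_C_A/EV_S_A.
* A degenerate bounding-box axis (z under Structure A) keeps its 11
  identical grid values: the triple sum is taken literally and the
  constant ×11 multiplicity is absorbed by the proportional form.
* A lattice point that falls on a charged site (the bounding box corners
  touch the outermost sites by construction) would make one term singular;
  that single charge contribution is skipped and counted in a warning.
  The skipped terms are the method's own boundary artifact, shared by any
  faithful implementation of the lattice definition.
* Duplicate detection rounds score triples to 10 decimals before
  comparison so floating-point noise cannot split true duplicates; the
  reported percentage of unique vectors is rounded to integer percent.

## SMEL and disease discrimination

Given per-disease expression records (fold change FC > 0 and/or log2FC;
whichever is absent is derived from the other), $\mathrm{SMEL} =
\text{score} \times x$. FC and log2FC are parallel tracks and are never
mixed in one regression.

Regressions are ordinary least squares on the cyclic axis pairs x–y, y–z,
z–x (first component predicts the second). Raw-score regressions keep an
intercept; SMEL regressions force it to zero, since SMEL is an exact scalar
multiple of the score and its point cloud passes through the origin by
construction. Both are flags. The reported dispersion is the *slope
standard error* (magnitudes of a few hundredths on thousand-point fits are
consistent with a standard error, not a sample standard deviation), the
p-value is the slope t-test, and the fit statistic is the signed
$\mathrm{sign}(\text{slope}) \cdot r^2$ (plain $r^2$ is also returned);
through-origin fits report the uncentered $r^2 = 1 - \mathrm{RSS}/\sum
y^2$. Zero-variance predictors and fewer than 3 points are errors;
identically zero axes are reported as `NA` rather than fitted.

Two diseases differ on an axis pair at level $k \in \{1,2,3\}$ when their
slope $\pm\, k \cdot SE$ intervals are disjoint; an axis pair is marked `o`
when *every* disease pair differs, `x` otherwise. No multiple-testing
correction is applied across axes, methods or disease pairs — the
interval-overlap rule is already conservative and keeping it raw preserves
comparability of the o/x matrices; treat the marks as descriptive, not as
calibrated hypothesis tests.

The FC outlier rule sorts a disease's FC values in descending order and
scans from the top: while a value is at least twice the next smaller one it
is removed; the scan stops at the first gap under 2×. The rule's wording
("the larger value") could also be read as removing everything above *any*
2× gap; that more aggressive reading is available as `scanAll = TRUE`, but
the leading-scan reading is the default because it is the literal
sequential reading and is idempotent. log2FC values are never filtered.
Whether whole-corpus regressions should use all sequences or only unique
score vectors is likewise not forced: `uniqueOnly` toggles it, defaulting
to all sequences.

## The synthetic study generator

The disease panels the method was designed for are literature extractions
with no machine-readable deposit, so the package ships a seeded generator
(`simSpec()`, `simulateStudy()`) whose defaults are the study conditions
the analysis assumes:

* a pool of mature-length sequences, uniform 18–25 nt, uniform base
  composition;
* four disease labels (AD, COPD, ST, TB) with ~80 records each — the scale
  of a per-disease literature harvest of a few dozen reports;
* log2FC drawn Normal(0, 1.5) per record — roughly symmetric about zero,
  matching the shape of published differential-expression spreads — and
  FC = 2^log2FC, giving the heavy-tailed positive FC distribution;
* with probability 0.02 a record's FC is multiplied by 50 (FC track only),
  reproducing the occasional extreme fold-change that motivates the
  outlier rule;
* a per-disease *slope-separation* factor: sampling weights
  $\propto \exp(\gamma_d z)$, where $z$ is the standardized second/first
  site VS ratio, bias a disease toward miRNAs with high (or low) ratio, so
  injected $\gamma$ values pull the diseases' SMEL slopes apart in a
  controlled way. $\gamma = 0$ (the default) gives exchangeable diseases.

What the generator does *not* emulate: real miRNA base-composition bias,
length–composition correlation, shared miRNAs across diseases with
correlated fold changes, study-level heterogeneity, or any disease
biology. Passing tests on synthetic panels therefore demonstrate that the
pipeline is correct and that it discriminates when slope separation truly
exists — not that any real disease pair is discriminable.

## Problem sizes

The test suite cross-checks the vectorized field sums against brute-force
loops on sequences of up to 8 nt (relative tolerance 1e-10), OLS against
closed-form formulas at 1e-10, and runs the discrimination monotonicity
sweep over 100 seeded two-disease panels of 30 records each with VS
scores — sizes chosen so the entire suite completes in about a minute
while exercising every code path. `scripts/acceptance.R` uses a 250-sequence
pool with the full method × structure grid. The whole-corpus check against
the miRBase Release 22.1 human mature file runs only when that pinned file
is supplied locally.

## Known limitations

* The torus is a deliberate simplification: real nucleobases are tilted by
  stacking and backbone constraints, and no secondary-structure prediction
  is attempted.
* Field components are gauge-dependent (rotational phase, site ordering);
  only norms and within-gauge comparisons are portable.
* The EV_S lattice inherits boundary singularities from its definition
  (handled by skipping, above), and its bounding box — hence the score —
  is not rotation-invariant.
* Modified nucleobases and ambiguity codes are rejected, not approximated.
* The o/x discrimination matrix is descriptive; it makes no causal or
  diagnostic claim about disease biology.
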