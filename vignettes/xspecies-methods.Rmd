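---
title: "Cross-species probe masking and SFP screening: models and methods"
author: "xspecies package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species probe masking and SFP screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xspecies)
```

## The problem

High-density Affymetrix expression arrays exist for only a handful of model
species.  The cross-species ("Xspecies") workaround hybridises genomic DNA
of the species of interest onto a model-species chip: probes whose 25-mer
target is conserved light up, probes sitting on diverged sequence stay at
background.  Thresholding the gDNA hybridisation intensity and rewriting
the chip description file (CDF) without the failing probe-pairs yields a
species-specific array definition usable for transcriptomics — and, with a
suitable experimental design, the same probe-level data expose
single-feature polymorphisms (SFPs): reproducible single-probe
hybridisation differences between genotypes.

This package provides the computational core of that workflow as a
scriptable library and CLI: CEL/CDF I/O, preprocessing, retention curves,
automated threshold selection, masked-CDF generation, and SFP screening for
a four-chip single-trait bulked-segregant design.

## Retention curves and automated threshold mapping (ATM)

For a candidate cut-off $x$, let $f_1(x)$ be the number of probe-pairs with
PM intensity strictly above $x$ and $f_2(x)$ the number of probe-sets with
at least one such pair (a set is removed only when it has no retained
pair).  The vector-valued retention function $F(x) = (f_1(x), f_2(x))$ is
non-increasing, with $f_1$ falling at least as fast as $f_2$.  On real
cross-species data $f_2$ shows a plateau (conserved genes keep at least one
strong probe) followed by a quasi-linear drop; the sensible cut-offs live
at the knee between the two.

ATM locates this knee in three stages:

1. **Projection.**  Each curve point $(x, f_1, f_2)$ is projected through
   $P = B(B^\top B)^{-1}B^\top$; the default basis $B = (0,0,1)^\top$ keeps
   the retained-probe-set coordinate, which carries the knee.  The
   projected values are rescaled to $[0,1]$ so clustering is
   scale-invariant; all reported intervals are in threshold units.
2. **Fuzzy c-means.**  The learning set is clustered by FCM, minimising
   $J_q = \sum_i \sum_j m_{ij}^q d_{ij}^2$ with alternating membership and
   centroid updates.  Clusters are relabelled by descending centroid, so
   cluster 1 is the plateau and cluster 2 the first drop cluster.  The
   *tolerance interval* $I$ runs between the two cluster anchors (the
   points of maximal membership in clusters 1 and 2; membership ties —
   crisp partitions — resolve towards the knee).  The *fuzzy boundary* is
   the set of points with membership at least $\varepsilon$ in **both**
   clusters; its extremes span the *target interval* $I'$.
3. **Interpolation.**  $\bar u$ is the arithmetic mean of the projected
   values over the boundary; the suggested cut-off $x_{ATM}$ is the
   piecewise-linear inverse of $f_2$ at $\bar u$, restricted to $I'$ (a
   quadratic Lagrange inverse is available as an option).  Flat runs equal
   to $\bar u$ resolve to their midpoint; a $\bar u$ outside the range of
   $f_2$ over $I'$ clamps to the nearer endpoint with a warning.  By
   construction $x_{ATM} \in I' \subseteq I$.

Cluster quality is scored by the Fukuyama–Sugeno index
$FS_q = \sum_{i,j} m_{ij}^q (d_{ij}^2 - \lVert\omega_i - \bar u_g\rVert^2)$
(recommended default) or by partition entropy
$PE = -\tfrac1n \sum_{i,j} m_{ij}\ln m_{ij}$; `select_c()` picks the
cluster count minimising either over a candidate range.

**Defaults and why.**  Fuzzifier $q = 2$ and 10 seeded restarts keeping
the lowest $J_q$ are standard FCM practice; $c = 3$ suits the
plateau / drop / tail anatomy of these curves, with index-driven
auto-selection over $2..6$ optional; $\varepsilon = 0.1$ ("at least 10%
membership in both clusters") with automatic halving down to $10^{-3}$
when a partition is too crisp; convergence at a maximum centroid shift of
$10^{-6}$, capped at 300 iterations.  The threshold grid defaults to
$0..1000$ in steps of 1, the grid used by the published case studies.
Coincident points and centroids receive full membership in the coincident
cluster (split on ties), the standard FCM degeneracy rule.

**Low confidence.**  When the tolerance interval spans more than 30% of
the threshold grid the knee is poorly localized — the behaviour of
plateau-free, quasi-linear curves — and the result carries
`low_confidence = TRUE`.  The suggestion is still returned; the flag is
advice to inspect the curve.

## Preprocessing

Background correction uses the exponential–normal convolution model
(observed = exponential signal + normal noise), replacing each intensity by
the strictly positive posterior mean
$E[s\mid x] = a + \sigma\,\phi(a/\sigma)/\Phi(a/\sigma)$,
$a = x - \mu - \sigma^2\alpha$.  The model parameters are estimated per
chip, deterministically: $\mu$ as the mode of the intensities below their
75th percentile (512-bin density), $\sigma$ from the RMS of deviations
below $\mu$ (left-half estimator), $\alpha$ as the reciprocal mean excess
above $\mu$ — the usual RMA-style recipe.  Quantile normalization forces
every chip onto the across-chip mean of order statistics; ties receive the
mean of their tied quantile slots, which makes the transform deterministic
and (on tie-free data) exactly idempotent.  With ties the tied columns are
stable but their averaged values perturb the common distribution at order
$1/n$ on a second application — the same behaviour as
`limma::normalizeQuantiles(ties = TRUE)`, which the test suite uses as an
independent oracle.  The pipeline order is background correction first,
then normalization, as in RMA.  Whether masking should use raw or
preprocessed intensities is left to the caller (`--raw` / `--no-bg` /
`--no-norm`); the published case studies do not say which was used, so
both paths are exposed.

## The four-chip design and SFP screening

The single-trait design hybridises four gDNA samples: parents
$\mathfrak{B}_1, \mathfrak{B}_2$ and two phenotypically contrasted F2
bulks $\mathfrak{B}_3, \mathfrak{B}_4$, paired
$\mathfrak{B}_1\!\sim\!\mathfrak{B}_3$ vs
$\mathfrak{B}_2\!\sim\!\mathfrak{B}_4$.

**DFC (dual fold-change).**  With ratios $Q^1 = b^1/b^2$ (parents) and
$Q^2 = b^3/b^4$ (bulks) mapped to symmetric fold-changes
($q \mapsto q$ if $q \ge 1$, else $-1/q$), a probe is a DFC hit when all
four intensities exceed the gDNA threshold (normally $x_{ATM}$), both
$|FC^1| \ge \epsilon_1$ and $|FC^2| \ge \epsilon_2$, and the two
fold-changes agree in sign — the bulks acting as a cross-check that the
parental difference segregates with the trait.

**POST (probe-wise one-sample tests).**  Between groups, each probe's
MA-value $\rho = (\log_2 Q^1 + \log_2 Q^2)/2$ is compared with the other
$n_i$ probes of its set:
$T = (\rho_k - \bar\rho_{(k)}) / (S_{(k)}\sqrt{1 + 1/n_i})$, $t$ with
$n_i - 1$ df.  The $\sqrt{1+1/n}$ prediction factor reflects that probe
$k$ is excluded from the reference sample; without it the test would be
anti-conservative (and would fail the null-calibration test in the suite).
Within a group the intensity *difference* ($D$-value; $b^1 - b^2$ or
$b^3 - b^4$) replaces the ratio, and because a set may carry more than one
SFP the location/scale estimates are robust: the $\gamma$-trimmed mean and
$\gamma$-Winsorized variance with $h = \lfloor\gamma n_i\rfloor$,
studentized as
$t = (\delta_k - \bar\delta_{(k)}) / (s_{(k)} / ((1 - 2h/n_i)\sqrt{n_i}))$
with Tukey–McLaughlin $n_i - 2h - 1$ df.  The scale uses the *realized*
trim fraction $h/n_i$ rather than $\gamma$ itself so that $h = 0$ recovers
the ordinary one-sample $t$ exactly.  For $n_i < 18$ Patel's small-sample
scaling $a(n,h) = 1 + 16\sqrt{h}\,e^{2h-n}$ multiplies the statistic
(switchable; the matching refined df is not published, so the
Tukey–McLaughlin df is kept).  Default $\gamma = 0.1$ tolerates two SFPs
per 11-probe set.  Zero-spread reference samples give $p = 1$ when the
probe agrees and the smallest representable $p$ (flagged degenerate) when
it does not; sets with fewer than 3 probes are skipped.

All p-values are two-sided; Benjamini–Hochberg adjustment is applied
separately to the between-group and the two within-group families.  The
volcano filter (VP) combines adjusted between-group significance with an
MA cut-off and optional bulk-fold-change and intensity-threshold
conditions; the twin-volcano filter (TVP) requires within-group
significance together with a large fold-change difference
$FCD = \mathrm{sign}(\delta)\sqrt{|\delta|}$ in the significant group,
recording which group drove the flag.

**Euler partition and candidates.**  Four canonical screens — VP4
(regions *a b d e*), DFC2 (*d e*), TVP2 (*b c e f*), TVP4 (*e f*) — define
a four-set Euler diagram.  The implementation uses a total precedence
(e = DFC2∩TVP4, d = DFC2∖TVP4, f = TVP4∖DFC2, b = remaining VP4∩TVP2,
a = VP4 only, c = TVP2 only) which reduces to the published region algebra
under the diagram's subset geometry and still labels every probe uniquely
when that geometry is violated; TVP4 ⊄ TVP2 is rejected as inconsistent.
The candidate strategy takes *e* unless its FCD only barely clears the
cut-off (margin `fcd_near`, default 0.5 on the square-root scale); takes
*b* and *a* when hybridisation is strong and the parental fold-change is
within `fcp_near` of its cut-off (default 0.15, wide enough to admit the
published worked examples at ratios 1.96 and 1.89 against a cut-off of 2);
takes *f* when the weakest intensity is within `th_near` of the threshold
(default a quarter of the threshold, which rejects the published
"very poor hybridisation" example at 42 vs 93); and never takes *c* or
*d*.

## What the synthetic generator emulates — and what it does not

`simulate_quad()` draws one base intensity per PM probe from a
two-component log-normal mix and one observation per chip with
multiplicative log-normal noise:

* **Bimodality.**  Background probes at $e^{\mu_{bg}}$ (default 40
  fluorescence units) versus hybridising probes at $e^{\mu_{hyb}}$
  (default 700), both with log-sd $\sigma = 0.45$ — a separation typical
  of the gDNA hybridisations behind the published case studies, and wide
  enough that the retention curve shows a genuine plateau-knee-drop.
* **Gene-level conservation.**  Hybridisation is assigned hierarchically
  (conserved sets hybridise at rate 0.9, others at 0.05, with the
  conserved-set fraction solving the marginal probe rate of
  `frac_hyb = 0.35`), because sequence conservation is a property of genes
  more than of individual 25-mers; this is what makes probe-sets die over
  a narrow threshold band rather than one at a time.
* **Technical noise.**  Chip-to-chip noise is log-normal with sd 0.1
  (≈10% CV), the magnitude commonly quoted for Affymetrix technical
  replicates.  Non-SFP probes carry identical gDNA dosage on all four
  chips, so this noise is the *only* source of spurious fold-change.
* **Planted SFPs.**  Each SFP multiplies one parent's intensity by
  `sfp_fold` (default 4) and propagates the same change to the paired bulk
  with probability `bulk_consistency` (default 1: fully trait-linked).

Not emulated: sequence-level probe/target mismatch structure, spatial chip
artefacts, saturation, partial bulk linkage, or probe-specific affinity
differences between the two parental genomes.  A green end-to-end test
therefore establishes that the pipeline recovers planted, fully-linked,
4-fold SFPs over technical noise — not that it would recover subtler
polymorphisms on real hybridisations, and not that the published tables
(which derive from undeposited raw data) are reproduced.

## Numerical choices and degenerate inputs

* Retention uses a strict `>` predicate, making mask flags and the DFC
  intensity condition consistent; intensities are compared as floats,
  without rounding, against the integer grid.
* Multi-chip masking thresholds the pseudo minimum array (elementwise
  minimum across chips), equivalent to requiring every chip to clear the
  cut-off.
* FCM non-convergence within `max_iter` is flagged, not fatal.
  A projected curve that is constant is an error (nothing to map).
* CEL version 3 (text) is the primary interchange format; version 4
  (little-endian binary) is supported as an extension; Command Console v1
  is not supported.  MM probes are parsed and stored but excluded from all
  computation unless explicitly requested.

## Known limitations

* The within-group trimmed test is calibrated by approximation
  (Tukey–McLaughlin df, optional Patel scaling); only the between-group
  test carries an exact-null guarantee, and only that guarantee is
  enforced by the calibration test.
* Background-parameter estimation assumes a dominant low-intensity mode;
  chips whose background is not the modal component will be
  mis-corrected.
* ATM assumes a monotone retention curve with one knee; curves with
  several plateaus report whichever knee the first two clusters bracket,
  and the `low_confidence` flag is only a coarse guard.
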