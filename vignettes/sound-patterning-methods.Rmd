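---
title: "Methods: simulating and quantifying sound-patterned microvascular networks"
author: "SonoMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying sound-patterned microvascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SonoMorph)
```

# Scope and model

SonoMorph implements the computational chain of a sound-patterning
(acoustic bioassembly) experiment in which low-frequency vertical vibration
of a cell-laden fibrin precursor excites Faraday waves whose nodal lines
collect suspended cells. Three days later the condensed endothelial and
pericyte cells have remodelled into capillary-like networks that preserve
the pattern. The package covers four stages:

1. **Standing-mode simulation.** For a round chamber the stationary surface
   displacement is $\zeta(r, \theta) = J_m(\alpha_{mn}\, r / R)\,
   \cos(m\theta)$, where $J_m$ is the Bessel function of the first kind,
   $\alpha_{mn}$ its $n$-th positive zero and $R$ the domain radius in mm.
   For a square chamber of side $l$ the honeycomb-like pattern is the
   antisymmetric superposition $\zeta(x, y) = \cos(n\pi x/l)\cos(m\pi y/l)
   - \cos(m\pi x/l)\cos(n\pi y/l)$. The drive settings (54 Hz, 1.2 g) are
   protocol metadata: experimentally they select the mode; the simulation
   is parameterized directly by $(m, n)$, here $(0, 4)$ round and $(5, 1)$
   square.
2. **Synthetic ground truth.** Generators produce patterned cell images,
   stationary controls, maturing ribbon networks and two-group protein
   abundance tables whose true parameters are recorded, so every
   quantification stage can be tested by parameter recovery.
3. **Morphometry.** Radial intensity profiles with peak/valley/FWHM
   statistics, ROI-based density enhancement, a local-thickness transform
   and FFT/structure-tensor orientation distributions.
4. **Differential expression.** Per-protein two-sample t tests on log2
   abundances with Benjamini–Hochberg control, PCA sample scores, and
   top-k selection with average-linkage ordering for heatmaps.

## The chamber-dimension question

With $R$ read as the chamber *diameter*, the $(0, 4)$ mode would place only
two nodal circles inside a 21 mm chamber, which contradicts the four
concentric cell rings the mode is meant to reproduce. SonoMorph therefore
treats the 21 mm figure as the radius of the simulated domain; the $(0,4)$
mode then has exactly four nodal circles at $R\,\alpha_{0,k}/\alpha_{0,4}$,
$k = 1\ldots4$, *counting the boundary circle $r = R$* (where
$J_0(\alpha_{0,4}) = 0$ by construction). `extractNodalSet()` counts the
boundary circle only when the simulated field itself vanishes along the
boundary, so uniform or non-modal fields are not affected.

# Numerical choices

* **Bessel zeros.** `besselZero()` brackets sign changes of `besselJ` and
  refines with `uniroot` (tolerance 1e-13). The test suite checks it to
  1e-8 against an independent oracle: a power-series evaluation of $J_m$
  for $x < 12$, switched to the Hankel asymptotic expansion beyond (the
  alternating series loses about eight digits to cancellation at
  $x \approx 20$), with bisection root finding.
* **Nodal sets.** Zero-level curves are traced by marching squares
  (`grDevices::contourLines`) with sub-cell linear interpolation; the
  near-zero mask uses `tol = 0.02` of the displacement maximum. Default
  grid 512×512. Doubling the resolution moves extracted nodal radii by
  less than one coarse-grid pitch (tested).
* **Accumulation density.** The density ridge used to bridge simulation
  and image generation is $\exp(-(d/s)^2)$ with $d = |\zeta| /
  |\nabla\zeta|$, a first-order distance to the nodal set, and $s$ fixed so
  the ridge FWHM equals the requested line width. For round $m = 0$ modes
  the generator instead uses the exact distance to the nodal circles: the
  first-order estimate is asymmetric around a circle of radius $r$ by
  $(w/2)^2/(2r)$, which at desk scale would shift the innermost ring band
  by several micrometres.

# The synthetic-data generators

**Cell images.** GFP+ cells are opaque discs of radius 7.5 µm (a typical
endothelial cell body is ~15 µm across) rendered under a Boolean model and
blurred with a Gaussian PSF of $\sigma$ = half the cell radius. The
on-pattern region is the nodal band of width 100 µm (the pattern line
width); the off-pattern GFP+ area fraction defaults to 0.05 and the
on-pattern fraction is programmed through the enhancement percentage. Disc
counts per region follow the Boolean-model inversion
$\lambda = -\log(1-f)/a$; an initial Poisson round at 85 % of the deficit
is followed by deterministically sized top-up rounds until the realized
binarized fraction is within 0.5 % of the programmed value (placement
always uniform; the realized fractions are recorded in the truth). The
default full image is 2048² px at 2.5 µm/px, a ~5 mm desk-scale stand-in
for the several-hundred-mm² chamber scans: the simulated chamber is
inscribed at 94 % of the field of view so the boundary nodal circle stays
fully visible. Tests use 256–1024² for runtime.

**Ribbon networks.** Capillary-like structures are geometric stand-ins:
smoothed random-walk centerlines (or segments of the nodal curves for
patterned networks) dilated to per-ribbon widths drawn from a normal
truncated at one pixel. The day presets carry the reported mean ± SD local
thickness of patterned (13.1 ± 24.7, 10.6 ± 18.9, 4.1 ± 9.5 µm for days
1/3/5) and stationary networks (6.6 ± 7.8, 9.3 ± 12.5, 4.5 ± 8.8 µm).
Because the SDs exceed the means, the truncated sampling shifts the
realized width distribution to the right; the sampled widths are recorded
per ribbon, and recovery tests compare the thickness-map mean to the
*area-weighted* mean of the sampled widths ($\sum w_i^2 / \sum w_i$), which
is what a per-pixel statistic estimates.

**Proteome.** Per-protein log2 baselines are Normal(20, 2); regulated
proteins shift the patterned group by ±Normal(2, 0.3) log2 units; every
sample adds Normal(0, 0.25) residual noise; abundances are $2^{\text{log2}}$.
The proteome size (4000) and the noise level are stand-ins — the study does
not report its identified-protein total or abundance variance — and are
configurable.

# Morphometry decisions

* **Radial profiles** average intensity over half-open annuli
  $[k\,dr, (k+1)\,dr)$ around the image centre (the generator's pattern
  centre); empty annuli are `NA`, never zero. Estimates that need a sample
  position (peaks, FWHM crossings) use annulus midpoints. Profiles of
  sparse disc images are smoothed before peak analysis with a
  pixel-count-weighted moving average (default 15 samples ≈ 3/8 line
  width): count weighting stops the tiny innermost annuli — where a single
  cell disc can cover whole annuli — from dominating the dynamic range,
  and a box average preserves the FWHM of the plateau-like ring peaks.
* **Peak detection** keeps local maxima with relative prominence above a
  fraction of the profile dynamic range (default 0.1; ties toward smaller
  radius). Ring quantification in the pipeline uses 0.5: patterned rings
  are ≈5× background, so half-range prominence admits every ring while
  rejecting background coverage fluctuations.
* **Ring FWHM** is measured against a baseline equal to the mean of the
  flanking valley depths, with half-maximum crossings interpolated
  linearly; one-sided non-crossings return a censored (`NA`) width with a
  warning. The midpoint of the two crossings is attached as a
  plateau-robust estimate of the ring radius and is used to centre the
  ROIs.
* **ROI layout** is automated (the study does not state a placement rule):
  three square ROIs per location at 0°, 120° and 240°, side equal to the
  100 µm line width; on-pattern at the measured ring radius,
  distal/proximal offset radially by ±1.5 line widths, control ROIs at the
  on-pattern positions in the stationary image. The enhancement denominator
  is the stationary-control mean, matching the study's "relative to
  control" definition. Patterned and control images are segmented with one
  common threshold (Otsu on the pooled histogram): per-image Otsu
  thresholds differ systematically between a patterned and a sparse image,
  which biases a ratio of area fractions.
* **Local thickness** assigns each foreground pixel the diameter of the
  largest inscribed disc containing it. The exact Euclidean distance
  transform supplies each pixel's maximal-disc radius; the disc inscription
  (pixels strictly inside each disc, painted largest-first) is implemented
  directly and is tested for exact equality against a brute-force oracle
  that enumerates every inscribed disc. The image border counts as
  background. Statistics default to foreground pixels only; the
  zero-inclusive convention is available and flagged, because the study's
  large SDs leave its convention ambiguous.
* **Orientation.** Gradients are cubic-spline derivatives (tridiagonal
  interpolating-spline solve per row/column), tensor-averaged under a
  Gaussian window of σ = 4 px with a 30 % minimum energy threshold — the
  published analysis settings. The histogram has 180 bins of 1°, a 5-bin
  periodic moving-average smooth (the upstream tool's exact kernel is not
  recoverable; both window and bin count are parameters), and sums to 1.
  `dominantAngle()` reports the circular mean on doubled angles, robust to
  the smoothing plateau. Angles are reported with y up, so a structure
  rotated counterclockwise by 45° reads +45°.
* **FFT high-pass** zeroes the centred low-frequency disc (default radius
  10 cycles/image) and always removes DC.

# Differential expression decisions

The study never defines its differential-expression criterion, so the
package's default — Welch's t-test on log2 abundances with BH $q < 0.05$
and no fold-change cutoff — is a deliberate choice; pooled-variance t and
an optional |log2FC| cutoff are flags. Two consequences at $n = 3$ per
group deserve note:

* The Satterthwaite degrees of freedom of Welch's test can drop to 2,
  which costs real power: at the programmed effects (|log2FC| = 2,
  residual SD 0.25) per-protein sensitivity is roughly 0.9, while the
  pooled test — whose $df = 4$ matches the design assumption of equal
  group variances, true for the generator — reaches the designed
  sensitivity ≥ 0.99 (both measured in the test suite). Recovered
  discovery counts under the Welch default therefore run some 5–8 % below
  the programmed subset sizes, while the pooled test slightly overshoots
  them through BH false positives. The package keeps Welch as the default
  (safer on real tables, where equal variances are not guaranteed) and
  documents the trade-off rather than tuning around it.
* The BH false-discovery proportion is verified empirically over 200
  synthetic replicates.

PCA operates on samples in centred log2 protein space; the sign of each
component is fixed by making its largest-magnitude loading positive.
Top-k selection orders by adjusted p with |log2FC| tie-breaks and orders
rows/columns by average-linkage clustering on Euclidean distances of
autoscaled values.

# What the synthetic benchmark does and does not show

The generators emulate the statistical structure the quantification
assumes: area fractions with Boolean-model overlap, PSF blur, pattern
geometry locked to the simulated modes, width-distributed ribbons,
log-normal abundances with a clean two-group shift. They do **not**
emulate cell migration or vasculogenesis dynamics, uneven illumination,
autofluorescence, segmentation-resistant texture, missing values or
MS-specific artefacts (the abundance tables are complete by construction;
a minimum-valid filter is provided for reuse on real tables). Passing
recovery tests therefore demonstrates that the estimators are correct and
calibrated on data satisfying their assumptions — not that those
assumptions hold for any particular microscope or mass spectrometer.

One quantitative caveat carries over from the study design itself: with
three 100 µm ROIs per location and a 5 % background GFP+ fraction, a
control ROI contains only a handful of cells, so enhancement recovery has
a spread comparable to the study's own reported ±100 % standard
deviations. Because the control denominator is so small-sample, a
per-replicate ratio is also inflated by Jensen's inequality
(E[1/x̄] > 1/E[x̄], roughly +20 % at this cell count). The recovery
benchmark therefore computes the enhancement as a ratio of means pooled
over the three replicate images — and pools the control ROIs of both ring
layouts, which estimate the same stationary fraction — bringing the
estimator within a few percent of the programmed value with a spread well
inside the published SDs. Tightening it further would require departing
from the prescribed three-ROI, 100 µm protocol.

# Problem sizes

Unit and property tests run on 48–1024² px images, 64² thickness-oracle
masks, and proteomes of 200–4000 proteins; the end-to-end recovery checks
use 2048² px images at 2.5 µm/px (three seeds) and a 4000-protein table,
the same sizes the acceptance script reruns.

# Known limitations

* All morphometry is 2-D (maximum-intensity-projection logic); no
  volumetric thickness, no vessel-graph topology, no lumen detection.
* The stationary mode shapes are evaluated directly; there is no fluid
  solver, no acoustic radiation force model and no time dependence.
* The square-chamber mode indices (5, 1) are taken as given; nothing in
  the package selects modes from drive parameters.
* `ROILayout` fixes three ROIs per location, matching the published
  protocol; enhancement estimates inherit that protocol's sampling noise.
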