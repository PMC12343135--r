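---
title: "Models and methods: myofibril morphometry with fibrilMorph"
author: "fibrilMorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: myofibril morphometry with fibrilMorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilMorph)
```

# Scope

`fibrilMorph` measures the two standard morphometric traits of fibrillar
muscle — sarcomere length and myofibril diameter — from two-channel
fluorescence micrographs (an F-actin/phalloidin channel and a Z-disc marker
channel), validates the measurement on simulated images with exactly known
ground truth, converts band widths into myofilament lengths, and builds
scaled models of the myofilament lattice of the *Drosophila* indirect
flight muscle (IFM). This vignette documents the models, the tunable
parameters, the numerical choices, and what the validation does and does
not demonstrate.

# The measurement models

## Sarcomere length: multi-Gaussian Z-disc fitting

A longitudinal intensity profile is recorded along the myofibril centerline
in the Z-disc channel, averaging over a narrow rectangular ROI
(`longitudinal_half_width_um`, default 0.3 µm on either side of the axis).
The profile is fitted jointly with

$$I(s) = B + \sum_{i=1}^{n} A_i \exp\!\left(-\frac{(s-\mu_i)^2}{2\sigma_i^2}\right),$$

initialised from prominence-filtered local maxima. Each $\mu_i$ is bounded
to within half the median initial peak spacing of its start value, which
prevents peak swapping during optimisation. Sarcomere lengths are the
successive differences $\mu_{i+1}-\mu_i$; since isolated myofibrils often
have damaged terminal sarcomeres, the first and last difference are dropped
by default (`exclude_terminal`, off in manual mode).

Because the photon-counting detector noise has variance roughly
proportional to the signal, the least-squares fit is repeated once with
inverse-variance weights taken from the first pass (`weighting =
"poisson"`). On noiseless profiles both passes return the same solution; on
Poisson-noisy single peaks (100-count amplitude, 0.2 µm sigma, 50 nm
sampling) the weighted fit reduces the center standard deviation from
roughly 8.5 nm to 7 nm over 100 replicate draws. Peak detection applies a
minimum separation (`0.5` µm) when accepting candidate maxima: Z-discs are
never closer than about 1 µm at any developmental stage, while Poisson
noise occasionally splits one summit into two local maxima, which would
otherwise seed a spurious doublet fit.

## Myofibril diameter: the PSF-convolved disc model

The transverse profile of a uniformly labelled cylinder of radius $R$ is
its projected chord $C(u) = 2\sqrt{R^2-u^2}$. The microscope blurs it, so
the model fitted to transverse phalloidin profiles is

$$I(x) = B + \frac{A}{2R}\,(C \ast G_{\sigma_{\mathrm{PSF}}})(x - c),$$

with $G$ a unit-area Gaussian. The convolution is evaluated numerically on
a grid no coarser than $R/50$ (and $\sigma_{\mathrm{PSF}}/4$ when blurred);
in the unblurred limit the implementation switches to the analytic chord.
The fitted diameter is $2R$. Initialisation: center at the intensity
centroid, $R$ at half the 20%-of-dynamic-range width,
$\sigma_{\mathrm{PSF}}$ at $0.21\lambda/\mathrm{NA}$ (78.8 nm for NA 1.4,
525 nm emission). Because the $(R, \sigma_{\mathrm{PSF}})$ residual valley
is shallow near $\sigma_{\mathrm{PSF}} \to 0$, the fit restarts from a
small deterministic set of PSF initialisations and keeps the best
least-squares solution.

The disc model exists to remove a bias that affects manual measurement:
the unblurred chord has FWHM $\sqrt3 R \approx 0.87\,D$, so reading widths
at half maximum systematically underestimates diameter; the model fit
recovers $D$ to better than 1% on its own noiseless profiles, and to about
3% on simulated profiles blurred with the (non-Gaussian) Airy pattern —
the Gaussian-PSF approximation bounds that residual mismatch.

Per-fibril diameter is the median of disc fits at several positions
(`n_transverse`, default 9) chosen among a three-fold denser candidate grid
ranked by local axial intensity; this keeps transverse profiles on labelled
regions and off the dim H-zone gaps, where a profile would measure only
blur bleed-through from neighbouring A-band regions (about 3% high on
noiseless fixtures).

## Segmentation and centerlines

The phalloidin channel (maximum-intensity projection for stacks) is median
filtered (3×3), thresholded (Otsu by default — parameter-free and adequate
for high-contrast isolated-myofibril preparations), morphologically closed
with a disc of `closingUm` (default 0.6 µm) so the dim H-zone gaps do not
split one fibril into per-sarcomere fragments, and labelled into connected
components. Components shorter than `min_length_um` (default 4 µm, about
one mature sarcomere plus margin) are dropped. Remaining components carry
deterministic QC flags — `touches_border`, `branched_skeleton` (more than
two skeleton endpoints, e.g. crossing fibrils), `overlaps_neighbour`
(within 2 px of another component) — and flagged components are excluded
from automatic analysis but still reported.

Centerlines come from Zhang–Suen thinning of the mask (implemented in the
package; terminal spurs of up to 5 px from the rounded caps are pruned),
ordering the skeleton endpoint-to-endpoint, and fitting smoothing splines
to $x$ and $y$ versus chord length with about one degree of freedom per
3 µm — enough to follow gentle arcs while keeping sub-pixel residuals on
straight fibrils. Thinning insets the skeleton from the fibril tips by
about one radius, so the spline is extended along its end tangents while
still inside the mask; the curve is then resampled at uniform 0.05 µm
arclength steps and trimmed by one estimated diameter per end to avoid cap
artefacts. On rendered quarter-circle arcs (radius 20 µm) the recovered
arclength is within 1% of the analytic value.

In manual mode (sectioned or microdissected muscle, where dense packing
defeats automatic segmentation) the user supplies polylines; an
interpolating cubic spline through the vertices replaces the skeleton
pipeline, and everything downstream is identical.

# The simulator

`simulateImage` reproduces the image-formation chain used to validate the
measurement pipeline:

1. **Ground truth** — each myofibril is a uniformly labelled cylinder drawn
   in 2D projection: transverse intensity is the analytic chord
   $2\sqrt{R^2-t^2}$, evaluated with 4× per-axis subpixel supersampling and
   binned to the pixel grid to avoid aliasing at 50 nm pixels; axial
   intensity is 1 in thin-filament regions, 2 inside the
   `nSarcomeres + 1` Z-disc overlap bands (two thin-filament sets overlap
   there), and 0 in the H-zone gaps. The Z-disc channel carries the chord
   restricted to the Z-disc bands. Curved fibrils are circular arcs of
   constant curvature — real IFM fibrils are near-straight, and arcs
   suffice for robustness testing.
2. **Uneven labelling** — zero-mean Gaussian noise, sd `labelNoiseSigma`
   (default 2) in grey levels of the ground truth normalised to a
   per-channel peak of 100, clipped at zero. The normalisation convention
   is the package's own choice: the noise magnitude is only meaningful
   relative to an intensity scale, and peak-100 makes "sd 2" a 2% peak
   perturbation.
3. **Diffraction** — convolution (reflect padding) with the in-plane Airy
   pattern $(2J_1(v)/v)^2$, $v = 2\pi\,\mathrm{NA}\,r/\lambda$, NA 1.4 and
   λ 525 nm by default; the kernel is normalised to unit sum and its first
   radial zero falls at $3.8317\,\lambda/(2\pi\,\mathrm{NA}) = 228.7$ nm.
   Detector-specific transfer functions (e.g. pixel-reassignment systems)
   are not modelled.
4. **Shot noise** — the blurred image is scaled by `photonScale` (default
   5 expected photons per grey level, putting simulated peaks at a few
   hundred counts, typical of confocal imaging of bright phalloidin
   samples) and Poisson counts are drawn. The same `rngSeed` reproduces an
   image bit for bit.

One caveat is documented deliberately: clipping the labelling noise at zero
introduces a small positive bias in dim regions, so the mean over many
noisy realisations exceeds the noiseless blurred image by several percent
where expected counts are low (<0.3% above 100 counts). The mean-preserving
property of the shot-noise stage is therefore asserted in tests in the
label-noise-free configuration, and only on bright pixels under full noise.

**What passing the simulation-based tests shows** — that segmentation,
profile extraction and both model fits recover known geometry through this
noise chain (mean sarcomere-length error <1%, mean diameter error <5% on a
20-fibril batch at the default noise settings). **What it does not show** —
robustness to background fluorescence and debris, uneven illumination,
out-of-focus haze in thick samples, labelling chemistry artefacts, or
detector effects beyond Poisson statistics; real micrographs vary in ways
the cylinder-plus-Airy model does not capture.

# Filament lengths and the stage table

Band widths convert to filament lengths through two identities that follow
from sarcomere geometry — thick filaments span the A-band, thin filaments
run from inside the Z-disc overlap to the H-zone boundary:

$$L_{\mathrm{thick}} = L_{\mathrm{sarcomere}} - W_{\mathrm{I\mbox{-}band}},
\qquad
L_{\mathrm{thin}} = \tfrac12\,(L_{\mathrm{sarcomere}} -
W_{\mathrm{H\mbox{-}zone}} + W_{\mathrm{Z\mbox{-}disc}}).$$

"Z-disc width" here always means the thin-filament overlap width at the
Z-disc; the package uses one symbol for it throughout. Both relations are
linear and homogeneous of degree one, which the test suite exercises as an
invariant.

The packaged stage table (`stageTable()`) covers four developmental stages
of IFM myofibrillogenesis, 36 h after puparium formation (APF) to 24 h
after eclosion (AE). Thick-filament counts (23, 32, 134, 846), lattice
spacings (53 nm early, 47 nm — the midpoint of the reported 46–48 nm range
— thereafter) and Z-disc overlaps (240, 140, 98, 94 nm) are measured
values; mature filament lengths are 3.24 µm (thick) and 1.68 µm (thin).
Per-stage sarcomere lengths are not available as printed numbers, so the
table carries representative values (1.80, 2.20, 3.00, 3.40 µm) chosen once
to match the known developmental growth course, and the I-band/H-zone
widths are then fixed by inverting the two identities against the measured
filament lengths — so every `StageMorphometrics` object satisfies both
identities exactly, which its validity method enforces. Analyses of real
data should replace these defaults with measured band widths
(`stageTable(path)` accepts a CSV with the same columns).

Superplot-style summaries (`summarizeMeasurements`) aggregate hierarchically
— per myofibril, then per experiment, then the grand mean across experiment
means. The grand mean is deliberately *not* the pooled mean: with 1000
measurements in one experiment and 10 in another, pooling would let one
experiment dominate. With a single experiment the between-experiment sd is
undefined and reported as 0 with an explicit flag. Hypothesis testing is
out of scope.

# Lattice and 3D sarcomere models

`buildHexLattice(nThick, d)` fills a triangular lattice in concentric
hexagonal rings from the centre; a partially filled outer ring is filled in
angular order counter-clockwise from angle 0 (ties toward the lower axial
index) — the fill order is a package convention, as real immature lattices
are irregular at their edges. Thin filaments sit at the midpoint of every
nearest-neighbour thick pair (the MyAc-layer constraint). Consequences,
tested rather than imposed: every interior thick site (6 thick neighbours)
touches 6 thin sites, each shared by two thick filaments — 3 thin per thick
— and the bulk thin:thick count ratio approaches 3 from below as the
lattice grows (the boundary deficit is $O(\sqrt n)$).

Derived quantities:

- `equivalentDiameter(n, d)` — diameter of the circle whose area equals
  $n$ hexagonal unit cells of area $(\sqrt3/2)d^2$; e.g. 1.47 µm for 846
  filaments at 48 nm.
- `incorporationTime(n1, n2, Δt)` — mean minutes per incorporated thick
  filament (equivalently, six thin filaments) between two stages:
  14.1 min between the 48 h APF (32 filaments) and 72 h APF (134) stages.
  Note that published incorporation times for the other intervals are not
  exactly reproducible from rounded integer counts and nominal stage
  times; the package reports the arithmetic value from its inputs.

`build3dSarcomere` assigns axial spans: thick filaments of length
$L_{\mathrm{thick}}$ centred on the M-line; at every thin lattice site two
thin filaments, one per Z-line, overhanging the Z-line by half the Z-disc
overlap and pointing toward the M-line — mirror-symmetric about the M-line,
assuming the same thin-filament symmetry at both Z-discs. Given the two
identities above, the model re-measures its generating
$W_{\mathrm{I\mbox{-}band}}$, $W_{\mathrm{H\mbox{-}zone}}$ and
$W_{\mathrm{Z\mbox{-}disc}}$ exactly (to double precision), which is the
package's geometric round-trip test. Models export as exact span CSVs or
display-only OBJ cylinders (8 nm/4 nm radii for thick/thin). Cross-bridge
geometry, bare-zone substructure and axial filament register are out of
scope.

```{r lattice-example}
lat <- buildHexLattice(134, 47)
interiorThinPerThick(lat)
m <- build3dSarcomere(getStage("24h AE"))
remeasureBandWidths(m)
```

# Numerical and design choices

- **Coordinates** — 0-based pixel indices; physical position = index ×
  pixel size at pixel centres; matrix rows are y, columns x.
- **Interpolation** — bilinear everywhere a profile samples the image:
  differentiable, standard, and adequate for the sub-10-nm parameter
  accuracy targeted after fitting. Profiles are sampled at half a pixel
  (Nyquist of the stored image).
- **Convolution edges** — reflect padding, implemented by mirroring the
  frame before an FFT convolution; blur then conserves total intensity to
  <0.1% for objects several kernel radii from the border.
- **Error signalling** — structured conditions (`SpecOutOfCanvas`,
  `BranchedSkeleton`, `TooFewPeaks`, `FitDiverged`, …) so callers and the
  batch pipeline can distinguish QC outcomes from genuine failures; the
  automatic pipeline logs one reason-coded record per rejected fibril.
- **Determinism** — the analysis path contains no random numbers; the
  simulator's randomness is fully determined by `rngSeed`. Batch results
  are reproducible from the configuration object and the input files.
- **Degenerate inputs** — empty scenes render zero images; flat profiles
  raise `NoPeaks`/`DegenerateProfile`; single-measurement summaries report
  sd 0 with a flag; a lattice of one filament has no bonds and no thin
  sites.
- **Problem sizes** — validation batches in the test suite use 20
  simulated fibrils of 6 sarcomeres at 50 nm pixels (140×480 canvases),
  Monte-Carlo noise checks use 100–1000 small-canvas realisations; these
  sizes give stable statistics while keeping the whole suite fast.

# Known limitations

- The Gaussian PSF inside the disc fit approximates the simulator's (and
  the microscope's) Airy profile; the residual diameter mismatch is about
  3% at NA 1.4 and is absorbed into the validation tolerances.
- Automatic segmentation targets isolated, well-separated myofibrils on a
  dark background; dense whole-muscle fields need manual polylines.
- The simulator is 2D: no z-extended PSF, no detector read noise, no
  background autofluorescence.
- TIFF interchange uses a minimal OME-XML ImageDescription (physical pixel
  size, channel names, channel maxima); exotic OME features (multi-series,
  non-XYCZT orders) are not parsed. Native microscope formats should be
  converted to OME-TIFF upstream.
- QC thresholds (closing diameter, minimum length, prominence fraction,
  ROI widths) are package defaults chosen on the simulated data, exposed
  in `analysisConfig()`; they are starting points for real data, not
  measured constants.
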