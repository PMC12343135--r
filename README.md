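# fibrilMorph

Automated morphometry of striated-muscle myofibrils from two-channel
fluorescence micrographs, with a validation simulator and scaled
myofilament-lattice models of the *Drosophila* indirect flight muscle (IFM).

## The problem

Sarcomere length and myofibril diameter are the standard morphometric traits
of fibrillar muscle, but manual measurement of intensity profiles is slow and
systematically biased: reading the full width at half maximum (FWHM) of a
myofibril cross-profile underestimates the true diameter, because the
projection of a uniformly labelled cylinder of diameter `D` has FWHM
`(√3/2)·D ≈ 0.87·D` even before diffraction blur. `fibrilMorph` replaces the
manual workflow with model fitting:

- **Sarcomere length** — a longitudinal intensity profile is extracted along
  the myofibril in the Z-disc marker channel and fitted with a sum of
  Gaussians, `B + Σᵢ Aᵢ·exp(−(s−μᵢ)²/2σᵢ²)`; successive center differences
  `μᵢ₊₁ − μᵢ` are the sarcomere lengths.
- **Myofibril diameter** — transverse profiles in the F-actin (phalloidin)
  channel are fitted with a *disc model*: the projected chord of a uniform
  cylinder, `C(u) = 2√(R² − u²)`, convolved with a Gaussian point-spread
  function; the fitted `2R` is the diameter, free of the FWHM bias.

Myofibrils are found automatically (Otsu threshold, connected components,
QC flags for border contact, branched skeletons and touching neighbours) and
a smoothing-spline centerline is fitted to each skeleton, so profiles follow
curved fibrils correctly. A manual mode accepts user-drawn polylines for
sectioned or microdissected muscle.

Because accuracy cannot be judged on real images, the package ships the
simulator used to validate it: myofibrils are rendered as 2D projections of
uniformly labelled cylinders with Z-disc overlap bands (doubled intensity)
and H-zone gaps, degraded with Gaussian uneven-labelling noise, convolved
with an Airy pattern `(2·J₁(v)/v)²`, `v = 2πNA·r/λ` (NA 1.4, λ 525 nm), and
finished with Poisson shot noise — all with exactly known ground truth.

Downstream, fitted band widths become filament lengths via

    L_thick = L_sarcomere − W_I-band
    L_thin  = (L_sarcomere − W_H-zone + W_Z-disc) / 2

and measured filament counts and lattice spacings become geometric models:
thick filaments on a hexagonal lattice, thin filaments at nearest-neighbour
bond midpoints (the MyAc layer), which makes every interior thick filament
adjacent to six half-shared thin filaments — the 1:3 thick-to-thin ratio of
the IFM lattice — and 3D sarcomere models whose re-measured band widths
reproduce their inputs exactly.

## Worked example

```r
library(fibrilMorph)

# simulate one mature-like myofibril: 6 sarcomeres of 3.2 um, diameter 1.5 um
spec  <- MyofibrilSpec(6, sarcomereLength = 3.2, diameter = 1.5,
                       origin = c(2, 3))
img   <- simulateImage(list(spec), ImagingSpec(rngSeed = 42), c(140, 480))
stack <- ImageStack(phalloidinChannel(img), zdiscChannel(img), pixelSize(img))

res <- analyzeStack(stack, analysisConfig())
res$fibrils[, c("mean_sarcomere_length_um", "diameter_um")]
#   mean_sarcomere_length_um diameter_um
# 1                 3.199455    1.508224
```

The recovered sarcomere length (3.199 µm vs 3.2 µm true) and diameter
(1.508 µm vs 1.5 µm true) illustrate the accuracy on the package's own
simulated data: across a 20-fibril batch the mean sarcomere-length error is
below 1% and the mean diameter error below 5% (see the test suite).

Lattice and developmental-kinetics quantities:

```r
interiorThinPerThick(buildHexLattice(134, 47))  # 3      (1:3 thick:thin)
incorporationTime(32, 134, 24)                  # 14.1 min per thick filament
thickLength(3.40, 0.16)                         # 3.24 um mature thick filament
thinLength(3.40, 0.134, 0.094)                  # 1.68 um mature thin filament
```

A command-line front end with `simulate`, `analyze`, `lattice` and `morph`
subcommands is installed at `inst/scripts/fibrilmorph`.

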