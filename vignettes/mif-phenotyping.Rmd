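---
title: "Simulating and phenotyping Opal multiplex immunofluorescence: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and phenotyping Opal multiplex immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplexpheno)
```

`mplexpheno` is a desk-scale model of an Opal multiplex-immunofluorescence
(mIF) digital-pathology workflow: a synthetic tissue-scene generator, a
linear multispectral acquisition and unmixing model, watershed nucleus
segmentation with compartment expansion, threshold-based sequential binary
hierarchical phenotyping, and the agreement statistics used to validate a
panel against a reference modality. This vignette is the package's account of
the science: what each stage assumes, which parameters matter and why their
defaults are what they are, and where the design was genuinely open.

## The acquisition and unmixing model

A scene is a set of cells, each with a nucleus disc (radius 4–5 px) and a
membrane annulus (width 3 px), expressing markers at abundances measured in
*counts* — exposure-normalised intensity units. Panel MP1 (CD3, CD4, CD8,
CD20, CK + DAPI) contains three markers co-expressed in the same membrane
compartment of T cells; MP2 (CD4, CD68, FOXP3, CK + DAPI) co-expresses CD4
(membrane) and FOXP3 (nucleus) in different compartments of regulatory T
cells. That contrast is the panels' point: same-compartment co-expression is
what makes classification order-sensitive, and MP2 is the negative control.

Acquisition is linear: channel $c$ records
$y_c = \sum_f M_{cf}\, a_f\, t_c + \varepsilon_c$, with $M$ the sensing
matrix (each emission spectrum integrated over each filter band by the
trapezoid rule on a 2 nm, 400–800 nm grid), $t_c$ the exposure in ms, and
$\varepsilon_c \sim N(0, \sigma^2 t_c)$ Gaussian read noise. Emission
spectra are unit-peak Gaussians at the nominal Opal peak wavelengths
(exact measured curves are not published; the Gaussian stand-in preserves
the one property the analyses depend on — peak spacing, hence spectral
overlap). Autofluorescence is one additional broad endmember
(peak 540 nm, FWHM 200 nm), matching the single representative
autofluorescence spectrum used in practice. Sensing columns are normalised
to unit maximum so that abundances come out in counts of the fluorophore's
brightest channel regardless of which library produced the matrix; this is
what makes a parametric library and a library estimated from singleplex
slides interchangeable to within measurement error (a property the test
suite asserts).

Unmixing solves, per pixel, non-negative least squares of the
exposure-normalised channel vector against $M$ (Lawson–Hanson active set,
compiled; tolerance scaled to the problem magnitude so exposure rescaling
cannot change the active set). Nonnegativity is a physical constraint —
abundances are concentrations — and on noiseless data with a nonnegative
true solution NNLS coincides with the unconstrained least-squares oracle,
which the acceptance checks verify to 10⁻⁶ counts. The exposure division
makes unmixed counts invariant to acquisition exposure, reproducing the
equivalence of batch and individual exposure protocols as an exact
property. The autofluorescence coefficient and the per-pixel residual norm
are kept as planes; the QC gate excludes an image when the upper-quartile
mean of either exceeds its bound (defaults 15 and 2 counts — roughly 3×
the calibrated τ = 1 autofluorescence level and 10× the noise-floor
residual). The upper quartile is an implementer's choice: the failure mode
being caught (autofluorescence beyond what one spectrum can subtract) is
spatially widespread, so a robust high-quantile statistic separates it
cleanly from local artefacts.

## What the scene generator emulates — and what it does not

The generator's defaults are the study conditions the rest of the package is
tested under:

* **Counts calibration.** Positive-marker means are 22 counts (CD20: 25, a
  low-expressing target paired with a brighter fluorophore), with lognormal
  per-cell dispersion σ = 0.2. After rendering, segmentation and
  measurement, positive-cell ring means land in the 20–25 count target band
  with every fluorophore below 30 — the signal-balance rule the assay
  calibrates to.
* **Hot spots.** Germinal-centre analogues: discs with a 4× density
  multiplier and a CD20-dominant phenotype mix (55% CD20+, ~31% T cells).
  Outside hot spots the minimum centroid separation (17 px) keeps membrane
  annuli disjoint; inside (12 px) nuclei stay disjoint but annuli overlap,
  which is precisely the regime where masking and spillover act.
* **Nonspecific co-stain.** Inside hot spots the rendered CD8 plane of each
  cell gains ν × its CD20 abundance (default ν = 0.3 — a free simulator
  knob, not a measured value; it is the qualitative phenomenon, CD20-CD8
  co-staining confined to lymphoid follicles, that is modelled).
* **Spillover and masking.** Cells whose annuli overlap a neighbour's
  receive κ-weighted contributions of the neighbour's membrane abundances
  painted across their annulus, and a crowded cell's weaker co-located
  membrane marker is attenuated by (1 − κ/2). κ = 0.3 by default. The two
  effects make over-detection (spillover) and under-detection (masking)
  both producible, without committing to a mechanism for what is, in the
  assay, an unresolved mixture of steric hindrance and optics.
* **Thickness.** The autofluorescence plane is τ × (baseline 4 counts +
  low-frequency texture, clipped at zero), so thickness scales
  autofluorescence exactly linearly and τ = 5 sections trip the QC gate
  while τ = 1 sections pass.
* **Exposure and noise.** Default exposures 10 ms (DAPI) / 50 ms (marker
  channels); read noise σ = 0.5 in raw units, i.e. ≈ 0.07 counts at 50 ms —
  small against a 22-count signal, as it is in practice after TSA
  amplification.

A single global seed fans out to labelled substreams (placement, phenotypes,
radii, abundances, autofluorescence, noise), so every artefact can be varied
without perturbing the others and identical configurations are bit-identical.

The generator does **not** emulate: realistic tissue texture or optics (point
spread, chromatic effects), Poisson photon statistics (Gaussian read noise
keeps every oracle closed-form), whole-slide scale, tiling or pyramids,
chromogenic DAB images (the reference arm enters as ground truth), staining
chemistry, or batch effects. Passing tests therefore demonstrate that the
*computational* pipeline is correct and that its documented failure modes
reproduce under controlled artefacts — not that the pipeline is robust to
everything real tissue can do.

## Segmentation

Nucleus detection is Gaussian smoothing (σ = 1 px), a threshold, and
connected components, with two numerical choices worth recording:

* The `"auto"` threshold is the **triangle method** on the smoothed plane:
  with sparse foreground (a few percent of pixels) the histogram is a
  background spike plus a long tail, exactly the shape the triangle
  construction is designed for, and it is deterministic.
* A **half-maximum refinement** sits between thresholding and watershed.
  Smoothing drags each nucleus ~2.5σ past its true edge at the low triangle
  threshold, which would inflate nucleus masks ~3× and dilute measured
  means. Each blob is trimmed to pixels above half its 90th-percentile
  level, computed on the *unsmoothed* plane — blur rounds the concave waist
  between touching nuclei and would erase the distance-transform saddle the
  watershed needs to split them.

Touching nuclei are split by watershed on the distance transform
(tolerance 1); objects under 20 px² are removed. Cells are expanded by
geodesic propagation (2 px default) so neighbouring expansions partition
contested pixels by distance with a deterministic tie-break, and the
membrane ring is the expanded cell minus the nucleus. The painted annulus
(3 px) is deliberately one pixel wider than the measurement ring: the
detected nucleus radius can differ from truth by ±1 px, and the wider
painted band keeps ring means within ~10% of the painted abundance instead
of halving them. Measured per-class fractions are stable under a 2× pixel
rescale of the same tissue (the package's analogue of scanning the same
section at higher magnification), which the acceptance checks bound at one
percentage point.

## Phenotyping and the detection order

Thresholding is strict (`mean > t`; ties at exactly `t` are negative — an
arbitrary, documented convention). Three threshold sources are provided:
manual counts, Otsu (midpoint of the flat maximal between-class-variance
plateau, so an empty gap yields the gap's centre), and quantile-matching to
a reference positive fraction — the stand-in for calibrating mIF thresholds
against a chromogenic reference arm. The default manual threshold is
4 counts: ~20% of the calibrated positive signal, far above unmixed
background, and low enough that nonspecific co-stain (ν·25 ≈ 7.5 counts)
and neighbour spillover (κ·22 ≈ 6.6 counts) are *detected*, as they are in
the assay.

The hierarchical classifier processes markers in a detection order:
unclaimed positive cells take the step's base class; already-classified
positive cells are relabelled only if a compound rule matches their current
class, otherwise they keep it. Compound matching consults the current class
only — this mirrors sequential binary relabelling and keeps the rule table
finite. The shipped MP1 tree carries the expected compounds CD3+/CD4+ and
CD3+/CD8+ with *directional rules in both directions*, and the unexpected
compound CD4+/CD8+. Two design points:

* Both directions are included so that true co-expressing phenotypes
  resolve identically under every order — in sparse artefact-free tissue
  the detection order must be provably irrelevant, and single-direction
  rules (a tree transcribed only for the final order) would break that.
* No compound involves CD20. A cell claimed CD20+ keeps that class, and a
  cell claimed CD8+ before the CD20 step keeps *that* class. The entire
  order effect of dense B-cell regions flows through this: detecting CD20
  early overestimates it by claiming spill-contaminated T cells; detecting
  CD8 before CD20 turns co-stained B cells into CD8+ cells. The final order
  (CK > CD4 > CD3 > CD20 > CD8) claims T-cell compounds first and puts CD20
  before CD8 so B cells stay B cells.

`order_sweep()` quantifies this as each order's summed absolute deviation of
class-derived per-marker fractions from independent singleplex detection.
Because a CD20/CD8 (or CD3/CD4) swap relocates the same per-cell deficit
between marker columns without changing the sum, orders close to the final
one can tie it exactly; the guarantee is that the final order *attains* the
minimum, and that CD20-first orders are strictly worse. The six shipped
orders are a reconstruction of a plausible refinement path — only the first
(the staining order) and the final order are canonical, and they are
labelled accordingly.

"Script 1" is the tree with unexpected rules stripped; "script 2" the full
tree. `compare_scripts()` reports reclassifications per tissue context, and
on the hotspot fixture every CD4-branch cell reassigned to CD4+/CD8+ lies
inside a hot spot — none are isolated cells — while the MP2 fixture shows no
differences at all, because its co-expressions live in different
compartments. The multilabel classifier (positive-marker sets, order-free by
construction) and the random-forest classifier (trained on all compartment
means, fixed seed, majority vote) are included as the contrasting
nonhierarchical approaches; the tree stops at pairwise compounds since
triple-positive labels are not part of the shipped vocabulary.

## Validation statistics

`validate_panel()` aggregates per-unit percent-positivity on both arms and
runs, per marker: Spearman rank correlation (mid-rank ties; exact p below
n = 10 without ties, t-approximation otherwise — the switchover is an
implementation choice, recorded here because the reference software's method
is not published), Bland–Altman bias with 95% limits of agreement
(bias ± 1.96 × sample sd), and the 10-percentage-point positivity criterion.
"Bias within the limits of agreement" is ambiguous as an acceptance phrase,
so both readings are reported — the fraction of per-unit differences inside
the limits, and |bias| against the half-width — and the verdict uses
significance (α = 0.05, two-tailed, no multiple-testing correction, as is
conventional for this panel size) plus the bias-within-half-width reading.
Degenerate inputs have explicit conventions: constant vectors yield an
undefined Spearman coefficient (reported as NA, not a number), zero-variance
nonzero-mean paired differences yield t = ±∞ with p = 0 and a flag.

Every statistic is checked against an independent brute-force oracle —
full permutation enumeration for Spearman's exact p, rank-assignment
enumeration for Mann–Whitney, closed forms for Bland–Altman and paired t —
on all fixtures with n ≤ 8.

## Problem sizes and determinism

The bundled fixtures are the sizes the package's own analyses use: 512² px /
300 cells for the sparse and hotspot MP1 scenes, 384² / 200 cells for MP2,
224² / 60 cells for the spectral-overlap singleplexes, 192² / 60 cells for
the thickness pair. At these sizes the full test suite runs in well under a
minute per heavy fixture and the acceptance script completes in about half a
minute on one CPU, while every effect of interest (hot-spot density, order
sensitivity, crosstalk ordering, QC separation) is comfortably resolved.
All randomness flows from explicit integer seeds; rerunning any stage with
the same configuration reproduces its outputs bit-identically, and the
pipeline manifest records MD5 checksums to make that checkable.

## Known limitations

* The linear-mixing + NNLS model is an assumption standing in for
  proprietary unmixing software; real unmixing may differ in weighting and
  regularisation.
* One autofluorescence endmember cannot represent thickness-dependent
  spectral *shape* changes — only magnitude. Thickness-specific
  autofluorescence spectra are out of scope, which is exactly why the QC
  gate exists.
* The spillover/masking model is phenomenological (cell-level κ
  contamination on overlapping annuli), chosen to make both error
  directions producible rather than to be mechanistically faithful.
* Watershed-on-distance segmentation is the classical approach; crowded
  real tissue would favour learned nucleus detectors, which are
  deliberately not part of this package.
* Synthetic validation units are grid tiles of one simulated section, not
  tissue cores from multiple donors; the agreement statistics exercise the
  machinery, not biological generalisation.
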