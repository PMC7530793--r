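# mplexpheno

Multiplex immunofluorescence (mIF) lets one tissue section report half a dozen
protein markers at once, but the numbers that come out of a digital-pathology
pipeline depend on far more than the staining: how the acquired filter
channels are spectrally unmixed, how autofluorescence is subtracted, how
nuclei are segmented and expanded into membrane compartments, and — less
obviously — the *order* in which marker classifiers are applied when cells are
phenotyped by sequential binary thresholding. `mplexpheno` implements that
whole computation for tyramide-signal-amplification (Opal) panels as tested,
deterministic R code, together with a ground-truthed synthetic-scene generator
that reproduces the tissue structures where the pipeline's failure modes live:
CD20-rich lymphoid hot spots with nonspecific CD20–CD8 co-staining, membrane
spillover between crowded cells, spectrally overlapping fluorophore pairings,
and thickness-scaled autofluorescence.

It is aimed at image-analysis scientists who want to understand or stress-test
an mIF phenotyping workflow without access to scanner data: every artefact is
a dial, every cell has a known truth, and every stage is a plain R function.

## The computation

* **Acquisition model.** Channel `c` of the image is
  `y_c = Σ_f M[c,f] · a_f · t_c + ε`, where `a_f` are per-fluorophore
  abundances in counts, `t_c` the per-channel exposure, `ε` Gaussian read
  noise with sd `σ√t_c`, and `M` the sensing matrix obtained by integrating
  each emission spectrum (Gaussian stand-ins at the nominal Opal peaks, plus
  one broad autofluorescence endmember) over the filter bands.
* **Unmixing.** Per pixel, non-negative least squares of the
  exposure-normalised channel vector against `M` (Lawson–Hanson, compiled);
  the autofluorescence coefficient and the reconstruction-error norm come
  back as their own planes, and a QC gate excludes images whose
  autofluorescence or residual upper-quartile mean exceeds its bound.
* **Segmentation.** Triangle-threshold + half-maximum refinement on the DAPI
  plane, distance-transform watershed for touching nuclei, geodesic expansion
  into cell and membrane-ring compartments, and per-cell mean counts per
  marker per compartment.
* **Phenotyping.** Sequential binary hierarchical classification: markers are
  processed in a detection order; unclaimed cells above a marker's threshold
  take its base class, already-classified cells are relabelled only through
  explicit compound rules (`CD3+/CD4+`, `CD3+/CD8+`, and the
  unexpected-class rules such as `CD4+/CD8+` that distinguish "script 2" from
  "script 1"). A nonhierarchical multilabel classifier and a random-forest
  classifier are included for contrast, plus a detection-order sweep and a
  script-1-vs-script-2 comparison.
* **Validation statistics.** Spearman rank correlation (exact p for small n),
  Bland–Altman bias and 95% limits of agreement, Mann–Whitney U, paired t,
  and the 10-percentage-point positivity-difference criterion, assembled by
  `validate_panel()`.

## Worked example

```r
library(mplexpheno)

fx <- make_fixture("hotspot-mp1")      # 300 cells, two CD20-rich hot spots
un <- qc_autofluorescence(unmix(fx$image, fx$library))
mp <- marker_planes(un, fx$config$pairing)
labels <- detect_nuclei(mp$DAPI)
geo <- expand_cells(labels, 2)
cells <- measure_cells(labels, geo$cells, geo$rings, mp)

sw <- order_sweep(cells, default_thresholds("MP1"), default_tree("MP1"))
round(sw$deviation, 4)
#> order1_cd20_first      order2_recon      order3_recon      order4_recon
#>            0.5067            0.5067            0.3367            0.3367
#>      order5_recon             final
#>            0.3367            0.3367
```

Each number is an order's summed absolute deviation of class-derived
per-marker positive fractions from independent singleplex detection, over all
300 cells. Detecting CD20 first (the naive staining order) overestimates
CD20+ cells by claiming spill-contaminated T cells and misses their T-cell
classes, nearly 1.5× the deviation of the final order
(CK > CD4 > CD3 > CD20 > CD8). Comparing the expected-only and full decision
trees on the same cells:

```r
ctx <- ifelse((cells$y - 127.5)^2 + (cells$x - 127.5)^2 <= 72^2 |
              (cells$y - 383.5)^2 + (cells$x - 383.5)^2 <= 72^2,
              "hotspot", "sparse")
compare_scripts(cells, default_thresholds("MP1"),
                default_orders("MP1")$final, default_tree("MP1"), ctx)$report
#>   context      from        to  n fraction_of_from
#> 1 hotspot CD3+/CD4+ CD4+/CD8+ 22        0.6470588
```

All 22 reassigned dual-positive cells sit inside the hot spots; none are
isolated cells in sparse tissue.

A full run — simulate, acquire, unmix + QC, segment, measure, phenotype,
validate — with persisted intermediates and an MD5-checksummed manifest:

```r
man <- run_pipeline(scene_config(panel = "MP1", n_cells = 150, seed = 17),
                    "out/demo")
#> run_manifest: completed - 7 stages
```

A thin CLI wraps the same functions: `inst/cli/mplexpheno simulate|run|unmix|fixtures`.

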