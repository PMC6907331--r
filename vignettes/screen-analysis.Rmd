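---
title: "Analyzing fluorescence-reporter screens with hcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing fluorescence-reporter screens with hcscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
```

## The assay

hcscreen analyzes 384-well high-content screens in which a fluorescence
reporter — here, EGFP driven by a muscle gene promoter in differentiating
myotubes — reads out a compound's effect on promoter activity. Each plate
carries vehicle (DMSO-only) wells, positive-control wells (1%
insulin-transferrin-selenium, which raises the reporter about 1.4-fold),
and compound wells treated once each at a single dose. Wells are imaged at
two sites, myotube fluorescence is quantified by a segmentation chain, and
compounds are called as hits in two stages: a permissive single-well
primary screen, then a replicated confirmation rescreen.

The package covers the full path from raw inputs to hit tables, plus the
surrounding bench computations (ddCT qPCR quantification, fusion index,
densitometry, viability, dose-response summaries), and a synthetic-data
generator that emulates every input with known ground truth so each stage
is testable without access to screening hardware.

## The pipetting model

Final assay concentrations follow from simple conservation arithmetic
under a perfect-mixing assumption: additions accumulate solute amounts
(concentration × volume), and aspiration to a residual volume removes
solutes in proportion to the volume removed. The screen's protocol — seed
50 µl, aspirate to a 10 µl residual, add 30 µl media, add 0.5 µl of 1 mM
compound stock in 100% DMSO, add 50 µl media — leaves 90.5 µl containing
0.5 µl·mM of compound, i.e. 5.5 µM in 0.55% (v/v) DMSO:

```{r pipetting}
state <- apply_pipetting(screen_treatment_steps())
signif(state$concentrations, 2)
```

The default plate layout puts controls in fixed interior columns (2, 3 and
22, 23) rather than on the plate edge; published screens of this kind do
not state their plate maps, and interior columns leave the edge rows free
for edge-effect studies. Any real plate map read with `read_plate_map()`
overrides the default.

## The image-quantification chain

Per site, the chain is: white top-hat background removal, an adaptive
intensity threshold with width constraints, a minimum-area filter, and
fluorescence quantification under the final mask.

**Top hat.** `top_hat()` subtracts the grayscale morphological opening by
a flat disc from the image. It is exactly background-invariant
(`top_hat(x + c) = top_hat(x)`) and returns, for any object the
structuring element cannot fit inside, the object's intensity above its
local background. The disc is parameterized by the module's `size`
setting, 12 by default. We read this size as the disc **radius** (kernel
diameter 25 px): under a diameter-12 reading, any uniformly lit object
wider than ~12 px contains the disc, is reproduced by the opening, and
vanishes from the top hat — which would empty the assay's own 10–800 px
admissible width window. With the radius reading, objects up to ~22–24 px
wide (typical myotube widths at 10× magnification) survive the top hat at
full contrast. The convention is configurable
(`pipeline_config(tophat_size_as = "diameter")`).

A consequence worth stating plainly: objects wider than the structuring
element blend into the background estimate and cannot be detected from the
top-hat image. The `max_width_px = 800` filter is therefore a guard that
rarely binds; the effective upper width limit is set by the top-hat scale.
The synthetic generator's default myotube widths (12–22 px) sit inside
this detectable band.

**Adaptive threshold.** Candidate pixels are those whose top-hat value
meets `intensity_above_background` (500 counts by default — the top hat
*is* the local-background-subtracted signal). Connected candidate regions
(8-connectivity by default) are kept only if their width lies in
`[min_width_px, max_width_px]`. Width is measured as twice the component's
maximum inscribed-disc radius, i.e. the distance-transform maximum: for
elongated objects this tracks the anatomical width where a bounding box
would conflate width with length. The proprietary imaging software's exact
width definition is undocumented; the distance-transform width is this
package's explicit stand-in, and on rendered capsules it reproduces the
nominal width to within about one pixel of discretization.

**Area filter and quantification.** Components smaller than
`min_area_px = 500` px are removed; both area and width tests are
inclusive at their boundaries (a 500-px object survives a 500-px minimum).
Total fluorescence is summed from the **original** image under the final
mask — "fluorescence of identified cells" reads most naturally as cell
intensity including local background — with the top-hat-summed alternative
always recorded alongside (`intensity_source = "tophat"` swaps the
default).

**Sites and artifacts.** The two site images per well are each run through
the chain and aggregated by the mean of per-site totals (`"sum"` and
`"median"` are available; the published analysis does not state its rule,
and the mean is robust to per-site area differences). A site is flagged as
an artifact when (a) more than 0.1% of pixels are saturated (debris), (b)
an object's mean intensity exceeds 5× the plate's median object intensity
(auto-fluorescent compound), or (c) its background median exceeds 3× the
plate's median background (well-wide auto-fluorescence). Rules (b) and (c)
need plate context, which `analyze_plate_images()` computes in a first
pass. Flagged sites are dropped from the well aggregate and flag the well;
flagged wells are excluded from vehicle reference medians and can never be
hits.

## Robust plate QC and two-stage hit calling

All screen statistics are medians and unscaled median absolute deviations
(MADs). The central statistic is the robust strictly standardized mean
difference,

$$\mathrm{SSMD}^{*} \;=\; \frac{\tilde{X}_P - \tilde{X}_N}
  {1.4826\,\sqrt{s_P^2 + s_N^2}},$$

where $\tilde{X}_P, \tilde{X}_N$ are the medians and $s_P, s_N$ the
unscaled MADs of the positive and negative (vehicle) controls; 1.4826
rescales a MAD to a normal standard deviation. Conventions:

* **Plate QC**: SSMD\* over the plate's non-artifact controls; the plate
  passes when SSMD\* ≥ 1 (inclusive), the accepted quality bar for a
  moderate positive control.
* **Primary hits**: each compound has one well, so the compound-side MAD
  is undefined. `ssmd_star_single()` uses the standard no-replicate
  construction, setting the compound dispersion equal to the vehicle MAD:
  $(x - \tilde{X}_N) / (1.4826\sqrt{2}\,s_N)$. A compound is a primary hit
  when its vehicle-normalized fold change attains 1.4 (inclusive), its
  single-well SSMD\* strictly exceeds 0.25, and the well is not
  artifact-flagged.
* **Validation**: rescreen replicates (24 wells × 2 plates per compound)
  give a per-plate SSMD\* against that plate's vehicle wells; the
  per-compound aggregate is the median of the per-plate values (the
  published tables report one value per compound without stating the
  combination rule) and a compound validates when it strictly exceeds
  0.25.
* **Degenerate dispersion**: when both MADs are zero the statistic returns
  0 for equal medians and signed infinity otherwise, carrying a
  `degenerate` attribute instead of erroring, so batch runs survive
  pathological plates while surfacing them.

Fold changes are always normalized to the **per-plate vehicle median**
(not mean, not cross-plate): plate-wise normalization matches the
plate-wise QC and is robust to stray vehicle wells.

## The synthetic generator as study design

`simulate_screen()` draws well intensities from a lognormal parameterized
by its median — fluorescence is positive and right-skewed, and the median
parameterization makes planted fold effects exact statements about the
quantity the pipeline estimates. A coefficient of variation `well_cv` maps
to `sdlog = sqrt(log(1 + cv^2))`. Defaults encode the assay's conditions:
1.4-fold positive-control effect, 32 + 32 control wells, 320 compounds per
plate, 10% CV (the screen publishes no well-to-well variability, so the CV
is a modeling choice, stated here once), 2% planted enhancers at 1.5-fold,
and a 1% imaging-artifact rate. `simulate_well_image()` renders myotubes
as uniform-intensity capsules (rectangles with semicircular caps) at
uniform random orientation over a flat or gently textured background,
with exact pre-noise ground-truth masks; debris is rendered as saturating
disks and auto-fluorescence as a whole-image offset so both artifact
classes are separately testable. `simulate_ct_table()` and
`simulate_fusion_images()` plant known folds and fused fractions the
downstream estimators must recover.

What the generator does **not** emulate — point-spread blur, vignetting,
uneven confluency, spectral bleed-through, spatial plate effects
(edge/drift), compound carry-over — bounds what passing tests show: they
certify the analysis chain, not the imaging physics. In particular the
closure results (exact mask recovery on noiseless wells) are statements
about the chain's internal consistency on idealized inputs.

A single top-level seed drives every stage through derived per-module
streams, so an entire simulated screen, including its validation plates,
is bit-reproducible.

## Quantitative behavior under the default conditions

Simulated plates under the assay geometry (32 + 32 controls, 1.4-fold
positive effect, 10% CV) give plate SSMD\* values around 2.3, comfortably
above the QC bar. The primary hit rule at these settings recovers planted
1.5-fold enhancers with probability ≈ 0.75 per compound — the binding
constraint is the fold ≥ 1.4 cutoff applied to a single 10%-CV well, for
which $P(1.5\,e^{\sigma Z} \ge 1.4) = \Phi(0.69) \approx 0.76$ is a
distributional fact, not an implementation artifact — while the
end-to-end false-discovery path (primary *and* validation) passes null
compounds at a rate on the order of $10^{-4}$. Raising single-well
sensitivity materially would require replicating the primary screen or
relaxing the fold cutoff; both change the assay, so the package keeps the
published rule.

## ddCT, fusion index, densitometry

`ddct_fold_change()` averages replicate Cts per (sample, gene), excluding
"undetermined" (NA) replicates and erroring only when all replicates of a
pair are undetermined; then ΔCt = Ct(gene) − Ct(reference),
ΔΔCt = ΔCt(sample) − ΔCt(calibrator), fold = 2^(−ΔΔCt). The reference gene
is a required argument (experiments in this assay family normalize to
β-actin or GAPDH depending on context, so no default is safe). Standard
curves give `amplification_efficiency()` = 10^(−1/slope) − 1; efficiencies
are reported but do not correct folds unless explicitly requested
(`efficiency_corrected = TRUE`), keeping the default estimator the pure
ddCT.

`fusion_index()` counts nuclei whose centroid lies on a
myosin-heavy-chain-positive pixel, divided by all nuclei — centroid
membership matches how a person scores "nuclei within an MHC-positive
cell" and is unambiguous at boundaries. Fields are pooled by summed counts
(unbiased when fields differ in nucleus number); mean-of-field-indices is
available by flag. Mask-based counting merges touching nuclei under
8-connectivity — a documented limitation shared with any
connected-component counter.

`densitometry_normalize()` divides target by loading-control band density
and rescales so the calibrator (vehicle) lane is 1; `viability_percent()`
normalizes luminescence to the vehicle median;
`dose_response_summary()` reports per-dose median fold and MAD with
duplicate doses pooled.

## Numerical choices and problem sizes

* Morphology uses exact grayscale erosion/dilation with a flat disc
  (decomposed into vertical chords, implemented in C++); pixels outside
  the image are ignored, which preserves `opening(x) ≤ x` and the top
  hat's background invariance at borders.
* Connected components default to 8-connectivity (standard for bright
  objects); 4-connectivity is available.
* Ties and boundaries: width and area filters inclusive; QC cutoff
  inclusive; hit SSMD\* cutoffs strict — each matching the wording of the
  published rules.
* The verification suite uses 512×512 synthetic fields (50 wells noiseless
  + 25 noisy for image closure), 100-seed screen simulations of 11 plates
  × 320 compounds, and 1000-replicate Monte-Carlo runs for the ddCT and
  formula checks; these sizes give stable statistics while keeping the
  full suite inside a few minutes on one core.

## Known limitations

* The chain is not a bit-for-bit reproduction of the proprietary
  MetaXpress module; its adaptive-threshold internals and width definition
  are undocumented, and the stand-ins here are stated above.
* No spatial plate-effect correction (B-score/loess) is applied; the
  statistics assume plate-wise exchangeability of wells.
* Fold-change normalization assumes at least two usable vehicle wells per
  plate; plates below that are excluded with a warning rather than
  repaired.
* The generator's lognormal noise model is a choice, not a measurement;
  conclusions about absolute error rates transfer to real screens only to
  the extent the noise model does.
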