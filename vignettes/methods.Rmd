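---
title: "Layer-wise retinal immunofluorescence quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-wise retinal immunofluorescence quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retcoloc)
library(dplyr)
```

## The problem

Post-mortem retinal cross-sections are double-labelled for amyloid-beta
(red channel) and one cell marker per cohort -- TUBB3 (neurons), GFAP
(astrocytes and activated Müller cells), IBA-1 (microglia) -- or, in a
separate cohort, GS (Müller cells, red) together with GFAP (green).
Each image comes with a manually drawn label mask assigning every pixel
to one of six retinal layers (RNFL, GCL, IPL, INL, OPL, ONL, inner to
outer), background, or an artifact class. The questions are
quantitative and pixel-based:

* how much of each layer is positive for each stain, per donor group
  (AD vs control) and retinal region (central, ~5 mm from the optic
  nerve head, vs mid-peripheral, ~10 mm);
* whether amyloid positivity is *enriched* inside a marker's pixel
  footprint relative to outside it (conditional colocalization);
* how macroglia staining partitions into GS∩GFAP (activated Müller
  cells), GS-only (resting Müller cells) and GFAP-only (astrocytes);
* what fraction of amyloid-positive pixels is covered by microglia.

The package implements this pipeline end to end, together with a
synthetic-retina generator that produces images with *known* per-layer
positive fractions and a controllable amyloid-marker enrichment, so
every stage can be validated against ground truth.

## Data model

A `LayerMask` is an integer matrix with the fixed coding 0 background,
1--6 = RNFL..ONL, 7 = artifact. Channels are 16-bit intensity matrices
that must match the mask's shape exactly; the pipeline never resamples.
An `image_record()` bundles mask, channels and metadata and validates
all of it up front; unknown labels or shape mismatches are fatal for
the record. Artifact pixels never enter any numerator or denominator.
Whole layers can additionally be excluded per image
(`exclude_layer()`); the exclusion removes exactly that layer's rows
from every downstream table and leaves all other layers bit-identical,
which is tested. Excluding all six layers is equivalent to dropping the
image.

## Pixel classification

Positivity is defined by a single intensity threshold per channel and
image, with inclusive comparison (`intensity >= t`); inclusivity is an
arbitrary but fixed convention needed for bit-exact reproducibility.
The default policy recomputes an Otsu threshold per image *restricted
to tissue pixels* (background and artifact excluded), maximising the
between-class variance of the considered histogram; ties are broken
toward the lowest threshold. The restriction to an arbitrary pixel
subset is why the criterion is computed directly on the masked
histogram rather than on the full frame. Because the raters' original
numeric thresholds for such data are generally not published, a
`fixed` policy (per channel role, with per-cohort overrides) exists to
inject any externally chosen value; a fixed policy loaded with the
Otsu value reproduces the Otsu mask bit-exactly. `rater_panel()`
writes mask-outline overlays for candidate thresholds so human raters
can compare them side by side; it changes no analysis state.

Otsu thresholding is known to misplace the cut when the positive class
is an extreme minority *and* the modes are close. The synthetic
intensity model keeps the modes ~27 pooled standard deviations apart,
where this failure mode is absent; on real data with faint staining
the fixed policy is the recommended route.

## Per-image quantities

All percentages are on the 0--100 scale throughout. For a layer L and
positivity masks A (red/amyloid) and M (green/marker):

* layer fraction: `100 |A ∩ L| / |L|`;
* conditional colocalization: `p_pos = 100 |A ∩ M ∩ L| / |M ∩ L|`
  against `p_neg = 100 |A ∩ Mᶜ ∩ L| / |Mᶜ ∩ L|`. If amyloid were
  deposited at random locations the two would coincide; `p_pos > p_neg`
  is the colocalization signal.
* coverage: `100 |A ∩ M ∩ L| / |A ∩ L|` (microglial engagement with
  deposits);
* macroglia partition: the three disjoint classes GS∩GFAP, GS-only,
  GFAP-only as percentages of the inner (RNFL+GCL+IPL) or outer
  (INL+OPL+ONL) layer-group pixel count. Counts are pooled across the
  three layers *before* dividing; averaging per-layer percentages of
  unequal-size layers would bias the statistic.

Ratios with empty denominators propagate as `NA`, never as 0: a layer
with no amyloid has *undefined* -- not zero -- coverage. The identity
`|A∩L| = |A∩M∩L| + |A∩Mᶜ∩L|` holds bit-exactly on the pixel counts and
is exercised on random mask triples in the test suite.

## From images to inference

The unit of statistical analysis is the *data point*: one value per
donor, region and layer (or layer group), the arithmetic mean over the
donor's contributing images (up to 2 sections × 2 images). The
analysis grid therefore has 12 geo-layers per cohort (2 regions × 6
layers; 2 × 2 in layer-group mode).

**Outlier screening.** Group-by-geo-layer values are screened with the
modified z-score `0.6745 |x − median| / MAD > 3.5`, with no exclusion
below n = 3. When the MAD is zero the scaled mean absolute deviation
substitutes; if both are zero nothing is excluded. A single pass is
not idempotent (removing an extreme shrinks the MAD), so the rule is
iterated to convergence and the converged rule is tested for
idempotence. The threshold and minimum n are configurable
(`outlier_threshold`, `outlier_min_n`); `Inf` disables screening.

**Group comparisons.** AD vs control values are compared per geo-layer
with a two-sided Wilcoxon rank-sum test. The implementation enumerates
the exact permutation null of the midrank statistic whenever
`choose(n, n1)` is at most 2·10^5 -- *including under ties* -- and
falls back to a tie-corrected normal approximation beyond that. The
usual convention of switching to the normal approximation as soon as
ties appear was deliberately not adopted: at the sample sizes this
design produces (5--12 donors per group) the approximation is at its
weakest exactly when ties are most likely, while tie-aware enumeration
is cheap and agrees with brute-force permutation by construction. In
the no-ties regime the enumeration reproduces `stats::wilcox.test`'s
exact p-values, which the test suite checks as an independent
cross-check.

**Colocalization calls.** The enrichment hypothesis is within-image
and therefore paired: per donor and geo-layer the paired difference
`p_pos − p_neg` is tested with a two-sided exact Wilcoxon signed-rank
test (zero differences dropped; midranks; exact null by convolution
over sign patterns). Significant colocalization is declared at
p < 0.05 together with a positive median difference. A consequence
worth knowing: with only 5 donors the smallest attainable two-sided
exact p-value is 2/2^5 = 0.0625, so a 5-donor group can never produce
a p < 0.05 colocalization call under this test. Reports of significant
calls in 5-donor groups must therefore rest on a different (for
example unpaired or approximate) test; the package keeps the exact
paired test as the documented default and reports the attainable
p-values honestly.

No multiple-testing correction is applied by default -- per-geo-layer
p-values are reported raw, matching the reporting convention the
pipeline emulates -- and Benjamini-Hochberg adjustment is available via
`p_adjust = "BH"`.

## The synthetic-retina generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the pipeline is designed around: 5 AD and 7 control
donors, two cross-sections per donor, two images per region per
cross-section, giving 96 images per cohort. The default geometry is a
180 × 200-pixel banded cross-section with thicknesses
RNFL 20, GCL 20, IPL 30, INL 25, OPL 15, ONL 35 (pixels; no physical
pixel size is assumed anywhere -- the source protocols do not state
magnification, so synthetic geometry is in pixels only).

**Joint pixel law.** Within a layer, each pixel draws the green
channel Bernoulli(`p_green`); the red channel is then Bernoulli(`q_pos`)
on green-positive and Bernoulli(`q_neg`) on green-negative pixels, with

* `q_neg = p_red / (p_green·rho + 1 − p_green)`, `q_pos = rho·q_neg`,

so the red *marginal* is exactly `p_red` for every `rho`, and
`rho = q_pos/q_neg` is the enrichment the colocalization test is meant
to detect (`rho = 1` is independence). Triples for which the implied
conditionals leave [0, 1] are rejected at scenario validation, naming
the offending (group, region, layer) cell.

**Intensity model.** Foreground and background intensities are
Gaussian (defaults: background 3000 ± 1000, foreground 30000 ± 3000
grey levels), clipped to the 16-bit range. The wide separation makes
global thresholding essentially error-free, so recovery tests measure
the pipeline's accounting, not threshold luck.

**Donor variability.** A logit-scale random effect (sd 0.15 by
default) perturbs each marginal fraction independently per (donor,
region, layer, channel). The per-geo-layer independence mirrors the
analysis design, whose unit is the donor × geo-layer data point; a
single global per-donor shift would instead make all geo-layers of a
cohort succeed or fail together, which is neither how the statistics
treat them nor a useful validation regime. The magnitude 0.15
(multiplicative spread of roughly ±35% on small fractions across ±2
sd) was chosen once as a modest inter-donor staining/biology
variability and is a scenario parameter (`donor_sd`), with 0 giving
exactly parameter-faithful images.

**Default scenario patterns.** Per cohort, the parameter tables encode
the qualitative disease pattern the pipeline is meant to detect:
amyloid doubled in AD mid-peripheral GCL/IPL/INL/OPL with no central
group difference; GFAP reduced (×0.6) and IBA-1 elevated (×1.8) in AD
mid-peripheral layers; strong amyloid-neuron enrichment (rho = 3),
weak amyloid-astroglia enrichment (rho = 1.2), and amyloid-microglia
enrichment that is strong in controls (rho = 3) but blunted in AD
(rho = 1.5); a GS cohort with reduced activated-Müller overlap in AD
mid-peripheral retina. Control positive fractions are in the 1--50%
range typical of such stains (amyloid ~1--2.5%, GFAP up to 40% in the
RNFL, IBA-1 2--5%, TUBB3 15--50%, GS 20--30%).

**What the generator does not emulate.** Pixels are independent given
their layer: there is no spatial clustering into deposits or somata,
no point-spread function, no autofluorescence, no section-to-section
registration error, and the nuclei channel is purely cosmetic.
Passing validation therefore demonstrates that the *accounting and
inference* are correct under the declared sampling law -- it does not
certify performance on real microscopy, where threshold choice and
artifact segmentation dominate the error budget.

## Numerical conventions

* Every stochastic step derives its stream from a single scenario
  seed; per-image sub-seeds are produced by a fixed affine map modulo
  a < 2^31 prime, so datasets are bit-reproducible and helpers restore
  the caller's RNG state.
* Intensities are rounded then clipped to [0, 65535]; label masks
  round-trip pixel-for-pixel through 8-bit TIFF and NIfTI (the latter
  for ITK-SNAP interoperability).
* Otsu ties break toward the lowest maximising threshold; the
  threshold actually applied is logged per image.
* Degenerate inputs have defined behaviour: constant images admit no
  threshold (error); empty layers yield no row (with a warning);
  empty denominators yield `NA`; all-zero paired differences yield
  p = 1 with a flag; groups emptied by exclusion yield
  not-computable comparison rows rather than errors.

## Validation problem sizes

The test suite and the acceptance script validate on sizes chosen to
give tight statistical tolerances at interactive runtimes: binomial
concentration and conditional-law checks on 10^4--10^5-pixel layers;
parameter recovery pooled over ten 24-image replicate cohorts
(~3000--4200 pixels per geo-layer cell, 480 cells); test calibration
on 1000 simulated null geo-layers of 7 donors × 10^4 pixels (expected
rejection 4.7% at the attainable exact levels, checked against a
3--7% band) and power at rho = 3 on 200 replicates; and the full
study-size scenario (96 images, 180 × 200 px) for the end-to-end
disease-pattern check. Because a per-geo-layer test at alpha = 0.05
*should* false-positive occasionally, that check requires at least 3
of the 4 truly elevated mid-peripheral geo-layers to be called and at
most one alpha-level call among the six truly-null central geo-layers,
rather than literal all-or-nothing patterns.

## Known limitations

* The outlier rule emulates a "sample-size adapted" screen whose exact
  published form is not recoverable; the modified z-score with
  iterated convergence is a documented, deterministic stand-in, and
  the criterion is pluggable.
* The exact paired signed-rank floor at n = 5 (p ≥ 0.0625) discussed
  above.
* Per-cohort fixed thresholds versus per-image automatic thresholds
  are both supported, but nothing in the package can recover what a
  human rater would have chosen on real images.
* No mixed-effects modelling of the donor/section/image nesting: data
  points are plain means, matching the emulated design.
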