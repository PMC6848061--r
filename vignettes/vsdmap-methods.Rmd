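---
title: "Evoked cortical response mapping from VSD movies: models and methods"
author: "vsdmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evoked cortical response mapping from VSD movies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdmap)
```

## The measurement problem

Voltage-sensitive dye (VSD) imaging reports population membrane potential
of superficial cortical layers as small fractional changes of fluorescence.
In the trigeminal neuropathic-pain paradigm this package targets, rats
receive a partial infraorbital nerve ligation (pl-ION) or a sham surgery,
optionally with systemic minocycline, and three days later the exposed
cortex (primary somatosensory cortex S1 and the secondary somatosensory /
insular oral region, S2/IOR) is imaged while the whisker-pad skin, the
mandibular molar pulp or the mentum skin is electrically stimulated.  The
acquisition is a stimulus-locked movie: a 6.4 x 4.8 mm field imaged at
184 x 124 px, 4 ms per frame (250 Hz), 500 ms per sweep, with paired
no-stimulation ("blank") sweeps.  Evoked depolarizations are fractions of
a percent of the resting fluorescence, so the analysis chain — bleaching
removal, trial averaging, dF/F, spatial smoothing, noise-referenced
detection — *is* the measurement.  `vsdmap` implements that chain, the
cross-animal overlap mapping, the behavioral threshold rule and the group
statistics, plus a synthetic generator that emulates the acquisition so
every stage can be validated against ground truth.

## The generative model behind the synthetic cohorts

`simulateTrialSet()` draws stimulated and blank raw-fluorescence stacks as

$$\mathrm{stim}_i(x, t) = F_0\, b(t)\,\bigl(1 + s_i \textstyle\sum_j
  A_j\, G_j(x)\, g_j(t)\bigr) + \varepsilon,\qquad
  \mathrm{blank}_i(x, t) = F_0\, b(t) + \varepsilon,$$

with $b(t) = e^{-t/\tau_b}$ the dye-bleaching drift shared by the members
of a trial pair, $G_j$ a Gaussian spatial profile of spread $\sigma_j$
pixels, $s_i$ a per-trial amplitude scale with configurable CV, and
$\varepsilon$ iid Gaussian sensor noise.  The temporal kernel is an
alpha-function rise times an exponential decay,

$$g(t) \propto (t/\tau_r)\, e^{1 - t/\tau_r}\, e^{-t/\tau_d},$$

with defaults $\tau_r = 10$ ms, $\tau_d = 80$ ms, chosen so the 90–10%
decay completes well inside the 500 ms sweep, as the recordings it
emulates do.  Two numerical choices matter:

* **Discrete normalization.**  The kernel is normalized to peak 1 *on the
  sampled frame grid*, not at its continuous maximum, so a focus's
  configured amplitude is exactly the peak dF/F it produces at the focus
  centre.  This is what makes the generative equation invertible: with
  zero noise and no bleaching, the preprocessing chain returns the
  configured amplitude to numerical precision, which the test suite
  asserts at 1e-6.
* **Noise model.**  Additive Gaussian per pixel per frame.  Only the
  baseline SD enters the detection rule, so a photon-count model would
  add parameters without changing what is being tested.

Bleaching is a single spatially uniform exponential; the pipeline removes
it by blank subtraction, so its exact form is irrelevant to the
correctness of that contract (the tests assert the blank and stimulated
members of a pair share the same curve).  Amplitudes are dimensionless
fractions internally and become percent only at reporting boundaries.
The stimulus is delivered at frame 26 (100 ms into the sweep) by
default; the alignment of stimulus to sweep is an acquisition convention,
not a measured quantity.  All frame indices in the R interface are
1-based; frame $i$ covers $[(i-1)\cdot 4, i\cdot 4)$ ms.

### Cohort calibration

`simulateCohort()` turns published group summaries (mean % dF/F, SEM, N)
into per-animal true amplitudes.  Peak amplitudes are physically
non-negative and, for groups whose SD is comparable to the mean,
right-skewed, so base draws come from a gamma distribution matched to
the target mean and SD and then standardized.  In *exact* calibration
mode each group's draws are affinely rescaled so the realized mean and
SEM equal the targets to numerical precision (this needs n >= 2, since a
SEM is otherwise undefined); draw sets whose calibrated minimum falls
below a detectable amplitude (default 0.01% dF/F) are redrawn with a
deterministically advanced seed.  In *stochastic* mode the draws are
left untouched and converge on the targets over seeds.  Draws are seeded
per site, so two groups with identical targets and n receive identical
draws — a deliberate property that makes calibration transparent.

### Gain calibration of the measurement chain

The 9 x 9 smoothing filter attenuates a Gaussian focus: for the default
$\sigma = 8$ px the measured peak is about 95.5% of the generated one.
Since the whole chain (generation through detection) is linear in
amplitude when noiseless, `runPipeline()` measures this gain once per
focus template by probing with a known amplitude, and divides the
generator amplitudes by it.  Recovered peaks then sit exactly on the
calibrated draws — the same gain calibration an imaging rig undergoes —
and the group statistics computed from recovered amplitudes equal the
statistics of the targets.  With noise present the gain compensation is
still applied but exactness is no longer claimed.

## The preprocessing chain

The order is fixed and recorded in each object's provenance:
**subtract** (blank from stimulated, framewise; the per-pixel
pre-stimulus mean of the blank is added back so the later dF/F
denominator remains a physical fluorescence level) → **average**
(pixelwise mean over the 40 stimulated/blank trial pairs of one
acquisition; the two orders, subtract-then-average and
average-then-subtract, are equal by linearity and the suite asserts it)
→ **dF/F** (per pixel, $F$ = mean over the baseline window, every frame
becomes $(v - F)/F$; a non-positive $F$ anywhere is an error naming the
pixel) → **filter** (per-frame 9 x 9 uniform box mean).

Numerical choices:

* **Baseline window.**  Frames 1 to (stimulus onset − 1).  The source
  protocol says only "initial intensity"; all pre-stimulus frames give
  the most stable $F$.
* **Box, not Gaussian.**  "Spatial filter (9 x 9 pixels)" describes a
  footprint, not a weighting; a uniform mean is the minimal reading, and
  a Gaussian of the same footprint is selectable
  (`spatialFilter(type = "gaussian")`).
* **Border rule.**  Symmetric (mirrored, edge included) padding, so a
  spatially constant frame is exactly unchanged.  The filter is
  implemented as a separable running mean and is tested against a direct
  convolution oracle at 1e-12.

## Detection: the 7 x SD rule and the response descriptors

`estimateNoise()` computes the per-pixel sample SD of the smoothed dF/F
signal over the pre-stimulus window (a globally pooled variant exists
behind `pooled = TRUE`; the per-pixel map is the default because sensor
noise varies across the field).  A pixel is *significant* in a frame iff
its value exceeds `k = 7` times its baseline SD — one-sided, because the
analysis targets excitation.  On noiseless synthetic input the SD map is
identically zero, so detection takes an absolute floor (`floor`,
default 0.005% dF/F in the pipeline driver); supplying no floor with a
zero SD map is an error rather than a silent always-significant rule.

The descriptors mirror the published definitions:

* **Initial response** — the first frame with at least `mMin = 5`
  significant pixels (a speckle guard; a single super-threshold pixel
  should not define the response onset), outlined as the largest
  8-connected significant component in that frame; its
  intensity-weighted centroid, rounded to the nearest pixel, is the
  *initial centre*.
* **Peak amplitude / maximum response** — the maximum of the signal at
  the initial centre over frames from the initial frame on (ties resolve
  to the earliest frame); the maximum response is the significant
  component containing the centre in that frame.
* **90–10% decay** — measured on the falling phase of the centre trace
  with linear interpolation between frames; undefined (NA, flagged) when
  the trace does not fall below 10% of peak within the sweep.

Detection can be restricted to a disc around a configured site centre
(`within =`), which is how the S1 and S2/IOR responses evoked in the
same movie are measured separately.  Site labels are configuration, not
anatomy inference — within the barrel field the movie cannot
distinguish S1 from S2, and the package does not try.

An exhaustive brute-force reference (plain loops, flood fill, written
independently in the test helpers) must agree exactly with the
implementation on small movies; this is asserted in the suite.

## Cross-animal alignment and overlap maps

Animals are aligned by two anatomical lines: the middle cerebral artery
(MCA) and the rhinal fissure.  The transform family is rigid —
translation plus rotation, no scaling — because both landmarks are
lines (scale is not identifiable from them) and brain size varies
little at the ages in question; a translation-only mode exists.  The
fit maps the moving MCA–rhinal intersection onto the reference
intersection and aligns the rhinal-fissure directions (angles taken
modulo 180°, difference wrapped to (−90°, 90°]).  Animals whose
landmarks cannot be resolved are *excluded* from overlap maps, mirroring
the published exclusion rule; this is a flag, not an exception, and the
exclusion is logged in the pipeline output.

Outlines are warped by nearest-neighbour mapping (masks stay binary; no
interpolation); pixels leaving the field are dropped and counted.  The
overlap map counts covering animals per pixel and thresholds at
`ceiling(fraction * n)` with `fraction = 0.5`: with odd n, "50% of
animals" means the strict majority.  The contour is exported as the
boundary pixel set of the thresholded mask.  Overlap maps are
descriptive output only — the package deliberately computes no
excited-area statistics (pixel counts, mm²) as endpoints, since
excitation frequently propagates beyond the field of view and such
quantification would not be trustworthy.

## Behavioral thresholds

The head-withdrawal threshold (HWT) is the minimum von Frey filament
force (of the standard 4–100 g set) whose withdrawal count reaches the
criterion.  The published phrase "more than 3 of 5" is internally
inconsistent with "minimum intensity"; the package defaults to the
conventional majority reading, >= 3 of 5, with the strict >= 4 variant
selectable via `criterion = 4`.  Sessions where no force qualifies are
censored above 100 g and reported as `Inf` with a flag; censored values
are never averaged into group summaries (censored counts are reported
separately).  The synthetic session generator uses a logistic
psychometric function of force centred at the true threshold; its
infinite-slope limit is a step function, which makes the rule's
boundary behaviour exactly testable.

## Group statistics

Group summaries are mean ± SEM (sample SD over sqrt(n)).  Tests are
classic pooled-variance Student's t — the named test of the source
analysis — reconstructible from printed (mean, SEM, N) triplets alone:
$SD_i = SEM_i\sqrt{n_i}$, pooled variance with $n_1 + n_2 - 2$ df,
two-sided p.  A Welch variant sits behind `welch = TRUE`.  Multiple
comparisons use Bonferroni with family size 3 (the three pairwise group
comparisons per site); 0.05/3 is presented round-down as 0.016, but
significance is decided against the exact quotient 0.01666… by default,
with `strictPrinted = TRUE` deciding against the printed value — the
source text does not say which was used, and the default is the
mathematically exact one.  Zero-variance degeneracies are explicit:
equal means give t = 0, p = 1; unequal means are flagged degenerate with
p reported as 0.

Recomputing all 15 printed comparisons from the printed summaries
reproduces the printed significance statement for six of them; the
others are reported without assertion because two-decimal rounding of
the printed summaries does not pin their p-values down (for three
printed bounds the recomputed p in fact lands on the other side of the
threshold, which is expected behaviour of rounded inputs, not a defect
of the test).

## Problem sizes and study conditions

The deterministic end-to-end reproduction runs the full acquisition
geometry (184 x 124 px, 125 frames) with exact calibration, one trial
pair per animal (averaging identical noiseless trials is a no-op) and
bleaching disabled; 46 + 40 + 37 animals across the three stimulation
sites.  The stochastic studies run 40-trial acquisitions on a cropped
64 x 48 px field at the full pixel pitch and frame rate (75 frames),
with true peaks drawn from 0.2–0.9% dF/F, trial jitter CV 0.1, and raw
noise set so the post-averaging baseline dF/F SD is 0.03% (the 9 x 9
filter then reduces it further); 50 seeds for amplitude recovery and
100 noise-only seeds for the false-detection rate.  The focus spread in
these studies is sigma = 12 px (about 0.4 mm, a realistic cortical
response scale); substantially narrower foci would be attenuated by the
9 x 9 footprint by more than the recovery tolerance, which is a real
property of the method, not of the implementation.

## What the synthetic validation does and does not show

The generator reproduces the statistical structure the analysis
assumes: shared bleaching between pair members, white sensor noise,
alpha-kernel transients at configured foci, per-trial amplitude jitter,
cross-animal landmark displacement and group amplitude distributions
matched to published summaries.  It deliberately omits hemodynamic and
pulsation artifacts, dye internalization kinetics, spatially correlated
noise and response-shape variability across animals.  Passing tests
therefore demonstrate that the implementation computes the published
analysis correctly and recovers known ground truth under the stated
conditions — not that the analysis is robust to every artifact of real
recordings.  The published in-vivo amplitudes and behavioral time
courses are reproduced only through calibration (no raw data are
deposited with the source study), so agreement there validates the
statistical chain, not the biology.

## Known limitations

* The initial centre is a single pixel; with strong noise its position
  can shift by a pixel or two, which perturbs the peak estimate by the
  local curvature of the response profile.
* The 90–10% decay is undefined whenever the sweep ends above 10% of
  peak; long-tailed responses therefore report NA rather than an
  extrapolated value.
* Nearest-neighbour warping loses or duplicates single boundary pixels
  under rotation; alignment round trips are exact only for integer
  translations (the suite bounds the rotational case by a Jaccard
  criterion instead).
* Exact-mode group SEM reproduction relies on every animal's response
  being detected; amplitudes below the detection floor are excluded by
  the draw guard rather than modelled.
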