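---
title: "fluorquant: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluorquant: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorquant)
```

# The measurement problem

A nuclear-localized fluorescent biosensor is degraded unless stabilized by
its target, so a cell scores as "positive" when its nuclear EGFP signal
rises above what unstabilized sensor produces. The assay readout is
population-level: the fraction of positive cells per well, aggregated over
technical replicate wells per sample, and compared between conditions. A
companion in vivo experiment asks the same question of per-nucleus sensor
intensity in two-photon z-stacks, where bright autofluorescent structures
contaminate the sensor channel but are equally visible in a second (blue)
emission channel.

`fluorquant` implements this whole measurement chain, plus a synthetic
image generator with exact ground truth so that each stage — and the chain
as a whole — is testable without access to raw microscope data.

# Image model and containers

Images live in a `ChannelStack`: a `(row, col, channel, z)` array of raw
camera counts (AU) at 8- or 16-bit depth, with each biological role
(`nuclear`, `expression`, `sensor`, `auxiliary`) mapped to exactly one
channel. Counts are never rescaled on load. All coordinates in the package
are **1-based `(row, col)` with the origin at the top-left**, matching R's
matrix indexing; this is deliberate — a 0-based convention would fight
every base-R and Bioconductor container the tables interoperate with.
Multi-page TIFFs are read channel-fastest (`c1 z1, c2 z1, …`), and the
write/read round trip is bit-identical. Segmentations are `LabelImage`
objects: dense labels `1..K`, each one connected component under a declared
4- or 8-connectivity, with labels assigned in raster-scan (row-major) order
of each object's first pixel so that relabeling is order-stable.

# Segmentation chain

`segmentCells()` runs: maximum z-projection → optional grayscale despeckle
→ global threshold → strict `> t` binarization → mask despeckle →
connected components → inclusive size filter → dense relabel. The same
operator chain serves both workflows; only the threshold source and the
despeckle count differ. Rationale: the in vivo mask recipe is fully
specified (Li threshold, four despeckle rounds, 20–150 px), while the
plate-side cell identification is only described as automatic; reusing one
audited chain keeps a single code path under test.

**Li threshold.** `liThreshold()` returns the integer gray level `t`
minimizing the minimum cross-entropy criterion

$$\eta(t) = \sum_{g \le t} h(g)\,g \log\frac{g}{\mu_{low}(t)}
          + \sum_{g > t} h(g)\,g \log\frac{g}{\mu_{high}(t)},$$

where $h$ is the intensity histogram and $\mu_{low},\mu_{high}$ are the
class mean intensities. The implementation evaluates $\eta$ for *every*
candidate threshold via cumulative histogram sums, so the returned value is
the global argmin — not a fixed-point iteration that could stall in a local
optimum. Conventions: zero-intensity bins contribute 0 (the limit
$g\log g \to 0$); candidates range over `[min, max)` so both classes are
non-empty; ties resolve to the smallest `t`; a constant image is a
degenerate-input error. Binarization is strict (`pixel > t` is foreground),
reading "above" literally; ties at the threshold go to background.

**Despeckling.** `despeckle()` is an iterated 3×3 median with
edge-replicated borders, implemented as a 19-comparator median-of-9
selection network over shifted pixel planes (vectorized, no sorting). A
median never introduces values absent from the input; idempotence is *not*
claimed (not generally true) — tests assert equivalence with a naive
sliding-window oracle instead. The in vivo workflow uses four rounds; the
plate default is one round, which is enough to remove isolated noise pixels
at the generator's default noise level while eroding small nuclei less.
Whether the original processing despeckled the binary mask or the grayscale
image is ambiguous; the mask side is the default (`despeckleStage =
"post"`), with the grayscale option behind `"pre"`.

**Components and size filter.** Connected components are found on a
pixel-adjacency graph (igraph) under the configured connectivity
(8-connected by default, the common particle-analysis convention). The
20–150 px nucleus-size band is read as a **closed interval** (areas of
exactly 20 or 150 px survive). Border-touching objects are kept by default
(`borderPolicy = "drop"` available). No watershed splitting of touching
nuclei is attempted — the generator avoids overlap by construction, and
this is a real limitation for dense real-world fields (see Limitations).

# Quantification and classification

The background region of interest is the complement of the union of all
objects dilated by `marginPx` (default 3 px, Chebyshev radius); the
background estimate is the mean intensity over that region, computed per
image and per channel. Per-cell raw means are arithmetic means of in-mask
pixels; corrected means subtract the background estimate and floor at zero.
The sensor/expression ratio normalizes for induction level and is undefined
(NA) when the corrected expression mean is not positive; such cells stay in
the positive-fraction denominator but drop out of ratio summaries.

Two positivity rules, both strict (`>`):

* `control_null`: threshold `mean + k·SD` of the background-corrected
  signal in negative-control cells, `k = 2` by default, sample SD (n−1
  denominator — the data are a sample of the null population). Controls
  are pooled across all control images of the experiment, maximizing the
  null sample size; per-plate pooling is a configuration choice.
* `fixed`: threshold 400 AU by default. Whether that constant refers to
  the 16-bit camera scale is not derivable, so it is a free parameter.

Under a normal null, the control-null rule's false-positive rate converges
to $1 - \Phi(2) \approx 0.0228$; the test suite and acceptance script
verify this calibration at $n = 10{,}000$ within ±0.005.

Aggregation follows the replicate structure: per-image fraction → per-well
fraction (cells pooled across the well's fields) → per-sample value
(unweighted mean of the sample's replicate-well fractions). Wells with zero
cells are flagged and excluded from the sample mean. The replicate unit
entering group statistics is the per-sample value.

# Group statistics

`oneWayAnova()`, `tukeyHsd()` and `tTestUnpaired()` wrap `stats::aov`,
`stats::TukeyHSD` and `stats::t.test` behind a uniform `StatsResult`
container. "Student's t" is read as the pooled-variance form (df
$n_a+n_b-2$), with Welch's correction behind a flag. Tukey adjusted
p-values come from R's studentized-range distribution (`ptukey`), which
handles unequal group sizes via the Tukey–Kramer standard error; the test
suite pins it against the tabulated critical value $q_{0.05}(3, 12) =
3.773$ and against the exact two-group identity $q = \sqrt{2}\,|t|$.
Edge conventions: zero between-group variance gives $F = 0, p = 1$; zero
variance both between and within is undefined (error); a t-test with zero
pooled variance and unequal means follows the $p \to 0$ convention with a
warning.

# The synthetic generator

`generateWellField()` renders nuclei as anti-aliased disks (coverage
$\mathrm{clamp}(r + 0.5 - d, 0, 1)$; mask = pixel centers within $r$),
placed by rejection sampling with centers at least the sum of radii plus
2 px apart — cells are resolvable by construction, matching the per-cell
averaging assumption. Each cell draws a lognormal mCherry intensity; a
Bernoulli draw with `pPositive` decides positivity; sensor intensity is
`baseline` for negatives and `baseline + gain × mCherry` for positives, so
positive sensor signal is coupled to expression as in an induced reporter.
Uniform background, optional Poisson shot noise (applied to the noise-free
signal) and Gaussian read noise are added, in that order, then values are
rounded and clipped to the bit depth. The returned label image is the exact
ground-truth mask, and `true_mcherry`/`true_sensor` record the mean
noise-free rendered value (background included) over the mask pixels, so
anti-aliased rim pixels are accounted for exactly.

Randomness is split into four documented sub-streams (placement,
expression, positivity, noise) derived from the master seed
(`synthStreamSeeds()`), and noise is drawn in fixed channel order. Two
consequences are contractual: any single stream can be replayed in
isolation (the positivity draws are literally `rbinom(nCells, 1,
pPositive)` under the positivity sub-seed), and changing `pPositive`
alters only the sensor channel, bit for bit.

`generateInvivoStack()` emits a two-channel z-stack: green = nuclei plus
bright blobs, blue = the same blobs only, co-localized and
intensity-matched, so green − blue cancels the blobs exactly in the
noise-free render. Each nucleus and blob occupies one z-plane (planes are
otherwise independent — no 3D PSF). Nucleus radii are drawn from
[2.8, 6.4] px so rendered mask areas stay within the 20–150 px band;
out-of-band renders are redrawn. The blob count is an exact integer per
field, not a Poisson rate, keeping the determinism contract simple.

**Default parameters are synthetic choices, not measurements.** No
intensity statistics for positive versus negative cells are derivable from
the assay description, so defaults were fixed once for comfortable class
separability on a 16-bit scale: 512×512 fields, 200 cells, nucleus radius
3–5 px (areas ≈ 28–78 px), nuclear stain 3000 AU, mCherry lognormal
(meanlog = log 2000, sdlog = 0.4), sensor baseline 100 AU with unit gain,
background 100 AU, read noise 20 AU, shot noise off, blobs 6000 AU. The
simulated in vivo control side uses 800 AU nuclei — dim but resolvable
above the ~30 AU noise floor of the subtracted projection, so both masks
capture real nuclei rather than noise. What passing tests therefore show is
that the chain is *correct and calibrated* under resolvable-cell,
uniform-background conditions; they do not show robustness to overlapping
nuclei, illumination gradients, debris, or weakly separated intensity
distributions, none of which the generator emulates.

# Pipelines and determinism

`runPlate()` orchestrates plate analysis from one YAML-serializable
configuration: per well and field — read, segment on the mCherry expression
channel by default (so untransduced cells never enter the denominator),
measure, classify (control-null thresholds pooled from the configured
control condition), aggregate, then ANOVA + Tukey on per-sample fractions
by condition. Per-field errors quarantine the field and are logged with its
identity; the run aborts only if more than 50 % of fields fail (an
arbitrary, documented cutoff). `runInvivo()` runs the published mask recipe
per stack and pools per-nucleus intensities per condition into an unpaired
two-tailed t-test; unreadable stacks and stacks with no surviving nuclei
are skipped with a logged warning. The analysis path contains no random
step, so identical configuration and inputs reproduce output CSVs byte for
byte; generator invocations derive per-field sub-seeds from one master
seed. Every output row carries its sample/well/field/cell identity.

# Numerical choices and problem sizes

* Histogram thresholds operate on integer AU values; non-integer inputs
  (e.g. after projection arithmetic) are rounded.
* Threshold tie-break: smallest argmin; binarization strict `>`.
* Median/dilation border policy: edge replication.
* Ratio guard: expression mean must exceed 1e-6 AU.
* The test suite and acceptance script size simulations to desk scale:
  50 random images for the Li oracle, 20 for the despeckle oracle,
  10,000 + 10,000 cells for null calibration, 500-cell wells over
  `pPositive` ∈ {0, 0.1, 0.3, 0.7, 1} for recovery (20 seeded runs per
  value in the suite, 10 in the script), 2,000 simulated null experiments
  for ANOVA type-I error, four stacks for the in vivo rates. Recovery
  error at these sizes is dominated by the Bernoulli sampling noise of the
  generator itself (±0.02 SD at n = 500), not by the pipeline.

# Known limitations

* No watershed or other splitting of touching objects; dense or
  overlapping nuclei in real data will merge and be size-filtered out.
* Background is modeled and estimated as spatially uniform per image; no
  flat-field or illumination-gradient correction.
* No PSF, photobleaching, or true 3D rendering; z-planes are independent.
* The 400 AU fixed threshold is scale-dependent and must be recalibrated
  for any other acquisition setup.
* Statistics are limited to ANOVA/Tukey/Student's t on replicate-level
  values; no nonparametric alternatives or mixed models.
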