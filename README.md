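# fluorquant

Quantification pipeline for **nuclear fluorescent-reporter (biosensor)
assays** in multi-channel fluorescence microscopy. The package is written
for experiments in which a cell line expresses a conditionally stabilized
EGFP sensor targeted to the nucleus together with an mCherry induction
control: the scientific readout is the *fraction of reporter-positive
cells* per well, compared across treatment conditions, and the distribution
of per-nucleus sensor intensity in vivo.

It covers the full analysis path:

* **Segmentation** — cells/nuclei are identified automatically on the
  nuclear-stain or mCherry channel: maximum z-projection, global threshold
  (Li's minimum cross-entropy by default, Otsu or fixed as alternatives),
  strict `> t` binarization, iterated 3×3 median despeckling, connected
  components (4- or 8-connectivity) and an inclusive 20–150 px nucleus-size
  filter.
* **Quantification** — per-cell mean intensity in every channel, corrected
  by a per-image background estimate (mean over all pixels outside the
  dilated cell footprints) and floored at zero; sensor/expression ratio to
  normalize for induction level.
* **Classification** — a cell is positive when its background-corrected
  sensor mean is *above* (strictly) either `mean + k·SD` of a
  negative-control cell population (k = 2 by default) or a fixed cutoff
  (400 AU by default).
* **Aggregation** — per-image and per-well fractions (cells pooled within a
  well) and per-sample values (unweighted mean over a sample's replicate
  wells, as for patient CSF triplicates).
* **Statistics** — one-way ANOVA with Tukey HSD post-hoc comparisons on the
  per-sample fractions, unpaired two-tailed Student's *t*, and SEM
  summaries.
* **In vivo workflow** — for two-channel z-stacks with autofluorescent
  blobs visible in both channels: subtract the blue maximum projection from
  the green one (clipped at 0), Li-threshold, despeckle ×4, keep 20–150 px
  components, measure per-nucleus mean intensity and compare conditions
  with a pooled *t*-test.
* **Synthetic data** — a generator with exact ground truth (anti-aliased
  disk nuclei, lognormal mCherry, bimodal sensor signal coupled to
  expression, background, Poisson/Gaussian noise, co-localized blob mode)
  so every stage is testable without raw images.

The central statistic: with per-cell background-corrected sensor mean
`s_i`, a control population `C`, and threshold
`t = mean(C) + 2·SD(C)` (or `t = 400 AU`), the well-level readout is
`f = #{i : s_i > t} / n`, and samples are compared by one-way ANOVA
(`F = MS_between / MS_within`, df `(k−1, N−k)`) with Tukey HSD adjusted
p-values from the studentized-range distribution.

## Worked example

Simulate a small two-condition plate (30 % positive cells vs. an untreated
control), then run the full analysis with the control-derived mean + 2 SD
rule:

```r
library(fluorquant)

dir <- file.path(tempdir(), "demo")
simulatePlate(dir,
              data.frame(condition = c("csf", "control"),
                         p_positive = c(0.3, 0), n_wells = c(3, 3)),
              fieldsPerWell = 2,
              params = synthParams(imageHeightPx = 256, imageWidthPx = 256,
                                   nCells = 80),
              seed = 42, wellsPerSample = 1)

res <- runPlate(runConfig(
  paths = list(images_dir = dir, plate_map = "plate_map.csv"),
  classification = list(kind = "control_null",
                        control_condition = "control"),
  output_dir = file.path(dir, "out")))

res$summaries$perSample
#>     sample_id condition n_wells fraction_positive mean_ratio
#> 1 control_S01   control       1        0.03750000 0.05614766
#> 2 control_S02   control       1        0.02515723 0.05499787
#> 3 control_S03   control       1        0.00000000 0.05655396
#> 4     csf_S01       csf       1        0.30625000 0.34396527
#> 5     csf_S02       csf       1        0.31875000 0.34793244
#> 6     csf_S03       csf       1        0.30625000 0.34689455

res$tukey
#> StatsResult: tukey_hsd
#>   statistic = 602.603, df = (1, 4), p = 1.634e-05
#>   pairwise:
#>         pair mean_diff        adj_p
#>  csf-control 0.2895309 2.119524e-05
```

The treated wells recover the simulated 30 % positive fraction; the control
wells, classified against their own null, sit near the analytic 2-SD tail
(1 − Φ(2) ≈ 2.3 %); and the condition contrast is highly significant. All
tables (`cells.csv`, `per_image.csv`, `per_well.csv`, `per_sample.csv`,
`stats.csv`) plus the config copy and log land in `output_dir`, and a rerun
with the same configuration is byte-identical.

A thin command-line wrapper for simulation and both workflows is installed
at `inst/scripts/fluorquant.R` (`simulate`, `plate`, `invivo` subcommands
over the same YAML configuration).

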