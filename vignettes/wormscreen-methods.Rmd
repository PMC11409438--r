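---
title: "Methods: simulation, detection, and decision rules in wormscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, detection, and decision rules in wormscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormscreen)
```

## The assay being modeled

In *C. elegans*, vulval cell fates are specified by RAS-RAF-MEK-ERK (MAPK/ERK)
signaling, while pharyngeal muscle develops independently of that pathway. A
reporter strain with strong GFP in both tissues therefore exposes pathway
activity anatomically: adults normally develop one bright GFP vulval focus at
mid-body, pathway inhibition produces vulvaless (Vul) adults with no focus,
and pathway over-activation (e.g. lin-1 loss of function) produces multivulva
(Muv) adults with several ectopic foci. In a 96-well liquid-culture format,
each well holds a few dozen animals imaged as four non-overlapping
fluorescence fields, and two well-level readouts summarize the biology:

* **vulvae per adult** — vulva-sized GFP foci divided by adult-sized
  pharynges; around 1 in controls, near 0 under MEK/ERK inhibition;
* **percent larvae** — non-adult-sized pharynges as a share of all animals; a
  proxy for compound toxicity (animals that failed to reach adulthood).

wormscreen implements the full decision pipeline around these readouts:
synthetic plate generation with exact ground truth, object detection and
three-class gating, well scoring, Z-factor assay statistics, rule-based
primary hit selection, and a genetic counter-screen classifier.

## The synthetic-data generator

No quantitative optics are published for this assay, so the generator renders
a stylized but parametrically controlled version of what the detector must
cope with. Each worm is a soft-edged capsule of dim autofluorescence, with a
bright two-lobed pharyngeal Gaussian blob at one end and, on adults, zero or
more compact very bright vulval Gaussian foci at mid-body. Confounder
"speckles" (fluorescent debris from drugs, bacteria or progeny) are compact
foci whose area *and* peak intensity deliberately fall inside the vulval
gate: they are indistinguishable object-by-object, which is exactly the
failure mode the screen's artifact-exclusion rule exists for.

Key conventions (all configurable via `worm_geometry()` and
`well_sim_params()`):

| quantity | default | rationale |
|---|---|---|
| worm count per well | normal, mean 25.5, SD 7.4, clipped to [5, 66] | the assay's published per-well dispensing statistics |
| adult fraction | 0.8 | healthy wells at scoring time are mostly day-1 adults |
| fields per well | 4 tiles, 600 x 600 px, 2.5 um/px | four non-overlapping fields; size/scale are internal conventions |
| intensity ladder | background 500; body +900; larval pharynx +5500; adult pharynx +7000; vulva +16000 (16-bit units) | enforces vulva > pharynx > body > background, with the vulval peak at least twice the pharyngeal peak |
| noise | additive Gaussian, SD 1600 | 10% of the vulval amplitude |
| speckles | 0.5/field by default; amplitude 13.5k-26k, vulva-sized | mild contamination as baseline; test fixtures raise it |

Vulval focus counts per adult are drawn Poisson (wild-type rate 1), set
exactly (`"fixed"`), or drawn as a Muv mixture (a fraction of adults carries
`muv_count` foci) for lin-1-like genotypes. Larvae never carry foci.

Placement rejects poses that overlap another body (minimum surface gap 10 px)
or put bright organs of different worms closer than 34 px. Together with the
intensity ladder this gives a *class-separability guarantee*: in noise-free
renders, the area and peak distributions of the three countable classes are
disjoint and no two bright objects merge, so a correctly gated detector must
recover ground truth exactly. Infeasible placements (too many worms for the
field) raise an explicit error rather than silently dropping animals.

Determinism: every well draws from an RNG substream keyed by
(seed, plate, well) via `derive_seed()`, so the same configuration always
produces byte-identical TIFFs and adding wells never perturbs existing ones.

What the generator does *not* emulate: real worm posture and curvature,
overlap/clumping, z-stack defocus, brightfield texture beyond silhouettes,
photobleaching, or illumination gradients. Passing tests therefore
demonstrate the correctness of the *pipeline logic* under controlled optics,
not instrument-grade robustness on real micrographs.

## Detection and classification

Each GFP field is smoothed (Gaussian, sigma 1 px), thresholded, and labeled
into connected components; features (centroid, area, peak, mean,
eccentricity) are measured on the original intensities. The default
threshold is 4x the field median. A median-multiple was chosen over a
median-plus-k-MAD rule because the noise-free limit (MAD = 0) would place
that threshold at the background level, merging the dim body with its bright
organs and defeating per-organ counting; the field median itself is robust to
both noise and object content, and 4x sits between the body ridge (~1400)
and the dimmest pharynx (~6000).

Objects are classified by the first matching gate in precedence order
vulva -> adult pharynx -> larval pharynx -> rejected:

| class | area (px^2) | peak >= |
|---|---|---|
| vulva | 30-250 | 13000 |
| adult pharynx | 250-900 | 7500 |
| larval pharynx | 40-220 | 7500 |

Vulva-first precedence resolves the deliberate area overlap with larval
pharynges ("large, intense" foci win by brightness). The pharynx `peak_min`
of 7500 sits between the brightest noise-only components we observe under
default noise (<= ~6800, max over a component of original pixels) and the
dimmest true pharynx (>= ~8300); the vulva `area_max` of 250 (adjoining the
adult gate's floor) keeps noise-inflated or bridged masks of genuine foci
(noise-free footprints 65-94 px^2; adjacent foci on one Muv animal can merge
under noise) from falling through to the larval gate — safe because no
larval pharynx approaches the vulval peak gate. These gates are calibrated to the
simulator's optics — deliberately so, since the assay's instrument-specific
cutoffs live in proprietary acquisition software; on real data every gate is
configuration, not constant.

Fields are processed independently and counts summed (the acquisition
guarantees non-overlapping fields, so nothing is double-counted); an object's
field membership is its centroid's field.

For the counter-screen, bodies are segmented at 1.6x the field median
(above background, below the body ridge) with a 300 px^2 minimum area so
stray off-body foci are not mistaken for animals. Each vulva focus is
assigned to the body containing its centroid, else the nearest body within
12 px; a body containing an adult pharynx is an adult, and an adult with two
or more assigned foci is flagged Muv. This is an automated stand-in for what
was originally manual scoring, and is declared as such.

## Scoring and statistics

`score_well()` computes vulvae/adult and percent larvae from the summed
class counts. Undefined ratios (no adults; no animals) are explicit `NA`
markers with notes — never coerced to 0 — and are excluded from aggregation
with a logged count. The percent-larvae denominator is adults + larvae:
animals only, excluding rejected objects and vulvae. Wells above 1.5
vulvae/adult are flagged for inspection but kept; `drop_outliers` removes
them on request, keeping the human-triage step explicit.

The Z-factor uses the standard screening-window form
`1 - 3(sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample SDs (n-1) —
material with 4-8 control wells per plate — and is computed on
vulvae/adult scores. Buckets: >= 0.5 excellent, [0, 0.5) marginal,
< 0 unusable. Equal control means make Z undefined and raise an error rather
than returning a sentinel.

Dose-response aggregation is experiment-first: replicate wells are averaged
within an experiment, then the mean and SD are taken across experiment means,
matching how replicated assay development data are summarized. Pipeline
comparisons use ordinary least squares (`stats::lm`) and report
R^2 = 1 - SS_res/SS_tot.

## The screen decision layer

Primary hit selection applies, in order and with strict inequalities exactly
as stated (boundary values never trigger):

1. **artifact**: well vulva count > 2x the positive-control adult count —
   speckle-flooded wells;
2. **toxic**: well adult count < 30% of the positive-control adult count;
3. **hit**: remaining compounds with vulvae/adult < 0.4.

"The positive-control adult count" is operationalized as the mean over the
same plate's positive-control wells — the mean is stable and controls are
laid out per plate. Validation re-applies the same per-well exclusions at
several concentrations, averages over experiments, and keeps a compound if
any concentration stays at or below 0.4.

The counter-screen classifier orders its rules growth-first: a compound
whose lin-1 adult fraction falls below 30% of the untreated control is
`indeterminate_growth` (no analyzable adults) before any Muv interpretation;
then a Muv fraction below 0.5 of the untreated control's is
`downstream_or_parallel`; the rest are `on_pathway_hit`. The 0.5 suppression
threshold is a package convention — the underlying judgement was qualitative
— and is configurable and echoed into every output's metadata.

## Numerical and design notes

* Images are 16-bit grayscale TIFFs; integer intensities round-trip exactly
  through `tiff::writeTIFF`/`readTIFF`.
* Heavy pixel loops (separable Gaussian blur, capsule/Gaussian rendering,
  noise + clipping) are small C++ kernels; connected-component labeling is
  EBImage's.
* The detection evaluation oracle matches detections to ground-truth objects
  greedily by centroid distance (8 px). Speckle-matched vulva detections are
  reported separately and removed from the vulva count-error metric: a
  detector faithful to its gates *must* count them, so they are a property
  of the well, not a detector error. For the same reason the
  pipeline-vs-truth regression uses the gate-level oracle score
  `(vulvae + speckles)/adults`; the raw-vulvae regression is also reported
  and is visibly depressed by speckle Poisson noise in low-adult wells —
  the very artifact the screen's exclusion criterion (i) and outlier flag
  target.
* Problem sizes used by the test-suite and acceptance computations: 100
  noise-free wells for exact recovery; one 96-well calibration plate
  (vulva rates 0-2.1, speckles 2/field, default noise) for robustness and
  regression; the planted screen at its full published scale (433 compounds,
  five 96-well plates, 480 wells) run twice for the determinism check; a
  ~11-well counter-screen plate. These sizes were chosen so each property is
  measured at the scale that defines it.
* The planted screen fixture separates its planted classes from the decision
  thresholds *by construction*: suppressor and toxic wells use a fixed count
  of 26 worms with deterministic stage rounding (so a suppressor well can
  never drift under the toxicity cutoff by an unlucky draw), artifact wells
  carry 50 speckles/field (vulva counts far above any plausible 2x cutoff),
  and non-artifact wells are speckle-free so every artifact exclusion is
  attributable to a planted storm. Unplanted test wells keep the full
  empirical worm-count distribution, including occasional low-count wells
  that are realistically excluded or miscalled — the planted-recovery
  guarantees deliberately do not extend to them.

## Known limitations

* Gates are calibrated to the simulator; real instruments need their own
  `DetectionConfig` (the YAML surface exists for exactly that).
* The body-assignment Muv proxy undercounts when worms touch (prevented in
  simulation, common in reality).
* Speckles indistinguishable from vulvae object-by-object are an accepted,
  quantified contamination of the vulva channel, handled at the
  decision-rule level rather than the detector level — mirroring the
  original assay's design.
* Brightfield images are generated for format fidelity but unused by the
  default analysis path.
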