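---
title: "Methods: the autofluorescence viability assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the autofluorescence viability assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanovia)
```

## The measurement principle

Unicellular cyanobacteria carry their own live/dead stain. Chlorophyll *a*
autofluoresces red under blue excitation, so a viable, pigmented cell is
bright in the red channel of an RGB micrograph. When the cell dies the
chlorophyll degrades; dead cells instead exhibit a weaker, unspecific green
autofluorescence. Imaged in a counting chamber of known depth, one pair of
colour channels therefore contains everything needed for a viability count
and an absolute concentration: find the cells, decide each cell's colour,
divide by the imaged volume.

The package models this as a five-stage deterministic pipeline
(`run_assay()`): per-channel maximum-entropy thresholding, mask union,
connected-component registration, sub-area artefact removal, and mean-green
classification, followed by pooled quantification.

### Segmentation by maximum entropy

Each channel is reduced to its 256-bin intensity histogram and thresholded
with the Kapur–Sahoo–Wong maximum-entropy criterion (`max_entropy_threshold()`),
the "MaxEntropy" method familiar from ImageJ. Writing \(p_i\) for the bin
probabilities and \(P_t = \sum_{i \le t} p_i\), the chosen level maximises

\[
H_b(t) + H_f(t)
 = -\sum_{i \le t}\frac{p_i}{P_t}\ln\frac{p_i}{P_t}
   \;-\sum_{i > t}\frac{p_i}{1-P_t}\ln\frac{p_i}{1-P_t},
\]

and pixels strictly above \(t\) are foreground. The criterion suits this
assay because background and cell pixels form two well-populated intensity
populations of very unequal size; entropy maximisation does not assume any
particular modal shape.

Numerical choices, all of which affect reproducibility and are therefore
fixed and documented:

* entropies use the natural logarithm (any base gives the same argmax);
* empty bins contribute zero (the \(x \ln x \to 0\) limit);
* candidate levels whose background or foreground class would be empty are
  skipped rather than scored \(-\infty\);
* ties are broken towards the smallest level;
* a histogram with fewer than two occupied bins raises a typed
  degenerate-histogram error rather than guessing.

The implementation is a vectorised cumulative-sum evaluation; the package
also exports `max_entropy_threshold_oracle()`, a literal double-loop
evaluation of the same criterion. The two are algebraically identical but
computationally independent, and the test suite asserts elementwise
agreement on 100 seeded random histograms.

Degenerate channels are expected in practice, not an error of the run: a
fully viable culture has an essentially blank green channel. `run_assay()`
therefore gives a degenerate channel an empty mask and continues; only when
*both* channels of a field are degenerate is a warning emitted (the field
then contributes zero particles).

### Particles, artefacts, classification

The red and green masks are OR-combined — each cell is bright in one channel
and must be registered exactly once — and connected components are extracted
under 8-connectivity (ImageJ's Particle Analyzer convention; 4-connectivity
is available via `assay_config(connectivity = 4)`). Per component the
pipeline measures pixel area, calibrated area \(A = n_{px} \cdot
(\mu m/px)^2\), centroid, and the mean red and green intensity **over the
original channels**, not the binarised ones: the classification rule
thresholds a raw 8-bit intensity and would be meaningless on mask values.

Components with \(A < 35\,\mu m^2\) are removed (`filter_artifacts()`).
The cutoff is read strictly: a particle of exactly 35 µm² is retained. This
filter is the pipeline's entire defence against threshold noise, which is
why the thresholder itself may be permissive.

Classification is deliberately one-sided: a particle is non-viable iff its
mean green intensity exceeds `green_cutoff` (default 50, strict inequality,
so a mean of exactly 50 scores viable). No red-based rule is applied — red
brightness varies with pigment content and focus far more than the presence
vs absence of green signal does. The cutoff of 50 is an empirical,
microscope-dependent constant; it is exposed in the configuration and the
package makes no claim that it transfers to other instruments unchanged.

### Quantification

Counts are pooled over all fields of a run and converted as

\[
\text{cells/ml} = \frac{n_{total}}{V_{\mu l}} \times 1000 \times d .
\]

`imaged_volume_ul` (\(V_{\mu l}\), default 0.084 µl) is the volume covered by
**all** fields of one chamber fill together, not per field. The dilution
factor \(d\) undoes the glycerol pre-mix that immobilises the cells. The
protocol phrase "mixed 1:2 with glycerol" is ambiguous between final
concentrations of 1/2 and 1/3 of the original; the package reads it as 1/2
(\(d = 2\)) and exposes the factor so either convention is a one-argument
change. Replicate statistics are left to the caller: one `run_assay()` call
is one chamber fill, and pooling across biological replicates is an
experimental-design decision, not an image-analysis one.

Edge-touching particles are *included* by default: the protocol images
outside the counting grid and prescribes no border correction. Chamber
conventions that exclude two borders can set
`assay_config(include_edge_particles = FALSE)`.

## Companion measurements

**Colony counting** (`count_colonies()`) reuses the same primitives on
plate images of phycocyanin-fluorescent colonies: channel selection,
maximum-entropy threshold, 8-connected components, then a minimum-area
filter in *pixels* (`min_colony_area_px`), for which no universal constant
exists — it depends on plate magnification and must be supplied. A uniform
(degenerate) plate counts zero colonies with a warning, because an empty
plate is a legitimate biological outcome for a non-viable sample.
`plating_viability()` normalises a sample's count to an all-viable control,
`100 \cdot n_s / n_c`; the plated cell number and plate areas cancel in this
ratio and are not modelled.

**Chlorophyll** (`chlorophyll_ug_per_ml()`) evaluates the methanol-extract
formula \( \text{µg/ml} = A_{650} \times 13.9 / V \) with \(V = 2\) ml of
pelleted culture by default; both constants are arguments so other
extraction protocols can reuse the function. No conversion from optical
density to cell count is provided anywhere in the package: turbidity
confounds concentration with pigmentation state, which is precisely the
failure mode this assay avoids.

## The synthetic scene generator

`render_field()` renders what the segmentation stages assume: disk-shaped
cells on a darker background, each bright in exactly one channel, with
per-cell brightness drawn from a class distribution, optional small bright
"specks" standing in for segmentation artefacts, and pixelwise Gaussian read
noise. Every scene is a pure function of its `scene_spec()`, including the
mandatory seed, and returns exact ground truth (positions, classes, radii),
so pipeline claims can be tested as equalities against construction rather
than approximations against annotation.

Default geometry and intensities, chosen once as a plausible configuration
of the real assay and then left alone:

| parameter | default | rationale |
|---|---|---|
| field, calibration | 640×480 px at 0.5 µm/px | a typical 40× camera field (320×240 µm) |
| cell radius | 4 µm (~50 µm² footprint) | a *fluorescent* footprint: the 35 µm² artefact cutoff implies blurred/out-of-focus halos well above the ~3 µm² physical cross-section of the organism, so the rendered disks model the signal, not the cell wall |
| red cells (on-channel) | mean 180, sd 15 | bright chlorophyll signal |
| green cells (on-channel) | mean 120, sd 15 | weaker unspecific signal |
| off-channel level | 20 | below the green cutoff of 50 by a wide margin |
| background / read noise | 8 / sd 3 | darker-field background with mild sensor noise |
| speck area | 10 µm² | safely below the 35 µm² cutoff |
| min centre separation | 2.5 × radius | prevents merged particles, which the pipeline deliberately does not split |

Placement is sequential rejection sampling with a bounded retry budget;
an infeasible request (too many cells for the field) errors rather than
looping. Specks are kept from touching cells so that adding specks is, by
construction, a pure perturbation of the background — which is exactly the
property the artefact filter is supposed to guarantee and the tests assert.
`render_mixture_series()` reproduces the validation design of mixing a
viable and a heat-killed culture at known ratios: requested per-sample
compositions are honoured exactly and cells are assigned to fields uniformly
at random. An optional Gaussian blur (`blur_sigma_px`) approximates a point
spread function for robustness checks; it is off by default because hard
disks make ground-truth areas exact.

What the generator does **not** emulate — and hence what passing tests do
not establish about real micrographs: touching or dividing cells (no
watershed splitting exists in the pipeline, so clumps undercount), focus
gradients across a field, uneven illumination, autofluorescence bleed-through
between channels, photobleaching, and debris with cell-sized footprints.
On real data those effects are controlled operationally (chamber loading,
autofocus, the empirical cutoff), not algorithmically.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run entirely on synthetic scenes
chosen to keep a full run in tens of seconds on one CPU: 100 random
histograms for the oracle-equivalence property, single 640×480 fields with
80–200 objects for count recovery and artefact immunity, a five-fraction
mixture series of 200 cells over four fields each (20 fields total), and
800×800 plates with 60 colonies. These sizes are the package's own test
design; nothing in the implementation depends on them.

End-to-end determinism is treated as a correctness property: repeated runs
on identical inputs must reproduce the summary CSV, particle CSV *and* the
JSON run manifest byte for byte. For that reason the manifest's audit
timestamp records the newest modification time of the input images
("input_snapshot") rather than the wall-clock time of the analysis — a
deliberate trade of one metadatum for bitwise reproducibility.

## Known limitations

* The green cutoff (50) and the 35 µm² artefact cutoff are instrument- and
  magnification-specific constants; both are configuration, not biology.
* Touching cells register as one particle; dense chamber loadings bias
  counts downward. Keep loadings in the regime where cells are separable.
* The viable/non-viable decision is binary. Vitality grading (pigment per
  viable cell) requires absorbance spectra and is out of scope here.
* 16-bit inputs are rescaled by the per-image maximum at ingest, which
  assumes the brightest pixel is signal; heavily saturated or empty 16-bit
  frames should be converted upstream.
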