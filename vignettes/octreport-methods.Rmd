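---
title: "Extracting structured measurements from OCT report images"
author: "octreport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting structured measurements from OCT report images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Optical coherence tomography (OCT) devices produce their results as report
*images*: a page with a title, a handful of printed measurements (central
macular thickness in µm, total macular volume in mm³, retinal nerve fiber
layer thicknesses) and one or more tomographic panels. Hospitals accumulate
hundreds of thousands of these pages, but the numbers on them are pixels,
not data: longitudinal review, registry building, and loading into a common
data model (CDM) all require the values as typed, unit-bearing records.

`octreport` converts such report images into structured longitudinal
records. The pipeline is:

1. **Report classifier** — identify which of six fixed report layouts a
   page follows, from its header region alone.
2. **Area explorer** — crop each region named in a layout-catalog
   configuration file and decide whether it holds numeric text, a
   tomographic image, or nothing.
3. **Value reader** — convert numeric/text regions to character strings:
   either with a trainable three-stage scene-text recognizer, or with a
   deterministic template-matching reference recognizer.
4. **Finding classifier** — flag pathologic findings (subretinal fluid,
   macular edema) on tomographic regions; a small baseline model is
   bundled and the interface is pluggable.
5. **Structuring** — assemble per-eye records, derive disease-activity
   labels over each patient's visit series, and write CSV,
   CDM-measurement-shaped rows, and lossless crop exports.

Because real device pages cannot be redistributed, the package carries a
first-class synthetic renderer that draws all six report types with
known ground truth ("sidecars"), plus a text-image corpus generator for
recognizer training and tomogram phantoms for the finding baseline. All
tests and the bundled accuracy study run against these synthetic pages.

## The layout catalog

A catalog maps each report type to named pixel regions. Coordinates are
0-based, half-open rectangles `(x0, y0, x1, y1)` with x rightward and y
downward, so widths are exact subtractions. The bundled catalog defines
six layouts on a 640×480 page: unilateral/bilateral RNFL thickness,
unilateral macula thickness+volume (current only, and previous+current),
and two scan-only layouts whose regions are exclusively tomographic. The
two scan-only layouts carry no text fields at all; records extracted from
them take patient/visit metadata from the sidecar (or any external
manifest), which mirrors how scan-only pages would be joined to an
imaging worklist in practice.

The catalog is an editable YAML file (`inst/extdata/default_catalog.yaml`);
adapting the package to another device's reports means editing
coordinates, not code. Type resolution is always by header title, never by
device software version: `version_range` is informational.

Header titles are descriptive stand-ins chosen by this package; the titles
on real devices' pages differ between report types in the same way, and a
user-supplied catalog replaces them wholesale.

## Synthetic data: what it emulates and what it does not

The renderer paints values into their configured boxes with self-authored
bitmap faces (a 5×7 monospaced face and a programmatically emboldened
variant), at continuous glyph scales, with adjustable contrast, additive
Gaussian noise, background level, and an optional smooth background
texture. The OCR corpus generator samples labels from the content classes
that actually occur on reports — integers, decimals, ISO dates, uppercase
words, and mixed alphanumerics up to 12 characters — and renders each into
a field-box-like canvas (text flush left, background to the right) so the
training distribution matches the crops the pipeline produces. Corpus
images are stored pre-processed at the recognizer input geometry.

Tomogram phantoms are layered bright bands over a dark background with
speckle: subretinal fluid adds a dark blob between the inner band and the
bright lower band; macular edema adds round hypo-reflective cysts and a
dome-shaped elevation.

What passing tests on this material shows: the *pipeline* is lossless, the
recognizer architecture can be trained to read this page family at high
accuracy, and the structuring rules behave as specified. What it does not
show: accuracy on real scanned or photographed pages (anti-aliased vendor
fonts, JPEG artifacts, skew), realism of B-scan texture, or clinical
validity of the finding baseline. The recognizer trained here is expected
to transfer to a new page family only after retraining on images rendered
with that family's fonts.

Default study conditions: corpora split 0.92/0.08 into training and
validation; the desk-scale corpus is 50,000 samples (a knob —
`corpus_spec(n_total = ...)` scales to the million-sample regime
unchanged); label length ≤ 12 of a 42-character set (digits, `.-%/:`,
space, A–Z); glyph scales 1.5–3; contrast 0.55–1; noise SD 0–0.12.

## The recognizer

The value reader follows the standard three-stage scene-text design:

* **Feature extraction** — two 3×3 convolution + 2×2 max-pool stages
  (6 and 12 channels) followed by one residual block at 12 channels; a
  32×128 grayscale input becomes a 32-step sequence of 96-dim column
  features. The residual block keeps gradients healthy as depth grows.
* **Sequence modeling** — a bidirectional LSTM (32 hidden units per
  direction) over the column sequence.
* **Prediction** — an attention decoder (64 hidden units, additive
  attention with 48 energy units) that emits characters recurrently until
  an end-of-sequence symbol, capped at 50 characters. The attention is
  location-aware: the previous step's alignment is convolved (8 channels,
  kernel width 7) and fed to the scorer. Content-only attention is prone
  to skipping or doubling characters inside runs of identical glyphs —
  an eight-digit patient id with repeated digits is exactly the hard
  case — and the location features suppress that failure mode.

Inference is greedy — no beam search — so recognition is a deterministic
function of the weights. A field specification may declare the character
class its content is drawn from (digits for a patient id, digits plus
`.-` for a measurement); when it does, decoding is charset-constrained:
logits of disallowed characters are masked before the argmax, the
standard lexicon-constraint trick of scene-text pipelines. The reference
recognizer filters its template set the same way. Fields that declare no
charset decode unconstrained. Confidence is the geometric mean of the
per-character probabilities (an empty readout reports confidence 0, which
keeps blank regions below any sensible reject threshold). Crops are
resized to height 32 with aspect preserved, right-padded with background
or squeezed to width 128, and standardized to `[-1, 1]`.

Training uses teacher forcing with cross-entropy, batch size 32, and
AdaDelta (learning rate 1, decay rate 0.95), with global gradient-norm
clipping at 5. The checkpoint with the best validation sequence accuracy
is kept, and the learning curve (iteration, loss, validation accuracy) is
recorded. Checkpoint selection evaluates the lowest-noise stratum of the
validation split restricted to the structured label kinds that occur on
report fields (numbers, decimals, dates, ids, words): report pages are
crisp device renders, so model selection is aligned with that deployment
distribution rather than with the heavy-noise tail of the training
corpus. The whole engine — forward, backpropagation through the
attention decoder, BiLSTM and convolutions, and the AdaDelta update — is
implemented in compiled code inside the package and verified against
numerical differentiation in the test suite.

Desk-scale defaults train for a few thousand iterations on the 50,000
sample corpus, which takes on the order of ten minutes on one CPU core;
full-scale settings (10⁶ samples, 160,000 iterations) remain expressible
through `corpus_spec()` and `train_config()` for anyone wanting the
long-run regime.

### The reference recognizer

A second, trainingless recognizer does left-to-right per-glyph template
matching against the same bitmap faces the renderer uses: binarize (Otsu),
segment at blank columns, and match each segment against every glyph
template with a scale-symmetric similarity (resampling blurs whichever
image is resized, so both directions are scored and the better kept) plus
penalties for vertical position, aspect, and height. Inter-character
tight-bbox gaps reach about 5 glyph units between narrow characters, while
a true space adds a full cell (≥ 7 units); the space threshold sits at 6
units. A glyph whose best similarity falls below 0.8 raises a
recognition-failure error, which is what heavy noise produces.

Because generator and reference recognizer share glyph templates, the
reference recognizer is exact on clean renders. That makes it the
*plumbing oracle*: any end-to-end mismatch against a sidecar indicts the
pipeline, not the recognizer. It is also the fallback header-text matcher
of the report classifier and the independent oracle the trained model is
compared against.

## Classification, routing, parsing

The **classifier** correlates the binarized header crop against a rendered
template of each layout's title (built by the same painting routine the
renderer uses, so alignment is exact by construction). Normalized
correlation makes it invariant to global brightness scaling; the accept
threshold is 0.7 and ties break to the lexicographically lowest type id,
so catalog order never matters. If no template clears the threshold, the
reference recognizer reads the header and an exact text match is tried;
if both fail, the page is rejected as unknown rather than guessed.

The **area explorer** classifies each crop by content: a dynamic-range
floor and an ink fraction below 0.5 % mark empty regions; dark mean
intensity (< 0.55) or a mid-tone fraction above 0.35 marks tomographic
content (phantoms are dark-background with broad gray levels, text crops
are bimodal); everything else is numeric text. A conflict between detected
content and the configured kind logs a routing warning and honors the
*detected* class — a shifted or corrupted page should fail loudly, not
feed a tomogram to the character reader.

**Parsing** validates recognized text against the field's pattern before
conversion; the dash placeholder (`--` or `-`) becomes a missing value,
never zero; pattern mismatches raise parse errors that carry the raw text
and end up as per-record warnings, so failures are always visible in the
output.

## Activity labels

Disease activity over a patient/eye series is rule-based: visit 1 is
`not_applicable`; later visits compare central macular thickness with the
immediately preceding visit. A relative change ≤ −θ is `improvement`;
≥ +θ, or any finding newly appearing, is `worsening`; otherwise
`stationary`. Resolution of a finding alone never counts as improvement.

θ defaults to **0.25**. The constraint set comes from the published
worked example this package reproduces: printed consecutive relative CMT
changes of −31.0 % (labeled improvement) and −13.1 %, +8.3 %, +0.8 %,
−20.6 % (all labeled stationary) bound θ to (0.206, 0.310]; 0.25 is the
midpoint of that feasible interval. The rule is Markov — each label
depends only on the adjacent pair of visits — and θ is configurable.

## Validation methodology

Accuracy is tallied at report level: a report succeeds only if *every*
non-missing ground-truth field matches the predicted raw text exactly
(string equality; no tolerance for formatting differences). Only the three
numeric report categories are validated — unilateral and bilateral RNFL
pool into one column since they share one reading algorithm — and the
overall column pools counts rather than averaging rates. Field-level rates
are attached as diagnostics. The bundled study scores 300 synthetic
reports, 100 per category, sampled reproducibly by seed.

## Numerical and design choices

* Bilinear resampling is done by two small interpolation matrices — a
  deterministic linear-algebra routine, fast enough for 50,000 corpus
  renders.
* Empty labels are rejected by the text-image generator; an empty report
  field is the dash placeholder, not an empty image.
* The finding baseline is a fixed random 3×3 convolution bank + ReLU +
  coarse average pooling feeding per-finding logistic regressions,
  trained on 160 phantoms. It separates phantom findings near-perfectly
  and exists to keep the pipeline end-to-end testable; it makes no claim
  on real B-scans and any stronger model can be plugged in through the
  same interface.
* Dates are normalized to ISO-8601; the on-page format is a per-layout
  configuration choice (the bundled renderer prints ISO directly).
* Bilateral pages emit two records (one per eye) whose measurement names
  drop the `right_`/`left_` prefix, so a single CSV column set covers all
  layouts; the column order follows the catalog.
* All randomness is seed-threaded (`withr`-style local RNG state), and the
  compiled trainer uses its own Mersenne Twister seeded from the training
  configuration, so corpora, phantoms, training and decoding are
  reproducible end to end.

## Problem sizes used by the bundled checks

The test suite trains the desk-scale recognizer once (50,000 samples,
4,500 iterations, batch 32) and the acceptance script once at 3,500
iterations; each scores 300 synthetic reports per run; the plumbing oracle covers 60 reports (10 per type) and
the reference-recognizer property runs 1,000 random labels. These sizes
were chosen as the smallest at which the quantities of interest are stable
to well under one percentage point between seeds.

## Known limitations

* Real-page robustness (anti-aliasing, compression artifacts, rotation or
  skew, multi-page documents) is out of scope; no skew correction is
  attempted.
* The finding baseline is synthetic-only; clinical finding classification
  requires a validated model dropped into the pluggable interface.
* PACS/DICOM encapsulation and site-specific CDM loading stop at file
  emission (measurement-shaped CSV rows, lossless crop exports).
* Cross-vendor measurement calibration is not addressed: identical
  anatomy measured by different devices may yield different numbers.
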