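---
title: "Temporal refinement of 4D segmentation labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal refinement of 4D segmentation labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxelhmm)
```

## The model

A 4D label volume is a `(T, Z, Y, X)` grid of integer class labels produced
by running a 3D segmenter independently at each time step of an aligned time
series. Because the volumes are aligned, the labels at one spatial site
`(z, y, x)` form a length-`T` sequence describing the same physical point
through time, and every site can be treated independently. `toxelhmm` models
each such sequence with a hidden Markov model:

- the *hidden states* are the true segmentation classes `0..N-1`;
- the *observables* are the per-timepoint predictions — either the predicted
  class itself (the plain model, one observable per class), or the predicted
  class paired with a quantized confidence (the confidence-aware model,
  `N * b` composite observables);
- the refined output is the Viterbi path: the single most probable hidden
  sequence given the observations.

The three parameter blocks and where their values come from:

**Transition matrix `T`** — set from expected physical behaviour, not
learned. The default builder (`build_transition_default()`) describes a
slowly dissolving phase: each class persists with high probability, the
dissolving class converts to its product at 10% per time step (roughly the
rate at which a corroding deposit turns into a gas pocket between
consecutive scans), and every other ordered pair gets a small cross-term
`eps = 1e-3`. The cross-terms are deliberately non-zero: real time series
contain rare events outside experimental control (slight misalignment,
thermal expansion) and a model that assigns them probability zero could
never follow them no matter how much evidence accumulates. `eps` is uniform
across pairs; nothing in the systems we target motivates pair-specific
rarities, and a user who has such knowledge can supply a CSV matrix
verbatim. Two uninformed baselines calibrate how much the physics in `T`
buys: `build_transition_naive()` (all entries `1/N` — under it every
sequence is equally coherent, so decoding degenerates to a per-step
emission argmax and typical volumes pass through unchanged) and
`build_transition_naive_stable()` (stay with probability 0.5, otherwise
move uniformly).

**Emission matrix `O`** — derived from the segmenter's testing confusion
matrix by dividing each row by its sum (`emission_from_confusion()`). A row
with zero sum is an error naming the class: it means the test set never
contained that class and its emission distribution is simply unknown.

**Starting vector `S`** — uniform. Class imbalance is a property of every
time step, not of `t = 0` specifically, so there is no reason to prefer any
class at the first step.

## Confidence binning

The confidence-aware model also uses the segmenter's leading-class
probability, which for `N` classes lives in `(1/N, 1]` (at `1/N` the
prediction is a coin toss; at 1 it is certain). `confidence_bin()` splits
this range into `b` equal-width bins — with `b = 3` they are read as low-,
mid- and high-confidence — and `composite_observable()` maps a (class, bin)
pair to `class * b + bin`. Conventions worth stating because they are easy
to get subtly wrong:

- bins are closed below and open above, except the top bin which is closed
  at 1, so every probability maps to exactly one bin;
- a degenerate value `p <= 1/N` (which a leading class should never
  produce, but ties can) clamps to bin 0;
- the composite ordering is class-major, so the three confidence levels of
  one class sit in adjacent columns; serialized matrices carry the column
  labels (`class2.low`, `class2.mid`, ...) so files are self-describing.

### The diagonal adjustment

When class populations are very unbalanced, a rare class's emission row is
normalized by a small denominator, and a handful of misclassified voxels
can make a composite observable of class `c` *most* likely under a foreign
hidden class — e.g. a mid-confidence base-material prediction apparently
"emitted" most probably by the rare gas-pocket class. This contradicts what
the observable means, so `adjust_emission_diagonal()` restores the
intuitive reading: for every column whose argmax is not the same-titled
class, the same-titled entry is raised multiplicatively just above the
column maximum (factor 1.001), rows are renormalized, and the pass repeats
until every column is dominated by its own class. The loop converges in a
handful of passes and is idempotent; a hand-tuned matrix can always be
loaded from CSV instead. Ties in any argmax resolve to the lowest class
index, everywhere in the package, for determinism.

## Decoding

`viterbi_decode()` runs the standard dynamic program in log space, with
`log(0) = -Inf` marking forbidden transitions and emissions; this is exact
and safe against underflow for sequences far longer than any realistic time
series. If at some time step every partial path has probability zero, the
error names that first fully blocked step rather than returning an
arbitrary path. Tie-breaks go to the lowest class index both in the
per-step maximization and at the final state.

Volumes are dominated by sites whose observable never changes, so
`refine_volume()` first scans each site for constancy and, when the
shortcut is enabled (the default), assigns the emission-column argmax class
directly. The shortcut is an approximation: its answer need not match full
Viterbi decoding for every parameter set. `audit_shortcut()` decodes the
constant sequences for every observable over a range of lengths and reports
disagreements; for the default plain model the audit is empty, while for
binned emissions whose forced diagonal dominance is marginal the audit does
surface deviations — which is precisely the visibility the function exists
to provide. Because sites are independent, chunked processing
(`chunk_sites`) is bit-identical to whole-volume processing for any chunk
size; the whole pipeline is deterministic, with no randomness anywhere in
decoding.

Indexing conventions: class and observable indices are 0-based everywhere
(matching the values stored in label volumes), time indices are 0-based,
and the axis order is `(t, z, y, x)` with `y` the height axis used for
slice-based evaluation. The command-line report layer echoes height
selections in both 0-based half-open and 1-based inclusive forms.

## Evaluation choices

`iou()` computes per-class intersection-over-union and an *unweighted* mean
across classes. A class absent from both volumes has an undefined ratio; it
scores 1 and is flagged in the report, so the convention is visible rather
than silently inflating or deflating means. `median_filter_time()` — the
simplistic baseline — takes the median of the integer class codes in a
centred window (default 5) with nearest-edge padding; for more than two
classes this is order-dependent on the coding, which is inherent to using a
median on categorical data and is reproduced deliberately. One classical
caveat discovered while testing: a single pass of the window-3 filter is
*not* idempotent on all binary sequences (an alternating sequence needs
several passes to reach a root); the property suite therefore asserts
convergence under repeated application rather than one-pass idempotence.

## The synthetic phantom

`generate_phantom()` exists so every stage is testable end-to-end with a
known hidden truth. It emulates the statistical structure of a segmented
corrosion time series:

- a static background (air around a base-material cylinder) plus a dynamic
  region: spherical inclusions of the dissolving class that convert
  irreversibly to the product class at 10% per step;
- observations drawn per-toxel from the emission row of the hidden class,
  using a diagonal-dominant matrix (`default_emission()`) whose per-class
  accuracies mirror a real segmenter's profile — near-perfect on the large
  easy classes, noticeably weaker (0.80) on the small dissolving/product
  classes with most errors going to the base material;
- label flicker at spatial class boundaries: toxels within one voxel of a
  boundary flip to a neighbouring class with probability 0.5, emulating
  near-tied class probabilities at instance edges;
- informative confidences: correct interior predictions draw from
  (0.85, 1), confidently wrong interior predictions from (0.3, 0.8), and
  boundary toxels from (0.26, 0.45), just above the 4-class floor of 0.25.

The geometry (cylinder plus spheres) is arbitrary and irrelevant — decoding
is strictly per-site, so only the per-site statistics matter. What the
phantom does *not* emulate: tomographic reconstruction artifacts and their
spatially correlated noise, anisotropic voxel sizes, misalignment between
time steps, and any spatial correlation in the segmenter's errors beyond
the one-voxel boundary band. Passing tests on the phantom therefore
demonstrate that the refinement machinery does what the model says under
the stated noise structure — not that any particular real dataset will
enjoy the same margins.

All randomness flows from a single seed and regeneration is bit-identical.
The default configuration (`phantom_config()`) is a 21-step series of 64^3
volumes (about 5.5 million toxels); module tests use 9-step 16^3 phantoms,
and the brute-force Viterbi oracle enumerates paths for sequences up to
length 6 with up to 4 classes, sizes at which exhaustive enumeration is
exact and quick.

## Input and output formats

Volumes are exchanged as one multi-page TIFF stack per time step
(`<prefix>_t<index>.tif`, zero-padded 0-based index, one page per `z`
slice): labels as 8-bit samples, which round-trip exactly for up to 256
classes, and confidences as 32-bit float samples, which round-trip at
single precision (well below the width of any confidence bin). Matrices
travel as labelled CSV and complete model specifications as a single JSON
document, both at a precision (17 significant digits) that reproduces the
doubles exactly.

## Known limitations

- The model is strictly per-site temporal: no spatial regularization, so
  it cannot repair errors that are spatially coherent at a fixed time.
- Parameters are fixed, not learned; there is no Baum-Welch style fitting,
  by design, since the setting is precisely one where no trustworthy 4D
  ground truth exists to fit against.
- Only Viterbi decoding is provided; posterior-marginal (forward-backward)
  decoding would minimize per-toxel error rather than path error and is a
  deliberate non-goal.
- A single transition matrix applies to the whole volume; spatially varying
  transition models are out of scope.
- The confidence-aware model inherits the weaknesses of its adjusted
  emission matrix: the forced diagonal dominance is minimal by
  construction, and the shortcut audit shows it can be marginal enough
  that constant-sequence decoding disagrees with the column argmax. When
  that matters, disable the shortcut (`use_shortcut = FALSE`) and accept
  the extra compute.
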