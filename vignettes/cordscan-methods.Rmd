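---
title: "Atlas-free cervical cord segmentation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-free cervical cord segmentation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordscan)
```

## The problem

On a sagittal T2-weighted cervical-spine series the spinal cord occupies a
few percent of the midsagittal image, yet clinical measurements of cord
compression (the hallmark of cervical spondylotic myelopathy) require its
outline. Atlas-based segmenters struggle exactly where those measurements
matter most: when stenosis erases the bright CSF rim around the cord, the
local contrast that drives registration vanishes. `cordscan` instead
encodes the anatomy directly as search constraints — the cord is the only
isointense structure crossing the image from top to bottom, the ligaments
bounding canal and column are thin hypointense bands at bounded distances
from it, and vertebral bodies come in predictable sizes — and turns each
detection into a banded shortest-path-style optimisation.

Coordinates follow the radiological convention used throughout the code:
`y` grows anterior to posterior, `z` superior to inferior, both 1-based,
with 320 × 320 pixels at 0.6875 mm/px as the conformant geometry.

## Pipeline

### 1. Midsagittal selection

The spine is bilaterally symmetric about the midsagittal plane, so of the
13 sagittal slices the one closest to that plane minimises the mean
asymmetry of mirror-image pairs. The difference metric `D` between two
slices is the population standard deviation of their per-pixel signed
gray-level differences — insensitive to global intensity offsets, cheap,
and in our hands more robust to field inhomogeneity than mutual
information. Candidate positions `k` run over integers and half-integers;
pairs `(j, 2k − j)` are enumerated with `j < 2k − j` so that no pair is
counted twice and the degenerate self-pair (whose `D` is identically zero
and would bias integer candidates) never enters the score, although it
does count toward the at-least-four-pairs availability rule that yields
the candidate grid 4, 4.5, …, 10 for a 13-slice stack. An integer winner
designates one slice; a half-integer winner designates two, arbitrated
later by the stability of the signal along the detected cord path
(absolute deviation from a 31-pixel moving average, summed over the lower
two thirds of the image, where a vertebral body plus a disk fit inside the
window).

### 2. Histogram classification

Pixels are classified relative to the cord: air, hypointense, isointense,
hyperintense. A Gaussian mixture with up to four components is fitted to
the 256-bin histogram by EM, growing the model one component at a time.
The growth schedule is the design decision that mattered most in
practice. Splitting the heaviest component — the first scheme tried —
reliably refines whichever of air or soft tissue dominates the image
(together they cover most of it) and never discovers the small cord peak.
The shipped scheme is greedy EM with a candidate pool: each stage proposes
new components at up to four residual peaks (gray levels where the model
most underestimates the histogram, mutually at least 16 levels apart and
away from existing means), runs EM to convergence from each proposal, and
keeps the best final log-likelihood. This is deterministic, needs no
random restarts, and finds the air, soft-tissue, cord and CSF peaks in
order of unexplained mass.

Numerical guards: component weights below `1e-4` collapse the component;
variances are floored at 4 (gray levels are quantized integers, and
without the floor a component collapses onto the single-bin spike that
0-clipped background noise produces); convergence is a relative
log-likelihood change below `1e-6`, at most 500 iterations; all E-steps
work in log space so the extreme gray levels never underflow. A
single-valued image degenerates to one component with a warning.

Each gray level takes the class of the component dominating it
(weight × density), with levels below the air mean forced to air. The
upper isointense threshold is then sanity-checked, because windowing and
truncation artifacts routinely corrupt the hyperintense component: a value
in `[64, 128]` stands; above that it is recomputed as the isointense mean
plus two standard deviations (covering ~98% of cord pixels) and clamped
into `[127, 159]`; below 64 — meaning three Gaussians crowded into the
dark peaks — it is reset to 128 outright. Treating 128 itself as
acceptable is deliberate: 128 is the low-branch repair value, and the
repair must be idempotent.

### 3. Banded dynamic programming

All eight detections share one engine. A path assigns a column `b_z` to
every row of `[z_sup, z_inf]`, may move at most one column between rows,
and maximises the cumulative fitness `q`, which is zeroed outside the
per-row band `[y_ant(z), y_post(z)]`. Ties are resolved by a fixed
precedence — straight predecessor first, then anterior, then posterior —
and the backtrack start (the argmax of the last row) breaks ties toward
the smaller column, so identical inputs always give identical paths.
Because out-of-band cells hold `q = 0`, callers must supply fields that
are non-negative inside the band (each fitness adds a constant offset to
guarantee this); the engine asserts it. Under that contract a path can
never profit from leaving the band, so re-entry semantics never arise.

The fitness fields, with pixels outside the image treated as gray level 0
and non-isointense (the borders of this acquisition are air):

* `f1`: count of isointense pixels among the five `y`-neighbours —
  finds the coarse cord `B1` over the whole image (a compressed cord can
  be as shallow as 5 px, hence the window).
* `f2`: `Σ (65536 − (ΔI)²)` over the six consecutive pixel pairs spanning
  `y−3 … y+3` — refines to the most locally homogeneous path `B2` within
  ±40 columns of `B1`. Neither is required to be a centerline.
* `f3 = f4`: `(256 − I)²` — darkness; finds the posterior longitudinal
  ligament `B3` in `[B2−30, B2−1]` and the ligamentum flavum `B4` in
  `[B2+1, B2+30]` (the normal canal is 22–30 px deep).
* `f5`: darkness plus `Σ I²` over the 16 pixels behind the candidate —
  the anterior longitudinal ligament `B5` in `[B3−60, B3−21]` must be
  backed by bright marrow, which distinguishes it from the air-filled
  trachea just anterior.
* `f6`: darkness plus `65536 ×` the count of sub-`t_VB` pixels among the
  20 behind — the "truncated ALL" `B6` in `[B5, B3−1]`, which hugs the
  disks' anterior edges and cuts prevertebral soft tissue (and the
  anterior-most marrow) off the column.

### 4. Vertebral bodies, disks, canal extent

`t_VB` separates the hypointense cortex/annulus group from isointense
marrow inside the column (`B5`–`B3`): the histogram is smoothed with a
width-5 moving average, the two most prominent peaks (prominence ≥ 5% of
the tallest bin, each refined to the largest raw bin within the smoothing
half-width, since smoothing flattens sharp peaks into plateaus) define the
groups, and the threshold is their midpoint. A unimodal histogram falls
back to the EM-derived lower isointense threshold with a warning.

Pixels at or above `t_VB` between `B6` and the column-side neighbour of
`B3` are grown into 4-connected regions (4-connectivity prevents leakage
through one-pixel cortical gaps); regions over 150 px — half a normal
body — are candidate vertebral bodies. C2 is recognised by shape and
context: its odontoid-plus-body complex is about 1.5× the height of a
lower cervical body, so the topmost region at least 1.3× the median
height of the valid regions below it (the margin absorbs the jagged `B6`
clipping), followed by more than five such regions with the next centre
within 70 px (50 mm), is C2; labels then run C3, C4, … inferiorly. The
canal's superior edge is the C2 region's superior edge; the inferior edge
comes from a T1 extent extrapolated on `z` from the C3 and C7 centres
(T1 centre = C7 centre + mean spacing, T1 height = C7's), because regions
beyond the reliably-detected C3–C7 run should not be trusted directly —
T1 is included at all only so the C7-T1 disk can be labeled. When any of
this fails the pipeline raises a typed error and accepts a manually
designated canal extent instead, exactly as a reading-room workflow
would.

Disks are the 4-connected voids left in the column after removing the
valid bodies, kept when over 100 px and labeled by the nearest bodies
above and below. The rule deliberately ignores intensity, which makes it
robust to dehydrated, hypointense disks.

### 5. Cord edges

The cord's reference intensity varies along its course (field
inhomogeneity, saturation bands, a genuine superior-to-inferior signal
decline), so a per-row median profile `c_z` is taken over the hypointense
and isointense pixels in an 11 × 31 window around `B2`, truncated at the
canal and image borders; empty windows copy the nearest defined row. The
anterior edge fitness `f7` sums four terms: similarity of the pixels
`y … y+3` to `c_z` with the outside pixel `y−1` rewarded for differing
(weights 0.5 / −3 / −1 / −1 / −1), homogeneity among `y … y+3`, contrast
across the edge (0.5 weight), and a flat −65536 penalty for letting the
path pass through hyperintense or air pixels. The penalty term's exact
form was an open choice; a class-based step of magnitude 65536 dominates
any single squared-difference term (at most 255² = 65025) without
swamping the sums of several of them. `f8` is `f7` with its constituent
pixels in reverse `y`-order. The DP bands — `[B3+1, B2]` for the anterior
edge and `[B2, B4−1]` for the posterior — are not uniquely dictated
either; they encode that the cord lies between the two ligaments and that
`B2` runs inside it. Rows where the edges would cross (degenerate
stenosis) clamp to `B2` with a warning. The cord mask is everything
between the edges, inclusive.

Within a normal canal the edges land on the cord–CSF interface; when
stenosis removes the CSF the same functions latch onto the cord–ligament
interface, because the similarity and penalty terms care about cord
membership, not about which bright or dark tissue lies outside. The known
failure mode is a CSF rim narrowed to a single pixel, whose
partial-volume average becomes isointense; the package does not attempt
to patch this.

## Evaluation

Jaccard `J = TP/(TP+FP+FN)` over the canal rows, Dice via
`D = 2J/(1+J)`, and the symmetric Hausdorff distance between edge curves
rasterised as integer point sets on their common row range, in pixels and
millimetres. A majority-vote utility builds a reference mask from three or
more manual segmentations.

## The phantom: what it emulates, and what it does not

The generator builds a 13-slice, 320 × 320 stack around a midsagittal
template with the T2 ordering air ≪ ligament/cortex < muscle <
marrow/cord < CSF/nucleus (defaults 5, 25/30, 48, 80, 175/180), a
C2–T2 column (bodies 22 × 18 px, area 396 px, within the normal
300–600 px; C2 1.5× taller; 8 px disks with an optional bright nucleus),
a 24 px canal (6 px CSF, 12 px cord, 6 px CSF) bounded by 1 px PLL and
LF bands, a gentle lordotic in-plane curve (5 px amplitude), a linear
cord signal decline (8 gray levels over the image, which with the default
noise sd of 3 gives a gray-versus-`z` correlation near −0.6, matching
what degenerated cervical cords show), Gaussian noise, and off-centre
slices whose canal content is blended toward a uniform lateral gray so
the stack is mirror-symmetric about a planted midsagittal position.
Stenosis replaces CSF at a chosen level with bulging disk and thickened
ligament, leaving the cord untouched; degradations emulate extra
intensity drift, Gibbs-like longitudinal lines, and display windowing
that saturates the bright pixels.

Three texture choices are load-bearing rather than cosmetic. Bone,
end plates and annulus carry bounded deterministic texture (±3) while
cord and CSF are smooth, because trabecular bone genuinely is
heterogeneous on T2 and because a perfectly uniform column would tie with
the cord under the homogeneity fitness, leaving `B2` to a coin flip.
Muscle is textured more strongly (±10) for the same reason. Marrow
brightens slightly anterior to posterior (±4 ramp), which pins the
truncated-ALL path at the column's anterior edge instead of letting it
wander across an otherwise flat fitness plateau. The CSF gaps are
narrower than the 7-pixel homogeneity window by construction, so no CSF
column can host a fully uniform window — on real images the CSF rim is
similarly thin and wavy.

What the phantom does not emulate: MR physics (no k-space, no coil or
bias field), partial-volume averaging, scoliosis or kyphosis, C1, and
pathology beyond CSF-effacing stenosis. Passing the phantom suite
therefore demonstrates that the algorithmic chain is implemented
correctly and is robust to noise, drift and planted artifacts under the
geometry it assumes — not that the pipeline meets any particular accuracy
on clinical images.

## Problem sizes in the test suite

The suite exercises full-size 320 × 320 phantoms: twenty seeded
end-to-end runs (noise sd 3) asserting cord Jaccard ≥ 0.95, edge
Hausdorff ≤ 2 px and ≥ 85% fully-correct vertebral labels; twenty seeded
histograms for EM parameter recovery within ±3 gray levels; one hundred
random fields up to 10 × 10 for DP-versus-enumeration equivalence; plus
the analytic worked examples (Dice conversion, pixel–millimetre
arithmetic, ratio percentages) and the stenosis regression. These sizes
were chosen so the whole suite runs in a few minutes on one core while
still using the pipeline's native image geometry.

## Known limitations

* The candidate grid logic assumes an approximately centred patient; a
  series whose true symmetry plane lies outside slices 4–10 selects the
  nearest admissible candidate.
* Labeling trusts the C2 height ratio; congenital fusions or a C2 region
  merged with the clivus defeat it, which is exactly what the manual
  canal override exists for.
* All pixel constants (band widths, region floors, the 70 px gap) are
  calibrated for cervical anatomy at 0.6875 mm/px and are exposed in
  `pipeline_config()` for retuning, but no automatic rescaling with
  resolution is attempted.
* Inputs are PNG stacks or in-memory matrices; DICOM mapping to 8-bit
  gray is out of scope.
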