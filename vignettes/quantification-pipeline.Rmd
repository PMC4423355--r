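---
title: "Quantifying blastoderm gene expression from embryo images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blastoderm gene expression from embryo images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastoquant)
```

## The measurement problem

Colorimetric whole-mount in-situ hybridisation renders the mRNA of a
segmentation gene as a coloured precipitate in the early fly embryo.
Turning such micrographs into quantitative, comparable measurements of
*where* expression domains sit along the antero-posterior (A--P) axis
requires a chain of image-processing steps, each with conventions that must
be fixed precisely for the resulting atlas to be reproducible. This
vignette documents those conventions as implemented here: the model behind
each stage, the tunable parameters with their defaults, and the numerical
choices made where the procedure left freedom.

Each embryo is photographed four times: a bright-field image carrying the
stain, a DIC (differential interference contrast) image of overall
morphology, a DAPI nuclear counterstain, and a higher-magnification DIC
image of membrane morphology. The first three are registered; the membrane
image is not and is used only for staging.

## Segmentation and alignment

The whole-embryo mask is computed from the DIC image: Otsu thresholding
(the embryo is dark against a bright background), morphological closing
with a 7-px disc to bridge texture gaps, selection of the largest connected
component, and hole filling. A mask must be a single component whose
foreground fills 50--95% of its bounding box — an ellipse fills
$\pi/4 \approx 0.785$ — so frames with no embryo, two embryos, or
non-embryo debris fail loudly rather than silently.

The embryo is then rotated into the canonical frame (anterior left, major
axis horizontal) about the mask centroid, using the principal axis of the
mask pixel coordinates; a circular mask has no defined axis and is treated
as already horizontal. Images are interpolated bilinearly, the mask by
nearest neighbour so it stays binary. The frame is cropped to the mask
bounding box plus a 10-px margin. A--P polarity cannot be inferred from
these images, so `anterior_on_left` is curator metadata; `FALSE` triggers a
horizontal mirror. On synthetic ellipses the recovered axis angle is
accurate to well under 0.5 degrees across rotations up to ±60°.

## The midline strip

Expression is read along a lateral midline strip. The midline is modelled
as a natural cubic spline through **five knots**. Knot abscissae are
equidistant in $x$ across the mask's horizontal span (this is the
interpretation of "equidistant" used throughout: equidistant in $x$, not in
arc length, matching the tabulated `spline_x1..x5` convention). Knot
ordinates come from the mask's morphological skeleton (Zhang--Suen
thinning, pruned to the longest 8-connected path), smoothed with a 15-px
moving average — knots, not the raw skeleton, define the band, and the
smoothing suppresses skeleton jaggedness. Manual knot overrides replace the
computed knots verbatim.

The strip height is 10% of the mask's pixel height, rounded half-up to a
whole pixel (the stored value is an integer pixel count; half-up is the
documented tie-break). For each integer $x$ between the outer knots, the
profile sample is the per-channel arithmetic mean of RGB values along the
column *perpendicular to the local spline tangent*, of length equal to the
strip height, sampled at unit spacing with nearest-pixel lookup;
out-of-image samples are dropped from the mean. The strip is not clamped to
the mask near the poles; instead, the pole regions are excluded later at
detection time (below).

## Channel unmixing

Stain intensity is extracted from the averaged RGB profile by two fixed
formulas:

* **NBT/BCIP (purple)**: $I = 255 - R$. The purple precipitate absorbs the
  red channel; blue is ignored because its signal resembles red with a
  weaker signal-to-background ratio.
* **FastRed (red)**: the red-minus-green difference isolates the stain from
  both the blue component of a purple co-stain and the yellowish background
  of unstained tissue. The default mode reports
  $I = \mathrm{clamp}(R - G,\ 0,\ 255)$, since on a bright background the
  subtraction itself already yields a stain-positive signal. A literal
  alternative, $I = 255 - (R - G)$, is selectable via
  `pipeline_config(fastred_mode = "literal_invert")`; the two differ only
  by orientation of the scale, and the default is the one under which
  stained regions score high.

Positions are mapped to **percent embryo length** (%EL) affinely from the
aligned mask's horizontal extremes: 0% at the anterior pole, 100% at the
posterior.

## Boundary detection and clamped-spline fitting

An expression boundary is the sigmoid transition between an expression
plateau and background. Candidate boundaries are found automatically (the
stand-in for visual identification): the intensity profile is smoothed with
a 5-sample moving average, reduced to its alternating local extrema, and
extrema pairs with amplitude below `min_amplitude` (default 30 intensity
units) are pruned, persistence-style. Each surviving monotone segment
becomes one window, trimmed to where the profile departs from the flanking
plateaus by 5% of the amplitude, i.e. the window spans the 5--95%
transition. The first and last 2 %EL are excluded from detection: where a
stained domain abuts an embryo pole the strip leaves the mask and the
profile steps to the slide background, which would otherwise merge with (or
masquerade as) a boundary ramp; a curator would never call these expression
boundaries.

Each boundary is fitted with a **clamped cubic spline** through three
control points $(x_1,y_1), (x_2,y_2), (x_3,y_3)$ with first derivative
fixed to 0 at $x_1$ and $x_3$. The spline is built from two cubic Hermite
segments with the interior slope at $x_2$ chosen to make the second
derivative continuous — the unique $C^2$ clamped interpolant. Initial
control points: $x_1, x_3$ at the window edges with $y_1, y_3$ the median
intensity over a small shoulder outside each edge; $x_2$ at the
half-amplitude crossing with $y_2 = (y_1+y_3)/2$; the abscissae are then
refined by Nelder--Mead least squares against the raw (unsmoothed) profile
within the window, capped at 100 iterations (non-convergence returns the
initial fit, flagged). Manual control-point overrides bypass everything,
mirroring manual curation.

Two derived quantities summarise a fit, following the standard convention
in the gap-gene literature: **position** is the %EL of $x_2$ (the half-max
point), and **width** is the %EL span $x_3 - x_1$. Note that for strongly
asymmetric control-point spacing the $C^2$ clamped interpolant can
overshoot its plateaus; fits produced by the detection/initialisation above
have near-symmetric spacing and are monotone in practice (asserted in the
tests), but arbitrary user-supplied control points need not be.

Fitted boundaries are matched to the gene's catalogue of boundary IDs by
A--P rank. The catalogue ships as editable configuration
(`inst/extdata/boundary_catalogue.csv`); IDs are kept consistent with
homologous boundaries across species, which leaves deliberate gaps — *gt*
uses IDs 2, 5, 6, 7 with 3--4 reserved. Count mismatches flag the surplus
fits rather than dropping them. On disk, control-point ordinates are stored
in the profile-graph convention (origin at the upper-left of the graph,
$y$ increasing downward, i.e. $y_\mathrm{stored} = 255 - I$); the package
works in intensity space internally and converts on I/O.

## Staging

Cleavage cycles are synchronous, so an embryo in cycle $c$ carries
$2^{c-1}$ nuclei. Nuclei are counted in the DAPI channel by light Gaussian
smoothing ($\sigma = 0.7$ px), 3×3 local-maximum detection above 35% of the
image maximum within the mask, and connected-component merging of plateau
maxima. The cycle is then
$\mathrm{clamp}(\mathrm{round}(\log_2 n) + 1,\ 1,\ 14)$ — class boundaries
at the geometric midpoints between successive powers of two, so e.g. a
count of 700 still assigns cycle 10 (512 nuclei nominal).

Cycle 14A is subdivided into **eight equal time classes** T1--T8. The
timetable encodes the cycle durations: ~10 min per cycle up to C9; then 13,
11, 14, 23 and 58 min for C10--C14A; 58/8 = 7.25 min per time class. Within
C14A the class is read from membrane morphology: progression is summarised
as an invagination-depth fraction $d \in [0,1]$ and
$T = \min(8, \lfloor 8d \rfloor + 1)$. On real images this depth (or the
label itself) is curator metadata — visual staging checked by a second
observer is the practice this mirrors — and any supplied label overrides
inference; on synthetic images the depth is read from the rendered
membrane front. The full label space has exactly 21 values: C1..C13 and
C14_T1..C14_T8.

## Integration into the atlas

Boundary positions are aggregated per (gene × time class × boundary ID)
into the wild-type atlas. Both moment and robust summaries are reported:
arithmetic mean and sample standard deviation ($n-1$ denominator), and
median and **unscaled** MAD — $\mathrm{median}(|x - \mathrm{median}(x)|)$,
with no 1.4826 consistency factor, since it is reported as a raw deviation
in %EL, not as a normal-σ estimate. Single-member groups report zero
dispersion, and an optional `n` column (not part of the 7-column table
schema) lets users filter them. RNAi-treated embryos are refused by the
aggregator unless forced: knock-down strength varies between embryos, so
averaged positions from an RNAi batch are not meaningful.

## The synthetic generator as oracle

`generate_embryo()` renders the four-image quadruplet with known ground
truth, so that every stage above can be tested without microscopy data.
The forward model is deliberately the inverse of the extraction formulas:

* **Geometry**: an ellipse (default semi-axes 300 × 120 px on a 700 × 350
  canvas — a realistic 2:1 embryo that is still fast to process; rotated
  geometries get a matching canvas from `canvas_for_geometry()`).
* **Stain**: local stain strength $s(x) \in [0,1]$ along the A--P axis is a
  sum of logistic ramps, one per boundary, centred at the true position
  with scale set so the 5--95% rise spans the stated width; pixel colour is
  the linear mix $(1-s)\cdot\mathrm{background} + s\cdot\mathrm{full\ stain}$.
  The default colours satisfy the constraints the unmixing formulas rely
  on (purple: full-stain red far below background red; red: green far
  below red). Consecutive boundaries closer than the mean of their widths
  are rejected, as their ramps would overlap.
* **Nuclei**: exactly $2^{c-1}$ Gaussian intensity peaks placed on a
  jittered grid inside the ellipse (minimum separation half the grid
  spacing, so peaks remain resolvable even at the 8192 nuclei of C14).
* **Membrane**: a dark front covering fraction $d$ of the frame encodes
  the time class; generated embryos use the class-midpoint depth
  $(T - 1/2)/8$.
* **Noise**: i.i.d. Gaussian per channel, clipped to [0, 255] — the
  simplest model sufficient for recovery tests.

What the generator does **not** emulate: optics (no point-spread function,
no DIC shear, no vignetting or illumination gradients), 3-D embryo shape,
staining variability across batches, double-stained two-gene images, or
the real morphological criteria that distinguish membrane classes. Passing
recovery tests on synthetic data therefore demonstrates that the
extraction chain is self-consistent and numerically correct — not that it
is robust to every artefact of real microscopy, where curator checks
remain part of the workflow.

## Numerical choices and degenerate inputs

* Strip-height rounding: half-up (`floor(x + 0.5)`), so a 305-px mask gets
  a 31-px strip.
* Principal-axis tie (circular mask): the image x-axis is declared the
  major axis; the skeleton of such a mask is rejected as degenerate when a
  midline is requested.
* Rotation interpolation: bilinear for images, nearest-neighbour for
  masks; mask area changes by well under 1% under alignment.
* Column sampling along the strip: nearest pixel at unit spacing —
  reproducible integer arithmetic rather than subpixel interpolation.
* Window trimming threshold (5% of amplitude) defines the fitted plateau
  edges; with the generator's 5--95% ramp-width convention this makes the
  fitted width estimate the stated width directly.
* CSV writers emit plain decimal numbers at up to 15 significant digits
  (lossless for doubles), comma separators, LF line endings, and the exact
  deposited header names — including `boundary id` with a space in the
  integrated table but `boundary_id` in the per-embryo table. Re-writing a
  read file is byte-identical.
* Profile `_prof.dat` files are whitespace-separated text
  (`x R G B intensity`) with a `#` header; the dialect is unspecified
  upstream, so the reader accepts any whitespace.

## Problem sizes used by the test-suite

The recovery experiments in the tests run at the generator's native scale:
50 embryos per noise condition (σ = 0 and σ = 8 intensity units) for the
end-to-end position-recovery study, 100-case sweeps for the clamped-spline
contract, 1,000 random groups against the brute-force integration oracle,
and staging round-trips across cycles C8--C14A. These sizes give stable
medians while keeping a full run of the suite in the minutes range on a
single CPU.

## A worked example

```{r example, eval = FALSE}
library(blastoquant)

## render a synthetic gt-stained embryo with known boundaries
cv <- canvas_for_geometry(300, 120, rotation_deg = 17)
geom <- embryo_geometry(300, 120, cv$center_xy, rotation_deg = 17)
dom <- domain_spec("gt", data.frame(
  boundary_id = c(2L, 5L, 6L, 7L),
  facing = c("posterior", "anterior", "posterior", "anterior"),
  position_pct_el = c(25, 45, 62, 80),
  width_pct_el = 6, plateau_intensity = 1))
ge <- generate_embryo(geom, dom, stage = "C14_T4", noise_sd = 4, seed = 7,
                      canvas = cv$canvas)

## quantify it
q <- quantify_embryo(ge$record)
q$stage$label                     # "C14_T4"
t(vapply(q$fits, position_and_width, numeric(2), mask = q$mask))
```

## Known limitations

Orientation and (on real data) time class are metadata, not inferences;
out-of-focus or damaged embryos are caught only insofar as they break the
mask invariants; the boundary catalogue beyond *gt* is a plausible editable
default rather than a published table; and boundary widths are stored in
pixels and converted to %EL on demand, since the deposited tables do not
state the unit.
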