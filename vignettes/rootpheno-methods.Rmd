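---
title: "Root trait estimation from 2-D scans: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root trait estimation from 2-D scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootpheno)
```

# The measurement model

A washed root system scanned on a flatbed appears as a dark, branched
silhouette on a light background. `rootpheno` treats trait estimation as
three successive reductions of that raster:

1. **Segmentation** — a binary mask of "root" pixels, obtained by
   histogram-based automatic thresholding after grayscale conversion,
   median smoothing and inversion (so the root is the *bright* foreground
   everywhere downstream).
2. **Skeletonization** — iterative boundary peeling (Zhang–Suen parallel
   thinning) down to a one-pixel-wide, topology-preserving medial curve.
3. **Local cylinder integration** — at each skeleton pixel the exact
   Euclidean distance transform (EDT) of the mask reads off the local
   half-width; traits are per-pixel sums of the corresponding cylinder
   quantities, scaled by the pixel size `ps` (cm/pixel).

The trait formulas are, with `r_i = DT_i * ps` and `N` skeleton pixels:
`AD = sum(2 r_i) / N`, `SA = ps * sum(2 pi r_i)`,
`RV = ps * sum(pi r_i^2)`, `PA = N_fg * ps^2`. Total root length counts
unique 8-adjacent skeleton pixel pairs, 1 per orthogonal step and
`sqrt(2)` per diagonal step.

The underlying assumptions: roots are locally circular in cross-section,
do not overlap themselves in the scan, and are well separated from the
background in intensity. Crossings and overlaps are *not* resolved — they
are counted once, which underestimates TRL and PA of heavily overlapping
systems.

# Why two thresholds

The default `method = "auto"` runs two segmentation branches:

- **Triangle → skeleton/TRL.** The triangle threshold is designed for the
  strongly skewed histograms of background-dominated scans and admits more
  of the faint thin laterals; after thinning this preserves root parts that
  stricter thresholds lose, giving length estimates in range of reference
  software.
- **Otsu → EDT traits and PA.** The Otsu threshold (maximal between-class
  variance) produces mask widths that track reference diameters; since AD,
  SA and RV all derive from the per-pixel radius, the Otsu mask drives the
  whole distance-transform branch. PA is taken from the same Otsu mask so
  the area-like traits share one segmentation; this is a package decision
  where the choice was genuinely open.

Both adaptive methods (mean / Gaussian local thresholds) are implemented
and selectable, but they respond to local contrast: on wide roots they
hollow out the interior (underestimating radii) and trace contour-like
double edges that inflate length; they are provided for experimentation,
not used by the default pairing.

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `median_kernel` | 3 | px | smallest odd kernel that removes salt noise without erasing 3-px laterals; the source method states a median blur but no size |
| `invert` | TRUE | – | downstream code assumes root-bright polarity |
| `block_size` | 11 | px | adaptive neighbourhood; must exceed the widest root for sensible local statistics |
| `offset_c` | 2 | gray | adaptive local-contrast margin; suppresses speckle on flat background |
| `min_particle_area` | 50 | px | particle clearance floor; debris on scanner glass is typically far below 50 px at 400 dpi while the faintest real lateral fragment is above |
| `connectivity` | 8 | – | matches the diagonal adjacency used by the length rule |
| `length_rule` | "edges" | – | per-edge counting is the only reading under which a pure diagonal chain's length equals its Euclidean length; the literal per-pixel variant is available for comparability |

# Numerical choices

- **Histogram grid.** Thresholds are computed on the 256-bin histogram of
  rounded intensities; both thresholds return an integer cutoff `t` and a
  mask `v > t`. Manual "threshold level" pairs seen in other tools are
  interpreted as (cutoff, fill-value) semantics; only the cutoff matters
  here.
- **Otsu ties** (several `t` with equal between-class variance): the
  smallest `t` wins — deterministic and asserted against an exhaustive
  256-candidate oracle.
- **Triangle geometry.** The baseline runs from the histogram peak to the
  *farther* nonzero extreme taken at height zero, and the maximised
  distance is **signed** (positive below the chord). The signed form
  matters: with an unsigned distance a tall bin at the tail end (e.g. a
  perfectly two-level image) would itself maximise the distance and the
  threshold would degenerate. Ties break toward the tail end.
- **Thinning** uses the Zhang–Suen two-subiteration parallel rules with a
  one-pixel background pad (so border-touching roots thin cleanly),
  followed by a topology-safe sequential clean-up that removes the rare
  residual 2×2 square by deleting a simple pixel (crossing number 1).
  Known degeneracy: an *isolated* 2×2 blob is entirely deleted by the
  parallel rules; particle clearance removes such blobs first under the
  defaults. No pruning is applied, so short lateral spurs survive — the
  upstream method does not prune either.
- **EDT** is exact Euclidean (Felzenszwalb–Huttenlocher), not a chamfer
  approximation, because its value is used directly as a radius. Distances
  are between pixel centres: a foreground pixel with an adjacent
  background pixel has DT = 1. An all-foreground mask gets an implicit
  one-pixel background ring (logged). A skeleton pixel with DT = 0 is an
  internal error (skeleton outside its mask), never clamped.
- **Diagonal double-counting.** A diagonal skeleton step whose two pixels
  share an orthogonal skeleton neighbour would re-traverse a path already
  counted; such triangles are suppressed, which is what makes the chain
  oracle (polyline length through pixel centres) hold to 1e-9.

# The half-pixel radius bias (deliberately kept)

Because DT measures to the nearest background pixel *centre*, the medial
pixel of a `w`-px-wide stroke reads `DT = (w + 1) / 2`, not `w / 2`. The
published estimator `r = DT * ps` therefore overestimates the diameter by
exactly one pixel, and consequently SA by the factor `(w+1)/w` and RV by
its square: +20%/+44% at `w = 5`, +11%/+23% at `w = 9`, +6.7%/+14% at
`w = 15`. The AD bias (+1 px) sits inside the method's stated 1.5 px
band, and real validation data for this estimator family show the same
overestimation signature. We keep the published formula rather than
subtracting half a pixel: the correction would silently change the
printed equations, and would make sub-pixel DT values routine where the
contract treats them as internal errors. The acceptance suite documents
the consequence honestly: the SA/RV recovery bands fail for narrow wires
and the failure is annotated in the test file.

# What the phantom generator emulates — and what it does not

`render_phantom()` reproduces the classic validation design: wires of
known diameter and length arranged on a scanning tray. Strokes are
disc-swept (a pixel is foreground iff its centre lies within `width/2` of
the polyline), rendered without anti-aliasing on a light canvas
(background 235, wire intensity ≤ 80), with seeded additive Gaussian
noise clipped to [0, 255]. Ground truth is closed-form cylinder geometry
from the polyline length and stroke width. Overlapping or edge-touching
wires are rejected as invalid fixtures. The default grid spans widths
{3, 5, 9, 15} px × lengths {100, 300, 600} px at 400 dpi — fine lateral
to coarse tap-root scale at the typical scan resolution — with noise
`sd = 5` gray levels, a realistic scanner noise floor.

The generator does **not** emulate: branching topology, root hairs, soil
debris, intensity gradients along roots, wet-scan optical effects
(water immersion is known to inflate reference SA measurements), or JPEG
artefacts. A green phantom test therefore establishes that the
*measurement chain* is correct on known geometry — not that segmentation
is robust to every real-world scan pathology.

`render_ruler()` draws tick marks on the exact cm grid (rounded to
pixels, so 400 dpi spacings alternate 157/158 px) to exercise the
two-point ruler calibration, mirroring the standard bench procedure.

# Validation statistics

`rmse()` and `mbe()` are the plain paired formulas; the MBE sign
convention is observed − reference, so negative means the algorithm
underestimates. `r_squared()` defaults to the squared Pearson correlation
(the quantity usually quoted next to 1:1 agreement plots); because some
reports instead quote the regression coefficient of determination, a
`mode = "regression"` variant is provided — for a simple straight-line
fit with intercept the two coincide, and the tests assert that.

# Known limitations

- PNG and JPEG input only; no TIFF reader is available in the supported
  dependency set (convert TIFF scans to PNG first).
- Whole-image aggregate traits; per-root reporting requires the image to
  contain a single root system (the intended scanning protocol).
- Tips, forks, branching angles and diameter-class distributions are out
  of scope.
- TRL of skeletons with many short spurs includes the spurs (no pruning).
- The distance-transform diameter bias described above is inherent to the
  estimator, not a bug; compare against references with that in mind.
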