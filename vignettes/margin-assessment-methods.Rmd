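---
title: "Methods: intraoperative margin assessment and tumor mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intraoperative margin assessment and tumor mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(marginmap)
```

# The problem

Mohs micrographic surgery (MMS) removes basal cell carcinoma in stages,
examining frozen sections of 100% of the peripheral and deep margin while
the patient waits. Three steps dominate the turnaround time and demand
expertise: grossing the excised specimen (measuring, deciding where to cut,
and inking 12 and 6 o'clock), reading the serial frozen sections for tumor
and for section quality (holes and tears invalidate a negative margin), and
mapping what was seen on glass back onto the surgeon's hand-drawn diagram of
the surgical site in the correct position and orientation.

`marginmap` implements that workflow as a tested R pipeline: 3D point-cloud
measurement of the gross specimen with grossing/inking recommendations,
whole-slide preprocessing into labeled patch sets, a convolutional
embedding backbone plus graph attention network (GAT) for per-patch tumor
and completeness calls, ink-driven orientation, follicle-confounder
docking, and a sliced-Wasserstein morphing of section results into the
surgeon's templated ellipse. A seeded synthetic fixture generator stands in
for the clinical data, which are not publicly available.

# Conventions

All angles are reported in degrees under one clock convention: 0° points to
12 o'clock ("up", the negative-y image direction), angles grow clockwise,
so a correctly laid section — blue ink at the top, red at the bottom — has a
blue-to-red line angle of 180°. `relative_angle(a, b)` is the signed
smallest rotation taking `b` onto `a`, in [-180, 180). Pixel coordinates
are 0-based with the origin at the top-left and y growing downward; patches
are addressed by their top-left corner and laid out on a non-overlapping
grid with stride equal to the patch size.

# Slide preprocessing

The tissue mask removes near-white pixels (mean RGB above 235/255), strips
large low-saturation gray objects (scanner text, pen; saturation below 0.08
and area above 10^4 px), smooths with binary closing and Gaussian blur, and
removes small objects and holes (64 px² cutoffs). All cutoffs are
parameters of `mask_params()`; the defaults match the fixture contrast.

Patches with tissue fraction at or above `min_tissue_frac` form the
`tumor_map` configuration. The threshold has no canonical value in
practice; the package default is 0.5 and it is exposed in `run_config()`.

Section identities come from connected components of the radius graph over
patch centers at 4096 px (which joins the pieces of one section), pieces
from components at 512 px (which separates pieces unless conjoined); both
radii scale linearly with patch size so smaller desk fixtures behave like
256-px production patches. While a section holds fewer pieces than the
histotechnician said it should, its largest candidate piece is split by
spectral clustering — an RBF affinity over patch centers with bandwidth
equal to the piece radius, the symmetric normalized Laplacian, k smallest
eigenvectors, and k-means with a deterministic farthest-point start — into
deficit + 1 parts, iterating to expectation. Observing *more* sections than
expected raises an error rather than merging, since silent merging would
corrupt the downstream per-section mapping. Sections and pieces are
numbered 0-based in reading order of their centroids, which makes labels
invariant to patch enumeration order and to global translation.

Hole and tear candidates come from the alpha shape of each piece's patch
centers (default alpha = 1/(2·patch size)). Rather than walking boundary
loops — which is fragile when the alpha complex pinches — membership of the
*filled* outline is decided directly: a grid cell is inside when its center
lies in a kept Delaunay triangle (circumradius at most 1/alpha) or in a
region enclosed by kept triangles (flood fill from the outside). This
fills interior holes and tears whose mouths the complex bridges, while
concavities genuinely open to the exterior stay open. Degenerate complexes
fall back to the convex hull with a warning. Candidates absent from the
tissue set join it as the `macro_map` configuration, which is therefore
always a superset of `tumor_map`.

# Ink orientation

Tissue edges are found by a Sobel gradient on the mask, dilated to a
band (default 16 px) and opened. Per color, HSV in-range pixels (blue hue
200–260°, red 345–15°, saturation ≥ 0.35, value ≥ 0.2 — the package's own
calibration against the fixture ink palette, and fully configurable for a
lab's dyes) intersect the band;
connected components under 50 px are discarded as spurious applications,
and interior seepage never reports because detection is restricted to the
band. Centroids can be the mean, coordinatewise median, or 10% trimmed
mean. The blue and red centroids define the orientation line.

# Patch models

The embedding backbone is a small four-block convolutional classifier
(3×3 kernels, leaky rectifier with slope 0.1, 2×2 max pooling, global
average pooling into a 64-d embedding, softmax head), trained with Adam
under cosine annealing. It is written directly on BLAS matrix products
(im2col); a wider/deeper backbone and 2048-d embeddings are a configuration
choice, not a code change. The production-scale schedule (batch 32,
learning rate 1e-4, 100 epochs) is the `model_config()` default; the desk
profile used in tests raises the rate to 1e-3 and trains 20 epochs on
24–32 px inputs.
Small networks occasionally start in a flat region of the loss; training
monitors its own progress and deterministically reinitializes (seeds
derived from the config seed) when the loss fails to move, so retraining
with one config is still bit-reproducible.

The patch graph joins all pairs of patch centers within a radius (desk
default 1.5 patch sizes). The GAT stacks three single-head attention layers
of width 32, 32, 64 with DropEdge 0.2 and Dropout 0.2 active only during
training, followed by a dense softmax head that sees the last attention
layer *concatenated with the input embedding*. The skip connection means
graph context can only add to node-level evidence — without it a
poorly-converged attention stack can fall below the plain CNN. Training is
full-graph with Adam at 1e-2 under cosine annealing (production default:
1500 epochs, batch 16 graphs; desk: 400 epochs, batch 4).

Prediction propagation is fixed-weight message passing: a query point
receives the inverse-distance-weighted average of the probabilities of all
nodes within the graph radius, returns the node's own probability at an
exact hit, and is flagged missing (never extrapolated) when no node is in
range. The pass deliberately has no learned parameters, so propagated
maps are reproducible without a model checkpoint.

Follicle docking places concentric circles of 128, 256 and 512 px around a
patch, measures each circle's fractional area overlap with the detected
follicle polygons by exact convex clipping (a 64-gon circle against the
polygon; a seeded Monte-Carlo fallback handles degenerate geometry), and
docks the tumor probability by the convex combination of overlaps with
weights (0.6, 0.3, 0.1), decreasing with radius. The convex combination is
the package's chosen normalization of the penalty to [0, 1]: it guarantees
the adjusted probability never increases and is monotone in each overlap.

# Gross 3D measurement

Turntable frames are segmented by intensity thresholding, component
labeling and a size filter; only the specimen's centroid traces an ellipse
over a revolution, so a RANSAC ellipse over (de-duplicated) centroids
rejects static distractors and noise. GrabCut-style refinement is not
offered; thresholding suffices for the fixture imagery this package ships.
Scale calibration fits a RANSAC ellipse to Scharr edges of the turntable
rim; an obliquely viewed circle preserves its diameter along the major
axis, so scale = diameter / (2a).

Cloud orientation: k-NN outlier removal (mean distance to 8 neighbors
beyond mean + 2 sd), PCA pre-alignment with the densest thin z-band turned
downward (the bottom face sat on the table and is sampled about three times
as densely), RANSAC plane fit over the lowest 20% of points with an inlier
tolerance of twice the robust noise estimate, then three rounds of
least-squares refinement on re-selected bottom points — the refinement
brings the residual tilt from about half a degree to under 0.2°, which
matters because a tilt of e over a 2 cm specimen smears face positions by
about 2e cm. If suture-colored points (dark navy by default) are found,
an in-plane rotation sends their centroid to +y; otherwise the cloud is
flagged unoriented-in-plane rather than guessed.

Extents are *not* raw max–min ranges: with measurement noise of sd sigma the
extreme of n points overestimates each face by about sigma·sqrt(2 log n).
Instead each face position is the kernel-density peak of the coordinate
near its robust extreme, with the bandwidth tied to the noise scale
estimated from the bottom-plane residuals. On the package's box fixtures
(0.02 cm noise) this recovers extents within 1.5% with a median absolute
deviation under 0.01 cm (the acceptance script recomputes both numbers).
Accuracy against manual caliper measurement of real specimens depends on
photogrammetry quality and cannot be assessed from synthetic clouds.

Grossing plans: Mohs mode draws the blue (12 o'clock) to red (6 o'clock)
line, bisecting with a black line plus a blue-red pair per half when the
length exceeds what fits one slide (the 2.0 cm default matches a standard
glass slide's usable width; configurable). Breadloaf mode places cut lines across the specimen at
regular increments (0.5–1 cm; values outside warn), left halves blue for
orientation, right halves cycling red/yellow/green/purple/orange to mark
unique sections.

# Mapping to the surgical site

The sliced Wasserstein distance of order 2 projects both point sets onto
random directions and averages squared 1D Wasserstein distances
(quantile-matched for unequal sizes); with 512 projections the estimate of
the translation closed form |t|/sqrt(2) is within a few percent. Morphing
minimizes this distance to a fixed uniform sample of the template ellipse
interior (n = max(1024, section size)) by moving points along the mean
transport field: 300 iterations, initial step 0.5 of the field with 0.98
decay, 64 projections per iteration, all seeded; reported distances use 512
projections. The section is first rigidly recentered (and isotropically
pre-scaled unless already within 5%). A section whose first-iteration
distance is already at the sampling-noise floor — the distance between an
independent uniform sample of the same size and the target — is left
untouched, which makes an already-uniform section a fixed point up to
sampling noise. The target sample is fixed per run rather than re-drawn
per iteration; re-sampling adds variance without a measurable gain at these
sizes. Ink centroids ride along as landmarks moved by the locally averaged
displacement field, and the final rotation about the ellipse center is the
signed clock difference between the morphed section's blue-red line and the
template's. Probabilities are never altered by transport.

Density overlays are Gaussian product-kernel densities over the transported
points weighted by a class probability, normalized to peak 1 (Scott's rule
bandwidth by default) and contoured at the user threshold, so raising the
threshold never enlarges the contoured area.

Concordance between algorithm-generated and surgeon-drawn maps is a
proportion with a Jeffreys Beta(0.5, 0.5) prior: `concordance_posterior(k, n)`
returns the exact Beta(0.5 + k, 0.5 + n − k) quantiles at 2.5, 50 and 97.5%.
Pooled AUC uses the Mann-Whitney statistic with the tie convention; macro
AUC averages per-slide AUCs with equal weight, skipping one-class slides
with a warning; uncertainty comes from a slide-level (cluster) bootstrap
percentile interval.

# The synthetic fixture generator

No slide, video or cloud data ship with the package; every test input is
generated by code with machine-readable ground truth. Section fixtures draw
tissue pieces as polygons with low-amplitude value noise and cell-like
speckle, saturated ink bands on the outer boundary at known clock
positions, holes/tears as background, and follicle disks. Tumor regions
carry a *region-level* latent "depth" that adds speckle density
(0.005·depth over a fixed 0.0045 benign rate, depth uniform on 0.3–1)
without a reliable tint shift: single-patch evidence is then a noisy
counting statistic while patches of one region share the latent, which is
the regime in which spatial context genuinely helps — the same reason
graph context outperforms patch-only calls on real sections.
Cloud fixtures sample a box surface (bottom face three times denser), add
Gaussian noise, color a suture blob on the top rim, and apply a rigid
transform, keeping the true extents, plane normal and suture direction.

What passing tests show — and do not show. The fixtures exercise the
geometry, statistics and learning machinery end to end under controlled
truth, at desk scale (single sections of a few hundred patches, 4000-point
clouds, 8 + 4 slides for the model experiment; these sizes were chosen so
the full suite runs on one CPU). They do not emulate H&E stain variation,
scanner artifacts, real follicle morphology, or photogrammetry
reconstruction error, so passing says the algorithms are implemented
correctly, not that the clinical accuracies transfer.

# Known limitations

* The GAT uses one attention head per layer; multi-head attention is a
  straightforward extension of the same backward pass.
* Circle-polygon overlap assumes the follicle polygons are mutually
  disjoint (overlap fractions are summed and capped at 1).
* The spectral piece split assumes the conjoined pieces are balanced enough
  that the largest candidate piece is the conjoined one.
* `measure()` expects the flat face down; strongly non-boxlike specimens
  will still be measured, but the face-peak estimator degrades toward the
  raw extent.
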