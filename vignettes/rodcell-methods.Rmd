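---
title: "Models and numerics behind rodcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind rodcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodcell)
```

`rodcell` analyses fluorescence images of rod-shaped cells: it segments
each cell with a stadium-shaped parametric active contour, detects and
tracks labeled structures (such as spindle pole bodies) through noisy
time-lapse sequences, estimates their intensities with a Gaussian
point-spread-function model, and renders the motion as kymographs. This
vignette records the models, the numerical choices, and the reasoning
behind the design decisions that were genuinely open — the material a
maintainer needs that does not fit in function reference pages.

## Coordinate conventions

Images are numeric matrices with rows as *y* and columns as *x*; pixel
centers sit at integer coordinates starting at (1, 1), the native R and
EBImage convention. All lengths are in pixels; physical units enter only
through the `pixel_size` configuration entry when tables are written.
Orientations are reported in (−π/2, π/2], the natural range for an
undirected cell axis.

## The rodscule

### Geometry

A stadium (a rectangle with semicircular caps) is the idealised outline of
a rod-shaped cell. The snake is parametrised by three points $P, Q, R$
that lie on the border of an ellipse $\Gamma$ whose center $M$ is the
centroid of the triangle $PQR$ — the *Steiner circumellipse*, recovered in
closed form from the conjugate semi-diameters $u = P - M$ and
$v = (Q - R)/\sqrt3$. Three points are the minimal parametrisation in
which each coordinate has comparable influence on the enclosed area,
which keeps the optimisation well conditioned.

The outer rod $\Sigma$ is the stadium with radius equal to the semi-minor
axis $b$ and straight-segment half-length $a - b$, so all four extremal
points of the ellipse lie on the rod's border. The inner rod $\Sigma'$ is
$\Sigma$ scaled by $1/\sqrt2$ about $M$: it shares the barycenter and the
orientation and has *exactly* half the area. The uniform scaling is our
construction choice; any shape satisfying the three constraints (shared
pose, half area, inner-ellipse incidence) would do, and the scaled copy
satisfies all of them in closed form. When the three points form an
equilateral triangle the ellipse is a circle, the straight segment has
zero length, and the rod degenerates — gracefully — to a disk.

### Energy

The contrast energy is

$$E_R \;=\; \frac{1}{|\Sigma|}\left[\int_{\Sigma\setminus\Sigma'} f \; -
\int_{\Sigma'} f\right].$$

Because the two regions have equal area, $E_R$ vanishes identically on
constant images and is most negative when $\Sigma'$ covers the bright cell
while the ring $\Sigma\setminus\Sigma'$ samples darker background. The
segmentation result is therefore the **inner** rod, and all reported cell
measurements (length tip-to-tip, width = twice the rod radius,
extremities) refer to it.

**Discretisation.** The integrals are pixel sums weighted by an
anti-aliased coverage profile: a quintic smootherstep ramp over a 1-px
band of the signed distance to the rod boundary. Two properties drove
this choice over boundary supersampling:

* supersampled coverage is quantised (a pixel's weight jumps in steps of
  $1/n^2$), which turns the energy into a staircase and defeats
  finite-difference gradients; the smootherstep profile is $C^2$ in the
  shape parameters;
* the inner weights are renormalised so the *discrete* inner area is
  exactly half the discrete outer area, making $E_R = 0$ exact — not just
  approximate — on constant images, which we treat as a normative property
  of the energy.

Pixels outside the image take mirrored boundary values, avoiding energy
cliffs at the frame edge. A rod entirely outside the image is an error.

### Gradient and optimiser

The gradient is computed by central finite differences with step 0.1 px.
With the $C^2$ coverage profile the FD gradient is step-consistent to a
few percent and, more importantly, an accurate descent direction; the
residual step dependence comes from the 1-px integration band, not from
the image. The optimiser is a Polak–Ribière nonlinear conjugate gradient
with backtracking line search, monotone in energy by construction,
terminating on gradient norm (10⁻⁴), relative energy change (10⁻⁹), line
search failure, or 500 iterations. Non-convergence returns the best state
with a flag rather than an error. On the standard noisy phantom the fit
typically converges in 20–40 iterations, well under a second.

`segment_cells` flags a result as failed when the geometry leaves the
image or when $|E_R|$ at convergence is below 3× the median energy of
equally sized rods placed on a deterministic grid of background windows —
a data-driven floor for "no cell here".

### Initialisation

In the intended workflow the two spots of a cell are detected first; they
approximately span the cell's longitudinal axis, so
`initialize_from_spots` lays the inner rod axis through them, extended by
a margin (default 8 px) at both ends, with a default width (14 px for the
phantom regime). Preprocessing for segmentation is an average z-projection
(noise shrinks by $\sqrt n$) followed by a linear contrast stretch between
the 0.3% and 99.7% intensity percentiles — a conventional robust stretch;
the exact enhancement used is not critical because $E_R$ is linear in the
image.

## Spot intensity estimation

The PSF model is a rotated 2D Gaussian with offset,
$A\,e^{-(a\,\Delta x^2 + 2b\,\Delta x\Delta y + c\,\Delta y^2)} + B$ with
the standard quadratic-form coefficients in $\sigma_x, \sigma_y, \theta$;
at $\theta = 0$ it reduces exactly to the axis-aligned Gaussian and it is
invariant under $(\theta + \pi/2,\ \sigma_x \leftrightarrow \sigma_y)$,
which is how we resolve the angle's identifiability: $\theta$ is reported
in (−π/2, π/2] and set to 0 when $\sigma_x = \sigma_y$. Fitting is
Levenberg–Marquardt over a 9×9 window (covering ±3σ for σ up to ~1.4 px),
with σ initialised from `diffraction_limit / pixel_size` and a small
deterministic multi-start over the angle, because a symmetric start
($\theta_0 = 0$, $\sigma_{x0} = \sigma_{y0}$) has an exactly zero angle
gradient.

**Center anchoring.** For spots whose σ is below a pixel — the regime of
the 5×5 reference kernel (σ = 0.65 px) — the fully free least-squares
problem is weakly identifiable under noise: σ can collapse towards zero
while the amplitude inflates, because a narrow continuous peak can hide
between sample points. Empirically the free fit's mean absolute amplitude
error at noise std 15 is ~27 gray levels with heavy tails, which no
reasonable intensity estimator should exhibit. The packaged estimator
therefore *anchors* the center at the detected candidate (the detection
already localises the peak pixel) and bounds σ ≥ 0.5 px (a PSF narrower
than half a pixel is under-sampled by Nyquist and cannot be
distinguished from aliasing artefacts). With these constraints the
estimator is nearly unbiased with MAE ≈ 12 at noise std 15 — matching the
published accuracy of this estimator family — while remaining exact on
noise-free data. The fully free fit stays available (`center = "free"`)
and is the right choice for noise-free calibration and for well-sampled
spots; it recovers all seven parameters to 10⁻³ on noise-free kernels.

The two baselines kept for comparison are the neighborhood maximum (no
background subtraction — biased by the full offset, error ≈ 80 when the
spot sits on an offset of 80) and rolling-ball background subtraction
(grayscale opening with a disc; accurate on flat backgrounds, degrades
several-fold when the spot sits on cell-scale structure). The Gaussian
fit's error changes by under 20% across these backgrounds.

## Tracking

### Candidate-graph dynamic programming

Per-frame candidates form an acyclic graph; edges connect candidates of
consecutive frames within `max_displacement` (no gap closing — a lost spot
is handled by the loss-frame detector, not by skipping frames). Edge costs
are $C(i,j) = \sum_q \lambda_q f_q(i,j)$ with all terms bounded in [0, 1]
except the deliberate outside-cell penalty:

| term | form | default λ |
|---|---|---|
| intensity | $1 - \hat I_j$ (normalised to the sequence's 0.99 quantile) | 1 |
| intensity variation | $|\hat I_j - \hat I_i|$ | 0.5 |
| distance | $d(i,j)/\text{max\_displacement}$ | 0.5 |
| direction | $(1 - \cos\varphi)/2$, turn angle vs the previous step | 0.25 |
| outside cell | 1 if the target lies outside the rod | 10 |

These forms and defaults are our declared choices; the framework
deliberately leaves them tunable. The directional term depends on the
predecessor's predecessor, so the DP state is the (predecessor, current)
vertex pair — an exact, still-polynomial reformulation of the Bellman
recursion. Ties (within 10⁻⁹) resolve to the lowest predecessor index,
and the brute-force enumeration oracle implements the identical rule, so
DP-vs-oracle equality is exact on random graphs.

### Dense DP for very low PSNR

At PSNR near 0 dB a per-frame detector misses the spot in a third or more
of frames, and a candidate graph without gap closing cannot recover. The
dense tracker runs the same recursion over *every pixel* of the LoG
response — vertex cost $\lambda_{int}(1 - \hat R)$, transition cost
$\lambda_{dist}\, d/D$ within the displacement bound, outside-cell
penalty from a mask — so filter evidence accumulates across frames before
any commitment is made. This is what makes tracking reliable at 0 dB; the
directional term is omitted there because it would square the state
space, and the admissible mask is the segmented cell eroded by 2 px so
that the filter's cell-edge response cannot capture the tracker after a
spot has faded.

### Loss of fluorescence

The per-frame amplitude series (fitted peak height above the cell's
background fluorescence — robust to fits whose own offset strays when the
window touches the cell edge) is fit with a two-level step function by
least squares over all change points, equivalent to maximising the
correlation with a step template. The spot is declared lost at the change
point when the high level is at least $k\sigma$ above background and the
low level below it ($k = 3$ by default; σ estimated as the median absolute
deviation of background pixels). Constant series return no loss frame;
series shorter than 3 frames are flagged.

## Kymographs

Two views of tracked motion, one row per frame. *Cell-frame*: each spot at
its signed orthogonal projection onto the cell axis (origin at the
barycenter; the positive direction fixed from cap C1 to C2 at
segmentation time, stable across frames). Off-axis displacement is
discarded by the projection. *Relative*: the two spots placed at ±d/2
about the midline, where d is their Euclidean separation — positions are
mirror-symmetric by construction while the rendered amplitudes preserve
any brightness asymmetry, and frames past a track's loss frame render at
zero. Raw single-column matrices are used for numeric checks; a 1-px
Gaussian smear is available for display. We render the *fitted* amplitude
rather than raw pixel intensity so the kymograph inherits the estimator's
background independence.

## The phantom generator

The generator is the package's study-condition definition, not a tuning
knob. Defaults:

* 8-bit images, background 25, cell interior 229: the background-
  subtracted RMS signal over the cell support is ≈ 204, so the noise
  series std ∈ {10, 30, 60, 90, 120} spans ≈ 26 dB down to ≈ 4.6 dB —
  the published segmentation stress range (an image SNR definition is not
  unique; we record ours — `snr()` — alongside rather than force a match);
* cells are stadiums with anti-aliased (smootherstep) edges; optional
  darker "nucleus holes" emulate markers excluded from the nucleus, and an
  optional disc emulates the petri dish;
* spots are point-sampled isotropic Gaussians *added* on top of the local
  level, default peak 95.9719 and σ = 0.65 px — exactly the reference
  5×5 kernel, which is shipped as a plain-text fixture and regenerated
  analytically;
* intensity-estimation scenes place spots on a cell interior of 80 (the
  conventional offset), giving spot peaks of ≈ 176 — safely below the
  8-bit ceiling;
* noise is added before quantisation, then values are rounded and clipped
  to the bit range; every noise draw is seeded, and rendering is
  bit-identical across runs for a fixed spec.

What the phantoms deliberately do **not** model: Poisson/shot noise,
camera gain, optical aberrations beyond the isotropic Gaussian PSF, cell
motion or growth, bent or touching cells, and out-of-focus light. Passing
the validation suite therefore demonstrates correctness of the algorithms
under the stated noise model, not performance on any particular
microscope's data. In particular the published ~87% success rate on real
yeast images depends on that dataset and is not reproducible here.

Problem sizes used by the validation suite — a 90×120 single-cell scene
for segmentation (10 noise seeds at std 120), 38 spots × 10 seeds for the
intensity benchmark, 64×64 × 50 frames × 20 replicates for 0 dB tracking,
100 random small graphs for the DP oracle — were chosen so the whole
suite exercises every claim at meaningful statistical depth.

## Observer-variability metrics

For a complete observer × repetition × spot grid the inter-observer
variability averages |differences| over all observer pairs within each
repetition (normaliser 18P for 4 observers × 3 repetitions), and the
intra-observer variability over repetition pairs within each observer
(normaliser 12P). The automated pipeline is deterministic, so its
repetition-wise variability is exactly 0 — the test suite asserts this on
repeated full-pipeline runs.

## Known limitations

* Cells must be straight rods; bent, dividing or overlapping cells are
  out of scope, as is interactive re-initialisation.
* The dense tracker reports integer-pixel positions (sub-pixel refinement
  happens in the per-frame Gaussian fit, not in the path).
* 3D support is by projection: detection on the maximum-intensity
  z-projection, segmentation on the average projection; there is no full
  3D PSF model.
* The rolling-ball baseline is implemented as grayscale opening with a
  disc, the standard morphological reading of the algorithm.
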