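# rodcell

Image analysis for fluorescence microscopy of rod-shaped cells, built for
the classic fission-yeast problem: quantifying how signaling proteins
distribute between the two spindle pole bodies (SPBs) during mitosis. The
SPBs appear as diffraction-limited spots inside a rod-shaped cell; to
measure their brightness asymmetry over time one needs to (i) segment every
cell, (ii) detect and track both spots through a noisy time-lapse movie —
including the moment a fading spot drops below the noise floor — and
(iii) estimate each spot's true intensity despite background fluorescence
and photometric noise. `rodcell` does all of this, and ships a synthetic
phantom generator with exact ground truth so that every stage can be
validated end to end without external data.

## The models at the core

**Segmentation — the rodscule.** A rod-shaped cell is modeled as a stadium
(a rectangle capped by two semicircles). The active contour is parametrised
by three points *P, Q, R* on an ellipse whose center is the centroid of the
triangle they span; the ellipse carries an outer rod Σ and an inner rod Σ′
with the same barycenter and orientation and exactly half the area,
|Σ′| = |Σ|/2. The contour minimises the contrast energy

    E_R = (1/|Σ|) [ ∫_{Σ∖Σ′} f dA − ∫_{Σ′} f dA ],

which is zero on constant images and most negative when the inner rod
covers the bright cell while the surrounding ring samples background. The
inner rod at the optimum *is* the segmentation; cell length, width,
orientation, extremities and background fluorescence follow from it.
Minimisation uses nonlinear conjugate gradients with finite-difference
gradients and a backtracking line search.

**Spot detection and intensity.** Candidates come from a scale-normalised
Laplacian-of-Gaussian filter (one parameter, σ, tied to the spot size)
followed by non-maximum suppression. Each spot's intensity is the amplitude
*A* of a rotated 2D Gaussian with offset,

    f(x, y) = A exp(−(a Δx² + 2b ΔxΔy + c Δy²)) + B,

fit by Levenberg–Marquardt; *B* absorbs local background and noise, and the
fit is insensitive to the pixel grid and to the image content outside the
window.

**Tracking — dynamic programming.** Per-frame candidates form an acyclic
weighted graph (edges only between consecutive frames within a displacement
bound). With edge costs C(i,j) = Σ_q λ_q f_q(i,j) — normalised intensity,
intensity variation, migration distance, directional persistence, and a
heavy penalty for leaving the segmented cell — the Bellman recursion
G(x) = min_j {G(j) + C(j,x)} yields the globally optimal trajectory. For
very low PSNR (down to 0 dB, with PSNR = 20·log₁₀(A/σ)) the same recursion
runs densely over every pixel of the LoG response, accumulating filter
evidence over time instead of committing to per-frame detections. A
step-function fit to the amplitude series against the threshold
*background + k·noise_std* dates the frame F_t0 where a fading spot is
lost. Tracked motion is rendered as two kymographs: spot position along the
cell axis versus time, and the two spots placed symmetrically about their
midline versus time.

## Worked example

```r
library(rodcell)

# a noisy synthetic scene: one cell (length 60 px, width 14 px, rotated
# 0.3 rad, interior 229) on background 25, noise std 120 on an 8-bit scale
cell <- phantom_cell(center = c(60, 45), length = 60, width = 14,
                     orientation = 0.3, intensity = 229)
spec <- phantom_spec(c(90, 120), cells = list(cell),
                     background_intensity = 25, noise_std = 120, seed = 7)
scene <- render_phantom(spec)
snr(scene$clean, 120, background = 25)
#> [1] 4.2        # dB -- the hardest regime of the validation series

# segment from a deliberately wrong overlapping initialization
init <- rodscule_from_rod(c(55, 41), angle = 0.1, half_length = 18,
                          radius = 9)
fit <- rodscule_optimize(scene$noisy, init)
fit$iterations; fit$energy
#> [1] 28
#> [1] -65.08
cell_measurements(fit$state, scene$noisy)
#> cell: length 59.69 px, width 14.44 px, angle 0.294 rad, background 222.0
```

Despite a signal-to-noise ratio of about 4 dB, the recovered length (59.7
vs 60), width (14.4 vs 14) and orientation (0.294 vs 0.3 rad) are all
within half a pixel / a hundredth of a radian of the truth.

Spot intensities are exact on noise-free data:

```r
fit_spot_gaussian(reference_kernel(80), c(3, 3), window = 5,
                  init_sigma = 1, center = "free")
#> spot_fit: A=95.972 B=80.000 mu=(3.00, 3.00) sigma=(0.65, 0.65) theta=0.000
```

A command-line front end with `phantom`, `segment`, `spots`, `track`,
`kymo` and `run` subcommands lives in `inst/scripts/rodcell`.

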