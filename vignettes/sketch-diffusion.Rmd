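---
title: "Sketch-conditioned diffusion for annotated microscopy data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketch-conditioned diffusion for annotated microscopy data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchdiff)
```

## The problem

Training segmentation networks for fluorescence microscopy needs
annotated image data, and manual annotation is the bottleneck.
`sketchdiff` implements a generative shortcut: simulate the *annotation*
(an instance label mask of cell nuclei or membranes), render it into a
coarse intensity *sketch*, and let a denoising diffusion probabilistic
model (DDPM) trained on unannotated real images turn the sketch into a
realistic image. Because the generated image inherits the sketched
structure, the simulated mask is a correct annotation of it by
construction — image/mask pairs come out of the pipeline fully
annotated and error-free.

## The diffusion model

The forward process is the usual Markov chain
$$q(x_t \mid x_{t-1}) = \mathcal N\!\left(x_t;\ \sqrt{1-\beta_t}\,x_{t-1},\ \beta_t I\right),
\qquad t = 1,\dots,T,$$
with $\beta_t$ from the cosine schedule
($\bar\alpha_t = f(t)/f(0)$, $f(t) = \cos^2\big(\tfrac{t/T + s}{1+s}\cdot\tfrac{\pi}{2}\big)$,
$s = 0.008$, $\beta_t$ clipped at 0.999). Its closed form
$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon$ is what
`forward_sample()` evaluates; `forward_step()` exists so tests can verify
the closed form against the iterated chain distributionally. The
backward step is
$$x_{t-1} = \tfrac{1}{\sqrt{\alpha_t}}\Big(x_t -
\tfrac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}\,\hat\epsilon_\theta(x_t,t)\Big)
+ \sqrt{\tilde\beta_t}\,z .$$

Choices the backward step needed that are conventions rather than
results:

* $\tilde\beta_t$ is the DDPM posterior variance
  $\beta_t(1-\bar\alpha_{t-1})/(1-\bar\alpha_t)$ with
  $\tilde\beta_1 = \beta_1$ and $z = 0$ at $t = 1$ — stable at the
  boundary and standard for this model family.
* Timesteps are 1-based ($t \in 1..T$); element `t` of each schedule
  vector is the coefficient for timestep `t`, and $\bar\alpha_0 = 1$ is
  available through `sched_alpha_bar(sch, 0)`.
* All public interfaces speak intensities in $[0,1]$ (so PSNR has peak
  1); the generated $\hat x_0$ is clipped to $[0,1]$ after the final
  step only, because per-step clipping biases the chain.
* Training minimizes the simple noise-prediction objective
  $E\lVert\epsilon - \hat\epsilon_\theta(x_t,t)\rVert^2$ with $t$
  uniform on $1..T$; the loss variant is an assumption (the variational
  bound is a non-goal).
* Randomness is always drawn under an explicit seed
  (`with_seed()`-style), never left to hidden global state, so every
  sampler output is reproducible bit for bit.

## The denoiser

The denoiser contract is deliberately thin: anything callable as
`f(x_t, t)` returning an equally shaped noise prediction works, which
lets the algebra be tested against analytic oracles
(`oracle_denoiser()` knows the true injected noise and must invert the
chain exactly).

The package's trainable denoiser, `ddpm()`, is a multiscale linear
filter bank with sinusoidal time conditioning: per voxel
$$\hat\epsilon(x_t, t) = \sum_{j,k} W_{jk}\, F_j(x_t)\, e_k(t),$$
where the feature maps $F$ are the raw state, Gaussian smooths at
scales 1, 2 and 4 px, a high-pass residual and an intercept, and
$e(t)$ is the sinusoidal timestep embedding (frequencies spaced
geometrically from $1$ to $1/T$, so the embedding is injective over
$0..T$). The weights are fitted in closed form by ridge-penalized least
squares over the accumulated training draws. This is a deliberately
small, convex, CPU-friendly model: it captures exactly the structure a
denoiser needs at these scales — noise is separated from signal by
spatial frequency, and the right mixing proportions depend on $t$
through $\bar\alpha_t$ — while training in seconds and staying fully
deterministic given a seed. A deep encoder–decoder denoiser (U-Net with
sub-pixel upsampling and time embeddings in every block) is the natural
drop-in replacement at production scale; everything else in the package
is agnostic to that choice because only the contract is used.

`ddpm()` returns a classed fit with the familiar surface: `print`,
`summary`, `coef` (the $W$ matrix), `predict` (noise or implied
$\hat x_0$), `residuals` (noise-prediction residuals on fresh draws),
`simulate` (unconditional or sketch-conditioned sampling) and `plot`
(schedule and per-timestep loss). `write_checkpoint()` /
`read_checkpoint()` serialize weights, schedule and normalization
metadata with a version field.

## Sketch-conditioned generation

Unconditional sampling starts from pure noise at $t = T$ and gives no
control over structure. The conditional pipeline
(`generate_annotated_image()`) instead

1. Gaussian-smooths the sketch with $\sigma$ (sharp cartoon edges are
   never seen in real data; smoothing also lets the noisy sketch
   distribution match the real-image distribution earlier),
2. noises it to an early timestep $t_{start} < T$ with the closed-form
   forward sample, and
3. runs the learned backward process from $t_{start}$ down to 1.

$t_{start}$ balances two failure modes: too late and the sketch
structure drowns in noise (annotations stop matching the image); too
early and the injected noise cannot carry the real-image texture. The
defaults $t_{start} = 400$ and $\sigma = 1$ (for $T = 1000$) are the
empirically determined trade-off; for shorter schedules scale
$t_{start}$ proportionally. `tstart_sweep()` re-runs the underlying
optimization protocol: for each $(t_{start}, \sigma)$ it measures the
Bhattacharyya distance and Kullback–Leibler divergence between the
noisy-sketch and noisy-image intensity histograms (forward side), and —
when a denoiser is supplied — PSNR and ZNCC of generated vs. real
images (backward side).

A note on the sweep estimator: empirical histogram distances are biased
upward by sampling noise, roughly in proportion to bins/pixels. At
desk-scale image sizes that floor is visible, so the sweep reports
distances computed on histograms pooled over all images and replicate
noise draws (the least-biased point estimate) alongside the
per-replicate spread. The same floor is why measured distances plateau
rather than decrease strictly once noise dominates both domains —
visible in published measurements of this protocol too, where the
tail values wobble at the fourth decimal.

## Scene simulation

Nuclei are ellipsoids (`rasterize_ellipsoid()`): voxel $p$ belongs to a
nucleus at center $c$ with radius $r$ and directional scales
$(s_x, s_y, s_z)$ iff
$\sum_i \big((p'_i - c_i)/(s_i r)\big)^2 \le 1$, with $p'$ optionally
rotated by a random angle in $(0, 2\pi)$ about a random axis (in-plane
in 2D); the z term is omitted in 2D. Irregular shapes come from a
random B-spline free-form deformation (`deform_bspline()`): cubic
B-spline interpolation of uniform control-point displacements, default
grid spacing $2r$ and maximum displacement $0.15r$ (kept below half the
spacing so the warp stays fold-free). The "distortion" mechanism is
one reused knob because the source recipes leave its strength
unquantified.

`simulate_scene()` + `scene_preset()` reproduce the per-dataset
recipes, including:

* **celegans3d** — centered ellipsoidal embryo outline; radii shrink
  with crowding as $r = r_{ref}(n_{ref}/n)^{1/d}$ (the proportionality
  constant is unstated in the source recipes, so $r_{ref} = 10$,
  $n_{ref} = 50$ are documented defaults); scales
  $(1, U(0.5,1), 0.09)$; 10% of cells shrunken along two random axes
  (post-mitotic, more cylindrical shape).
* **tribolium3d** — nuclei on a spherical embryo surface, rendered as
  13 stacked equirectangular layers ($x = \phi$, $y = \theta$, poles
  stretched); radii in $(5,6)$, scales $(1,1,1)$. Whether the 13 radii
  are equally spaced is unstated; they are unit-spaced here, outermost
  layer last, with the outer radius set so the equator samples at
  about one voxel per pixel.
* **stemcells2d** — whole image, non-overlapping cells, radii
  $(30,45)$, scales $(U(0.75,1),1)$, B-spline deformation, 0–2 dark
  nucleoli per cell.
* **hela2d** — foreground from randomly placed overlapping circles,
  radii $(10,20)$, scales $(U(0.5,1),1)$, B-spline deformation.

Sketch rendering (`render_sketch()`): homogeneous per-cell illumination
(default $U(0.4, 0.9)$ on background 0.05 — the exact ranges are never
printed in the source recipes and are configurable per preset), or the
mean reference intensity per cell when a paired real image exists;
voxels covered by $k$ cells dimmed by $(1-0.10)^{k-1}$; optional linear
intensity decay along z (deepest slice scaled by a factor) or radially
towards the organism center (the radial slope is likewise unprinted and
exposed as the `factor` parameter). Membrane datasets use
`render_membrane_sketch()`: bright inter-label boundaries (face-
neighbour disagreement, so a seam between touching cells is two voxels
wide at width 1), dark interiors.

Conventions: arrays are ordered `(z, )y, x` with time-lapse (2D+t)
stacks stored as 3D volumes with time on the leading axis — generating
them as volumes keeps textures temporally consistent. Voxel indices
are R's native 1-based, voxel-centered; bolting 0-based bookkeeping
onto a 1-based language invites off-by-one bugs, and only internal
consistency and the TIFF boundary matter. Overlap-forbidden placement
rejection-samples up to $100n$ attempts and then returns a partial
scene with a warning rather than failing hard.

## Metrics

`intensity_histogram()` (256 bins over $[0,1]$ by default — the
binning behind published values of this protocol is unstated, so it is
configurable and recorded), `bhattacharyya()`
($-\ln\sum\sqrt{P_iQ_i}$), `kl_divergence()` ($\sum P_i\ln(P_i/Q_i)$,
natural log for both distances), `psnr()` and `zncc()`, and `iou()` /
`matched_instance_iou()` (greedy overlap matching, each predicted label
used once).

Two definitional wrinkles are handled explicitly:

* The source prints PSNR as $20\log_{10}(1/MSE)$, which differs from
  the standard $10\log_{10}(1/MSE)$. Both conventions are implemented
  (`convention = "paper"` is the default) and reports should name the
  one used.
* The ZNCC text calls $\sigma$ "the intensity variance"; dividing by
  the variance would not give 1 for an image against itself, so the
  standard deviation is used, as in the standard ZNCC definition.
* Zero bins in the KL/Bhattacharyya sums are smoothed by adding
  $10^{-10}$ per bin and renormalizing; `Inf` is returned only for
  supports disjoint before smoothing.

## The toy world

`make_toy_dataset()` is the self-contained stand-in for real microscopy
used by every test: simulated scenes provide exact masks; sketches are
their homogeneous renderings; "real" images are the same structure
passed through an imaging model — Gaussian PSF blur
(`psf_sigma = 1` px), a smooth multiplicative illumination field
(relative sd 0.2, mimicking the 10–30% shading typical of
widefield/light-sheet data), a mid-frequency multiplicative texture
(relative sd 0.25, the chromatin-like intra-nuclear variation that
real fluorescent nuclei show and homogeneous sketches do not), and
additive Gaussian noise (sd 0.1 of the dynamic range). The texture and
blur matter: they are what gives the image domain a persistent
intensity-distribution gap from the sketch domain, which is the
phenomenon the $t_{start}$ optimization exists to manage.

What the toy world does **not** emulate: realistic optical anisotropy
and depth-dependent aberrations, shot-noise statistics (noise is
Gaussian, not Poisson), true chromatin morphology, cell-cycle
heterogeneity, or any dataset-specific appearance. Passing tests
therefore demonstrate that the machinery is correct and that the
conditioning mechanism behaves as designed — not that generated images
match any particular real dataset.

Problem sizes: tests fit denoisers on 24×24 to 32×32 images with
$T = 40..100$ and tens of epochs; the sweep runs 12 images at 64×64
with 20 pooled replicates. These sizes were chosen so the whole suite
runs in well under a minute while keeping every assertion
statistically meaningful (forward/backward checks use $10^4$ draws and
4-standard-error bands).

## Known limitations

* The filter-bank denoiser is linear per timestep: it denoises
  structure and matches second-order statistics but cannot synthesize
  sharp high-order texture the way a deep U-Net does. The package's
  claims are therefore about the pipeline mechanics; image realism at
  production scale requires a stronger denoiser behind the same
  contract.
* Very dark cells remain a structural limitation of sketch
  conditioning itself: structure whose contrast is below the injected
  noise amplitude at $t_{start}$ cannot be preserved.
* `deform_bspline()` uses nearest-neighbour resampling, so extreme
  parameter choices can fragment a mask; the fold-free guard
  (displacement < spacing/2) plus the default strength keep shapes
  connected in practice.
* Histogram distances at small pixel counts sit on a sampling floor;
  compare sweep values only across settings measured at the same
  problem size.
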