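# sketchdiff

Generation of realistic, fully annotated fluorescence-microscopy
datasets with sketch-conditioned denoising diffusion.

Training cell-segmentation models needs annotated images, and manual
annotation is the bottleneck. `sketchdiff` implements the generative
alternative: simulate instance label masks (ellipsoidal nuclei or
membrane partitions, per-dataset scene recipes), render them into
coarse intensity **sketches**, and convert the sketches into realistic
images with a diffusion model trained on unannotated real data. The
input mask is, by construction, an exact annotation of the output
image — the pipeline emits ready-to-train image/mask pairs.

## Method in brief

A denoising diffusion probabilistic model (DDPM) uses a fixed noising
chain q(x_t | x_{t-1}) = N(√(1−β_t) x_{t-1}, β_t I) with a cosine
schedule for β_t, and a learned backward chain driven by a network
ε̂_θ(x_t, t) that predicts the injected noise:

    x_{t-1} = (x_t − (1−α_t)/√(1−ᾱ_t) · ε̂_θ(x_t, t)) / √α_t + √β̃_t z .

Instead of sampling from pure noise at t = T, the conditional pipeline
Gaussian-smooths a sketch (σ), noises it only to an early timestep
t_start < T via the closed form x_t = √ᾱ_t x_0 + √(1−ᾱ_t) ε, and
denoises from there — late enough that the noise statistics match the
real-image domain, early enough that the sketched structure survives.
Defaults t_start = 400, σ = 1 (for T = 1000). The package includes the
(t_start, σ) optimization sweep, scored by Bhattacharyya distance and
KL divergence between noisy-sketch and noisy-image intensity
histograms, plus PSNR and zero-normalized cross-correlation for the
backward side, and IoU metrics for downstream segmentation checks.

The trainable denoiser is a multiscale linear filter bank conditioned
on sinusoidal timestep embeddings, fitted in closed form — small,
convex and CPU-fast. Any drop-in denoiser satisfying the `f(x_t, t)`
contract (e.g. a deep U-Net at production scale) can replace it
everywhere.

## Worked example

```r
library(sketchdiff)

# toy world: paired (real image, exact mask, sketch) triples
toy <- make_toy_dataset(toy_world_config(), 8)

# fit the diffusion denoiser on the "real" images (T = 100 schedule)
fit <- train_tiny_denoiser(toy, T_steps = 100, epochs = 40, seed = 0)
print(fit)
#> Diffusion noise-prediction model (multiscale filter bank)
#>   schedule: T = 100 (cosine); training draws: 8 images x 40 epochs
#>   features: intercept, x, smooth_s1, smooth_s2, smooth_s4, highpass; time embedding dim 8
#>   training loss: 0.1070 (baseline 1.0008, reduction 89.3%)

# sketch-conditioned generation at an early start (40% of T)
cfg <- generation_config(t_start = 40, sigma = 1, seed = 7)
smp <- generate_annotated_image(toy[[1]]$sketch, toy[[1]]$labels,
                                fit, fit$schedule, cfg)
zncc(smp$image, smp$sketch)          # 0.669  — sketched structure preserved
psnr(smp$image, toy[[1]]$image)      # 29.5 dB (paper convention)
identical(smp$labels, toy[[1]]$labels)  # TRUE — annotation untouched
```

The training loss falls from the zero-prediction baseline of ~1.0 to
0.107 (an 89% reduction); the generated image correlates strongly with
its sketch (ZNCC 0.67, versus ~0 when sampling from pure noise), and
the emitted mask is bitwise the input mask.

Batch emission with `generate_dataset()` writes `images/0001.tif` +
`masks/0001_masks.tif` pairs and a manifest, reproducible per master
seed. Scene presets (`scene_preset("celegans3d")`, `"tribolium3d"`,
`"stemcells2d"`, `"hela2d"`) reproduce the published simulation
recipes; `tstart_sweep()` re-runs the optimization protocol. A thin
command-line front end lives at `inst/cli/sketchdiff.R`
(`sketch`, `train`, `generate`, `sweep`, `smoke` subcommands).

See `vignettes/sketch-diffusion.Rmd` for the full model description,
parameter rationale and limitations.

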