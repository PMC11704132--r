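# diffva — generative visual attribution with latent diffusion counterfactuals

`diffva` is an R toolkit for **generative visual attribution** in medical
imaging: instead of classifying or segmenting disease, it generates a
*normal counterpart* of a diseased image — same subject, disease markers
removed — and reads the signed difference

    M(I_a) = I_a − I_n

as the visual attribution (VA) map. The generator is a text- and
image-prior-conditioned **latent diffusion model**: a variational
autoencoder compresses images into a spatial latent space, a conditional
denoiser is trained with the epsilon-prediction objective
`E‖ε − ε_θ(z_t, t, τ_θ(y))‖²`, and counterfactuals are produced by noising
the input's latent a fraction `strength` along the forward trajectory
(SDEdit-style image prior) and denoising it under classifier-free guidance
`ε_u + g (ε_c − ε_u)` toward a target prompt such as `"normal chest scan"`.

Everything runs at desk scale on one CPU core. Because no public dataset
ships with exact per-pixel disease ground truth, the package includes a
**phantom generator**: chest-scan-like images in which the healthy and
diseased render of one subject differ *only* in planted lesions (focal
opacity, diffuse haze, enlarged cardiac shadow), so attribution quality is
measurable against an exact lesion mask. The evaluation suite implements
SSIM, multi-scale SSIM, and the Fréchet distance between feature Gaussians
with pluggable extractors, plus a hyperparameter-based component-ablation
protocol (eliminating image priors, the text encoder, or both).

Who this is for: researchers studying counterfactual explanation methods
for medical images who want a complete, inspectable, dependency-light
reference implementation of the latent-diffusion attribution pipeline with
ground-truth-controlled evaluation.

## Worked example

```r
library(diffva)

# 1. data: 400 paired-ground-truth phantoms over four classes
ds  <- make_dataset(list(normal = 160, focal_opacity = 120,
                         diffuse_haze = 60, enlarged_center = 60),
                    image_size = 32, seed = 42)

# 2. two-stage training: patch VAE, then the conditional latent denoiser
vae <- train_autoencoder(ds, vae_config(steps = 2000), seed = 42)
den <- train_diffusion(ds, vae, diffusion_config(steps = 5000), seed = 42)
models <- list(vae = vae, denoiser = den)

# 3. counterfactual attribution of a fresh diseased phantom
pair <- make_paired_phantom(phantom_spec("focal_opacity", "left",
                                         lesion_intensity = 0.7,
                                         lesion_radius_frac = 0.33,
                                         anatomy_seed = 1, noise_seed = 2))
res <- generate_counterfactual(pair$diseased$image, "normal chest scan",
                               sampler_preset("counterfactual", seed = 7),
                               models, mask = lung_region_mask(pair$diseased$spec))

ssim(res$original, res$counterfactual)
#> [1] 0.9256
localization_score(res$va_map, pair$diseased$lesion_mask)
#> [1] 0.5395
```

The SSIM (~0.93) says the counterfactual is structurally close to the
original — only minimal perturbation was made — while the localization
score says over half of the attribution mass falls inside the true lesion
mask (the study median over 50 such cases is 0.54; see the tests). Disease
can be induced in the other direction with positional prompts:

```r
healthy <- make_paired_phantom(phantom_spec("normal", "none",
                                            anatomy_seed = 3, noise_seed = 4))$healthy
ind <- induce_disease(healthy$image, "large lung opacity on the left",
                      sampler_config(0.85, 7.5, 75, seed = 1), models)
```

and the ablation protocol compares component-eliminated generations to a
reference set:

```r
ref <- lapply(Filter(function(s) s$spec$class_label == "normal", ds$samples),
              function(s) s$image)
ex  <- extractor_flatten_pca(ref, d = 24)
run_ablation_study(models, ref, ref, n = 256, seed = 3, extractor = ex)
```

A thin command-line wrapper over these functions ships in
`inst/cli/diffva.R` (subcommands `phantoms`, `train-vae`, `train-diffusion`,
`sample`, `attribute`, `metrics`, `ablate`, `run`).

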