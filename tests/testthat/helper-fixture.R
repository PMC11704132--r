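# Shared fixture: the desk-scale study models (400 phantoms over 4 classes at
# 32 px, f=4 autoencoder trained 2000 steps, conditional denoiser trained 5000
# steps, master seed 42). Trained once per test session and reused by every
# test that needs a trained model.

.diffva_fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function() {
  if (is.null(.diffva_fixture_env$ds)) {
    .diffva_fixture_env$ds <- make_dataset(
      list(normal = 160, focal_opacity = 120, diffuse_haze = 60,
           enlarged_center = 60),
      image_size = 32, seed = 42)
  }
  .diffva_fixture_env$ds
}

fixture_models <- function() {
  if (is.null(.diffva_fixture_env$models)) {
    ds <- fixture_dataset()
    vae <- train_autoencoder(ds, vae_config(steps = 2000), seed = 42)
    den <- train_diffusion(ds, vae, diffusion_config(steps = 5000), seed = 42)
    .diffva_fixture_env$models <- list(vae = vae, denoiser = den)
  }
  .diffva_fixture_env$models
}

# Fresh paired evaluation phantoms (held out of the training set by seed).
fixture_eval_pairs <- function(n, class_label = "focal_opacity",
                               intensity = 0.70, radius = 0.33,
                               seed_base = 1000L) {
  lapply(seq_len(n), function(i) {
    side <- if (class_label %in% c("focal_opacity", "diffuse_haze")) {
      if (i %% 2 == 1) "left" else "right"
    } else "none"
    make_paired_phantom(phantom_spec(
      class_label, side, 32,
      lesion_intensity = if (class_label == "normal") 0 else intensity,
      lesion_radius_frac = radius,
      anatomy_seed = derive_seed(seed_base + i, "eval/anatomy"),
      noise_seed = derive_seed(seed_base + i, "eval/noise")))
  })
}

fixture_healthy_images <- function(n, seed_base = 5000L) {
  lapply(fixture_eval_pairs(n, "normal", seed_base = seed_base),
         function(pr) pr$healthy$image)
}
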