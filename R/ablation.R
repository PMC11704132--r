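#' @title Hyperparameter-based component ablation
#'
#' @description
#' The proxy ablation protocol: the strength and guidance knobs control the
#' influence of the two pipeline components (image priors and text encoder),
#' so extreme settings eliminate them individually or jointly. Each arm
#' generates a set of images which is compared with a real reference set by
#' the Frechet distance under a shared feature extractor; orderings across
#' arms, not absolute values, are the object of interest, and bootstrap
#' confidence intervals keep ordinal claims honest at desk-scale sample
#' sizes.
#'
#' Arms (settings inherited from the ablation protocol this package
#' reproduces): `full` uses the counterfactual preset (strength 0.55,
#' guidance 4) with healthy priors and the normal-class prompt;
#' `no_image_prior` starts from pure noise (strength 0.99, guidance 8.5,
#' normal-class prompt); `no_text` keeps moderate priors (strength 0.4) with
#' guidance 0.01 and an empty prompt; `neither` is unconditional generation
#' (strength 0.99, guidance 0.1, empty prompt).
#'
#' @name ablation
NULL

#' Settings for one ablation arm
#'
#' @param name One of `"full"`, `"no_image_prior"`, `"no_text"`, `"neither"`.
#' @return An `diffva_ablation_mode` list: `name`, `strength`, `guidance`,
#'   `prompt`, `needs_priors`.
#' @export
ablation_mode <- function(name = c("full", "no_image_prior", "no_text", "neither")) {
  name <- match.arg(name)
  m <- switch(name,
    full = list(strength = 0.55, guidance = 4, prompt = "normal chest scan",
                needs_priors = TRUE),
    no_image_prior = list(strength = 0.99, guidance = 8.5,
                          prompt = "normal chest scan", needs_priors = FALSE),
    no_text = list(strength = 0.4, guidance = 0.01, prompt = "",
                   needs_priors = TRUE),
    neither = list(strength = 0.99, guidance = 0.1, prompt = "",
                   needs_priors = FALSE))
  structure(c(list(name = name), m), class = "diffva_ablation_mode")
}

#' Run one ablation arm
#'
#' Generates `n` images under the arm's settings and scores them against the
#' reference set. Reported per arm: the Frechet distance to the reference
#' set, the mean SSIM of each generation to its prior (where priors are
#' used), and as a secondary statistic the mean over generations of the best
#' (global) SSIM to a reference subsample — a guard against the known
#' blind spot of Frechet scores for structurally poor but
#' distribution-matching sets.
#'
#' @param models List with `vae` and `denoiser`.
#' @param reference_set List of reference images (e.g. real healthy).
#' @param prior_set List of prior images (required when the arm uses
#'   priors).
#' @param mode An [ablation_mode()] (or its name).
#' @param n Number of generations (> 0).
#' @param seed Arm seed.
#' @param extractor Feature extractor shared across arms.
#' @param steps Inference steps per generation.
#' @return A one-row data.frame report.
#' @export
run_ablation <- function(models, reference_set, prior_set = NULL, mode = "full",
                         n = 256, seed = 0L, extractor, steps = 40) {
  if (is.character(mode)) mode <- ablation_mode(mode)
  stopifnot(inherits(mode, "diffva_ablation_mode"))
  if (n <= 0) stop("run_ablation: n must be > 0")
  if (length(reference_set) == 0) stop("run_ablation: empty reference set")
  if (mode$needs_priors && (is.null(prior_set) || length(prior_set) == 0))
    stop("run_ablation: mode '", mode$name, "' requires a prior set")
  vae <- models$vae
  cfg <- sampler_config(mode$strength, mode$guidance, steps,
                        seed = derive_seed(seed, paste0("ablation/", mode$name)))
  if (mode$needs_priors) {
    pick <- with_local_seed(derive_seed(seed, "ablation/prior-pick"), function() {
      sample(seq_along(prior_set), n, replace = n > length(prior_set))
    })
    priors <- prior_set[pick]
    z0 <- lapply(priors, function(im) latent_normalize(vae, encode(vae, im)$z))
    zs <- sample_latents(models$denoiser, config = cfg, prompt = mode$prompt,
                         init_latent = z0)
  } else {
    zs <- sample_latents(models$denoiser, config = cfg, prompt = mode$prompt,
                         init_latent = NULL, n = n)
  }
  if (!is.list(zs)) zs <- list(zs)
  gen <- lapply(zs, function(z) decode(vae, latent_denormalize(vae, z)))
  stats_ref <- feature_stats(reference_set, extractor)
  stats_gen <- feature_stats(gen, extractor)
  fid_val <- fid(stats_ref, stats_gen)
  ssim_prior <- if (mode$needs_priors) {
    mean(vapply(seq_len(n), function(i) ssim(gen[[i]], priors[[i]]), numeric(1)))
  } else NA_real_
  ref_sub <- reference_set[seq_len(min(64, length(reference_set)))]
  nn_ssim <- mean(vapply(gen, function(gimg)
    max(vapply(ref_sub, function(r) ssim(gimg, r), numeric(1))), numeric(1)))
  data.frame(mode = mode$name, n = n, fid = fid_val,
             ssim_prior_mean = ssim_prior, nn_ssim_mean = nn_ssim,
             strength = mode$strength, guidance = mode$guidance,
             prompt = mode$prompt, steps = steps, seed = seed,
             extractor_id = extractor$id, stringsAsFactors = FALSE)
}

#' Run the full ablation study
#'
#' @inheritParams run_ablation
#' @param modes Character vector of arm names.
#' @return A data.frame with one row per arm (shared extractor id).
#' @export
run_ablation_study <- function(models, reference_set, prior_set, modes =
                                 c("full", "no_text", "no_image_prior", "neither"),
                               n = 256, seed = 0L, extractor, steps = 40) {
  do.call(rbind, lapply(modes, function(m)
    run_ablation(models, reference_set, prior_set, m, n = n, seed = seed,
                 extractor = extractor, steps = steps)))
}

#' Bootstrap confidence interval for a Frechet-distance difference
#'
#' Resamples both generated sets (with replacement, features precomputed)
#' and returns quantiles of `fid(ref, a) - fid(ref, b)`; an interval
#' excluding 0 supports a strict ordering of the two arms.
#'
#' @param reference_set,images_a,images_b Lists of images.
#' @param extractor Shared feature extractor.
#' @param n_boot Number of resamples.
#' @param seed Resampling seed.
#' @param probs Quantiles to report.
#' @return Named numeric vector of quantiles of the difference.
#' @export
fid_diff_bootstrap <- function(reference_set, images_a, images_b, extractor,
                               n_boot = 500, seed = 0L,
                               probs = c(0.025, 0.5, 0.975)) {
  Fr <- do.call(rbind, lapply(reference_set, extractor$fn))
  Fa <- do.call(rbind, lapply(images_a, extractor$fn))
  Fb <- do.call(rbind, lapply(images_b, extractor$fn))
  gs <- function(M) structure(list(mean = colMeans(M), cov = stats::cov(M),
                                   n = nrow(M), extractor_id = extractor$id),
                              class = "diffva_gaussian_stats")
  ref_stats <- gs(Fr)
  diffs <- with_local_seed(derive_seed(seed, "ablation/bootstrap"), function() {
    vapply(seq_len(n_boot), function(b) {
      ia <- sample.int(nrow(Fa), replace = TRUE)
      ib <- sample.int(nrow(Fb), replace = TRUE)
      fid(ref_stats, gs(Fa[ia, , drop = FALSE])) -
        fid(ref_stats, gs(Fb[ib, , drop = FALSE]))
    }, numeric(1))
  })
  stats::quantile(diffs, probs)
}
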