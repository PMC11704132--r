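test_that("va_map arithmetic is exact, masked, and validated", {
  set.seed(3)
  cf <- matrix(runif(64), 8, 8)
  orig <- cf
  orig[3:5, 3:5] <- cf[3:5, 3:5] + 0.2
  vm <- va_map(orig, cf)
  inside <- matrix(FALSE, 8, 8); inside[3:5, 3:5] <- TRUE
  expect_equal(vm$signed[inside], rep(0.2, 9), tolerance = 1e-15)
  expect_true(all(vm$signed[!inside] == 0))
  expect_equal(cf + vm$signed, orig, tolerance = 1e-15)
  # identical images give the all-zero map
  vz <- va_map(cf, cf)
  expect_true(all(vz$signed == 0))
  # mask restricts the magnitude support
  mask <- matrix(0, 8, 8); mask[3:4, 3:4] <- 1
  vmm <- va_map(orig, cf, mask)
  expect_true(all(vmm$magnitude[mask == 0] == 0))
  expect_error(va_map(orig, cf[1:4, ]), "shape")
  expect_error(va_map(orig, cf, mask * 0.5), "binary")
})

test_that("localization_score has its closed forms and degenerate handling", {
  mask <- matrix(0, 8, 8); mask[1:4, ] <- 1 # 50% of pixels
  m_in <- va_map(matrix(0, 8, 8) + 0.3 * mask, matrix(0, 8, 8))
  expect_equal(localization_score(m_in, mask), 1.0)
  uniform <- va_map(matrix(0.5, 8, 8), matrix(0.3, 8, 8))
  q_mask <- matrix(0, 8, 8); q_mask[1:4, 1:4] <- 1 # 25% of pixels
  expect_equal(localization_score(uniform, q_mask), 0.25)
  expect_error(localization_score(uniform, matrix(0, 8, 8)), "empty")
  expect_warning(z <- localization_score(va_map(uniform$signed * 0, uniform$signed * 0),
                                         q_mask), "all-zero")
  expect_equal(z, 0)
})

test_that("strength 0 counterfactual equals the autoencoder reconstruction", {
  models <- fixture_models()
  pr <- fixture_eval_pairs(1, seed_base = 9200L)[[1]]
  cfg <- sampler_config(0, 4, 50, seed = 1)
  res <- generate_counterfactual(pr$diseased$image, "normal chest scan", cfg, models)
  recon <- decode(models$vae, encode(models$vae, pr$diseased$image))
  expect_equal(res$counterfactual, recon, tolerance = 1e-12)
  expect_equal(res$va_map$signed, pr$diseased$image - recon, tolerance = 1e-12)
  # provenance: config echoed verbatim
  expect_identical(res$config, cfg)
})

test_that("counterfactuals remove lesions while minimally perturbing anatomy", {
  models <- fixture_models()
  pairs <- fixture_eval_pairs(25, "focal_opacity", seed_base = 1000L)
  cfg <- sampler_preset("counterfactual", seed = 7)
  improved <- logical(length(pairs))
  ssims <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    res <- generate_counterfactual(pr$diseased$image, "normal chest scan",
                                   cfg, models)
    m <- pr$diseased$lesion_mask > 0
    h_mean <- mean(pr$healthy$image[m])
    improved[i] <- abs(mean(res$counterfactual[m]) - h_mean) <
      abs(mean(pr$diseased$image[m]) - h_mean)
    ssims[i] <- ssim(res$original, res$counterfactual)
  }
  expect_gte(mean(improved), 0.8)
  expect_gte(mean(ssims), 0.7)
})

test_that("healthy inputs pass through with minimal perturbation", {
  models <- fixture_models()
  healthy <- fixture_healthy_images(8, seed_base = 9300L)
  cfg <- sampler_config(0.3, 4, 50, seed = 3)
  ssims <- vapply(healthy, function(im) {
    res <- generate_counterfactual(im, "normal chest scan", cfg, models)
    ssim(res$counterfactual, res$original)
  }, numeric(1))
  expect_gt(mean(ssims), 0.9)
})

test_that("attribution maps localize to the true lesion, not to mismatched anatomy", {
  models <- fixture_models()
  pairs <- fixture_eval_pairs(25, "focal_opacity", seed_base = 1000L)
  cfg <- sampler_preset("counterfactual", seed = 7)
  locs <- numeric(length(pairs)); locs_mm <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    lung <- lung_region_mask(pr$diseased$spec)
    res <- generate_counterfactual(pr$diseased$image, "normal chest scan",
                                   cfg, models, mask = lung)
    locs[i] <- localization_score(res$va_map, pr$diseased$lesion_mask)
    other <- pairs[[(i %% length(pairs)) + 1]]$healthy$image
    locs_mm[i] <- localization_score(va_map(pr$diseased$image, other, lung),
                                     pr$diseased$lesion_mask)
  }
  expect_gte(median(locs), 0.5)
  # specificity direction: matched-subject maps are better localized than
  # wrong-subject control maps
  expect_gt(median(locs), median(locs_mm))
})

test_that("positional prompts induce opacity on the prompted side", {
  models <- fixture_models()
  hp <- fixture_healthy_images(1, seed_base = 9400L)[[1]]
  sp <- phantom_spec("normal", "none", 32, 0,
                     anatomy_seed = derive_seed(9401L, "eval/anatomy"),
                     noise_seed = derive_seed(9401L, "eval/noise"))
  lung <- lung_region_mask(sp)
  mid <- (ncol(hp) + 1) / 2
  ok <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    cfg <- sampler_config(0.85, 7.5, 75, seed = s)
    rl <- induce_disease(hp, "large lung opacity on the left", cfg, models, mask = lung)
    rr <- induce_disease(hp, "large lung opacity on the right", cfg, models, mask = lung)
    cl <- diffva:::magnitude_centroid(rl$va_map$magnitude)
    cr <- diffva:::magnitude_centroid(rr$va_map$magnitude)
    if (is.finite(cl[2]) && is.finite(cr[2]) && cl[2] < mid && cr[2] > mid)
      ok <- ok + 1L
  }
  expect_gt(ok, n_seeds / 2)
})

test_that("near-zero guidance with an empty prompt matches unconditional regeneration", {
  models <- fixture_models()
  hp <- fixture_healthy_images(1, seed_base = 9500L)[[1]]
  cfg <- sampler_config(0.4, 0.01, 40, seed = 2)
  a <- induce_disease(hp, "", cfg, models)
  # empty prompt: conditional branch IS the null branch, guidance is inert
  cfg2 <- sampler_config(0.4, 0, 40, seed = 2)
  b <- induce_disease(hp, "", cfg2, models)
  expect_equal(a$counterfactual, b$counterfactual, tolerance = 1e-12)
})

test_that("induction of a held-out prompt combination stays in the prompted lung", {
  models <- fixture_models()
  hp <- fixture_healthy_images(1, seed_base = 9600L)[[1]]
  sp <- phantom_spec("normal", "none", 32, 0,
                     anatomy_seed = derive_seed(9601L, "eval/anatomy"),
                     noise_seed = derive_seed(9601L, "eval/noise"))
  left_lung <- lung_region_mask(sp, "left")
  lung <- lung_region_mask(sp)
  wins <- 0L
  for (s in 1:9) {
    cfg <- sampler_config(0.85, 7.5, 75, seed = 100 + s)
    # "large" never occurs in training prompts: a held-out token combination
    r <- induce_disease(hp, "large lung opacity on the left", cfg, models,
                        mask = lung)
    frac_left <- sum(r$va_map$magnitude * left_lung) / sum(r$va_map$magnitude)
    if (frac_left >= 0.6) wins <- wins + 1L
  }
  expect_gt(wins, 4L)
})
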