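test_that("phantom specification validation rejects invalid class/side combinations by field name", {
  expect_error(phantom_spec("normal", "left"), "side")
  expect_error(phantom_spec("focal_opacity", "none"), "side")
  expect_error(phantom_spec("enlarged_center", "right"), "side")
  expect_error(phantom_spec("nodule", "left"), "class_label")
  expect_error(phantom_spec("focal_opacity", "left", lesion_radius_frac = 0.7),
               "lesion_radius_frac")
})

test_that("paired renders differ only inside the lesion mask", {
  for (cl in c("focal_opacity", "diffuse_haze", "enlarged_center")) {
    side <- if (cl == "enlarged_center") "none" else "left"
    pr <- make_paired_phantom(phantom_spec(cl, side, 32, 0.8,
                                           anatomy_seed = 5, noise_seed = 9))
    d <- pr$diseased$image - pr$healthy$image
    expect_equal(max(abs(d * (1 - pr$diseased$lesion_mask))), 0)
    expect_gt(sum(pr$diseased$lesion_mask), 0)
    expect_true(all(pr$diseased$image >= 0 & pr$diseased$image <= 1))
    expect_true(all(pr$healthy$image >= 0 & pr$healthy$image <= 1))
  }
})

test_that("zero lesion intensity reproduces the normal phantom pixelwise", {
  pr <- make_paired_phantom(phantom_spec("focal_opacity", "left", 32, 0,
                                         anatomy_seed = 5, noise_seed = 9))
  expect_identical(pr$healthy$image, pr$diseased$image)
  expect_equal(sum(pr$diseased$lesion_mask), 0)
})

test_that("left and right lesions of one subject are exact mirror images", {
  for (seed in c(5, 17, 123)) {
    mk <- function(side) make_paired_phantom(
      phantom_spec("focal_opacity", side, 32, 0.8, 0.35,
                   anatomy_seed = seed, noise_seed = seed))$diseased$lesion_mask
    mL <- mk("left"); mR <- mk("right")
    expect_identical(mL, mR[, ncol(mR):1])
  }
})

test_that("renders are deterministic in (anatomy_seed, noise_seed, spec)", {
  sp <- phantom_spec("diffuse_haze", "both", 32, 0.6, anatomy_seed = 3, noise_seed = 4)
  expect_identical(make_paired_phantom(sp), make_paired_phantom(sp))
})

test_that("prompts are a deterministic function of class and side", {
  expect_identical(phantom_prompt("normal", "none"), "normal chest scan")
  expect_identical(phantom_prompt("focal_opacity", "left"), "lung opacity on the left")
  expect_identical(phantom_prompt("diffuse_haze", "both"), "diffuse haze on both sides")
  vocab <- default_vocabulary()
  for (cl in c("normal", "focal_opacity", "diffuse_haze", "enlarged_center")) {
    side <- if (cl %in% c("focal_opacity", "diffuse_haze")) "right" else "none"
    words <- strsplit(phantom_prompt(cl, side), " ")[[1]]
    expect_true(all(words %in% vocab$tokens))
  }
})

test_that("make_dataset is deterministic, validates counts, honors proportions", {
  expect_error(make_dataset(list(normal = 0)), "zero total")
  expect_error(make_dataset(list(nodule = 3)), "class labels")
  d1 <- make_dataset(list(normal = 4, focal_opacity = 4), seed = 7)
  d2 <- make_dataset(list(normal = 4, focal_opacity = 4), seed = 7)
  expect_identical(d1, d2)
  # scaled version of the four-class training-set ratios (10192:3616:4945:1345)
  s <- 1 / 100
  counts <- list(normal = round(10192 * s), diffuse_haze = round(3616 * s),
                 focal_opacity = round(4945 * s), enlarged_center = round(1345 * s))
  ds <- make_dataset(counts, seed = 1)
  got <- table(vapply(ds$samples, function(x) x$spec$class_label, character(1)))
  expect_equal(as.integer(got[names(counts)]), unlist(counts, use.names = FALSE))
})

test_that("per-pixel mean anatomy is stable across disjoint sample halves", {
  ds <- make_dataset(list(normal = 100), seed = 21)
  imgs <- lapply(ds$samples, function(s) s$image)
  h1 <- Reduce(`+`, imgs[1:50]) / 50
  h2 <- Reduce(`+`, imgs[51:100]) / 50
  pix_sd <- sqrt((Reduce(`+`, lapply(imgs, function(im) (im - (h1 + h2) / 2)^2))) / 99)
  pooled_se <- pix_sd * sqrt(2 / 50)
  frac_ok <- mean(abs(h1 - h2) <= 4 * pmax(pooled_se, 1e-6))
  expect_gte(frac_ok, 0.95)
})

test_that("a mean-intensity threshold separates normal from focal_opacity", {
  ds <- make_dataset(list(normal = 100, focal_opacity = 100), seed = 11)
  sc <- vapply(ds$samples, function(s)
    max(mean(s$image[expected_lesion_region(s$spec, "left") > 0]),
        mean(s$image[expected_lesion_region(s$spec, "right") > 0])), numeric(1))
  lab <- vapply(ds$samples, function(s) s$spec$class_label, character(1))
  acc <- max(vapply(sort(unique(sc)), function(th)
    mean((sc >= th) == (lab == "focal_opacity")), numeric(1)))
  expect_gte(acc, 0.95)
})

test_that("dataset round-trips through disk after one 8-bit quantization", {
  ds <- make_dataset(list(normal = 3, focal_opacity = 3), seed = 2)
  dir1 <- file.path(tempdir(), "diffva_rt1")
  dir2 <- file.path(tempdir(), "diffva_rt2")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE))
  write_dataset(ds, dir1)
  back <- read_dataset(dir1)
  expect_equal(length(back$samples), 6)
  for (i in seq_along(back$samples)) {
    expect_equal(back$samples[[i]]$image,
                 round(ds$samples[[i]]$image * 255) / 255, tolerance = 1e-12)
    expect_identical(back$samples[[i]]$lesion_mask, ds$samples[[i]]$lesion_mask)
    expect_identical(back$samples[[i]]$prompt, ds$samples[[i]]$prompt)
  }
  # second write/read is a fixed point
  write_dataset(back, dir2)
  again <- read_dataset(dir2)
  expect_equal(again$samples[[1]]$image, back$samples[[1]]$image)
})

test_that("read_dataset fails loudly on missing or inconsistent manifests", {
  empty <- file.path(tempdir(), "diffva_empty")
  dir.create(empty, showWarnings = FALSE)
  on.exit(unlink(empty, recursive = TRUE))
  expect_error(read_dataset(empty), "manifest")
  ds <- make_dataset(list(normal = 2), seed = 1)
  d3 <- file.path(tempdir(), "diffva_bad")
  write_dataset(ds, d3)
  on.exit(unlink(d3, recursive = TRUE), add = TRUE)
  file.remove(file.path(d3, "sample_0002.png"))
  expect_error(read_dataset(d3), "on disk")
})
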