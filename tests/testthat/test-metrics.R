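test_that("global SSIM matches the hand-evaluated closed form on constant images", {
  x <- matrix(0.5, 8, 8)
  y <- matrix(0.7, 8, 8)
  # means 0.5 / 0.7, variances and covariance exactly zero:
  C1 <- 0.01^2; C2 <- 0.03^2
  expected <- ((2 * 0.5 * 0.7 + C1) * (0 + C2)) / ((0.25 + 0.49 + C1) * (0 + C2))
  expect_equal(ssim(x, y), expected, tolerance = 1e-10)
})

test_that("ssim is 1 at identity and symmetric, global and windowed", {
  set.seed(1)
  for (rep in 1:20) {
    x <- matrix(runif(256), 16, 16)
    y <- matrix(runif(256), 16, 16)
    for (w in c("global", "gaussian-11")) {
      p <- ssim_params(window = w)
      expect_equal(ssim(x, x, p), 1, tolerance = 1e-12)
      expect_equal(ssim(x, y, p), ssim(y, x, p), tolerance = 1e-12)
      expect_lte(abs(ssim(x, y, p)), 1 + 1e-12)
    }
  }
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
  expect_error(ssim_params(L = 0), "L")
})

test_that("windowed SSIM reproduces an independently computed reference value", {
  # reference values computed once with scikit-image (gaussian_weights=TRUE,
  # sigma=1.5, use_sample_covariance=FALSE, data_range=1) on these exact inputs
  ig <- matrix(1:16, 16, 16); jg <- t(ig)
  x <- (sin(ig * 0.7) + cos(jg * 1.3)) / 4 + 0.5
  y <- pmin(pmax(x + 0.1 * sin(ig * 1.1) * cos(jg * 0.5), 0), 1)
  expect_equal(ssim(x, y, ssim_params(window = "gaussian-11")),
               0.9784680449058221, tolerance = 1e-9)
  ig <- matrix(1:32, 32, 32); jg <- t(ig)
  x2 <- (sin(ig * 0.7) + cos(jg * 1.3)) / 4 + 0.5
  y2 <- pmin(pmax(x2 + 0.1 * sin(ig * 1.1) * cos(jg * 0.5), 0), 1)
  expect_equal(ssim(x2, y2, ssim_params(window = "gaussian-11")),
               0.976955817176048, tolerance = 1e-9)
})

test_that("ms_ssim: identity, single-scale reduction, and scale feasibility", {
  ig <- matrix(1:32, 32, 32); jg <- t(ig)
  x <- (sin(ig * 0.7) + cos(jg * 1.3)) / 4 + 0.5
  y <- pmin(pmax(x + 0.1 * sin(ig * 1.1) * cos(jg * 0.5), 0), 1)
  expect_equal(ms_ssim(x, x), 1, tolerance = 1e-12)
  # M = 1 with its (renormalized unit) weight equals windowed ssim exactly
  p1 <- ssim_params(window = "gaussian-11", n_scales = 1)
  expect_equal(ms_ssim(x, y, p1), ssim(x, y, p1), tolerance = 1e-12)
  # 32 px supports scales 32, 16, 8 (M = 3) but not five scales
  expect_silent(ms_ssim(x, y, ssim_params(n_scales = 3)))
  expect_error(ms_ssim(x, y, ssim_params(n_scales = 5)), "feasible")
  # downsampling chain arithmetic
  expect_equal(dim(diffva:::downsample2(x)), c(16L, 16L))
  expect_equal(dim(diffva:::downsample2(diffva:::downsample2(x))), c(8L, 8L))
})

test_that("feature_stats computes Gaussian moments and records the extractor", {
  ex <- extractor_random_projection(16, d = 16, seed = 3)
  imgs <- list(matrix(0.3, 4, 4), matrix(0.3, 4, 4))
  st <- feature_stats(imgs, ex)
  expect_equal(max(abs(st$cov)), 0)
  expect_equal(st$n, 2)
  expect_match(st$extractor_id, "random-projection")
  expect_error(feature_stats(imgs[1], ex), ">= 2")
  # flatten extractor dimensionality
  exp_ <- extractor_flatten_pca(lapply(1:20, function(i) matrix(runif(16), 4, 4)), d = 5)
  expect_length(exp_$fn(matrix(0.5, 4, 4)), 5)
})

test_that("feature_stats recovers moments of synthetic injected features", {
  # identity "extractor" on 1x d images turns feature_stats into a plain
  # Gaussian moment estimator we can check against Monte-Carlo bounds
  d <- 4
  ex <- structure(list(id = "identity", fn = function(img) as.vector(img)),
                  class = "diffva_extractor")
  mu <- c(1, -2, 0.5, 3)
  sds <- c(1, 0.5, 2, 1)
  set.seed(9)
  feats <- lapply(1:5000, function(i) matrix(rnorm(d, mu, sds), 1))
  st <- feature_stats(feats, ex)
  expect_true(all(abs(st$mean - mu) <= 4 * sds / sqrt(5000)))
  expect_equal(unname(diag(st$cov)), sds^2, tolerance = 0.15)
})

test_that("fid matches scalar closed forms and is a symmetric premetric", {
  gs <- function(mean, var, id = "t") structure(
    list(mean = mean, cov = diag(var, length(mean)), n = 100, extractor_id = id),
    class = "diffva_gaussian_stats")
  expect_equal(fid(gs(0, 1), gs(0, 1)), 0, tolerance = 1e-8)
  expect_equal(fid(gs(0, 1), gs(1, 1)), 1.0, tolerance = 1e-8)
  expect_equal(fid(gs(0, 1), gs(0, 4)), 1.0, tolerance = 1e-8)
  # diagonal-covariance brute force across dimensions
  set.seed(4)
  for (d in c(2, 5, 9)) {
    ma <- rnorm(d); mb <- rnorm(d)
    va <- runif(d, 0.2, 2); vb <- runif(d, 0.2, 2)
    brute <- sum((ma - mb)^2) + sum(va + vb - 2 * sqrt(va * vb))
    expect_equal(fid(gs(ma, va), gs(mb, vb)), brute, tolerance = 1e-8)
  }
  # symmetry and non-negativity on random full covariances
  for (rep in 1:10) {
    d <- 6
    A <- matrix(rnorm(d * d), d); B <- matrix(rnorm(d * d), d)
    sa <- structure(list(mean = rnorm(d), cov = crossprod(A) / d, n = 50,
                         extractor_id = "t"), class = "diffva_gaussian_stats")
    sb <- structure(list(mean = rnorm(d), cov = crossprod(B) / d, n = 50,
                         extractor_id = "t"), class = "diffva_gaussian_stats")
    expect_equal(fid(sa, sb), fid(sb, sa), tolerance = 1e-6)
    expect_gte(fid(sa, sb), 0)
    expect_equal(fid(sa, sa), 0, tolerance = 1e-8)
  }
  expect_error(fid(gs(0, 1, "a"), gs(0, 1, "b")), "different extractors")
})

test_that("fid separates healthy from diseased phantom sets but not healthy splits", {
  dsA <- make_dataset(list(normal = 200), seed = 31)
  dsB <- make_dataset(list(normal = 200), seed = 32)
  dsD <- make_dataset(list(focal_opacity = 200), seed = 33)
  h1 <- lapply(dsA$samples, function(s) s$image)
  h2 <- lapply(dsB$samples, function(s) s$image)
  dis <- lapply(dsD$samples, function(s) s$image)
  # the extractor must represent the whole domain, not one class
  ex <- extractor_flatten_pca(c(h1[1:100], dis[1:100]), d = 24)
  f_hh <- fid(feature_stats(h1, ex), feature_stats(h2, ex))
  f_hd <- fid(feature_stats(h1, ex), feature_stats(dis, ex))
  expect_lt(f_hh, f_hd)
})
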