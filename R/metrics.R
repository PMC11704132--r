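#' @title Image-similarity and distribution-distance metrics
#'
#' @description
#' The quantitative evaluation suite used throughout the package: structural
#' similarity (SSIM) in its global single-window and Gaussian 11x11 windowed
#' forms, multi-scale SSIM, and the Frechet distance between Gaussian fits of
#' image features with pluggable feature extractors. Absolute Frechet values
#' depend entirely on the extractor and are only meaningful as orderings
#' between image sets measured with the *same* extractor; the extractor id is
#' therefore recorded in every statistics object and checked on comparison.
#'
#' @name metrics
NULL

#' SSIM parameter set
#'
#' @param L Dynamic range of the images (1 for `[0,1]` data).
#' @param K1,K2 Stability constants; `C1 = (K1*L)^2`, `C2 = (K2*L)^2`,
#'   `C3 = C2/2` (the luminance/contrast/structure form with unit exponents).
#' @param window `"global"` (one window covering the image — the printed
#'   closed form) or `"gaussian-11"` (11x11 Gaussian window, sd 1.5, averaged
#'   over positions — the form used inside MS-SSIM).
#' @param n_scales Number of scales for [ms_ssim()].
#' @param weights Per-scale MS-SSIM exponents; the standard 5-scale set,
#'   truncated and renormalized when `n_scales < 5`.
#' @return A list of parameters.
#' @export
ssim_params <- function(L = 1, K1 = 0.01, K2 = 0.03, window = c("global", "gaussian-11"),
                        n_scales = 3, weights = NULL) {
  if (L <= 0) stop("dynamic range L must be > 0")
  window <- match.arg(window)
  std_w <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  if (is.null(weights)) {
    if (n_scales > 5) stop("n_scales > 5 requires explicit weights")
    weights <- std_w[seq_len(n_scales)]
    weights <- weights / sum(weights)
  }
  if (any(weights <= 0)) stop("weights must be positive")
  list(L = L, C1 = (K1 * L)^2, C2 = (K2 * L)^2, C3 = (K2 * L)^2 / 2,
       window = window, n_scales = n_scales, weights = weights)
}

gaussian_window_11 <- function() {
  g <- exp(-((-5:5)^2) / (2 * 1.5^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'valid' 2-d correlation of image with a (small, separable-symmetric) kernel.
filter2_valid <- function(img, k) {
  kn <- nrow(k)
  n1 <- nrow(img) - kn + 1L
  n2 <- ncol(img) - kn + 1L
  out <- matrix(0, n1, n2)
  for (a in seq_len(kn)) for (b in seq_len(kn)) {
    if (k[a, b] == 0) next
    out <- out + k[a, b] * img[a:(a + n1 - 1L), b:(b + n2 - 1L), drop = FALSE]
  }
  out
}

# Windowed SSIM moment maps; weighted (biased) moments per window position.
# Images smaller than the 11x11 window fall back to one global window
# (population moments), so coarse MS-SSIM scales of small images stay defined.
ssim_maps <- function(x, y, params) {
  if (nrow(x) < 11 || ncol(x) < 11) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    sxx <- mean(x^2) - mx^2; syy <- mean(y^2) - my^2
    sxy <- mean(x * y) - mx * my
    return(list(
      l = matrix((2 * mx * my + params$C1) / (mx^2 + my^2 + params$C1), 1, 1),
      cs = matrix((2 * sxy + params$C2) / (sxx + syy + params$C2), 1, 1)))
  }
  w <- gaussian_window_11()
  mx <- filter2_valid(x, w); my <- filter2_valid(y, w)
  sxx <- filter2_valid(x * x, w) - mx^2
  syy <- filter2_valid(y * y, w) - my^2
  sxy <- filter2_valid(x * y, w) - mx * my
  C1 <- params$C1; C2 <- params$C2
  l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
  cs <- (2 * sxy + C2) / (sxx + syy + C2)
  list(l = l, cs = cs)
}

#' Structural similarity between two images
#'
#' Computes the luminance-contrast-structure similarity with unit exponents
#' and `C3 = C2/2`, which collapses to
#' `(2*mu_x*mu_y + C1)(2*sigma_xy + C2) / ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`.
#' With `window = "global"` the statistics are computed once over the whole
#' image (unbiased variance/covariance); with `"gaussian-11"` they are
#' computed per window position and averaged.
#'
#' @param x,y Numeric matrices of equal shape with values in `[0, L]`.
#' @param params A [ssim_params()] list.
#' @return A scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, params = ssim_params()) {
  if (!all(dim(x) == dim(y))) stop("ssim: shape mismatch")
  if (params$window == "global") {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- stats::var(as.vector(x)); vy <- stats::var(as.vector(y))
    cxy <- stats::cov(as.vector(x), as.vector(y))
    ((2 * mx * my + params$C1) * (2 * cxy + params$C2)) /
      ((mx^2 + my^2 + params$C1) * (vx + vy + params$C2))
  } else {
    m <- ssim_maps(x, y, params)
    mean(m$l * m$cs)
  }
}

downsample2 <- function(img) {
  n1 <- floor(nrow(img) / 2) * 2L
  n2 <- floor(ncol(img) / 2) * 2L
  img <- img[seq_len(n1), seq_len(n2), drop = FALSE]
  0.25 * (img[seq(1, n1, 2), seq(1, n2, 2), drop = FALSE] +
          img[seq(2, n1, 2), seq(1, n2, 2), drop = FALSE] +
          img[seq(1, n1, 2), seq(2, n2, 2), drop = FALSE] +
          img[seq(2, n1, 2), seq(2, n2, 2), drop = FALSE])
}

#' Multi-scale structural similarity
#'
#' Product over scales of the windowed contrast-structure term (each raised
#' to its scale weight), times the luminance term applied at the coarsest
#' scale, with scales produced by 2x2 mean filtering and factor-2 decimation.
#' Negative contrast-structure means are clamped at zero before
#' exponentiation (fractional powers of negative values are undefined; the
#' clamp only matters for pathological anticorrelated inputs).
#'
#' @inheritParams ssim
#' @return A scalar similarity.
#' @export
ms_ssim <- function(x, y, params = ssim_params()) {
  if (!all(dim(x) == dim(y))) stop("ms_ssim: shape mismatch")
  M <- params$n_scales
  min_size <- 4 * 2^(M - 1) # coarsest scale must keep at least 4 px
  if (min(dim(x)) < min_size) {
    feasible <- floor(log2(min(dim(x)) / 4)) + 1
    stop("ms_ssim: image too small for ", M, " scales; maximum feasible n_scales is ",
         max(feasible, 0))
  }
  total <- 1
  for (j in seq_len(M)) {
    m <- ssim_maps(x, y, params)
    if (j < M) {
      total <- total * max(mean(m$cs), 0)^params$weights[j]
      x <- downsample2(x); y <- downsample2(y)
    } else {
      # luminance enters at the coarsest scale, combined per window position
      # so that M = 1 with unit weight reduces exactly to windowed SSIM
      total <- total * max(mean(m$l * m$cs), 0)^params$weights[j]
    }
  }
  total
}

#' Feature extractors for distribution distances
#'
#' Stand-ins for large pretrained feature networks, suited to desk-scale
#' phantom studies. Three families are provided:
#' \describe{
#'   \item{flatten-pca}{PCA (fit on a reference image set) of flattened
#'     pixels, keeping `d` components.}
#'   \item{random-projection}{a fixed seeded Gaussian random projection of
#'     flattened pixels to `d` dimensions.}
#'   \item{classifier}{the penultimate (hidden-layer) activations of a small
#'     phantom-trained classifier, see [train_feature_classifier()].}
#' }
#' Each extractor carries an `id`; Gaussian statistics from different
#' extractors are never comparable and [fid()] refuses to mix them.
#'
#' @param images List of image matrices used to fit the PCA.
#' @param d Feature dimension (d <= 64 recommended at desk scale).
#' @return An extractor object (list with `id` and `fn`).
#' @export
extractor_flatten_pca <- function(images, d = 32) {
  X <- do.call(rbind, lapply(images, as.vector))
  d <- min(d, ncol(X), nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
  structure(list(
    id = sprintf("flatten-pca-d%d", d),
    fn = function(img) as.vector(scale(matrix(as.vector(img), 1),
                                       center = pc$center, scale = FALSE) %*% pc$rotation)
  ), class = "diffva_extractor")
}

#' @rdname extractor_flatten_pca
#' @param n_pixels Flattened input length the projection expects.
#' @param seed Seed fixing the projection matrix.
#' @export
extractor_random_projection <- function(n_pixels, d = 32, seed = 0L) {
  P <- with_local_seed(derive_seed(seed, "extractor/random-projection"), function() {
    matrix(rnorm(n_pixels * d) / sqrt(n_pixels), n_pixels, d)
  })
  structure(list(
    id = sprintf("random-projection-d%d-s%d", d, as.integer(seed)),
    fn = function(img) {
      v <- as.vector(img)
      if (length(v) != n_pixels)
        stop("extractor expects ", n_pixels, " pixels, got ", length(v))
      as.vector(v %*% P)
    }
  ), class = "diffva_extractor")
}

#' Gaussian statistics of extracted features
#'
#' @param images List of image matrices (>= 2).
#' @param extractor An extractor object.
#' @return A `diffva_gaussian_stats` list: `mean`, `cov` (unbiased), `n`,
#'   `extractor_id`.
#' @export
feature_stats <- function(images, extractor) {
  stopifnot(inherits(extractor, "diffva_extractor"))
  if (length(images) < 2) stop("feature_stats: need >= 2 images")
  F <- do.call(rbind, lapply(images, extractor$fn))
  structure(list(mean = colMeans(F), cov = stats::cov(F),
                 n = nrow(F), extractor_id = extractor$id),
            class = "diffva_gaussian_stats")
}

sym_sqrtm <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two feature Gaussians
#'
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, with the matrix
#' square root computed as `Tr sqrt(S_a^{1/2} S_b S_a^{1/2})` via symmetric
#' eigendecomposition (negative eigenvalues clipped at zero), which is
#' symmetric in its arguments and numerically stable for near-singular
#' covariances.
#'
#' @param a,b `diffva_gaussian_stats` from the *same* extractor.
#' @return A non-negative scalar.
#' @export
fid <- function(a, b) {
  stopifnot(inherits(a, "diffva_gaussian_stats"), inherits(b, "diffva_gaussian_stats"))
  if (a$extractor_id != b$extractor_id)
    stop("fid: stats come from different extractors ('", a$extractor_id,
         "' vs '", b$extractor_id, "')")
  if (length(a$mean) != length(b$mean)) stop("fid: dimension mismatch")
  Sa <- (a$cov + t(a$cov)) / 2
  Sb <- (b$cov + t(b$cov)) / 2
  Ra <- sym_sqrtm(Sa)
  M <- Ra %*% Sb %*% Ra
  tr_sqrt <- sum(sqrt(pmax(eigen((M + t(M)) / 2, symmetric = TRUE,
                                 only.values = TRUE)$values, 0)))
  val <- sum((a$mean - b$mean)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * tr_sqrt
  max(val, 0)
}
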