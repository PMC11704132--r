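#' @title Variational autoencoder over image patches
#'
#' @description
#' Maps images to a compact spatial latent grid and back so that diffusion
#' runs in latent space. The encoder/decoder act per non-overlapping
#' `f x f` patch (a strided-convolution architecture with one hidden layer),
#' giving a latent of shape `(H/f) x (W/f) x c`. The posterior is diagonal
#' Gaussian; its mean is used deterministically at inference. Training
#' minimizes pixel reconstruction error plus a small latent regularizer (KL
#' toward a standard normal, or a plain L2 on the posterior mean), with an
#' optional patch-discriminator adversarial term forming the full min-max
#' objective (off by default at desk scale; a perceptual term is not used and
#' this is recorded in the config).
#'
#' @name autoencoder
NULL

#' Autoencoder configuration
#'
#' @param f Downsampling factor (patch size); latent side is `image_size/f`.
#' @param c Latent channels per patch.
#' @param hidden Hidden width of the per-patch MLPs.
#' @param steps Training steps.
#' @param lr Adam learning rate.
#' @param batch Images per training batch.
#' @param reg_weight Weight of the latent regularizer.
#' @param regularizer `"kl"` (variational) or `"l2"` (plain L2 on latents).
#' @param adversarial Enable the patch-discriminator min-max term.
#' @param adv_weight Weight of the adversarial term when enabled.
#' @return A config list.
#' @export
vae_config <- function(f = 4, c = 8, hidden = 64, steps = 2000, lr = 2e-3,
                       batch = 32, reg_weight = 1e-6,
                       regularizer = c("kl", "l2"),
                       adversarial = FALSE, adv_weight = 0.05) {
  list(f = as.integer(f), c = as.integer(c), hidden = as.integer(hidden),
       steps = as.integer(steps), lr = lr, batch = as.integer(batch),
       reg_weight = reg_weight, regularizer = match.arg(regularizer),
       adversarial = adversarial, adv_weight = adv_weight,
       perceptual = "none")
}

init_vae <- function(config, seed = 0L) {
  f2 <- config$f^2; h <- config$hidden; c <- config$c
  p <- with_local_seed(derive_seed(seed, "vae/init"), function() {
    list(
      enc.W1 = rmat(f2, h, 0.3), enc.b1 = rep(0, h),
      enc.Wmu = rmat(h, c, 0.3), enc.bmu = rep(0, c),
      enc.Wlv = matrix(0, h, c), enc.blv = rep(-4, c),
      dec.W1 = rmat(c, h, 0.3), dec.b1 = rep(0, h),
      dec.W2 = rmat(h, f2, 0.3), dec.b2 = rep(0, f2)
    )
  })
  disc <- with_local_seed(derive_seed(seed, "vae/disc-init"), function() {
    list(disc.W1 = rmat(f2, h, 0.3), disc.b1 = rep(0, h),
         disc.W2 = rmat(h, 1, 0.3), disc.b2 = 0)
  })
  structure(list(params = p, disc = disc, config = config,
                 latent_stats = NULL, history = NULL),
            class = "diffva_vae")
}

# image (n x n) -> patches (m^2 x f^2), patch index column-major over the
# latent grid, pixels within a patch column-major.
patchify <- function(img, f) {
  n <- nrow(img)
  m <- n %/% f
  A <- array(img, c(f, m, f, m))
  t(matrix(aperm(A, c(1, 3, 2, 4)), f * f, m * m))
}

unpatchify <- function(P, f, n) {
  m <- n %/% f
  A <- array(t(P), c(f, f, m, m))
  matrix(aperm(A, c(1, 3, 2, 4)), n, n)
}

vae_enc_fwd <- function(p, X) {
  H1pre <- sweep(X %*% p$enc.W1, 2, p$enc.b1, `+`)
  H1 <- tanh(H1pre)
  mu <- sweep(H1 %*% p$enc.Wmu, 2, p$enc.bmu, `+`)
  lv <- sweep(H1 %*% p$enc.Wlv, 2, p$enc.blv, `+`)
  list(H1 = H1, mu = mu, lv = lv)
}

vae_dec_fwd <- function(p, Z) {
  H2pre <- sweep(Z %*% p$dec.W1, 2, p$dec.b1, `+`)
  H2 <- tanh(H2pre)
  logits <- sweep(H2 %*% p$dec.W2, 2, p$dec.b2, `+`)
  list(H2 = H2, logits = logits, xhat = sigmoid(logits))
}

#' Encode an image to its latent code
#'
#' Deterministic: returns the variational posterior's mean.
#'
#' @param vae A trained (or initialized) `diffva_vae`.
#' @param image Numeric matrix with side divisible by `f`, values in `[0,1]`.
#' @return A `diffva_latent`: `z` (h x w x c array), `f`, `c`.
#' @export
encode <- function(vae, image) {
  stopifnot(inherits(vae, "diffva_vae"))
  f <- vae$config$f
  n <- nrow(image)
  if (n %% f != 0 || ncol(image) %% f != 0)
    stop("image size ", n, "x", ncol(image), " not divisible by f=", f)
  if (min(image) < -1e-8 || max(image) > 1 + 1e-8)
    stop("encode: image values must lie in [0,1]")
  mu <- vae_enc_fwd(vae$params, patchify(image, f))$mu
  m <- n %/% f
  structure(list(z = array(mu, c(m, m, vae$config$c)), f = f, c = vae$config$c),
            class = "diffva_latent")
}

#' Decode a latent code to an image
#'
#' Output is squashed to `[0,1]` by the decoder's sigmoid.
#'
#' @param vae A `diffva_vae`.
#' @param z A `diffva_latent` or an h x w x c array.
#' @return Image matrix of side `h * f`.
#' @export
decode <- function(vae, z) {
  stopifnot(inherits(vae, "diffva_vae"))
  za <- if (inherits(z, "diffva_latent")) z$z else z
  if (length(dim(za)) != 3 || dim(za)[3] != vae$config$c)
    stop("decode: latent shape ", paste(dim(za), collapse = "x"),
         " does not match trained channels c=", vae$config$c)
  if (!all(is.finite(za))) stop("decode: non-finite latent")
  m <- dim(za)[1]
  Z <- matrix(za, m * dim(za)[2], vae$config$c)
  unpatchify(vae_dec_fwd(vae$params, Z)$xhat, vae$config$f, m * vae$config$f)
}

disc_fwd <- function(dp, X) {
  H <- tanh(sweep(X %*% dp$disc.W1, 2, dp$disc.b1, `+`))
  list(H = H, p = sigmoid(sweep(H %*% dp$disc.W2, 2, dp$disc.b2, `+`)))
}

#' Train the patch autoencoder on a phantom dataset
#'
#' Two-stage pipeline convention: the autoencoder is trained first and then
#' frozen during diffusion training. The training history records every
#' enabled loss term at every step; training aborts with the step index if
#' the loss turns non-finite. After training, per-channel latent moments are
#' estimated on the training images and stored (`latent_stats`) so diffusion
#' can operate on approximately unit-scale latents.
#'
#' @param ds A `diffva_dataset` (nonempty).
#' @param config A [vae_config()].
#' @param seed Master seed for initialization, batch order and posterior
#'   noise.
#' @return A trained `diffva_vae` with a `history` data.frame.
#' @export
train_autoencoder <- function(ds, config = vae_config(), seed = 0L) {
  stopifnot(inherits(ds, "diffva_dataset"))
  if (length(ds$samples) == 0) stop("train_autoencoder: empty dataset")
  vae <- init_vae(config, seed)
  f <- config$f
  n_img <- length(ds$samples)
  patches <- lapply(ds$samples, function(s) patchify(s$image, f))
  p <- vae$params
  dp <- vae$disc
  opt <- adam_init(p)
  dopt <- adam_init(dp)
  hist <- vector("list", config$steps)
  rng <- derive_seed(seed, "vae/train")
  set.seed(rng)
  for (step in seq_len(config$steps)) {
    idx <- sample.int(n_img, min(config$batch, n_img))
    X <- do.call(rbind, patches[idx])
    N <- nrow(X); ce <- config$c
    enc <- vae_enc_fwd(p, X)
    epsd <- matrix(rnorm(N * ce), N, ce)
    Z <- enc$mu + exp(0.5 * enc$lv) * epsd
    dec <- vae_dec_fwd(p, Z)
    rec <- mean((dec$xhat - X)^2)
    if (config$regularizer == "kl") {
      reg <- -0.5 * mean(1 + enc$lv - enc$mu^2 - exp(enc$lv))
    } else {
      reg <- mean(enc$mu^2)
    }
    adv <- NA_real_
    loss <- rec + config$reg_weight * reg
    if (!is.finite(loss))
      stop("train_autoencoder: non-finite loss at step ", step)
    # backward: reconstruction
    nel <- length(X)
    dxhat <- 2 * (dec$xhat - X) / nel
    dlogits <- dxhat * dec$xhat * (1 - dec$xhat)
    g <- list()
    g$dec.W2 <- t(dec$H2) %*% dlogits
    g$dec.b2 <- colSums(dlogits)
    dH2 <- (dlogits %*% t(p$dec.W2)) * (1 - dec$H2^2)
    g$dec.W1 <- t(Z) %*% dH2
    g$dec.b1 <- colSums(dH2)
    dZ <- dH2 %*% t(p$dec.W1)
    if (config$adversarial) {
      # discriminator update on real vs reconstructed patches
      dfr <- disc_fwd(dp, X)
      dff <- disc_fwd(dp, dec$xhat)
      adv <- -mean(log(dff$p + 1e-8)) # generator's term
      loss <- loss + config$adv_weight * adv
      dd <- list()
      dlog_r <- -(1 - dfr$p) / N
      dlog_f <- dff$p / N
      dd$disc.W2 <- t(dfr$H) %*% dlog_r + t(dff$H) %*% dlog_f
      dd$disc.b2 <- sum(dlog_r) + sum(dlog_f)
      dHr <- (dlog_r %*% t(dp$disc.W2)) * (1 - dfr$H^2)
      dHf <- (dlog_f %*% t(dp$disc.W2)) * (1 - dff$H^2)
      dd$disc.W1 <- t(X) %*% dHr + t(dec$xhat) %*% dHf
      dd$disc.b1 <- colSums(dHr) + colSums(dHf)
      st <- adam_step(dp, dd, dopt, lr = config$lr)
      dp <- st$params; dopt <- st$state
      # generator gradient through D(xhat): adv = -mean(log D(xhat))
      do_adv <- -config$adv_weight * (1 - dff$p) / N
      dH_adv <- (do_adv %*% t(dp$disc.W2)) * (1 - dff$H^2)
      dxhat_adv <- dH_adv %*% t(dp$disc.W1)
      dlog_adv <- dxhat_adv * dec$xhat * (1 - dec$xhat)
      g$dec.W2 <- g$dec.W2 + t(dec$H2) %*% dlog_adv
      g$dec.b2 <- g$dec.b2 + colSums(dlog_adv)
      dH2a <- (dlog_adv %*% t(p$dec.W2)) * (1 - dec$H2^2)
      g$dec.W1 <- g$dec.W1 + t(Z) %*% dH2a
      g$dec.b1 <- g$dec.b1 + colSums(dH2a)
      dZ <- dZ + dH2a %*% t(p$dec.W1)
    }
    # encoder gradients (reparametrized) + regularizer
    dmu <- dZ
    dlv <- dZ * epsd * 0.5 * exp(0.5 * enc$lv)
    if (config$regularizer == "kl") {
      nl <- length(enc$mu)
      dmu <- dmu + config$reg_weight * enc$mu / nl
      dlv <- dlv + config$reg_weight * (-0.5) * (1 - exp(enc$lv)) / nl
    } else {
      dmu <- dmu + config$reg_weight * 2 * enc$mu / length(enc$mu)
    }
    g$enc.Wmu <- t(enc$H1) %*% dmu
    g$enc.bmu <- colSums(dmu)
    g$enc.Wlv <- t(enc$H1) %*% dlv
    g$enc.blv <- colSums(dlv)
    dH1 <- (dmu %*% t(p$enc.Wmu) + dlv %*% t(p$enc.Wlv)) * (1 - enc$H1^2)
    g$enc.W1 <- t(X) %*% dH1
    g$enc.b1 <- colSums(dH1)
    st <- adam_step(p, g, opt, lr = config$lr)
    p <- st$params; opt <- st$state
    hist[[step]] <- c(step = step, rec = rec, reg = reg, adv = adv)
  }
  vae$params <- p
  vae$disc <- dp
  vae$history <- as.data.frame(do.call(rbind, hist))
  # latent moments for diffusion-space normalization
  mus <- lapply(ds$samples[seq_len(min(n_img, 200))],
                function(s) vae_enc_fwd(p, patchify(s$image, f))$mu)
  Mu <- do.call(rbind, mus)
  vae$latent_stats <- list(mean = colMeans(Mu),
                           sd = pmax(apply(Mu, 2, stats::sd), 1e-6))
  vae
}

# Map a latent array to/from the approximately unit-scale space diffusion
# is trained in (per-channel standardization).
latent_normalize <- function(vae, za) {
  st <- vae$latent_stats
  if (is.null(st)) stop("vae has no latent_stats; train it first")
  sweep(sweep(za, 3, st$mean, `-`), 3, st$sd, `/`)
}

latent_denormalize <- function(vae, za) {
  st <- vae$latent_stats
  sweep(sweep(za, 3, st$sd, `*`), 3, st$mean, `+`)
}
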