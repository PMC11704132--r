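#' Diffusion training configuration
#'
#' @param T_steps Training noise-schedule grid size.
#' @param law VP discretization (`"cosine"` default, `"linear"` alternative).
#' @param steps Optimization steps.
#' @param lr Peak Adam learning rate (cosine-decayed to `lr_min`).
#' @param lr_min Final learning rate.
#' @param batch Examples per step.
#' @param cond_dropout Probability of replacing a prompt by the NULL
#'   condition during training (trains the unconditional branch used by
#'   classifier-free guidance).
#' @param d,n_blocks,n_text_blocks,max_tokens Denoiser architecture, see
#'   [init_denoiser()].
#' @return A config list.
#' @export
diffusion_config <- function(T_steps = 1000, law = "cosine", steps = 5000,
                             lr = 2e-3, lr_min = 2e-4, batch = 16,
                             cond_dropout = 0.1, d = 64, n_blocks = 2,
                             n_text_blocks = 2, max_tokens = 8) {
  list(T_steps = as.integer(T_steps), law = law, steps = as.integer(steps),
       lr = lr, lr_min = lr_min, batch = as.integer(batch),
       cond_dropout = cond_dropout, d = as.integer(d),
       n_blocks = as.integer(n_blocks), n_text_blocks = as.integer(n_text_blocks),
       max_tokens = as.integer(max_tokens))
}

#' Train the conditional latent denoiser
#'
#' Encodes the dataset with the frozen autoencoder, standardizes latents to
#' the diffusion scale, and minimizes the epsilon-prediction objective with
#' per-example uniform time draws. The text encoder is trained jointly with
#' the denoiser; with probability `cond_dropout` an example's prompt is
#' replaced by the NULL sequence. History records the running loss.
#'
#' @param ds A `diffva_dataset`.
#' @param vae A trained `diffva_vae` (frozen here).
#' @param config A [diffusion_config()].
#' @param seed Master seed (initialization, batch order, t/eps draws).
#' @return A trained `diffva_denoiser` carrying its schedule, vocabulary and
#'   the vae's latent statistics.
#' @export
train_diffusion <- function(ds, vae, config = diffusion_config(), seed = 0L) {
  stopifnot(inherits(ds, "diffva_dataset"), inherits(vae, "diffva_vae"))
  if (length(ds$samples) == 0) stop("train_diffusion: empty dataset")
  vocab <- ds$vocabulary
  n_img <- length(ds$samples)
  img_size <- nrow(ds$samples[[1]]$image)
  latent_hw <- img_size %/% vae$config$f
  model <- init_denoiser(vocab, latent_hw = latent_hw, c_lat = vae$config$c,
                         d = config$d, n_blocks = config$n_blocks,
                         n_text_blocks = config$n_text_blocks,
                         max_tokens = config$max_tokens,
                         seed = derive_seed(seed, "diffusion/init"))
  schedule <- build_schedule("VP", config$T_steps, law = config$law)
  # frozen-VAE latents, standardized per channel
  lat <- lapply(ds$samples, function(s) latent_normalize(vae, encode(vae, s$image)$z))
  prompts <- vapply(ds$samples, function(s) s$prompt, character(1))
  uniq <- unique(prompts)
  ids_by_prompt <- lapply(c(uniq, ".null"), function(pr) {
    if (pr == ".null") tokenize_prompt("", vocab, config$max_tokens)
    else tokenize_prompt(pr, vocab, config$max_tokens)
  })
  names(ids_by_prompt) <- c(uniq, ".null")
  prompt_idx <- match(prompts, uniq)
  p <- model$params
  opt <- adam_init(p)
  hist <- numeric(config$steps)
  set.seed(derive_seed(seed, "diffusion/train"))
  for (step in seq_len(config$steps)) {
    B <- min(config$batch, n_img)
    idx <- sample.int(n_img, B)
    keys <- ifelse(runif(B) < config$cond_dropout, ".null", uniq[prompt_idx[idx]])
    ts <- sample.int(schedule$T, B, replace = TRUE)
    xs <- vector("list", B); eps <- vector("list", B)
    for (i in seq_len(B)) {
      e <- array(rnorm(length(lat[[idx[i]]])), dim = dim(lat[[idx[i]]]))
      eps[[i]] <- e
      xs[[i]] <- forward_noise(lat[[idx[i]]], ts[i], e, schedule)
    }
    # encode each distinct prompt in the batch once
    bkeys <- unique(keys)
    model$params <- p
    txt <- lapply(bkeys, function(k) txt_fwd(model, ids_by_prompt[[k]], want_cache = TRUE))
    names(txt) <- bkeys
    Cs <- lapply(keys, function(k) txt[[k]]$C)
    fw <- den_fwd(model, xs, ts, Cs, want_cache = TRUE)
    dEs <- vector("list", B)
    loss <- 0
    for (i in seq_len(B)) {
      dd <- fw$eps[[i]] - eps[[i]]
      loss <- loss + mean(dd^2)
      dEs[[i]] <- 2 * dd / (B * length(dd))
    }
    loss <- loss / B
    if (!is.finite(loss)) stop("train_diffusion: non-finite loss at step ", step)
    hist[step] <- loss
    grads <- grad_zero_like(p)
    bw <- den_bwd(model, dEs, fw$cache, grads)
    grads <- bw$grads
    # fan the context gradients back through each distinct prompt encoding
    L <- model$config$max_tokens
    for (k in bkeys) {
      rows_k <- which(keys == k)
      dC <- matrix(0, L, model$config$d)
      for (i in rows_k)
        dC <- dC + bw$dCstack[((i - 1) * L + 1):(i * L), , drop = FALSE]
      grads <- txt_bwd(model, dC, txt[[k]]$cache, grads)
    }
    lr_t <- config$lr_min + 0.5 * (config$lr - config$lr_min) *
      (1 + cos(pi * (step - 1) / config$steps))
    st <- adam_step(p, grads, opt, lr = lr_t)
    p <- st$params; opt <- st$state
  }
  model$params <- p
  model$schedule <- schedule
  model$latent_stats <- vae$latent_stats
  model$history <- data.frame(step = seq_len(config$steps), loss = hist)
  model
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle the parameter arrays with their config records
#' (architecture, schedule, vocabulary, latent statistics) in R's portable
#' serialization format.
#'
#' @param object A `diffva_vae` or `diffva_denoiser`.
#' @param path File path.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
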