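#' @title Reverse-diffusion sampling with image priors
#'
#' @description
#' The generation engine: a reverse-diffusion loop over an evenly-spaced
#' inference subgrid of the training schedule, with classifier-free guidance
#' at every step, optionally initialized from a noised image prior
#' (SDEdit-style). `strength` selects the fraction of the forward-noising
#' trajectory applied to the prior: 0 returns the prior untouched, 1 starts
#' from (near-)pure noise. When no prior is supplied, strength is forced to
#' 1 and sampling starts at the terminal noise level — which makes
#' "eliminating image priors" in the ablation protocol the same code path.
#'
#' VP schedules use the DDIM-family update derived from the
#' epsilon-prediction, deterministic (`eta = 0`) by default with the
#' ancestral DDPM form available at `eta = 1`; VE schedules use the
#' Euler-Maruyama update on the converted score. The final reverse step
#' adds no noise.
#'
#' @name sampler
NULL

#' Sampler configuration
#'
#' @param strength Image-prior strength in `[0,1]`.
#' @param guidance Guidance scale in `[0,9]`.
#' @param steps Inference steps (must not exceed the trained grid size).
#' @param seed Sampling seed.
#' @param schedule_kind `"VP"` or `"VE"`.
#' @param eta Stochasticity of the VP reverse update in `[0, 1]`: 0 is the
#'   deterministic (DDIM-form) posterior-mean path, 1 the ancestral
#'   (DDPM-form) update. Ignored for VE.
#' @return A `diffva_sampler_config`.
#' @export
sampler_config <- function(strength = 0.55, guidance = 4, steps = 50,
                           seed = 0L, schedule_kind = "VP", eta = 0) {
  if (strength < 0 || strength > 1) stop("strength must be in [0,1]")
  if (guidance < 0 || guidance > 9) stop("guidance must be in [0,9]")
  if (steps < 1) stop("steps must be >= 1")
  if (eta < 0 || eta > 1) stop("eta must be in [0,1]")
  structure(list(strength = strength, guidance = guidance,
                 steps = as.integer(steps), seed = as.integer(seed),
                 schedule_kind = schedule_kind, eta = eta),
            class = "diffva_sampler_config")
}

#' Named presets for the two reference operating points
#'
#' `"counterfactual"`: strength 0.55, guidance 4 (the setting found most
#' effective for counterfactual generation across classes);
#' `"qualitative"`: strength 0.85, guidance 7.5, 75 inference steps (the
#' qualitative-evaluation setting).
#'
#' @param name `"counterfactual"` or `"qualitative"`.
#' @param seed Sampling seed.
#' @return A `diffva_sampler_config`.
#' @export
sampler_preset <- function(name = c("counterfactual", "qualitative"), seed = 0L) {
  name <- match.arg(name)
  switch(name,
         counterfactual = sampler_config(0.55, 4, 50, seed),
         qualitative = sampler_config(0.85, 7.5, 75, seed))
}

# Evenly spaced inference grid: steps+1 training-grid indices from 0 to T.
inference_grid <- function(schedule, steps) {
  if (steps > schedule$T)
    stop("steps (", steps, ") exceed the trained grid T=", schedule$T)
  unique(round(seq(0, schedule$T, length.out = steps + 1)))
}

round_half_up <- function(x) floor(x + 0.5)

#' SDEdit initialisation: noise an image-prior latent part-way
#'
#' The starting position on the inference grid is
#' `t0 = round(strength * steps)` (ties round half up); the latent is noised
#' to the corresponding training-grid point with a single forward draw.
#' `strength = 0` returns the latent unchanged at position 0.
#'
#' @param z0 Latent array (diffusion scale).
#' @param strength In `[0,1]`.
#' @param schedule The trained schedule.
#' @param steps Inference steps.
#' @param seed Noise seed.
#' @return List: `z_t0`, `t0_pos` (inference-grid position), `t0_index`
#'   (training-grid index), `grid`.
#' @export
sdedit_init <- function(z0, strength, schedule, steps, seed = 0L) {
  if (strength < 0 || strength > 1) stop("strength must be in [0,1]")
  grid <- inference_grid(schedule, steps)
  t0_pos <- round_half_up(strength * (length(grid) - 1))
  t0_index <- grid[t0_pos + 1]
  if (t0_pos == 0) return(list(z_t0 = z0, t0_pos = 0L, t0_index = 0L, grid = grid))
  z <- with_local_seed(derive_seed(seed, "sampler/sdedit"), function() {
    array(rnorm(length(z0)), dim = dim(as.array(z0)))
  })
  list(z_t0 = forward_noise(z0, t0_index, z, schedule),
       t0_pos = as.integer(t0_pos), t0_index = as.integer(t0_index), grid = grid)
}

#' Run the guided reverse-diffusion loop
#'
#' @param model A trained `diffva_denoiser`.
#' @param schedule The trained schedule (defaults to the model's).
#' @param config A [sampler_config()].
#' @param prompt Prompt string (or `""` for unconditional generation).
#' @param init_latent Optional image-prior latent (diffusion scale). When
#'   absent, strength is forced to 1 and sampling starts from pure terminal
#'   noise.
#' @param n When `init_latent` is absent: number of latents to draw.
#' @return A latent array (or list of arrays if `n > 1`).
#' @export
sample_latents <- function(model, schedule = model$schedule, config, prompt = "",
                           init_latent = NULL, n = 1) {
  stopifnot(inherits(config, "diffva_sampler_config"))
  hw <- model$config$latent_hw; cl <- model$config$c_lat
  batched_out <- is.null(init_latent) && n > 1
  if (is.null(init_latent)) {
    config$strength <- 1
    init <- with_local_seed(derive_seed(config$seed, "sampler/init-noise"), function() {
      lapply(seq_len(n), function(i) {
        z <- array(rnorm(hw * hw * cl), dim = c(hw, hw, cl))
        if (schedule$kind == "VE") z * schedule$sigma[schedule$T + 1] else z
      })
    })
  } else {
    init <- if (is.list(init_latent) && !is.array(init_latent)) init_latent
            else list(init_latent)
    batched_out <- length(init) > 1
  }
  sd0 <- sdedit_init(if (length(init) == 1) init[[1]] else init[[1]],
                     config$strength, schedule, config$steps,
                     seed = derive_seed(config$seed, "sampler/sdedit-seed"))
  grid <- sd0$grid
  t0_pos <- sd0$t0_pos
  if (t0_pos == 0) {
    out <- init
    return(if (batched_out) out else out[[1]])
  }
  # noise each prior independently (deterministic in config$seed)
  xs <- vector("list", length(init))
  for (i in seq_along(init)) {
    s <- sdedit_init(init[[i]], config$strength, schedule, config$steps,
                     seed = derive_seed(config$seed, paste0("sampler/sdedit/", i)))
    xs[[i]] <- s$z_t0
  }
  C_cond <- cond_matrix(model, prompt)
  C_null <- cond_matrix(model, NULL)
  null_prompt <- isTRUE(attr(tokenize_prompt(prompt, model$vocab,
                                             model$config$max_tokens), "is_null"))
  set.seed(derive_seed(config$seed, "sampler/loop"))
  B <- length(xs)
  for (k in seq(t0_pos, 1)) {
    i_hi <- grid[k + 1]; i_lo <- grid[k]
    eps_hat <- guided_eps(model, xs, i_hi, C_cond, C_null, config$guidance,
                          null_prompt, schedule)
    a_hi <- schedule$alpha[i_hi + 1]; s_hi <- schedule$sigma[i_hi + 1]
    a_lo <- schedule$alpha[i_lo + 1]; s_lo <- schedule$sigma[i_lo + 1]
    for (i in seq_len(B)) {
      e <- eps_hat[[i]]
      if (!all(is.finite(e)))
        stop("sample_latents: non-finite prediction at grid index ", i_hi)
      if (schedule$kind == "VP") {
        x0 <- (xs[[i]] - s_hi * e) / a_hi
        x0 <- pmin(pmax(x0, -4), 4)
        if (i_lo == 0) {
          xs[[i]] <- x0
        } else {
          eta <- if (is.null(config$eta)) 0 else config$eta
          sig <- eta * (s_lo / s_hi) * sqrt(pmax(1 - (a_hi / a_lo)^2, 0))
          dir <- sqrt(pmax(s_lo^2 - sig^2, 0)) * e
          z <- array(rnorm(length(e)), dim = dim(as.array(e)))
          xs[[i]] <- a_lo * x0 + dir + sig * z
        }
      } else {
        sc <- score_from_eps(e, i_hi, schedule)
        z <- if (i_lo == 0) 0 else array(rnorm(length(e)), dim = dim(as.array(e)))
        xs[[i]] <- em_step(xs[[i]], sc, i_lo, i_hi, schedule, z,
                           allow_skip = TRUE)
      }
    }
  }
  if (batched_out) xs else xs[[1]]
}

# Conditional + unconditional predictions in one batched forward, combined
# with classifier-free guidance. With a NULL prompt the two branches are the
# same forward pass, so guidance has no effect by construction.
guided_eps <- function(model, xs, t_index, C_cond, C_null, g, null_prompt,
                       schedule) {
  B <- length(xs)
  if (null_prompt || g == 1) {
    C <- if (null_prompt) C_null else C_cond
    return(den_fwd(model, xs, rep(t_index, B), rep(list(C), B))$eps)
  }
  both <- den_fwd(model, c(xs, xs), rep(t_index, 2 * B),
                  c(rep(list(C_cond), B), rep(list(C_null), B)))$eps
  lapply(seq_len(B), function(i)
    apply_guidance(both[[i]], both[[B + i]], g))
}
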