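#' @title Noise schedules and the forward/reverse diffusion primitives
#'
#' @description
#' Discretized noise schedules over a grid of `T + 1` points (index 0 is the
#' clean endpoint: `alpha(0) = 1`, `sigma(0) = 0`), the forward noising
#' `x_t = alpha(t) x_0 + sigma(t) z`, the epsilon-prediction training loss,
#' the epsilon-to-score conversion `s = -eps / sigma(t)`, and the
#' Euler-Maruyama reverse update for variance-exploding schedules.
#'
#' Two schedule laws are supported: variance preserving (VP,
#' `alpha^2 + sigma^2 = 1` at every grid point; cosine or linear-beta
#' discretizations) and variance exploding (VE, `alpha = 1`, geometric sigma
#' rising to a large terminal constant).
#'
#' @name diffusion_core
NULL

#' Build a discretized noise schedule
#'
#' @param kind `"VP"` or `"VE"`.
#' @param T_steps Number of diffusion steps (grid has `T_steps + 1` points).
#' @param law For VP: `"cosine"` (default) or `"linear"` (linear-beta).
#' @param sigma_min,sigma_max For VE: the geometric sigma range;
#'   `sigma(T) = sigma_max`.
#' @return A `diffva_schedule` list with `kind`, `T`, `alpha`, `sigma`
#'   (vectors of length `T_steps + 1`, index 1 = grid point 0).
#' @export
build_schedule <- function(kind = c("VP", "VE"), T_steps = 1000,
                           law = c("cosine", "linear"),
                           sigma_min = 0.02, sigma_max = 10) {
  kind <- match.arg(kind)
  law <- match.arg(law)
  if (T_steps < 2) stop("T_steps must be >= 2")
  t <- seq(0, 1, length.out = T_steps + 1)
  if (kind == "VP") {
    if (law == "cosine") {
      s <- 0.008
      ab <- cos((t + s) / (1 + s) * pi / 2)^2 / cos(s / (1 + s) * pi / 2)^2
      ab <- pmin(pmax(ab, 1e-6), 1)
    } else {
      beta <- seq(1e-4, 0.02, length.out = T_steps) * (1000 / T_steps)
      ab <- c(1, cumprod(1 - pmin(beta, 0.999)))
    }
    ab[1] <- 1
    # enforce strict monotonicity after clipping (multiplicative, keeps ab > 0)
    ab <- cummin(ab) * (1 - 1e-9)^(seq_along(ab) - 1)
    ab[1] <- 1
    alpha <- sqrt(ab)
    sigma <- sqrt(1 - ab)
  } else {
    alpha <- rep(1, T_steps + 1)
    sigma <- c(0, sigma_min * (sigma_max / sigma_min)^((seq_len(T_steps) - 1) / (T_steps - 1)))
  }
  structure(list(kind = kind, T = as.integer(T_steps),
                 alpha = alpha, sigma = sigma, law = law),
            class = "diffva_schedule")
}

sched_at <- function(schedule, t_index) {
  if (any(t_index < 0) || any(t_index > schedule$T))
    stop("t_index out of [0, ", schedule$T, "]")
  list(alpha = schedule$alpha[t_index + 1], sigma = schedule$sigma[t_index + 1])
}

#' Forward diffusion: noise a clean sample to grid point `t_index`
#'
#' `x_t = alpha(t) * x0 + sigma(t) * z`, exactly.
#'
#' @param x0 Clean array (any shape).
#' @param t_index Integer grid index in `[0, T]`.
#' @param z Standard-normal draw of the same shape as `x0`.
#' @param schedule A `diffva_schedule`.
#' @return Array of the shape of `x0`.
#' @export
forward_noise <- function(x0, t_index, z, schedule) {
  if (!all(dim(as.array(x0)) == dim(as.array(z))) || length(x0) != length(z))
    stop("forward_noise: x0 and z shapes differ")
  s <- sched_at(schedule, t_index)
  s$alpha * x0 + s$sigma * z
}

#' Convert an epsilon-prediction to a score
#'
#' The denoiser predicts the injected noise `eps`; the score of the noised
#' marginal is `s(x_t) = -eps / sigma(t)` (undefined at the clean endpoint).
#'
#' @param eps Epsilon array.
#' @param t_index Grid index with `sigma(t) > 0`.
#' @param schedule A `diffva_schedule`.
#' @return Score array of the same shape.
#' @export
score_from_eps <- function(eps, t_index, schedule) {
  s <- sched_at(schedule, t_index)
  if (s$sigma <= 0)
    stop("score_from_eps: sigma(t)=0 at t_index ", t_index, "; score undefined")
  -eps / s$sigma
}

#' One reverse Euler-Maruyama step (variance-exploding form)
#'
#' Integrates the reverse SDE from grid point `t_next_index` down to
#' `t_index` using the positive variance increment
#' `dvar = sigma^2(t_next) - sigma^2(t)` as the drift coefficient on the
#' score and `sqrt(dvar)` as the diffusion magnitude:
#' `x_t = x_next + dvar * score + sqrt(dvar) * z`.
#'
#' @param x_next State at the higher-noise grid point.
#' @param score Score evaluated at `x_next` (at its noise level).
#' @param t_index,t_next_index Grid indices with `t_index < t_next_index`;
#'   non-adjacent indices are allowed only with `allow_skip = TRUE`.
#' @param schedule A VE `diffva_schedule`.
#' @param z Standard-normal draw (use 0 for a deterministic final step).
#' @param allow_skip Permit `t_next_index - t_index > 1`.
#' @return The state at `t_index`.
#' @export
em_step <- function(x_next, score, t_index, t_next_index, schedule, z,
                    allow_skip = FALSE) {
  if (schedule$kind != "VE") stop("em_step is defined for VE schedules")
  if (t_index >= t_next_index) stop("em_step: t_index must be < t_next_index")
  if (!allow_skip && (t_next_index - t_index) != 1L)
    stop("em_step: non-adjacent indices need allow_skip = TRUE")
  s0 <- sched_at(schedule, t_index)
  s1 <- sched_at(schedule, t_next_index)
  dvar <- s1$sigma^2 - s0$sigma^2
  x_next + dvar * score + sqrt(dvar) * z
}

#' Epsilon-prediction denoising loss on a batch
#'
#' Draws `t` uniformly from `1..T` and `eps ~ N(0, I)` per example, and
#' returns the mean squared error between the drawn noise and the model's
#' prediction at the noised latent — the reweighted-ELBO objective of
#' (latent) diffusion training, in its class-conditional form when condition
#' embeddings are supplied.
#'
#' @param model A denoiser (see [init_denoiser()]), or any object with a
#'   `predict_eps(x_t, t_index, cond)` element (test doubles welcome).
#' @param x0_batch List of clean latent arrays.
#' @param cond_batch List of condition embeddings (or `NULL` entries for the
#'   null condition), parallel to `x0_batch`.
#' @param schedule A `diffva_schedule`.
#' @param seed Seed for the t- and eps-draws.
#' @return Scalar mean squared error.
#' @export
denoising_loss <- function(model, x0_batch, cond_batch = NULL, schedule, seed = 0L) {
  n <- length(x0_batch)
  if (is.null(cond_batch)) cond_batch <- vector("list", n)
  stopifnot(length(cond_batch) == n)
  with_local_seed(derive_seed(seed, "denoising-loss"), function() {
    total <- 0
    for (i in seq_len(n)) {
      x0 <- x0_batch[[i]]
      t_i <- sample.int(schedule$T, 1)
      eps <- array(rnorm(length(x0)), dim = dim(as.array(x0)))
      x_t <- forward_noise(x0, t_i, eps, schedule)
      eps_hat <- predict_eps(model, x_t, t_i, cond_batch[[i]], schedule)
      if (length(eps_hat) != length(x0))
        stop("denoising_loss: model output shape differs from latent shape")
      total <- total + mean((eps - eps_hat)^2)
    }
    total / n
  })
}
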