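#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' Every stochastic stage of the pipeline (data generation, noise draws,
#' training batches, sampler noise, ...) draws its seed from a single master
#' seed through a named stream, so that one run seed fans out deterministically
#' and independently-named stages do not share RNG state.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name, e.g. `"sampler"` or `"vae/init"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid R integers
  h <- abs(as.numeric(seed)) %% m
  for (ch in utf8ToInt(stream)) {
    h <- (h * 69069 + ch) %% m
  }
  as.integer(h)
}

# Evaluate fn() under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_local_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
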