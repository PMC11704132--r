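#' @title Counterfactual generation and visual attribution maps
#'
#' @description
#' The core use of the pipeline: given a diseased image and a target prompt
#' naming the normal class, encode the image, noise the latent part-way
#' (SDEdit initialisation), run the guided reverse loop, decode, and take
#' the signed difference `original - counterfactual` as the visual
#' attribution (VA) map. The same pipeline with a disease prompt applied to
#' a healthy image performs disease induction; its map is read in the
#' `counterfactual - original` direction (generated material is positive
#' under the additive-opacity convention). Both signs are stored.
#'
#' @name attribution
NULL

#' Signed visual attribution map
#'
#' `signed = original - counterfactual`, exact elementwise arithmetic
#' (pre-quantization), so `counterfactual + signed == original` always
#' holds. With a mask, the magnitude is zeroed outside it (the "masked
#' subtraction" convention; phantoms supply exact lung-region masks).
#'
#' @param original,counterfactual Equal-shape image matrices.
#' @param mask Optional binary matrix.
#' @return A `diffva_vamap`: `signed`, `magnitude`, `mask`.
#' @export
va_map <- function(original, counterfactual, mask = NULL) {
  if (!all(dim(original) == dim(counterfactual)))
    stop("va_map: shape mismatch")
  signed <- original - counterfactual
  magnitude <- abs(signed)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(original))) stop("va_map: mask shape mismatch")
    if (!all(mask %in% c(0, 1))) stop("va_map: mask must be binary")
    magnitude <- magnitude * mask
  }
  structure(list(signed = signed, magnitude = magnitude, mask = mask),
            class = "diffva_vamap")
}

#' Generate a counterfactual and its attribution map
#'
#' Pipeline: `encode -> sdedit_init -> guided reverse sampling -> decode ->
#' va_map`. Deterministic given `config$seed`. The exact decomposition
#' `original == counterfactual + signed` is asserted on every run.
#'
#' @param image Input image matrix in `[0,1]`.
#' @param target_prompt Prompt the generation is guided toward (e.g.
#'   `"normal chest scan"`).
#' @param config A [sampler_config()].
#' @param models List with elements `vae` and `denoiser`.
#' @param mask Optional binary region mask for the map (e.g.
#'   [lung_region_mask()]).
#' @return A `diffva_counterfactual`: `original`, `counterfactual`,
#'   `prompt`, `config`, `va_map`.
#' @export
generate_counterfactual <- function(image, target_prompt, config, models,
                                    mask = NULL) {
  vae <- models$vae
  den <- models$denoiser
  stopifnot(inherits(vae, "diffva_vae"), inherits(den, "diffva_denoiser"))
  z0 <- tryCatch(latent_normalize(vae, encode(vae, image)$z),
                 error = function(e) stop("encode stage: ", conditionMessage(e)))
  zs <- tryCatch(
    sample_latents(den, den$schedule, config, target_prompt, init_latent = z0),
    error = function(e) stop("sampling stage: ", conditionMessage(e)))
  cf <- tryCatch(decode(vae, latent_denormalize(vae, zs)),
                 error = function(e) stop("decode stage: ", conditionMessage(e)))
  vm <- va_map(image, cf, mask)
  stopifnot(isTRUE(all.equal(cf + vm$signed, image, tolerance = 1e-12)))
  structure(list(original = image, counterfactual = cf,
                 prompt = target_prompt, config = config, va_map = vm),
            class = "diffva_counterfactual")
}

#' Induce a disease appearance in a healthy image
#'
#' Same pipeline as [generate_counterfactual()] with a disease prompt; the
#' result additionally carries `induced = counterfactual - original`, the
#' display direction for generated material.
#'
#' @inheritParams generate_counterfactual
#' @param disease_prompt Disease-naming prompt, e.g.
#'   `"large lung opacity on the left"`.
#' @return A `diffva_counterfactual` with an `induced` field.
#' @export
induce_disease <- function(image, disease_prompt, config, models, mask = NULL) {
  res <- generate_counterfactual(image, disease_prompt, config, models, mask)
  res$induced <- res$counterfactual - res$original
  res
}

#' Fraction of attribution mass inside a lesion mask
#'
#' `sum(|map| inside mask) / sum(|map|)`; 1 means perfectly localized
#' attribution. An all-zero map scores 0 with a warning.
#'
#' @param map A `diffva_vamap`.
#' @param lesion_mask Nonempty binary matrix.
#' @return Scalar in `[0,1]`.
#' @export
localization_score <- function(map, lesion_mask) {
  stopifnot(inherits(map, "diffva_vamap"))
  if (!all(dim(lesion_mask) == dim(map$magnitude)))
    stop("localization_score: shape mismatch")
  if (sum(lesion_mask) == 0) stop("localization_score: empty lesion mask")
  total <- sum(map$magnitude)
  if (total == 0) {
    warning("localization_score: all-zero map, returning 0")
    return(0)
  }
  sum(map$magnitude * lesion_mask) / total
}

# Center of mass (row, col) of a nonnegative weight matrix.
magnitude_centroid <- function(w) {
  tot <- sum(w)
  if (tot == 0) return(c(NA_real_, NA_real_))
  c(sum(row(w) * w), sum(col(w) * w)) / tot
}
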