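#' @title Text conditioning over a closed vocabulary
#'
#' @description
#' Prompts are short phrases over a closed vocabulary (the phantom class
#' labels plus positional tokens). A trainable embedding table and a small
#' self-attention sequence mixer — trained jointly with the denoiser — stand
#' in for a pretrained domain-adapted language encoder. The empty prompt maps
#' to a dedicated learned NULL sequence, which is also the unconditional
#' branch used by classifier-free guidance.
#'
#' @name conditioning
NULL

#' The package's closed prompt vocabulary
#'
#' Covers every word of every phantom prompt, intensity/position modifiers,
#' and the reserved `NULL` and `PAD` tokens.
#' @return A `diffva_vocab` list: `tokens` (ordered) and `index`
#'   (token -> 1-based position, bijective).
#' @export
default_vocabulary <- function() {
  tokens <- c("<null>", "<pad>",
              "normal", "chest", "scan", "lung", "opacity", "diffuse", "haze",
              "enlarged", "heart", "large", "on", "the", "left", "right",
              "both", "sides")
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "diffva_vocab")
}

#' Tokenize a prompt to fixed-length id sequence
#'
#' Lowercases and splits on whitespace; every word must be in the vocabulary
#' (closed-vocabulary contract). The empty string produces the NULL sequence.
#'
#' @param text Prompt string.
#' @param vocab A `diffva_vocab`.
#' @param max_tokens Padded sequence length.
#' @return Integer vector of token ids, length `max_tokens`, with attribute
#'   `is_null`.
#' @export
tokenize_prompt <- function(text, vocab, max_tokens = 8) {
  stopifnot(inherits(vocab, "diffva_vocab"))
  text <- trimws(tolower(text))
  if (nchar(text) == 0) {
    ids <- c(vocab$index[["<null>"]], rep(vocab$index[["<pad>"]], max_tokens - 1))
    return(structure(as.integer(ids), is_null = TRUE))
  }
  words <- strsplit(text, "\\s+")[[1]]
  if (length(words) > max_tokens)
    stop("prompt longer than ", max_tokens, " tokens")
  bad <- setdiff(words, vocab$tokens)
  if (length(bad))
    stop("out-of-vocabulary word: '", bad[1], "'")
  ids <- c(vocab$index[words], rep(vocab$index[["<pad>"]], max_tokens - length(words)))
  structure(as.integer(ids), is_null = FALSE)
}

#' Embed a prompt with a trained model's text encoder
#'
#' @param text Prompt string (empty string gives the NULL embedding).
#' @param vocab A `diffva_vocab` (defaults to the model's).
#' @param model A `diffva_denoiser` (holds the jointly trained text-encoder
#'   parameters).
#' @return A `diffva_prompt_embedding`: `seq` (max_tokens x d context
#'   matrix), `tokens`, `is_null`.
#' @export
embed_prompt <- function(text, vocab = model$vocab, model) {
  ids <- tokenize_prompt(text, vocab, model$config$max_tokens)
  C <- txt_fwd(model, ids)$C
  structure(list(seq = C, tokens = ids, is_null = isTRUE(attr(ids, "is_null"))),
            class = "diffva_prompt_embedding")
}

#' Classifier-free guidance combination
#'
#' `eps_guided = eps_uncond + g * (eps_cond - eps_uncond)`: exact at the
#' endpoints (`g = 0` is fully unconditional, `g = 1` is the conditional
#' prediction) and linear in `g`. The admissible range `[0, 9]` follows the
#' guidance-scale semantics of the sampler.
#'
#' @param eps_cond,eps_uncond Conditional and unconditional predictions of
#'   equal shape.
#' @param g Guidance scale in `[0, 9]`.
#' @return The guided prediction.
#' @export
apply_guidance <- function(eps_cond, eps_uncond, g) {
  if (length(eps_cond) != length(eps_uncond))
    stop("apply_guidance: shape mismatch")
  if (g < 0 || g > 9) stop("guidance scale g must be in [0, 9]")
  eps_uncond + g * (eps_cond - eps_uncond)
}
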