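#' @title End-to-end pipeline configuration and execution
#'
#' @description
#' A single validated configuration drives the whole experiment: phantom
#' generation, autoencoder training, diffusion training, counterfactual
#' attribution, and the ablation study. One master seed fans out to named
#' substreams per stage, every output file is checksummed into a manifest
#' together with a hash of the configuration, and re-running a config
#' reproduces identical manifests for the deterministic stages.
#'
#' @name cli_config
NULL

.config_keys <- list(
  top = c("master_seed", "out_root", "phantoms", "vae", "diffusion",
          "attribute", "ablation"),
  phantoms = c("counts", "image_size"),
  vae = c("f", "c", "hidden", "steps", "lr", "batch", "reg_weight",
          "regularizer", "adversarial", "adv_weight"),
  diffusion = c("T_steps", "law", "steps", "lr", "lr_min", "batch",
                "cond_dropout", "d", "n_blocks", "n_text_blocks", "max_tokens"),
  attribute = c("n", "prompt", "preset"),
  ablation = c("n", "modes", "steps", "extractor_d")
)

#' Validate a pipeline configuration
#'
#' Stages run iff their section is present; unknown keys anywhere are
#' rejected by name.
#'
#' @param config Nested list (or path to a JSON/YAML-free plain list read by
#'   the caller).
#' @return The validated config, classed `diffva_run_config`.
#' @export
run_config <- function(config) {
  if (inherits(config, "diffva_run_config")) return(config)
  stopifnot(is.list(config))
  bad <- setdiff(names(config), .config_keys$top)
  if (length(bad)) stop("run_config: unknown key '", bad[1], "'")
  if (is.null(config$master_seed)) stop("run_config: master_seed is required")
  if (is.null(config$out_root)) stop("run_config: out_root is required")
  for (sec in intersect(names(config), names(.config_keys)[-1])) {
    bad <- setdiff(names(config[[sec]]), .config_keys[[sec]])
    if (length(bad)) stop("run_config: unknown key '", sec, ".", bad[1], "'")
  }
  structure(config, class = "diffva_run_config")
}

#' Execute the configured pipeline stages
#'
#' @param config A [run_config()] (or plain list).
#' @return Invisibly, the manifest list (also written to
#'   `out_root/manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  out <- config$out_root
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$master_seed
  artifacts <- character(0)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  ds <- NULL; vae <- NULL; den <- NULL
  if (!is.null(config$phantoms)) {
    ds <- stage("phantoms", function() {
      d <- make_dataset(config$phantoms$counts,
                        image_size = config$phantoms$image_size %||% 32,
                        seed = derive_seed(seed, "pipeline/phantoms"))
      write_dataset(d, file.path(out, "phantoms"))
      d
    })
    artifacts <- c(artifacts, list.files(file.path(out, "phantoms"),
                                         full.names = TRUE))
  }
  if (!is.null(config$vae)) {
    vae <- stage("train-vae", function() {
      if (is.null(ds)) ds <<- read_dataset(file.path(out, "phantoms"))
      v <- train_autoencoder(ds, do.call(vae_config, config$vae),
                             seed = derive_seed(seed, "pipeline/vae"))
      save_checkpoint(v, file.path(out, "vae.rds"))
      v
    })
    artifacts <- c(artifacts, file.path(out, "vae.rds"))
  }
  if (!is.null(config$diffusion)) {
    den <- stage("train-diffusion", function() {
      if (is.null(ds)) ds <<- read_dataset(file.path(out, "phantoms"))
      if (is.null(vae)) vae <<- load_checkpoint(file.path(out, "vae.rds"))
      m <- train_diffusion(ds, vae, do.call(diffusion_config, config$diffusion),
                           seed = derive_seed(seed, "pipeline/diffusion"))
      save_checkpoint(m, file.path(out, "diffusion.rds"))
      m
    })
    artifacts <- c(artifacts, file.path(out, "diffusion.rds"))
  }
  if (!is.null(config$attribute)) {
    stage("attribute", function() {
      if (is.null(ds)) ds <<- read_dataset(file.path(out, "phantoms"))
      if (is.null(vae)) vae <<- load_checkpoint(file.path(out, "vae.rds"))
      if (is.null(den)) den <<- load_checkpoint(file.path(out, "diffusion.rds"))
      adir <- file.path(out, "attribution")
      dir.create(adir, showWarnings = FALSE)
      diseased <- Filter(function(s) s$spec$class_label != "normal", ds$samples)
      n <- min(config$attribute$n %||% 4, length(diseased))
      cfg <- sampler_preset(config$attribute$preset %||% "counterfactual",
                            seed = derive_seed(seed, "pipeline/attribute"))
      for (i in seq_len(n)) {
        s <- diseased[[i]]
        res <- generate_counterfactual(
          s$image, config$attribute$prompt %||% "normal chest scan", cfg,
          list(vae = vae, denoiser = den), mask = lung_region_mask(s$spec))
        png::writePNG(quantize8(res$counterfactual),
                      file.path(adir, sprintf("cf_%03d.png", i)))
        png::writePNG(quantize8(res$va_map$magnitude / max(res$va_map$magnitude, 1e-9)),
                      file.path(adir, sprintf("map_%03d.png", i)))
        prov <- list(prompt = res$prompt, config = unclass(res$config),
                     seed = cfg$seed)
        jsonlite::write_json(prov, file.path(adir, sprintf("cf_%03d.json", i)),
                             auto_unbox = TRUE)
      }
      invisible(NULL)
    })
    artifacts <- c(artifacts, list.files(file.path(out, "attribution"),
                                         full.names = TRUE))
  }
  if (!is.null(config$ablation)) {
    stage("ablate", function() {
      if (is.null(ds)) ds <<- read_dataset(file.path(out, "phantoms"))
      if (is.null(vae)) vae <<- load_checkpoint(file.path(out, "vae.rds"))
      if (is.null(den)) den <<- load_checkpoint(file.path(out, "diffusion.rds"))
      healthy <- lapply(Filter(function(s) s$spec$class_label == "normal",
                               ds$samples), function(s) s$image)
      ex <- extractor_flatten_pca(healthy, config$ablation$extractor_d %||% 32)
      rep_df <- run_ablation_study(
        list(vae = vae, denoiser = den), healthy, healthy,
        modes = config$ablation$modes %||%
          c("full", "no_text", "no_image_prior", "neither"),
        n = config$ablation$n %||% 64,
        seed = derive_seed(seed, "pipeline/ablation"),
        extractor = ex, steps = config$ablation$steps %||% 40)
      jsonlite::write_json(rep_df, file.path(out, "ablation.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      invisible(NULL)
    })
    artifacts <- c(artifacts, file.path(out, "ablation.json"))
  }
  cfg_hash <- digest_config(config)
  manifest <- list(
    config_hash = cfg_hash,
    master_seed = seed,
    files = lapply(sort(unique(artifacts)), function(f)
      list(path = sub(paste0("^", out, "/?"), "", f),
           md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
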