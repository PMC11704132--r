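#' Write a phantom dataset to disk
#'
#' Images and masks are written as 8-bit grayscale PNG (the single
#' quantization step: `[0,1]` is mapped linearly to `[0,255]`); all spec
#' fields, prompts and filenames go into a plain-text tab-separated manifest
#' so the dataset round-trips losslessly after that one quantization.
#'
#' @param ds A `diffva_dataset`.
#' @param path Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "diffva_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$samples)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- ds$samples[[i]]
    img_file <- sprintf("sample_%04d.png", i)
    mask_file <- sprintf("sample_%04d_mask.png", i)
    png::writePNG(quantize8(s$image), file.path(path, img_file))
    png::writePNG(s$lesion_mask, file.path(path, mask_file))
    sp <- s$spec
    rows[[i]] <- data.frame(
      image = img_file, mask = mask_file, prompt = s$prompt,
      class_label = sp$class_label, side = sp$side,
      image_size = sp$image_size,
      lesion_intensity = sp$lesion_intensity,
      lesion_radius_frac = sp$lesion_radius_frac,
      anatomy_seed = sp$anatomy_seed, noise_seed = sp$noise_seed,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  mf <- file.path(path, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mf)
}

quantize8 <- function(img) round(clip01(img) * 255) / 255

#' Read a phantom dataset written by [write_dataset()]
#'
#' @param path Dataset directory containing `manifest.tsv`.
#' @return A `diffva_dataset`.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.tsv")
  if (!file.exists(mf))
    stop("read_dataset: missing manifest 'manifest.tsv' in ", path)
  manifest <- tryCatch(
    utils::read.table(mf, sep = "\t", header = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop("read_dataset: corrupt manifest: ", conditionMessage(e))
  )
  need <- c("image", "mask", "prompt", "class_label", "side", "image_size",
            "lesion_intensity", "lesion_radius_frac", "anatomy_seed", "noise_seed")
  if (!all(need %in% names(manifest)))
    stop("read_dataset: manifest missing columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  pngs <- list.files(path, pattern = "^sample_.*\\.png$")
  if (length(pngs) != 2L * nrow(manifest))
    stop("read_dataset: manifest lists ", nrow(manifest), " samples but ",
         length(pngs), " sample PNG files are on disk")
  samples <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    img <- png::readPNG(file.path(path, r$image))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    mask <- png::readPNG(file.path(path, r$mask))
    if (length(dim(mask)) == 3L) mask <- mask[, , 1]
    spec <- phantom_spec(r$class_label, r$side, r$image_size,
                         r$lesion_intensity, r$lesion_radius_frac,
                         r$anatomy_seed, r$noise_seed)
    samples[[i]] <- structure(
      list(image = img, lesion_mask = (mask > 0.5) * 1,
           prompt = r$prompt, spec = spec),
      class = "diffva_sample")
  }
  counts <- table(manifest$class_label)
  structure(list(samples = samples,
                 class_counts = as.list(as.integer(counts)) |>
                   stats::setNames(names(counts)),
                 vocabulary = default_vocabulary()),
            class = "diffva_dataset")
}
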