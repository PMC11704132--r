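#' @title Synthetic chest-scan phantoms with paired ground truth
#'
#' @description
#' The phantom generator produces grayscale chest-scan-like images in which a
#' healthy and a diseased render of the *same subject* differ only in planted
#' lesions. This embodies the paired-difference assumption underlying
#' counterfactual visual attribution: every pixel outside the lesion support is
#' bitwise identical between the pair, so attribution maps have an exact ground
#' truth. Anatomy is two bright elliptical lung fields on a darker torso disc
#' with a central cardiac ellipse, mild per-subject affine jitter, and additive
#' Gaussian acquisition noise shared within a pair.
#'
#' Disease classes:
#' \describe{
#'   \item{focal_opacity}{a focal Gaussian blob inside one (or both) lung
#'     fields — the "lung opacity" analogue.}
#'   \item{diffuse_haze}{a low-amplitude haze over the whole lung field — the
#'     "pneumonia" analogue.}
#'   \item{enlarged_center}{the central cardiac ellipse enlarged — the
#'     "cardiomegaly" analogue (no side).}
#' }
#' "Left"/"right" are image coordinates (viewer's left), not the radiological
#' patient-side convention.
#'
#' @name phantoms
NULL

PHANTOM_CLASSES <- c("normal", "focal_opacity", "diffuse_haze", "enlarged_center")
PHANTOM_SIDES <- c("left", "right", "both", "none")

#' Construct and validate a phantom specification
#'
#' @param class_label One of `"normal"`, `"focal_opacity"`, `"diffuse_haze"`,
#'   `"enlarged_center"`.
#' @param side Lesion side: `"left"`, `"right"`, `"both"`, or `"none"`.
#'   Must be `"none"` iff the class has no sided lesion (normal,
#'   enlarged_center).
#' @param image_size Square image side in pixels (>= 16).
#' @param lesion_intensity Additive lesion amplitude in `[0, 1]`.
#' @param lesion_radius_frac Focal lesion radius as a fraction of lung width,
#'   in `(0, 0.6]`.
#' @param anatomy_seed Integer fixing the subject anatomy.
#' @param noise_seed Integer fixing the acquisition noise.
#' @return A `diffva_phantom_spec` list.
#' @export
phantom_spec <- function(class_label, side = "none", image_size = 32,
                         lesion_intensity = 0.6, lesion_radius_frac = 0.25,
                         anatomy_seed = 0L, noise_seed = 0L) {
  if (!is.character(class_label) || !(class_label %in% PHANTOM_CLASSES))
    stop("class_label must be one of: ", paste(PHANTOM_CLASSES, collapse = ", "))
  if (!(side %in% PHANTOM_SIDES))
    stop("side must be one of: ", paste(PHANTOM_SIDES, collapse = ", "))
  sided <- class_label %in% c("focal_opacity", "diffuse_haze")
  if (sided && side == "none")
    stop("side: class_label '", class_label, "' requires side left/right/both")
  if (!sided && side != "none")
    stop("side: class_label '", class_label, "' requires side = 'none'")
  if (!is.numeric(image_size) || image_size < 16)
    stop("image_size must be >= 16")
  if (lesion_intensity < 0 || lesion_intensity > 1)
    stop("lesion_intensity must be in [0, 1]")
  if (lesion_radius_frac <= 0 || lesion_radius_frac > 0.6)
    stop("lesion_radius_frac must be in (0, 0.6]")
  structure(list(
    class_label = class_label, side = side,
    image_size = as.integer(image_size),
    lesion_intensity = lesion_intensity,
    lesion_radius_frac = lesion_radius_frac,
    anatomy_seed = as.integer(anatomy_seed),
    noise_seed = as.integer(noise_seed)
  ), class = "diffva_phantom_spec")
}

# Soft-edged ellipse field in [0,1]; x enters only through (x - cx)^2 so
# mirrored anatomies render as exact mirror images.
soft_ellipse <- function(xg, yg, cx, cy, ax, ay, sharp = 25) {
  r <- sqrt(((xg - cx) / ax)^2 + ((yg - cy) / ay)^2)
  1 / (1 + exp(-sharp * (1 - r)))
}

# Per-subject anatomy parameters (deterministic in anatomy_seed). Horizontal
# jitter is a symmetric lung spread, never a global x-shift, so that
# left/right lesions of the same subject are exact mirrors.
phantom_anatomy <- function(spec) {
  with_local_seed(derive_seed(spec$anatomy_seed, "phantom/anatomy"), function() {
    cl <- function(x, s) pmin(pmax(x, -2.2 * s), 2.2 * s)
    list(
      dy = cl(rnorm(1, 0, 0.015), 0.015),
      spread = cl(rnorm(1, 0, 0.015), 0.015),
      scale = 1 + cl(rnorm(1, 0, 0.025), 0.025),
      lung_scale = 1 + cl(rnorm(1, 0, 0.025), 0.025),
      heart_scale = 1 + cl(rnorm(1, 0, 0.025), 0.025),
      lesion_u = pmin(pmax(rnorm(2, 0, 0.15), -0.3), 0.3)
    )
  })
}

# Geometry of one lung: center (cx, cy) and semi-axes (ax, ay).
lung_geometry <- function(an, side) {
  lx <- (0.170 + an$spread) * an$scale
  cx <- if (side == "left") 0.5 - lx else 0.5 + lx
  list(cx = cx, cy = 0.45 + an$dy,
       ax = 0.115 * an$lung_scale * an$scale,
       ay = 0.205 * an$lung_scale * an$scale)
}

# Render the noiseless base anatomy; heart_factor > 1 enlarges the cardiac
# ellipse (the enlarged_center disease).
render_base <- function(spec, an, heart_factor = 1) {
  n <- spec$image_size
  xs <- (seq_len(n) - 0.5) / n
  xg <- matrix(xs, n, n, byrow = TRUE)  # column coordinate
  yg <- matrix(xs, n, n)                # row coordinate (y down)
  img <- matrix(0.06, n, n)
  img <- img + 0.18 * soft_ellipse(xg, yg, 0.5, 0.55 + an$dy,
                                   0.68 * an$scale, 0.52 * an$scale, 22)
  for (s in c("left", "right")) {
    g <- lung_geometry(an, s)
    img <- img + 0.30 * soft_ellipse(xg, yg, g$cx, g$cy, g$ax, g$ay)
  }
  img <- img + 0.18 * soft_ellipse(xg, yg, 0.5, 0.65 + an$dy,
                                   0.10 * an$heart_scale * an$scale * heart_factor,
                                   0.13 * an$heart_scale * an$scale * heart_factor)
  img
}

# Additive lesion field (zero for normal / zero intensity).
render_lesion <- function(spec, an) {
  n <- spec$image_size
  les <- matrix(0, n, n)
  if (spec$lesion_intensity == 0 || spec$class_label %in% c("normal", "enlarged_center"))
    return(les)
  xs <- (seq_len(n) - 0.5) / n
  xg <- matrix(xs, n, n, byrow = TRUE)
  yg <- matrix(xs, n, n)
  sides <- if (spec$side == "both") c("left", "right") else spec$side
  for (s in sides) {
    g <- lung_geometry(an, s)
    lung_field <- soft_ellipse(xg, yg, g$cx, g$cy, g$ax, g$ay)
    if (spec$class_label == "focal_opacity") {
      # mirrored lesion offset: x-offset flips with the side
      ox <- an$lesion_u[1] * g$ax * (if (s == "left") 1 else -1)
      oy <- an$lesion_u[2] * g$ay * 0.5
      R <- spec$lesion_radius_frac * (2 * g$ax) # fraction of lung width
      r2 <- (xg - (g$cx + ox))^2 + (yg - (g$cy + oy))^2
      blob <- spec$lesion_intensity * exp(-r2 / (2 * (R / 2)^2))
      f <- blob * lung_field
      f[f < 0.05 * spec$lesion_intensity] <- 0 # drop the faint skirt
    } else { # diffuse_haze
      f <- 0.55 * spec$lesion_intensity * lung_field
      f[f < 5e-3] <- 0
    }
    les <- les + f
  }
  les
}

#' Render a paired healthy/diseased phantom
#'
#' Both renders share the anatomy- and noise-seed-determined background
#' exactly; the diseased image differs from the healthy one only inside the
#' returned lesion mask (additive opacity, clipped to `[0, 1]`).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `healthy` and `diseased`, each a
#'   `diffva_sample` (fields `image`, `lesion_mask`, `prompt`, `spec`).
#' @export
make_paired_phantom <- function(spec) {
  stopifnot(inherits(spec, "diffva_phantom_spec"))
  an <- phantom_anatomy(spec)
  base_h <- clip01(render_base(spec, an))
  hf <- if (spec$class_label == "enlarged_center")
    1 + 0.5 * spec$lesion_intensity else 1
  base_d <- if (hf != 1) clip01(render_base(spec, an, heart_factor = hf))
            else clip01(base_h + render_lesion(spec, an))
  mask <- (abs(base_d - base_h) > 1e-9) * 1
  noise <- with_local_seed(derive_seed(spec$noise_seed, "phantom/noise"), function() {
    matrix(rnorm(spec$image_size^2, 0, 0.02), spec$image_size, spec$image_size)
  })
  img_h <- clip01(base_h + noise)
  img_d <- clip01(base_d + noise)
  # outside the mask the pair is identical pre-noise, hence identical post-noise
  healthy_spec <- spec
  healthy_spec$class_label <- "normal"
  healthy_spec$side <- "none"
  healthy_spec$lesion_intensity <- 0
  list(
    healthy = structure(list(image = img_h,
                             lesion_mask = matrix(0, spec$image_size, spec$image_size),
                             prompt = phantom_prompt("normal", "none"),
                             spec = healthy_spec), class = "diffva_sample"),
    diseased = structure(list(image = img_d, lesion_mask = mask,
                              prompt = phantom_prompt(spec$class_label, spec$side),
                              spec = spec), class = "diffva_sample")
  )
}

#' Prompt text for a phantom class and side
#'
#' Prompts are a deterministic function of `(class_label, side)` over the
#' closed vocabulary used for conditioning.
#' @param class_label,side As in [phantom_spec()].
#' @return A character prompt.
#' @export
phantom_prompt <- function(class_label, side) {
  pos <- switch(side,
                left = " on the left", right = " on the right",
                both = " on both sides", none = "")
  switch(class_label,
         normal = "normal chest scan",
         focal_opacity = paste0("lung opacity", pos),
         diffuse_haze = paste0("diffuse haze", pos),
         enlarged_center = "enlarged heart",
         stop("unknown class_label: ", class_label))
}

#' Binary lung-region mask for a phantom's anatomy
#'
#' The union of the two lung fields (threshold 0.5 of the soft ellipse), used
#' as the default region for masked subtraction in attribution, standing in
#' for the lung segmentation masks that accompany real datasets.
#'
#' @param spec A [phantom_spec()] (only anatomy fields are used).
#' @param side Optionally restrict to `"left"` or `"right"`; default `"both"`.
#' @return A binary matrix of the spec's image size.
#' @export
lung_region_mask <- function(spec, side = "both") {
  an <- phantom_anatomy(spec)
  n <- spec$image_size
  xs <- (seq_len(n) - 0.5) / n
  xg <- matrix(xs, n, n, byrow = TRUE)
  yg <- matrix(xs, n, n)
  sides <- if (side == "both") c("left", "right") else side
  m <- matrix(0, n, n)
  for (s in sides) {
    g <- lung_geometry(an, s)
    m <- pmax(m, (soft_ellipse(xg, yg, g$cx, g$cy, g$ax, g$ay) > 0.5) * 1)
  }
  m
}

#' Binary mask of the expected focal-lesion region of one lung
#'
#' The central disc of a lung field (0.8-scaled lung ellipse) — the region
#' focal lesion centers are drawn in. Useful as the scoring region for
#' trivial intensity-threshold class checks.
#'
#' @param spec A [phantom_spec()] (anatomy fields only).
#' @param side `"left"` or `"right"`.
#' @return A binary matrix.
#' @export
expected_lesion_region <- function(spec, side) {
  an <- phantom_anatomy(spec)
  g <- lung_geometry(an, side)
  n <- spec$image_size
  xs <- (seq_len(n) - 0.5) / n
  xg <- matrix(xs, n, n, byrow = TRUE)
  yg <- matrix(xs, n, n)
  (soft_ellipse(xg, yg, g$cx, g$cy, 0.8 * g$ax, 0.8 * g$ay) > 0.5) * 1
}

#' Generate a phantom dataset
#'
#' Per-sample anatomy and noise seeds are derived deterministically from the
#' master seed; sided classes draw left/right with equal probability, lesion
#' intensity from U(0.5, 0.8) and focal radius fraction from U(0.30, 0.40) —
#' the acquisition conditions all experiments in the package assume.
#'
#' @param class_counts Named integer vector/list mapping class label to count.
#' @param image_size Square image side in pixels (>= 16).
#' @param seed Master seed.
#' @return A `diffva_dataset`: list with `samples`, `class_counts`,
#'   `vocabulary`.
#' @export
make_dataset <- function(class_counts, image_size = 32, seed = 0L) {
  class_counts <- unlist(class_counts)
  if (is.null(names(class_counts)) || any(!names(class_counts) %in% PHANTOM_CLASSES))
    stop("class_counts must be named with valid class labels")
  if (any(class_counts < 0)) stop("class_counts must be >= 0")
  if (sum(class_counts) == 0) stop("class_counts: zero total samples")
  samples <- vector("list", sum(class_counts))
  k <- 0L
  for (cl in names(class_counts)) {
    for (j in seq_len(class_counts[[cl]])) {
      tag <- paste0("dataset/", cl, "/", j)
      draw <- with_local_seed(derive_seed(seed, tag), function() {
        list(side = sample(c("left", "right"), 1),
             intensity = runif(1, 0.55, 0.85),
             radius = runif(1, 0.28, 0.38))
      })
      sided <- cl %in% c("focal_opacity", "diffuse_haze")
      spec <- phantom_spec(
        class_label = cl,
        side = if (sided) draw$side else "none",
        image_size = image_size,
        lesion_intensity = if (cl == "normal") 0 else draw$intensity,
        lesion_radius_frac = draw$radius,
        anatomy_seed = derive_seed(seed, paste0(tag, "/anatomy")),
        noise_seed = derive_seed(seed, paste0(tag, "/noise"))
      )
      pair <- make_paired_phantom(spec)
      k <- k + 1L
      samples[[k]] <- if (cl == "normal") pair$healthy else pair$diseased
    }
  }
  structure(list(samples = samples,
                 class_counts = as.list(class_counts),
                 vocabulary = default_vocabulary()),
            class = "diffva_dataset")
}

#' @export
print.diffva_dataset <- function(x, ...) {
  cat("diffva phantom dataset:", length(x$samples), "samples\n")
  cc <- unlist(x$class_counts)
  for (cl in names(cc)) cat("  ", cl, ":", cc[[cl]], "\n")
  if (length(x$samples))
    cat("  image size:", nrow(x$samples[[1]]$image), "px\n")
  invisible(x)
}
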