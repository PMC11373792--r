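# Fixed six-transform augmentation family: 45 deg rotation, 90 deg
# rotation, colour enhancement, brightness enhancement, horizontal
# mirroring, contrast enhancement. With the original retained each crop
# becomes a family of seven.

#' Augmentation parameters
#'
#' Enhancement factors are multiplicative: 1 is the identity, values
#' above 1 strengthen the attribute. Factors are fixed (no jitter) so
#' augmentation is deterministic.
#'
#' @param brightness_factor,color_factor,contrast_factor Positive
#'   enhancement factors (defaults 1.3).
#' @param rotation_fill Fill value for out-of-frame corners after the
#'   45 deg rotation (default 0, black, matching the crop fill policy).
#' @param mirror_axis Mirror axis; only `"horizontal"` (left-right flip)
#'   is provided.
#' @return An object of class `augmentation_params`.
#' @export
augmentation_params <- function(brightness_factor = 1.3, color_factor = 1.3,
                                contrast_factor = 1.3, rotation_fill = 0,
                                mirror_axis = "horizontal") {
  if (any(c(brightness_factor, color_factor, contrast_factor) <= 0))
    stop("enhancement factors must be > 0")
  mirror_axis <- match.arg(mirror_axis, "horizontal")
  structure(list(brightness_factor = brightness_factor,
                 color_factor = color_factor,
                 contrast_factor = contrast_factor,
                 rotation_fill = rotation_fill, mirror_axis = mirror_axis),
            class = "augmentation_params")
}

# --- primitive transforms on H x W x 3 arrays (0-255) ----------------------

rotate45 <- function(px, fill = 0) {
  out <- EBImage::rotate(px, 45, output.dim = dim(px)[1:2], bg.col = fill)
  clip255(array(out, dim(px)))
}

rotate90 <- function(px) {
  # exact quarter-turn by index permutation (lossless pixel multiset)
  H <- dim(px)[1]
  aperm(px, c(2, 1, 3))[dim(px)[2]:1, , , drop = FALSE]
}

mirror_horizontal <- function(px) px[, dim(px)[2]:1, , drop = FALSE]

enhance_brightness <- function(px, f) clip255(px * f)

enhance_color <- function(px, f) {
  # interpolate between the grayscale image (f = 0) and the original
  # (f = 1); f > 1 extrapolates to stronger saturation
  g <- to_grayscale(px, round_output = FALSE)
  out <- px
  for (ch in 1:3) out[, , ch] <- g + f * (px[, , ch] - g)
  clip255(out)
}

enhance_contrast <- function(px, f) {
  # pivot around the mean luminance
  m <- mean(to_grayscale(px, round_output = FALSE))
  clip255(m + f * (px - m))
}

#' Apply the six augmentation transforms to one seed crop
#'
#' Returns exactly six crops in fixed order: rot45, rot90, color,
#' brightness, mirror, contrast. Dimensions and label are preserved;
#' provenance records the transform name.
#'
#' @param crop A `seed_crop` (from [crop_seed()]).
#' @param params An [augmentation_params()].
#' @return List of six `seed_crop` objects.
#' @export
augment_seed <- function(crop, params = augmentation_params()) {
  stopifnot(inherits(crop, "seed_crop"), inherits(params, "augmentation_params"))
  px <- crop$pixels
  outs <- list(
    rot45      = rotate45(px, params$rotation_fill),
    rot90      = rotate90(px),
    color      = enhance_color(px, params$color_factor),
    brightness = enhance_brightness(px, params$brightness_factor),
    mirror     = mirror_horizontal(px),
    contrast   = enhance_contrast(px, params$contrast_factor))
  lapply(names(outs), function(nm) {
    pr <- crop$provenance
    pr$transform <- nm
    pr$parent <- paste0(pr$scene_id, "_", pr$component_id)
    structure(list(pixels = outs[[nm]], label = crop$label, provenance = pr),
              class = "seed_crop")
  })
}

#' Expand a crop manifest sevenfold
#'
#' Reads each original crop, writes its six transformed variants next to
#' it, and returns the manifest with seven rows per input (original +
#' six transforms), labels preserved and provenance chained through
#' `parent_id`.
#'
#' @param manifest Data frame with columns `path`, `label`, and
#'   optionally `scene_id`, `component_id`.
#' @param params An [augmentation_params()].
#' @param out_dir Directory for augmented images (default: alongside the
#'   originals).
#' @return Expanded manifest data frame with columns `path`, `label`,
#'   `transform`, `parent_id`.
#' @export
expand_dataset <- function(manifest, params = augmentation_params(),
                           out_dir = NULL) {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0L,
            all(c("path", "label") %in% names(manifest)))
  transforms <- c("rot45", "rot90", "color", "brightness", "mirror", "contrast")
  stems <- tools::file_path_sans_ext(basename(manifest$path))
  dirs <- if (is.null(out_dir)) dirname(manifest$path) else rep(out_dir, nrow(manifest))
  all_out <- as.vector(t(outer(file.path(dirs, stems), transforms,
                               function(s, tr) paste0(s, "_", tr, ".png"))))
  if (anyDuplicated(c(manifest$path, all_out)))
    stop("augmented output path collides with an existing manifest path")
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    stem <- stems[i]
    dir <- dirs[i]
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    px <- read_image_png(p)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
    crop <- structure(list(pixels = px, label = manifest$label[i],
                           provenance = list(scene_id = stem, component_id = i,
                                             transform = "original")),
                      class = "seed_crop")
    variants <- augment_seed(crop, params)
    paths <- file.path(dir, paste0(stem, "_", transforms, ".png"))
    for (k in seq_along(variants)) write_image_png(variants[[k]]$pixels, paths[k])
    rows[[i]] <- data.frame(
      path = c(p, paths), label = manifest$label[i],
      transform = c("original", transforms), parent_id = stem,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sevenfold expansion of in-memory crops
#'
#' File-free counterpart of [expand_dataset()] used by the training
#' pipeline: returns originals plus their six variants.
#'
#' @param crops List of `seed_crop` objects.
#' @param params An [augmentation_params()].
#' @return List of `7 * length(crops)` seed crops.
#' @export
augment_crops <- function(crops, params = augmentation_params()) {
  out <- list()
  for (i in seq_along(crops)) {
    cr <- crops[[i]]
    cr$provenance$parent <- paste0(cr$provenance$scene_id, "_",
                                   cr$provenance$component_id)
    out <- c(out, list(cr), augment_seed(cr, params))
  }
  out
}

#' Per-channel normalization statistics
#'
#' Channel means and standard deviations (0-255 scale) over a set of
#' crops, used to standardize images at training time.
#'
#' @param crops List of `seed_crop` objects.
#' @return List with numeric `mean` and `sd`, each length 3.
#' @export
channel_stats <- function(crops) {
  stopifnot(length(crops) > 0L)
  sums <- numeric(3); sqs <- numeric(3); n <- 0
  for (cr in crops) {
    for (ch in 1:3) {
      v <- cr$pixels[, , ch]
      sums[ch] <- sums[ch] + sum(v)
      sqs[ch] <- sqs[ch] + sum(v^2)
    }
    n <- n + length(cr$pixels[, , 1])
  }
  m <- sums / n
  s <- sqrt(pmax(sqs / n - m^2, 1e-12))
  list(mean = m, sd = s)
}
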