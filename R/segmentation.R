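# Seed isolation: grayscale -> Otsu binarization -> hole filling ->
# morphological opening -> 8-connected component labelling -> crops.
# Seeds are assumed bright on a dark stage (set invert = TRUE otherwise).

#' Convert an RGB image to grayscale
#'
#' Fixed luminance weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param rgb `H x W x 3` array in 0-255.
#' @param round_output Round to whole gray levels (default TRUE, matching
#'   8-bit storage).
#' @return `H x W` numeric matrix in 0-255.
#' @export
to_grayscale <- function(rgb, round_output = TRUE) {
  rgb <- unclass(rgb)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("to_grayscale expects an H x W x 3 array")
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  dim(g) <- dim(rgb)[1:2]
  if (round_output) round(g) else g
}

#' Otsu threshold of an 8-bit grayscale image
#'
#' Scans all 256 candidate levels and returns the threshold maximizing
#' between-class variance; ties are broken towards the lower threshold.
#' Foreground is defined as strictly above the threshold.
#'
#' @param gray Numeric matrix; values are clamped and rounded to 0-255.
#' @return Integer threshold in 0-255, or `NA` for a constant image.
#' @export
otsu_threshold <- function(gray) {
  v <- as.integer(round(clip255(as.numeric(gray))))
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                  # P(class0) for threshold t = level
  mu <- cumsum(p * (0:255))           # first moment of class0
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254 (split at > t)
  w0 <- omega[1:255]; m0 <- mu[1:255]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  if (all(sigma_b == -Inf)) return(NA_integer_)   # constant image
  which.max(sigma_b) - 1L                         # lowest argmax
}

#' Binarize a grayscale image
#'
#' Otsu threshold; pixels strictly above threshold are foreground. A
#' constant image yields an all-background result.
#'
#' @param gray `H x W` numeric matrix (0-255 scale).
#' @param invert Set `TRUE` for dark seeds on a bright stage.
#' @return Logical `H x W` matrix (TRUE = foreground).
#' @export
binarize <- function(gray, invert = FALSE) {
  if (!is.matrix(gray)) stop("binarize expects a single-channel matrix")
  t <- otsu_threshold(gray)
  if (is.na(t)) return(matrix(FALSE, nrow(gray), ncol(gray)))
  bw <- round(clip255(gray)) > t
  if (invert) !bw else bw
}

# Connected-component labelling. 4-connected labelling comes from
# EBImage::bwlabel; 8-connectivity is obtained by union-find merging of
# 4-connected labels that touch diagonally.
label_components <- function(binary, connectivity = 8L) {
  stopifnot(is.matrix(binary), connectivity %in% c(4L, 8L))
  mode(binary) <- "logical"
  lab <- matrix(as.integer(EBImage::bwlabel(binary * 1)), nrow(binary))
  k <- max(lab)
  if (connectivity == 4L || k <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (p in seq_len(nrow(pairs))) {
    a <- find(pairs[p, 1]); b <- find(pairs[p, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), find, integer(1))
  dense <- match(root, sort(unique(root)))       # consecutive ids
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Fill holes in a binary image
#'
#' Background regions not connected to the image border (4-connected
#' background) become foreground; border-connected background is kept.
#' Idempotent.
#'
#' @param binary Logical `H x W` matrix.
#' @return Logical `H x W` matrix.
#' @export
fill_holes <- function(binary) {
  stopifnot(is.matrix(binary))
  mode(binary) <- "logical"
  H <- nrow(binary); W <- ncol(binary)
  # flood the border-connected background on a 1-px padded complement
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- binary
  bg <- label_components(!pad, connectivity = 4L)
  border_ids <- unique(c(bg[1, ], bg[H + 2L, ], bg[, 1], bg[, W + 2L]))
  border_ids <- border_ids[border_ids > 0L]
  keep_bg <- matrix(bg %in% border_ids, H + 2L, W + 2L)
  !keep_bg[2:(H + 1L), 2:(W + 1L)]
}

#' Extract per-seed masks from a binary image
#'
#' Morphological opening with a disk structuring element, 8-connected
#' component labelling, then an area filter. Touching seeds are not
#' split; a low-solidity component indicates a probable merge
#' (`merged_flag`).
#'
#' @param binary Logical `H x W` matrix.
#' @param min_area Minimum component area in pixels (default 0.1% of the
#'   frame).
#' @param opening_radius Disk radius in pixels for the opening (0 skips
#'   it).
#' @param solidity_threshold Components whose area / bbox-area falls
#'   below this are flagged as possible merges.
#' @return List of `seed_mask` objects (fields `mask`, `bbox` =
#'   (r0, c0, h, w), `area`, `component_id`, `merged_flag`), ordered by
#'   bbox top-left in raster order.
#' @export
extract_seed_masks <- function(binary, min_area = NULL, opening_radius = 2L,
                               solidity_threshold = 0.4) {
  stopifnot(is.matrix(binary))
  mode(binary) <- "logical"
  if (is.null(min_area)) min_area <- max(1L, round(0.001 * length(binary)))
  if (min_area < 1L) stop("min_area must be >= 1")
  opened <- binary
  if (opening_radius > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, shape = "disc")
    opened <- EBImage::opening(binary * 1, brush) > 0.5
  }
  lab <- label_components(opened, connectivity = 8L)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  masks <- list()
  for (id in ids) {
    m <- lab == id
    area <- sum(m)
    if (area < min_area) next
    rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
    bbox <- c(r0 = rr[1], c0 = cc[1], h = rr[2] - rr[1] + 1L, w = cc[2] - cc[1] + 1L)
    masks[[length(masks) + 1L]] <- structure(
      list(mask = m, bbox = bbox, area = area, component_id = id,
           merged_flag = area / (bbox["h"] * bbox["w"]) < solidity_threshold),
      class = "seed_mask")
  }
  if (length(masks) == 0L) return(masks)
  ord <- order(vapply(masks, function(m) (m$bbox["r0"] - 1) * ncol(binary) + m$bbox["c0"],
                      numeric(1)))
  masks <- masks[ord]
  for (i in seq_along(masks)) masks[[i]]$component_id <- i
  masks
}

#' Crop one seed from an image
#'
#' Expands the mask's bounding box by `pad` (clamped to the frame), zeroes
#' out-of-mask pixels, and resizes to `out_size` with bilinear
#' interpolation.
#'
#' @param image `H x W x 3` (or `H x W`) array in 0-255.
#' @param mask A `seed_mask` from [extract_seed_masks()].
#' @param pad Bounding-box padding in pixels.
#' @param out_size Output side length (default 224).
#' @param label Optional class label carried in the result.
#' @param scene_id Provenance identifier.
#' @return A `seed_crop`: list with `pixels`
#'   (`out_size x out_size x 3`, 0-255), `label`, and `provenance`.
#' @export
crop_seed <- function(image, mask, pad = 4L, out_size = 224L,
                      label = NA_character_, scene_id = "scene") {
  stopifnot(inherits(mask, "seed_mask"))
  if (mask$area == 0L) stop("empty mask")
  image <- unclass(image)
  if (length(dim(image)) == 2L) image <- array(rep(image, 3), c(dim(image), 3L))
  H <- dim(image)[1]; W <- dim(image)[2]
  if (nrow(mask$mask) != H || ncol(mask$mask) != W)
    stop("mask dimensions do not match the image")
  b <- mask$bbox
  r0 <- max(1L, b["r0"] - pad); c0 <- max(1L, b["c0"] - pad)
  r1 <- min(H, b["r0"] + b["h"] - 1L + pad); c1 <- min(W, b["c0"] + b["w"] - 1L + pad)
  sub <- image[r0:r1, c0:c1, , drop = FALSE]
  msub <- mask$mask[r0:r1, c0:c1]
  for (ch in 1:3) sub[, , ch] <- sub[, , ch] * msub
  px <- EBImage::resize(sub, w = out_size, h = out_size)
  px <- clip255(px)
  structure(list(pixels = px, label = label,
                 provenance = list(scene_id = scene_id,
                                   component_id = mask$component_id,
                                   transform = "original")),
            class = "seed_crop")
}
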