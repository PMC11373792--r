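# RGB pseudo-colour reconstruction: single-band grayscale extraction,
# band-triple composition, and the search over R/G/B band triples scored
# by downstream classification accuracy.

#' Physiological R/G/B band windows
#'
#' The imager's fixed per-channel index ranges: red bands 173-292
#' (620.05-779.75 nm), green 76-127 (491.19-558.79 nm), blue 23-44
#' (421.29-448.94 nm). A channel band must normally be chosen from its
#' window.
#'
#' @return A list with integer ranges `red`, `green`, `blue`
#'   (class `band_windows`).
#' @export
band_windows <- function() {
  structure(list(red = c(173L, 292L), green = c(76L, 127L), blue = c(23L, 44L)),
            class = "band_windows")
}

#' R/G/B band triple
#'
#' @param r_band,g_band,b_band 1-based band indices for the red, green and
#'   blue display channels. The best-performing published triple is
#'   188-83-41; the plain true-colour baseline is 188-120-60.
#' @param windows A [band_windows()] used for validation, or `NULL`.
#' @param enforce_windows If `TRUE` (default) each index must lie inside
#'   its window; set `FALSE` to override explicitly.
#' @return An object of class `band_triple`.
#' @export
band_triple <- function(r_band, g_band, b_band, windows = band_windows(),
                        enforce_windows = TRUE) {
  tr <- c(r = as.integer(r_band), g = as.integer(g_band), b = as.integer(b_band))
  if (enforce_windows && !is.null(windows)) {
    win <- list(windows$red, windows$green, windows$blue)
    chan <- c("red", "green", "blue")
    for (i in 1:3)
      if (tr[i] < win[[i]][1] || tr[i] > win[[i]][2])
        stop(sprintf("band %d outside the %s window %d-%d (use enforce_windows = FALSE to override)",
                     tr[i], chan[i], win[[i]][1], win[[i]][2]))
  }
  structure(as.list(tr), class = "band_triple")
}

#' @export
print.band_triple <- function(x, ...) {
  cat(sprintf("band_triple: %d-%d-%d\n", x$r, x$g, x$b)); invisible(x)
}

#' Extract a single-band grayscale image
#'
#' @param cube A [hypercube()].
#' @param band 1-based band index.
#' @param scaling `"minmax"` rescales the band to 0-255 (a constant band
#'   maps to 0); `"global"` maps the fixed reflectance range
#'   `global_range` linearly to 0-255.
#' @param global_range Reflectance range used by `"global"` scaling.
#' @return An `H x W` numeric matrix with values in 0-255.
#' @export
extract_band_image <- function(cube, band, scaling = c("minmax", "global"),
                               global_range = c(0, 1)) {
  stopifnot(inherits(cube, "hypercube"))
  scaling <- match.arg(scaling)
  band <- as.integer(band)
  if (band < 1L || band > n_bands(cube))
    stop(sprintf("band %d out of range 1..%d", band, n_bands(cube)))
  x <- cube$data[, , band]
  if (scaling == "minmax") {
    rng <- range(x)
    if (rng[2] == rng[1]) return(matrix(0, nrow(x), ncol(x)))
    (x - rng[1]) / (rng[2] - rng[1]) * 255
  } else {
    clip255((x - global_range[1]) / (global_range[2] - global_range[1]) * 255)
  }
}

#' Compose an RGB pseudo-colour image from a band triple
#'
#' Channel `c` of the output is [extract_band_image()] of the
#' corresponding band; provenance (source id and triple) is attached.
#'
#' @param cube A [hypercube()].
#' @param triple A [band_triple()].
#' @inheritParams extract_band_image
#' @param scene_id Identifier recorded in the provenance.
#' @return An `H x W x 3` array in 0-255 of class `rgb_image`, with a
#'   `provenance` attribute.
#' @export
compose_rgb <- function(cube, triple, scaling = c("minmax", "global"),
                        global_range = c(0, 1), scene_id = "cube") {
  stopifnot(inherits(triple, "band_triple"))
  scaling <- match.arg(scaling)
  bands <- c(triple$r, triple$g, triple$b)
  img <- array(0, c(dim(cube$data)[1], dim(cube$data)[2], 3L))
  for (i in 1:3)
    img[, , i] <- extract_band_image(cube, bands[i], scaling, global_range)
  structure(img, class = "rgb_image",
            provenance = list(scene_id = scene_id,
                              triple = sprintf("%d-%d-%d", bands[1], bands[2], bands[3])))
}

#' Linear-discriminant proxy evaluator for band search
#'
#' Desk-scale stand-in for training a deep classifier per candidate
#' triple: each scene is composed with the triple, segmented
#' ([extract_seed_masks()] chain), seeds are matched to their class via
#' the ground-truth mask, per-seed features are channel means and
#' standard deviations inside the mask, and accuracy is stratified k-fold
#' cross-validation of linear discriminant analysis.
#'
#' @param n_folds Cross-validation folds.
#' @param min_area,opening_radius Segmentation parameters passed through.
#' @return A function `(corpus, triple, rng_seed) -> accuracy in [0, 1]`
#'   suitable for [search_band_triples()]. `corpus` is a
#'   [generate_corpus()] result (scenes with ground truth).
#' @export
lda_proxy_evaluator <- function(n_folds = 5L, min_area = 20L, opening_radius = 1L) {
  force(n_folds); force(min_area); force(opening_radius)
  function(corpus, triple, rng_seed) {
    feats <- NULL; labs <- character()
    for (sc in corpus$scenes) {
      rgb <- compose_rgb(sc$cube, triple)
      gray <- to_grayscale(rgb)
      bw <- fill_holes(binarize(gray))
      masks <- extract_seed_masks(bw, min_area = min_area,
                                  opening_radius = opening_radius)
      for (m in masks) {
        idx <- which(m$mask)
        lab_ids <- sc$truth$label_mask[idx]
        lab_ids <- lab_ids[lab_ids > 0L]
        if (length(lab_ids) == 0L) next
        inst <- as.integer(names(which.max(table(lab_ids))))
        cls <- sc$truth$instances$class[match(inst, sc$truth$instances$instance_id)]
        f <- c(vapply(1:3, function(ch) mean(rgb[, , ch][idx]), numeric(1)),
               vapply(1:3, function(ch) stats::sd(rgb[, , ch][idx]), numeric(1)))
        feats <- rbind(feats, f); labs <- c(labs, cls)
      }
    }
    if (is.null(feats) || length(unique(labs)) < 2L) return(0)
    feats[is.na(feats)] <- 0
    with_seed(rng_seed, .cv_lda_accuracy(feats, labs, n_folds))
  }
}

.cv_lda_accuracy <- function(x, y, n_folds) {
  y <- factor(y)
  n <- length(y)
  folds <- integer(n)
  for (cl in levels(y)) {     # stratified fold assignment
    i <- which(y == cl)
    folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  correct <- 0L
  for (k in seq_len(n_folds)) {
    tr <- folds != k; te <- !tr
    if (!any(te)) next
    if (length(unique(y[tr])) < 2L) next
    # collinear features are routine on tiny corpora and harmless to the
    # proxy score, so the collinearity warning is muted
    fit <- tryCatch(suppressWarnings(MASS::lda(x[tr, , drop = FALSE], grouping = y[tr])),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pred <- stats::predict(fit, x[te, , drop = FALSE])$class
    correct <- correct + sum(pred == y[te])
  }
  correct / n
}

#' Search band triples for the best classification accuracy
#'
#' Scores every triple in the candidate grid by composing RGB images for
#' the corpus, running segmentation and the pluggable evaluator, and
#' ranks triples by accuracy (descending; ties broken by lexicographic
#' (r, g, b) order). Evaluator failures are recorded as `NA` scores and
#' rank last.
#'
#' @param corpus A labelled corpus as from [generate_corpus()].
#' @param grid List with integer vectors `r`, `g`, `b` of candidate bands
#'   per channel (all non-empty).
#' @param evaluator Function `(corpus, triple, rng_seed) -> accuracy`;
#'   default [lda_proxy_evaluator()].
#' @param rng_seed Integer seed passed to the evaluator.
#' @param baseline Optional [band_triple()]; the result then flags all
#'   triples scoring strictly above the baseline's accuracy.
#' @param enforce_windows Validate grid bands against [band_windows()].
#' @return A data frame (class `band_search_result`) with columns `r`,
#'   `g`, `b`, `accuracy`, `rank`, and `beats_baseline` when a baseline
#'   was given; attribute `baseline_accuracy` likewise.
#' @export
search_band_triples <- function(corpus, grid, evaluator = lda_proxy_evaluator(),
                                rng_seed = 1L, baseline = NULL,
                                enforce_windows = TRUE) {
  stopifnot(is.list(grid), all(c("r", "g", "b") %in% names(grid)))
  if (any(lengths(grid[c("r", "g", "b")]) == 0L))
    stop("grid must be non-empty for every channel")
  combos <- expand.grid(r = sort(unique(as.integer(grid$r))),
                        g = sort(unique(as.integer(grid$g))),
                        b = sort(unique(as.integer(grid$b))),
                        KEEP.OUT.ATTRS = FALSE)
  acc <- rep(NA_real_, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    tri <- band_triple(combos$r[i], combos$g[i], combos$b[i],
                       enforce_windows = enforce_windows)
    acc[i] <- tryCatch(evaluator(corpus, tri, rng_seed),
                       error = function(e) NA_real_)
  }
  res <- cbind(combos, accuracy = acc)
  ord <- order(-ifelse(is.na(res$accuracy), -Inf, res$accuracy),
               res$r, res$g, res$b)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res$rank <- seq_len(nrow(res))
  base_acc <- NULL
  if (!is.null(baseline)) {
    base_acc <- evaluator(corpus, baseline, rng_seed)
    res$beats_baseline <- !is.na(res$accuracy) & res$accuracy > base_acc
  }
  structure(res, class = c("band_search_result", "data.frame"),
            baseline_accuracy = base_acc)
}

#' Write an RGB image as PNG
#'
#' @param img An `rgb_image` (0-255) or plain `H x W x 3`/`H x W` array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clip255(unclass(img)) / 255, path)
  invisible(path)
}

#' Read a PNG as a 0-255 image array
#'
#' @param path PNG file path.
#' @return `H x W` matrix or `H x W x 3` array in 0-255 (alpha dropped).
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path) * 255
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3]
  a
}
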