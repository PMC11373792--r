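# Synthetic hyperspectral seed scenes with known per-class reflectance
# signatures and ground-truth instance masks. Emulates dark-stage line-scan
# acquisitions of non-overlapping, roughly ellipsoidal seeds, so that band
# search, segmentation and classification are all testable without
# instrument data.

#' Default per-class spectral signatures
#'
#' Each class is a set of Gaussian reflectance bumps over a common
#' baseline. The default centres sit inside the red/green/blue camera
#' windows (640.6, 500.7 and 444.7 nm, the wavelengths of bands 188, 83
#' and 41 under the default calibration); classes beyond three use
#' combinations of the same centres, so up to seven mutually
#' distinguishable varieties are available.
#'
#' @param n_classes Number of classes (1..7).
#' @param amplitude Bump amplitude (reflectance units).
#' @param width_nm Gaussian bump standard deviation in nm.
#' @return A list of data frames with columns `center_nm`, `width_nm`,
#'   `amplitude`, one per class.
#' @export
default_signatures <- function(n_classes = 3L, amplitude = 0.35, width_nm = 12) {
  centers <- c(640.6, 500.7, 444.7)
  combos <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), c(1L, 2L, 3L))
  if (n_classes < 1L || n_classes > length(combos))
    stop("n_classes must be between 1 and 7 for the default signature set")
  lapply(combos[seq_len(n_classes)], function(k)
    data.frame(center_nm = centers[k], width_nm = width_nm, amplitude = amplitude))
}

#' Synthetic scene specification
#'
#' @param n_classes Number of seed classes.
#' @param seeds_per_class Seeds planted per class (0 gives a
#'   background-only scene).
#' @param image_size `(lines, samples)` frame size in pixels.
#' @param band_count Number of spectral bands (default 462, the imager's
#'   band count; calibrated with [default_calibration()]).
#' @param signatures Per-class bump tables as from [default_signatures()].
#' @param baseline Common in-seed baseline reflectance.
#' @param background Stage reflectance (dark).
#' @param axis_range Ellipse semi-axis range in pixels, `c(min, max)`.
#' @param min_gap Minimum distance between seed envelopes, pixels.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param rng_seed Integer seed; all randomness derives from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_classes = 3L, seeds_per_class = 4L,
                       image_size = c(150L, 200L), band_count = 462L,
                       signatures = default_signatures(n_classes),
                       baseline = 0.35, background = 0.05,
                       axis_range = c(7, 12), min_gap = 6,
                       noise_sd = 0.02, rng_seed = 1L) {
  stopifnot(n_classes >= 1L, seeds_per_class >= 0L, band_count >= 1L,
            length(image_size) == 2L, all(image_size >= 1L),
            length(signatures) == n_classes, noise_sd >= 0,
            axis_range[1] > 0, axis_range[2] >= axis_range[1], min_gap >= 0)
  for (s in signatures)
    if (any(s$amplitude < 0)) stop("signature amplitudes must be >= 0")
  structure(list(n_classes = as.integer(n_classes),
                 seeds_per_class = as.integer(seeds_per_class),
                 image_size = as.integer(image_size),
                 band_count = as.integer(band_count),
                 signatures = signatures, baseline = baseline,
                 background = background, axis_range = axis_range,
                 min_gap = min_gap, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# Reflectance spectrum (over the calibrated wavelengths) for one class.
.class_spectrum <- function(wl, baseline, sig) {
  s <- rep(baseline, length(wl))
  for (i in seq_len(nrow(sig)))
    s <- s + sig$amplitude[i] *
      exp(-(wl - sig$center_nm[i])^2 / (2 * sig$width_nm[i]^2))
  s
}

#' Generate one synthetic seed scene
#'
#' Plants `n_classes * seeds_per_class` non-overlapping ellipses on a dark
#' stage; in-seed pixels carry their class's signature plus noise.
#' Deterministic for a fixed `rng_seed`.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `cube` (a [hypercube()]) and `truth`, a
#'   list with `label_mask` (integer instance-id matrix, 0 = background)
#'   and `instances` (data frame: instance_id, class, class_id, cy, cx,
#'   a, b, theta, and tight bbox r0/c0/h/w).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$rng_seed, .generate_scene_impl(spec))
}

.generate_scene_impl <- function(spec) {
  L <- spec$image_size[1]; S <- spec$image_size[2]; B <- spec$band_count
  cal <- default_calibration(B)
  wl <- wavelength_of_band(cal, seq_len(B))
  n_seeds <- spec$n_classes * spec$seeds_per_class

  # place ellipses by rejection sampling on bounding circles
  placed <- data.frame()
  amax <- spec$axis_range[2]
  for (i in seq_len(n_seeds)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      a <- stats::runif(1, spec$axis_range[1], spec$axis_range[2])
      b <- stats::runif(1, spec$axis_range[1], a)
      th <- stats::runif(1, 0, pi)
      if (L <= 2 * a + 2 || S <= 2 * a + 2) next
      cy <- stats::runif(1, a + 1, L - a)
      cx <- stats::runif(1, a + 1, S - a)
      if (nrow(placed) == 0L ||
          all(sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2) >=
              placed$a + a + spec$min_gap)) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(paste0("cannot place seed %d of %d: frame %dx%d too small for ",
                          "axis range [%g, %g] with min gap %g"),
                   i, n_seeds, L, S, spec$axis_range[1], spec$axis_range[2],
                   spec$min_gap))
    placed <- rbind(placed, data.frame(cy = cy, cx = cx, a = a, b = b, theta = th))
  }

  # background + noise in one draw
  cube <- if (spec$noise_sd > 0)
    array(stats::rnorm(L * S * B, spec$background, spec$noise_sd), c(L, S, B))
  else array(spec$background, c(L, S, B))

  label_mask <- matrix(0L, L, S)
  inst <- NULL
  if (n_seeds > 0L) {
    class_ids <- rep(seq_len(spec$n_classes), each = spec$seeds_per_class)
    spectra <- lapply(spec$signatures, .class_spectrum,
                      wl = wl, baseline = spec$baseline)
    rows <- matrix(seq_len(L), L, S)
    cols <- matrix(seq_len(S), L, S, byrow = TRUE)
    for (i in seq_len(n_seeds)) {
      p <- placed[i, ]
      dy <- rows - p$cy; dx <- cols - p$cx
      u <- (dx * cos(p$theta) + dy * sin(p$theta)) / p$a
      v <- (-dx * sin(p$theta) + dy * cos(p$theta)) / p$b
      inside <- which(u^2 + v^2 <= 1)
      label_mask[inside] <- i
      sig <- spectra[[class_ids[i]]]
      m <- length(inside)
      off <- outer(inside, (seq_len(B) - 1L) * L * S, "+")
      vals <- rep(sig, each = m)
      if (spec$noise_sd > 0) vals <- vals + stats::rnorm(m * B, 0, spec$noise_sd)
      cube[off] <- clip01(vals)
      rr <- range((inside - 1L) %% L + 1L); cc <- range((inside - 1L) %/% L + 1L)
      inst <- rbind(inst, data.frame(
        instance_id = i, class = paste0("C", class_ids[i]),
        class_id = class_ids[i], cy = p$cy, cx = p$cx, a = p$a, b = p$b,
        theta = p$theta, r0 = rr[1], c0 = cc[1],
        h = rr[2] - rr[1] + 1L, w = cc[2] - cc[1] + 1L))
    }
  }
  if (is.null(inst))
    inst <- data.frame(instance_id = integer(), class = character(),
                       class_id = integer(), cy = numeric(), cx = numeric(),
                       a = numeric(), b = numeric(), theta = numeric(),
                       r0 = integer(), c0 = integer(), h = integer(), w = integer())
  if (spec$noise_sd > 0) {
    cube[cube < 0] <- 0           # noise can dip below the storage floor
    if (spec$background + 6 * spec$noise_sd > 1) cube[cube > 1] <- 1
  }
  list(cube = hypercube(cube, calibration = cal, interleave = "bil"),
       truth = list(label_mask = label_mask, instances = inst))
}

#' Generate a corpus of synthetic scenes
#'
#' Scene `i` uses seed `rng_seed + i`, so corpora are reproducible and
#' scenes mutually independent.
#'
#' @param spec A [scene_spec()]; its `rng_seed` is the corpus seed.
#' @param n_scenes Number of scenes (>= 1).
#' @return A list with `scenes` (each a `generate_scene` result) and
#'   `manifest`, a data frame of per-scene, per-class instance counts.
#' @export
generate_corpus <- function(spec, n_scenes = 1L) {
  stopifnot(inherits(spec, "scene_spec"), n_scenes >= 1L)
  scenes <- vector("list", n_scenes)
  man <- NULL
  for (k in seq_len(n_scenes)) {
    sp <- spec; sp$rng_seed <- spec$rng_seed + k
    scenes[[k]] <- generate_scene(sp)
    cnt <- table(factor(scenes[[k]]$truth$instances$class,
                        levels = paste0("C", seq_len(spec$n_classes))))
    man <- rbind(man, data.frame(scene = k, class = names(cnt),
                                 count = as.integer(cnt)))
  }
  list(scenes = scenes, manifest = man)
}

#' Canonical planted-triple corpus for band-search experiments
#'
#' Four classes whose reflectance differs only at the wavelengths of the
#' planted triple (bands 188, 83, 41 under the default calibration):
#' class 1 has a narrow bump in the red window, class 2 in the green,
#' class 3 in the blue, and class 4 is baseline-only. Every channel of
#' the triple is therefore necessary to separate all four classes, and
#' bumps are narrow (3 nm s.d.) so candidate bands a few window steps
#' away carry essentially no class signal: the planted triple is the
#' Bayes-optimal choice on the companion grid of [planted_grid()].
#'
#' @param rng_seed Corpus seed.
#' @param n_scenes Number of scenes (default 3).
#' @param seeds_per_class Seeds per class per scene (default 3).
#' @param image_size Frame size (default `c(100, 140)`).
#' @param width_nm Bump standard deviation in nm (default 3).
#' @param amplitude Bump amplitude (default 0.35).
#' @param noise_sd Additive noise (default 0.02).
#' @return A [generate_corpus()] result with attribute `planted`, the
#'   planted [band_triple()].
#' @export
planted_corpus <- function(rng_seed = 1L, n_scenes = 3L, seeds_per_class = 3L,
                           image_size = c(100L, 140L), width_nm = 3,
                           amplitude = 0.35, noise_sd = 0.02) {
  sig <- default_signatures(3L, amplitude = amplitude, width_nm = width_nm)
  sig <- c(sig, list(data.frame(center_nm = numeric(), width_nm = numeric(),
                                amplitude = numeric())))   # baseline-only class
  spec <- scene_spec(n_classes = 4L, seeds_per_class = seeds_per_class,
                     image_size = image_size, signatures = sig,
                     noise_sd = noise_sd, rng_seed = rng_seed)
  corpus <- generate_corpus(spec, n_scenes = n_scenes)
  attr(corpus, "planted") <- band_triple(188L, 83L, 41L)
  corpus
}

#' Companion candidate grid for the planted corpus
#'
#' Four candidate bands per channel inside the legal windows, including
#' the planted bands; alternatives sit at least ~4 bump widths from the
#' planted centres, so only the planted triple carries full class
#' signal.
#'
#' @return List with integer vectors `r`, `g`, `b`.
#' @export
planted_grid <- function() {
  list(r = c(173L, 188L, 240L, 292L),
       g = c(83L, 96L, 110L, 127L),
       b = c(23L, 27L, 32L, 41L))
}

#' Write ground truth to disk
#'
#' Label mask as a grayscale PNG (instance id / 255) plus the instance
#' table as JSON.
#'
#' @param truth Ground truth from [generate_scene()].
#' @param path_prefix Output prefix; writes `<prefix>_mask.png` and
#'   `<prefix>_instances.json`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_ground_truth <- function(truth, path_prefix) {
  mask_path <- paste0(path_prefix, "_mask.png")
  json_path <- paste0(path_prefix, "_instances.json")
  png::writePNG(truth$label_mask / 255, mask_path)
  jsonlite::write_json(truth$instances, json_path, digits = NA)
  invisible(c(mask = mask_path, instances = json_path))
}
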