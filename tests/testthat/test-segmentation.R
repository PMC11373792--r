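test_that("grayscale conversion uses the fixed luminance weights", {
  white <- array(255, c(4, 4, 3))
  expect_true(all(to_grayscale(white) == 255))
  one <- array(0, c(1, 1, 3)); one[1, 1, ] <- c(100, 50, 200)
  expect_identical(to_grayscale(one)[1, 1], 82)        # 82.05 rounds to 82
  expect_equal(to_grayscale(one, round_output = FALSE)[1, 1], 82.05)
  flat <- array(73, c(3, 5, 3))
  expect_true(all(to_grayscale(flat) == 73))           # weights sum to 1
  expect_error(to_grayscale(array(1, c(4, 4, 2))), "3")
})

test_that("Otsu threshold separates a two-valued image exactly", {
  img <- matrix(c(rep(10, 30), rep(200, 20)), 5, 10)
  t <- otsu_threshold(img)
  expect_true(t >= 10 && t < 200)
  bw <- binarize(img)
  expect_identical(as.vector(bw), as.vector(img > t))
  expect_identical(sum(bw), 20L)
})

test_that("Otsu equals the exhaustive between-class-variance maximizer on 50 random histograms", {
  set.seed(1234)
  for (i in 1:50) {
    n <- sample(50:400, 1)
    v <- switch(1 + i %% 3,
      sample(0:255, n, replace = TRUE),
      c(rnorm(n %/% 2, 60, 25), rnorm(n - n %/% 2, 180, 30)),
      rnorm(n, 120, 60))
    img <- matrix(pmin(pmax(round(v), 0), 255), nrow = 1)
    expect_identical(otsu_threshold(img), otsu_bruteforce(img))
  }
})

test_that("a constant image binarizes to all background", {
  expect_true(is.na(otsu_threshold(matrix(42, 5, 5))))
  expect_identical(sum(binarize(matrix(42, 5, 5))), 0L)
})

test_that("polarity inversion flips foreground for dark seeds on a bright stage", {
  img <- matrix(c(rep(200, 30), rep(10, 20)), 5, 10)
  expect_identical(sum(binarize(img, invert = TRUE)), 20L)
})

test_that("fill_holes fills interior holes, keeps border background, and is idempotent", {
  disk <- ellipse_mask(21, 21, 11, 11, 6, 6)
  expect_identical(fill_holes(disk), disk)             # hole-free input unchanged
  annulus <- disk & !ellipse_mask(21, 21, 11, 11, 3, 3)
  expect_identical(fill_holes(annulus), disk)          # interior filled
  empty <- matrix(FALSE, 8, 8)
  expect_identical(fill_holes(empty), empty)
  # border-touching concavity is not a hole
  cup <- matrix(FALSE, 9, 9); cup[3:9, 3:7] <- TRUE; cup[1:7, 5] <- FALSE
  expect_identical(fill_holes(cup), cup)
  expect_identical(fill_holes(fill_holes(annulus)), fill_holes(annulus))
})

test_that("fill_holes agrees with EBImage::fillHull on random blob images", {
  set.seed(88)
  for (i in 1:10) {
    img <- matrix(FALSE, 40, 40)
    for (k in 1:4) {
      cy <- sample(8:32, 1); cx <- sample(8:32, 1)
      img <- img | (ellipse_mask(40, 40, cy, cx, sample(3:7, 1), sample(3:7, 1)) &
                    !ellipse_mask(40, 40, cy, cx, 2, 2))
    }
    expect_identical(fill_holes(img),
                     matrix(EBImage::fillHull(img * 1) > 0.5, 40, 40))
  }
})

test_that("8-connected labelling matches the flood-fill oracle on random images", {
  set.seed(99)
  for (i in 1:15) {
    img <- matrix(runif(30 * 30) < 0.35, 30, 30)
    fast <- hyperseed:::label_components(img, 8L)
    slow <- label_components_slow(img)
    expect_identical(max(fast), max(slow))
    # identical partitions up to label renaming
    expect_identical(unname(table(fast[fast > 0], slow[slow > 0]) > 0),
                     unname(table(fast[fast > 0], slow[slow > 0]) > 0))
    key <- tapply(slow[img], fast[img], function(v) length(unique(v)))
    expect_true(all(key == 1L))
  }
})

test_that("mask extraction filters specks, orders by raster position, and opening is anti-extensive", {
  img <- matrix(FALSE, 60, 80)
  img <- img | ellipse_mask(60, 80, 20, 25, 8, 10)
  set.seed(6)
  specks <- sample(which(!img), 5)
  img[specks] <- TRUE
  masks <- extract_seed_masks(img, min_area = 20L, opening_radius = 0L)
  expect_length(masks, 1L)
  expect_identical(masks[[1]]$area, sum(ellipse_mask(60, 80, 20, 25, 8, 10)))

  opened <- extract_seed_masks(img, min_area = 20L, opening_radius = 2L)
  expect_true(all(opened[[1]]$mask <= img))            # anti-extensive

  expect_length(extract_seed_masks(matrix(FALSE, 10, 10)), 0L)

  two <- ellipse_mask(60, 80, 15, 15, 6, 6) | ellipse_mask(60, 80, 45, 60, 6, 6)
  ms <- extract_seed_masks(two, min_area = 10L, opening_radius = 0L)
  expect_identical(vapply(ms, function(m) unname(m$bbox["r0"]), numeric(1)),
                   sort(vapply(ms, function(m) unname(m$bbox["r0"]), numeric(1))))
})

test_that("synthetic scenes are segmented to the planted instances with IoU above 0.8", {
  sp <- scene_spec(n_classes = 3L, seeds_per_class = 4L, image_size = c(120L, 160L),
                   band_count = 462L, noise_sd = 0, rng_seed = 41L)
  sc <- generate_scene(sp)
  rgb <- compose_rgb(sc$cube, band_triple(188L, 83L, 41L))
  bw <- fill_holes(binarize(to_grayscale(rgb)))
  masks <- extract_seed_masks(bw, min_area = 20L, opening_radius = 1L)
  expect_length(masks, 12L)
  for (m in masks) {
    ids <- sc$truth$label_mask[m$mask]
    id <- as.integer(names(which.max(table(ids[ids > 0]))))
    gt <- sc$truth$label_mask == id
    iou <- sum(m$mask & gt) / sum(m$mask | gt)
    expect_gt(iou, 0.8)
  }
})

test_that("crop_seed honors identity, output contract and fill policy", {
  set.seed(12)
  img <- array(runif(40 * 40 * 3) * 255, c(40, 40, 3))
  full <- structure(list(mask = matrix(TRUE, 40, 40),
                         bbox = c(r0 = 1, c0 = 1, h = 40, w = 40),
                         area = 1600L, component_id = 1L, merged_flag = FALSE),
                    class = "seed_mask")
  cr <- crop_seed(img, full, pad = 0L, out_size = 40L)
  expect_equal(cr$pixels, img, tolerance = 1e-9)       # identity crop

  m <- ellipse_mask(40, 40, 20, 20, 8, 8)
  sm <- structure(list(mask = m, bbox = c(r0 = 12, c0 = 12, h = 17, w = 17),
                       area = sum(m), component_id = 1L, merged_flag = FALSE),
                  class = "seed_mask")
  cr224 <- crop_seed(img, sm)
  expect_identical(dim(cr224$pixels), c(224L, 224L, 3L))   # default contract

  # out-of-mask pixels are black before resizing: crop at native size
  crn <- crop_seed(img, sm, pad = 0L, out_size = 17L)
  sub <- m[12:28, 12:28]
  for (ch in 1:3) expect_true(all(crn$pixels[, , ch][!sub] < 1e-9))

  empty <- structure(list(mask = matrix(FALSE, 40, 40),
                          bbox = c(r0 = 1, c0 = 1, h = 1, w = 1), area = 0L,
                          component_id = 1L, merged_flag = FALSE),
                     class = "seed_mask")
  expect_error(crop_seed(img, empty), "empty")
})

test_that("the segmentation chain is deterministic", {
  sp <- scene_spec(image_size = c(100L, 130L), band_count = 462L, rng_seed = 55L)
  sc <- generate_scene(sp)
  run <- function() {
    rgb <- compose_rgb(sc$cube, band_triple(188L, 83L, 41L))
    extract_seed_masks(fill_holes(binarize(to_grayscale(rgb))),
                       min_area = 20L, opening_radius = 1L)
  }
  a <- run(); b <- run()
  expect_identical(lapply(a, `[[`, "mask"), lapply(b, `[[`, "mask"))
})
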