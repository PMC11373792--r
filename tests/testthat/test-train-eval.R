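# builds a small in-memory colour-blob classification problem: class k is
# brightest in channel k, on a dark background
make_blob_data <- function(n_per_class, size = 16L, k = 3L, noise = 0.1, seed = 1L) {
  set.seed(seed)
  n <- n_per_class * k
  x <- array(rnorm(size * size * 3 * n, 0, noise), c(size, size, 3L, n))
  y <- rep(seq_len(k), each = n_per_class)
  for (i in seq_len(n)) x[, , y[i], i] <- x[, , y[i], i] + 1
  list(x = x, y = y)
}

small_model <- function(num_classes = 3L, input_size = 16L, seed = 1L)
  build_modified_model(model_config("se_resnet_small", num_classes = num_classes,
                                    input_size = input_size, base_channels = 4L,
                                    rng_seed = seed))

test_that("the training configuration defaults follow the study regimen", {
  tc <- train_config()
  expect_equal(tc$learning_rate, 0.001)
  expect_equal(tc$momentum, 0.9)
  expect_equal(tc$weight_decay, 0.01)
  expect_identical(tc$batch_size, 8L)
  expect_identical(tc$epochs, 50L)
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(batch_size = 0L), "batch_size")
})

test_that("zero epochs returns the model unchanged with an empty history", {
  m <- small_model()
  before <- predict_classifier(m, array(0.5, c(16, 16, 3, 1)))
  d <- make_blob_data(4L)
  m2 <- fit_classifier(m, d$x, d$y, config = train_config(epochs = 0L))
  expect_identical(nrow(m2$history), 0L)
  expect_equal(predict_classifier(m2, array(0.5, c(16, 16, 3, 1))), before)
})

test_that("training a small model on separable blobs reduces loss and lifts accuracy", {
  d <- make_blob_data(20L, seed = 7L)
  v <- make_blob_data(6L, seed = 8L)
  m <- small_model(seed = 2L)
  tc <- train_config(learning_rate = 0.01, epochs = 6L, rng_seed = 3L)
  m <- fit_classifier(m, d$x, d$y, v$x, v$y, tc)
  h <- m$history
  expect_identical(nrow(h), 6L)
  expect_gt(h$train_acc[6], h$train_acc[1])
  expect_lt(mean(tail(h$train_loss, 2)), mean(head(h$train_loss, 2)))
  expect_gte(max(h$val_acc), 0.9)
  expect_identical(m$best_epoch, which.max(h$val_acc))
})

test_that("training is reproducible for a fixed seed", {
  d <- make_blob_data(8L, seed = 11L)
  run <- function() {
    m <- small_model(seed = 4L)
    m <- fit_classifier(m, d$x, d$y, config = train_config(learning_rate = 0.01,
                                                           epochs = 2L, rng_seed = 5L))
    m$history
  }
  expect_identical(run(), run())
})

test_that("a non-finite loss raises a divergence error naming the epoch", {
  d <- make_blob_data(4L)
  m <- small_model()
  mods <- hyperseed:::collect_modules(m$net)
  dense <- mods[[which(vapply(mods, function(x) x$kind, character(1)) == "dense")]]
  dense$params$W[] <- 1e308   # overflowing logits turn the loss non-finite
  expect_error(fit_classifier(m, d$x, d$y,
                              config = train_config(learning_rate = 0.01, epochs = 3L)),
               "diverged.*epoch 1", perl = TRUE)
})

test_that("evaluate builds a confusion matrix whose rows are the manifest class counts", {
  d <- withr::local_tempdir()
  set.seed(15)
  n <- 12L
  paths <- file.path(d, sprintf("x%02d.png", seq_len(n)))
  labs <- rep(c("C1", "C2", "C3"), each = 4L)
  for (i in seq_len(n)) {
    px <- array(runif(16 * 16 * 3, 0, 40), c(16, 16, 3))
    px[, , match(labs[i], c("C1", "C2", "C3"))] <- 200
    write_image_png(px, paths[i])
  }
  man <- data.frame(path = paths, label = labs)
  m <- small_model()
  cm <- evaluate(m, man)
  expect_identical(rowSums(cm), c(C1 = 4, C2 = 4, C3 = 4))
  expect_identical(sum(cm), n)

  # a model forced to a constant prediction puts all mass in one column
  fc <- hyperseed:::collect_modules(m$net)
  dense <- fc[[which(vapply(fc, function(x) x$kind, character(1)) == "dense")]]
  dense$params$W[] <- 0
  dense$params$b <- c(0, 10, 0)
  cm2 <- evaluate(m, man)
  expect_identical(unname(colSums(cm2)), c(0, 12, 0))
})

test_that("missing image files give a manifest error listing offenders", {
  man <- data.frame(path = c("nope1.png", "nope2.png"), label = "C1")
  expect_error(train(small_model(), man), "missing image files.*nope1")
})

test_that("confusion-matrix metrics match hand-computed values on the toy matrix", {
  cm <- matrix(c(5, 2, 1, 4), 2, 2,
               dimnames = list(true = c("a", "b"), predicted = c("a", "b")))
  # rows: true a = (5, 1), true b = (2, 4)
  r <- suppressWarnings(metrics_from_cm(cm))
  expect_equal(r$accuracy, 75)
  expect_equal(r$per_class$precision[1], 100 * 5 / 7, tolerance = 1e-9)
  expect_equal(r$per_class$recall[1], 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(r$per_class$recall[2], 100 * 4 / 6, tolerance = 1e-9)
  expect_equal(r$per_class$specificity[1], 100 * 4 / 6, tolerance = 1e-9)
  expect_equal(r$macro_precision, 100 * (5 / 7 + 4 / 5) / 2, tolerance = 1e-9)
  expect_equal(r$macro_recall, 100 * (5 / 6 + 4 / 6) / 2, tolerance = 1e-9)
  p1 <- 5 / 7; r1 <- 5 / 6; p2 <- 4 / 5; r2 <- 4 / 6
  expect_equal(r$macro_f1,
               100 * (2 * p1 * r1 / (p1 + r1) + 2 * p2 * r2 / (p2 + r2)) / 2,
               tolerance = 1e-9)
})

test_that("a diagonal confusion matrix scores 100% on every metric", {
  cm <- diag(c(3L, 5L, 2L))
  r <- metrics_from_cm(cm)
  expect_equal(unlist(r[c("accuracy", "macro_precision", "macro_recall",
                          "macro_specificity", "macro_f1")]),
               c(accuracy = 100, macro_precision = 100, macro_recall = 100,
                 macro_specificity = 100, macro_f1 = 100))
})

test_that("metrics are invariant under simultaneous row/column permutation", {
  set.seed(31)
  cm <- matrix(sample(0:9, 16, replace = TRUE), 4, 4)
  diag(cm) <- diag(cm) + 5L
  perm <- c(3, 1, 4, 2)
  a <- metrics_from_cm(cm)
  b <- metrics_from_cm(cm[perm, perm])
  for (f in c("accuracy", "macro_precision", "macro_recall",
              "macro_specificity", "macro_f1"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
})

test_that("degenerate classes yield zero ratios with a warning, and empty matrices error", {
  cm <- matrix(c(3, 1, 0, 0), 2, 2)   # nothing predicted as class 2
  expect_warning(r <- metrics_from_cm(cm), "0/0")
  expect_true(r$degenerate)
  expect_equal(r$per_class$precision[2], 0)
  expect_error(metrics_from_cm(matrix(0L, 2, 2)), "empty")
  expect_error(metrics_from_cm(matrix(1, 2, 3)), "square")
})

test_that("accuracy and mean per-class recall are computed independently", {
  cm <- matrix(c(90, 5, 0, 5), 2, 2)  # unbalanced: 90 vs 10 items
  r <- metrics_from_cm(cm)
  expect_equal(r$accuracy, 95)
  expect_equal(r$macro_recall, 100 * (1 + 0.5) / 2)
  expect_false(isTRUE(all.equal(r$accuracy, r$macro_recall)))
})
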