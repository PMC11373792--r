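# Training regimen and confusion-matrix evaluation.

#' Training configuration
#'
#' Defaults follow the study regimen: SGD with learning rate 0.001,
#' momentum 0.9, weight decay 0.01, batch size 8, 50 epochs,
#' cross-entropy loss on softmax outputs.
#'
#' @param learning_rate Initial (and, by default, constant) learning
#'   rate; must be positive.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay coefficient.
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Number of epochs (>= 0; 0 returns the model unchanged).
#' @param lr_schedule `"constant"` (default) or `"step"` (divide by 10
#'   every `step_every` epochs).
#' @param step_every Epoch period of the step schedule.
#' @param rng_seed Seed for data order and any stochastic elements.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         weight_decay = 0.01, batch_size = 8L, epochs = 50L,
                         lr_schedule = c("constant", "step"), step_every = 20L,
                         rng_seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(learning_rate > 0, epochs >= 0L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_schedule = lr_schedule,
                 step_every = as.integer(step_every),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

# forward the whole set in chunks, returning mean CE loss and accuracy
.eval_pass <- function(model, x, y, batch_size = 32L) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0L
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    logits <- model$net$fwd(x[, , , b, drop = FALSE], training = FALSE)
    ce <- cross_entropy(logits, y[b])
    loss <- loss + ce$loss * length(b)
    correct <- correct + sum(max.col(t(logits), ties.method = "first") == y[b])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train a classifier on in-memory batches
#'
#' Runs the configured SGD regimen with per-epoch history; the best
#' validation-accuracy weights are restored at the end (and the final
#' epoch's metrics retained in the history).
#'
#' @param model A `seed_classifier`.
#' @param x Training batch `(H, W, 3, N)` of normalized inputs.
#' @param y Integer labels (1-based), length N.
#' @param x_val,y_val Validation set in the same format (optional; when
#'   absent the best epoch is chosen on training accuracy).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return The model, with a `history` data frame and `best_epoch`
#'   attached.
#' @export
fit_classifier <- function(model, x, y, x_val = NULL, y_val = NULL,
                           config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "seed_classifier"), inherits(config, "train_config"))
  n <- dim(x)[4]
  stopifnot(n >= 1L, length(y) == n)
  if (config$epochs == 0L) {
    model$history <- data.frame(epoch = integer(), lr = numeric(),
                                train_loss = numeric(), train_acc = numeric(),
                                val_loss = numeric(), val_acc = numeric())
    model$best_epoch <- NA_integer_
    return(model)
  }
  hist <- vector("list", config$epochs)
  best_metric <- -Inf; best_snap <- NULL; best_epoch <- NA_integer_
  with_seed(config$rng_seed, {
    for (ep in seq_len(config$epochs)) {
      lr <- config$learning_rate
      if (config$lr_schedule == "step")
        lr <- lr * 0.1^((ep - 1L) %/% config$step_every)
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0L
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        xb <- x[, , , b, drop = FALSE]
        zero_grads(model$net)
        logits <- model$net$fwd(xb, training = TRUE)
        ce <- cross_entropy(logits, y[b])
        if (!is.finite(ce$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        model$net$bwd(ce$dlogits)
        sgd_step(model$net, lr, config$momentum, config$weight_decay)
        ep_loss <- ep_loss + ce$loss * length(b)
        ep_correct <- ep_correct + sum(max.col(t(logits), ties.method = "first") == y[b])
      }
      va <- if (!is.null(x_val)) .eval_pass(model, x_val, y_val)
            else list(loss = NA_real_, acc = NA_real_)
      row <- data.frame(epoch = ep, lr = lr, train_loss = ep_loss / n,
                        train_acc = ep_correct / n,
                        val_loss = va$loss, val_acc = va$acc)
      hist[[ep]] <- row
      metric <- if (!is.null(x_val)) va$acc else row$train_acc
      if (metric > best_metric) {
        best_metric <- metric
        best_snap <- snapshot_params(model$net)
        best_epoch <- ep
      }
      if (verbose)
        message(sprintf("epoch %3d  lr %.4g  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
                        ep, lr, row$train_loss, row$train_acc, row$val_loss, row$val_acc))
    }
  })
  if (!is.null(best_snap)) restore_params(model$net, best_snap)
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best_epoch
  model
}

# load a manifest's images as a normalized (S, S, 3, N) batch
.load_batch <- function(manifest, model, labels = NULL) {
  S <- model$config$input_size
  n <- nrow(manifest)
  x <- array(0, c(S, S, 3L, n))
  for (i in seq_len(n)) {
    px <- read_image_png(manifest$path[i])
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
    if (dim(px)[1] != S || dim(px)[2] != S)
      px <- clip255(EBImage::resize(px, w = S, h = S))
    x[, , , i] <- px
  }
  y <- match(manifest$label, model$classes)
  if (any(is.na(y)))
    stop("manifest contains labels absent from the model head: ",
         paste(unique(manifest$label[is.na(y)]), collapse = ", "))
  list(x = x, y = y)
}

#' Train a classifier from train/validation manifests
#'
#' Loads the crops named in the manifests, resizes them to the model's
#' input size, fits the normalization constants on the training split,
#' stores them with the model, and runs [fit_classifier()].
#'
#' @param model A `seed_classifier` whose `classes` cover the manifest
#'   labels (set from the training manifest when still at defaults).
#' @param train_manifest,val_manifest Data frames with `path` and
#'   `label` columns.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained model with `history` and `best_epoch`.
#' @export
train <- function(model, train_manifest, val_manifest = NULL,
                  config = train_config(), verbose = FALSE) {
  stopifnot(nrow(train_manifest) > 0L)
  missing <- !file.exists(train_manifest$path)
  if (any(missing))
    stop("missing image files: ", paste(utils::head(train_manifest$path[missing], 5), collapse = ", "))
  labs <- sort(unique(train_manifest$label))
  if (length(labs) == length(model$classes)) model$classes <- labs
  tr <- .load_batch(train_manifest, model)
  norm <- list(mean = vapply(1:3, function(ch) mean(tr$x[, , ch, ]), numeric(1)),
               sd = vapply(1:3, function(ch) max(stats::sd(tr$x[, , ch, ]), 1e-6), numeric(1)))
  model$norm <- norm
  xtr <- normalize_batch(tr$x, norm)
  xv <- NULL; yv <- NULL
  if (!is.null(val_manifest) && nrow(val_manifest) > 0L) {
    va <- .load_batch(val_manifest, model)
    xv <- normalize_batch(va$x, norm); yv <- va$y
  }
  fit_classifier(model, xtr, tr$y, xv, yv, config, verbose)
}

#' Confusion matrix from truth and predictions
#'
#' @param true,pred Vectors of class labels (character or factor).
#' @param classes Class levels fixing row/column order.
#' @return A `k x k` integer matrix of class `confusion_matrix`; rows are
#'   true classes, columns predictions.
#' @export
confusion_matrix <- function(true, pred, classes = sort(unique(c(true, pred)))) {
  cm <- table(factor(true, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Evaluate a classifier on a test manifest
#'
#' One prediction per item (argmax of softmax; ties resolve to the
#' lowest class index).
#'
#' @param model A trained `seed_classifier`.
#' @param test_manifest Data frame with `path` and `label`.
#' @return A [confusion_matrix()] whose rows/columns follow
#'   `model$classes`.
#' @export
evaluate <- function(model, test_manifest) {
  te <- .load_batch(test_manifest, model)
  x <- normalize_batch(te$x, model$norm)
  n <- dim(x)[4]
  pred <- integer(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / 32L))) {
    p <- predict_classifier(model, x[, , , b, drop = FALSE])
    pred[b] <- max.col(t(p), ties.method = "first")
  }
  confusion_matrix(model$classes[te$y], model$classes[pred], model$classes)
}

#' Confusion-matrix statistics
#'
#' Per class k: TP is the diagonal entry, FP the rest of column k, FN
#' the rest of row k, TN the remainder. Precision = TP/(TP+FP),
#' recall = TP/(TP+FN), specificity = TN/(TN+FP),
#' F1 = 2PR/(P+R); macro values are unweighted class means. Per-class
#' accuracy in the per-variety sense is the class recall. Undefined 0/0
#' ratios are reported as 0 with `degenerate = TRUE`.
#'
#' @param cm A [confusion_matrix()] (or plain square count matrix).
#' @return A list of class `metrics_report`: `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_specificity`, `macro_f1`
#'   (all percentages), `per_class` data frame, and `degenerate` flag.
#' @export
metrics_from_cm <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 1L)
    stop("cm must be a square matrix")
  total <- sum(m)
  if (total == 0L) stop("empty confusion matrix")
  k <- nrow(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  degenerate <- any((tp + fp) == 0) || any((tp + fn) == 0)
  if (degenerate)
    warning("confusion matrix has a class with no predictions or no items; 0/0 ratios reported as 0")
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  classes <- rownames(m) %||% paste0("C", seq_len(k))
  structure(list(
    accuracy = 100 * sum(tp) / total,
    macro_precision = 100 * mean(precision),
    macro_recall = 100 * mean(recall),
    macro_specificity = 100 * mean(specificity),
    macro_f1 = 100 * mean(f1),
    per_class = data.frame(class = classes,
                           accuracy = 100 * recall,
                           precision = 100 * precision,
                           recall = 100 * recall,
                           specificity = 100 * specificity,
                           f1 = 100 * f1, row.names = NULL),
    degenerate = degenerate), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  macro precision %.2f%%  recall %.2f%%  specificity %.2f%%  F1 %.2f%%\n",
              x$accuracy, x$macro_precision, x$macro_recall,
              x$macro_specificity, x$macro_f1))
  invisible(x)
}
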