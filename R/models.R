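# Residual classifier families and the attention/deformable-conv
# modifications: plain depths 18/34/50/101, CBAM-ResNet34, SE-ResNet34
# and SE-ResNet34-DCN, plus a scaled-down SE-residual variant for
# desk-scale experiments.

.model_families <- c("resnet18", "resnet34", "resnet50", "resnet101",
                     "cbam_resnet34", "se_resnet34", "se_resnet34_dcn",
                     "se_resnet_small")

#' Model configuration
#'
#' @param family One of `resnet18`, `resnet34`, `resnet50`, `resnet101`,
#'   `cbam_resnet34`, `se_resnet34`, `se_resnet34_dcn`, or
#'   `se_resnet_small` (a narrow three-stage SE variant for small
#'   inputs).
#' @param num_classes Number of output classes (>= 2; the seed study uses
#'   7).
#' @param input_size Expected square input side (default 224; the small
#'   family defaults to 64).
#' @param se_reduction SE channel-reduction ratio (default 16).
#' @param cbam_kernel CBAM spatial-attention kernel size (odd, default 7).
#' @param base_channels Stem width of the small family (default 8).
#' @param rng_seed Seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(family = "resnet34", num_classes = 7L,
                         input_size = if (family == "se_resnet_small") 64L else 224L,
                         se_reduction = 16L, cbam_kernel = 7L,
                         base_channels = 8L, rng_seed = 1L) {
  family <- match.arg(family, .model_families)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (cbam_kernel %% 2L == 0L) stop("cbam_kernel must be odd")
  structure(list(family = family, num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 se_reduction = as.integer(se_reduction),
                 cbam_kernel = as.integer(cbam_kernel),
                 base_channels = as.integer(base_channels),
                 rng_seed = as.integer(rng_seed)),
            class = "model_config")
}

# --- residual blocks -------------------------------------------------------

basic_block_module <- function(cin, cout, stride = 1L, use_dcn = FALSE) {
  m <- new_module("basic_block")
  conv1 <- if (use_dcn) deform_conv_module(3L, 3L, cin, cout, stride, 1L)
           else conv_module(3L, 3L, cin, cout, stride, 1L)
  m$children <- list(conv1 = conv1, bn1 = bn_module(cout),
                     conv2 = conv_module(3L, 3L, cout, cout, 1L, 1L),
                     bn2 = bn_module(cout))
  m$downsample <- stride != 1L || cin != cout
  if (m$downsample)
    m$children <- c(m$children, list(down_conv = conv_module(1L, 1L, cin, cout, stride, 0L),
                                     down_bn = bn_module(cout)))
  ch <- m$children
  m$fwd <- function(x, training = TRUE) {
    h <- ch$bn1$fwd(ch$conv1$fwd(x, training), training)
    r1 <- h > 0; h <- h * r1
    h <- ch$bn2$fwd(ch$conv2$fwd(h, training), training)
    s <- if (m$downsample) ch$down_bn$fwd(ch$down_conv$fwd(x, training), training) else x
    y <- h + s
    r2 <- y > 0
    if (training) m$cache <- list(r1 = r1, r2 = r2)
    y * r2
  }
  m$bwd <- function(dy) {
    dy <- dy * m$cache$r2
    ds <- dy
    dh <- ch$conv2$bwd(ch$bn2$bwd(dy))
    dh <- dh * m$cache$r1
    dx <- ch$conv1$bwd(ch$bn1$bwd(dh))
    dx <- dx + if (m$downsample) ch$down_conv$bwd(ch$down_bn$bwd(ds)) else ds
    m$cache <- NULL
    dx
  }
  m
}

bottleneck_module <- function(cin, cmid, stride = 1L) {
  m <- new_module("bottleneck")
  cout <- 4L * cmid
  m$children <- list(
    conv1 = conv_module(1L, 1L, cin, cmid, 1L, 0L), bn1 = bn_module(cmid),
    conv2 = conv_module(3L, 3L, cmid, cmid, stride, 1L), bn2 = bn_module(cmid),
    conv3 = conv_module(1L, 1L, cmid, cout, 1L, 0L), bn3 = bn_module(cout))
  m$downsample <- stride != 1L || cin != cout
  if (m$downsample)
    m$children <- c(m$children, list(down_conv = conv_module(1L, 1L, cin, cout, stride, 0L),
                                     down_bn = bn_module(cout)))
  ch <- m$children
  m$fwd <- function(x, training = TRUE) {
    h <- ch$bn1$fwd(ch$conv1$fwd(x, training), training)
    r1 <- h > 0; h <- h * r1
    h <- ch$bn2$fwd(ch$conv2$fwd(h, training), training)
    r2 <- h > 0; h <- h * r2
    h <- ch$bn3$fwd(ch$conv3$fwd(h, training), training)
    s <- if (m$downsample) ch$down_bn$fwd(ch$down_conv$fwd(x, training), training) else x
    y <- h + s
    r3 <- y > 0
    if (training) m$cache <- list(r1 = r1, r2 = r2, r3 = r3)
    y * r3
  }
  m$bwd <- function(dy) {
    dy <- dy * m$cache$r3
    ds <- dy
    dh <- ch$conv3$bwd(ch$bn3$bwd(dy))
    dh <- dh * m$cache$r2
    dh <- ch$conv2$bwd(ch$bn2$bwd(dh))
    dh <- dh * m$cache$r1
    dx <- ch$conv1$bwd(ch$bn1$bwd(dh))
    dx <- dx + if (m$downsample) ch$down_conv$bwd(ch$down_bn$bwd(ds)) else ds
    m$cache <- NULL
    dx
  }
  m
}

make_stage <- function(n_blocks, cin, cout, stride, bottleneck = FALSE,
                       dcn_first = FALSE) {
  blocks <- list()
  for (i in seq_len(n_blocks)) {
    s <- if (i == 1L) stride else 1L
    ci <- if (i == 1L) cin else if (bottleneck) 4L * cout else cout
    blocks[[i]] <- if (bottleneck) bottleneck_module(ci, cout, s)
                   else basic_block_module(ci, cout, s, use_dcn = dcn_first && i == 1L)
  }
  sequential_module(blocks)
}

# --- family assembly -------------------------------------------------------

.family_layout <- list(
  resnet18 = list(blocks = c(2, 2, 2, 2), bottleneck = FALSE),
  resnet34 = list(blocks = c(3, 4, 6, 3), bottleneck = FALSE),
  resnet50 = list(blocks = c(3, 4, 6, 3), bottleneck = TRUE),
  resnet101 = list(blocks = c(3, 4, 23, 3), bottleneck = TRUE))

.build_backbone <- function(config) {
  family <- config$family
  base <- sub("^(cbam_|se_)", "", sub("_dcn$", "", family))
  if (base %in% c("resnet34")) lay <- .family_layout$resnet34
  else lay <- .family_layout[[base]]
  if (is.null(lay)) stop("no layout for family ", family)
  attention <- if (startsWith(family, "cbam_")) "cbam"
               else if (startsWith(family, "se_")) "se" else "none"
  use_dcn <- endsWith(family, "_dcn")
  widths <- c(64L, 128L, 256L, 512L)
  expansion <- if (lay$bottleneck) 4L else 1L

  att <- function(C) switch(attention,
    se = se_module(C, config$se_reduction),
    cbam = cbam_module(C, config$cbam_kernel, config$se_reduction),
    none = NULL)

  mods <- list(stem_conv = conv_module(7L, 7L, 3L, 64L, 2L, 3L),
               stem_bn = bn_module(64L), stem_relu = relu_module(),
               stem_pool = maxpool_module(3L, 2L, 1L))
  # first attention point: the stem max-pool output
  if (attention != "none") mods$att_pool <- att(64L)
  cin <- 64L
  for (st in 1:4) {
    mods[[paste0("stage", st)]] <- make_stage(
      lay$blocks[st], cin, widths[st], stride = if (st == 1L) 1L else 2L,
      bottleneck = lay$bottleneck, dcn_first = use_dcn && st == 1L)
    cin <- widths[st] * expansion
    # second attention point: after the Conv2 residual stage
    if (st == 1L && attention != "none")
      mods[[paste0("att_stage", st)]] <- att(cin)
  }
  mods$gap <- gap_module()
  mods$fc <- dense_module(512L * expansion, config$num_classes)
  sequential_module(mods)
}

.build_small_se <- function(config) {
  b <- config$base_channels
  mods <- list(stem_conv = conv_module(3L, 3L, 3L, b, 1L, 1L),
               stem_bn = bn_module(b), stem_relu = relu_module(),
               stem_pool = maxpool_module(3L, 2L, 1L),
               att_pool = se_module(b, config$se_reduction),
               stage1 = make_stage(1L, b, b, 1L),
               att_stage1 = se_module(b, config$se_reduction),
               stage2 = make_stage(1L, b, 2L * b, 2L),
               stage3 = make_stage(1L, 2L * b, 4L * b, 2L),
               gap = gap_module(),
               fc = dense_module(4L * b, config$num_classes))
  sequential_module(mods)
}

.wrap_classifier <- function(net, config) {
  structure(list(net = net, config = config,
                 classes = paste0("C", seq_len(config$num_classes)),
                 norm = list(mean = rep(0, 3), sd = rep(255, 3))),
            class = "seed_classifier")
}

#' Build a plain residual classifier
#'
#' Standard topology: 7x7/2 stem convolution, batch norm, ReLU, 3x3/2
#' max pool, four residual stages (basic blocks for depths 18/34,
#' bottlenecks for 50/101), global average pooling and a fully connected
#' head. Softmax is applied at inference ([predict_classifier()]);
#' training works on logits with cross-entropy.
#'
#' @param config A [model_config()] whose family is one of the four
#'   plain depths.
#' @return A `seed_classifier`.
#' @export
build_resnet <- function(config = model_config("resnet34")) {
  stopifnot(inherits(config, "model_config"))
  if (!config$family %in% names(.family_layout))
    stop("build_resnet handles the plain depths; use build_modified_model for ",
         config$family)
  net <- with_seed(config$rng_seed, .build_backbone(config))
  .wrap_classifier(net, config)
}

#' Build an attention/deformable-conv modified classifier
#'
#' `cbam_resnet34` inserts CBAM at the stem max-pool output and after
#' the Conv2 residual stage; `se_resnet34` places SE modules at the same
#' two points (two SE modules total); `se_resnet34_dcn` additionally
#' replaces the first 3x3 convolution of the first Conv2 block with a
#' deformable convolution. `se_resnet_small` is the scaled-down
#' three-stage SE variant.
#'
#' @param config A [model_config()] with a modified family.
#' @return A `seed_classifier`.
#' @export
build_modified_model <- function(config = model_config("se_resnet34_dcn")) {
  stopifnot(inherits(config, "model_config"))
  if (config$family %in% names(.family_layout))
    stop("use build_resnet for the plain depths")
  net <- with_seed(config$rng_seed,
                   if (config$family == "se_resnet_small") .build_small_se(config)
                   else .build_backbone(config))
  .wrap_classifier(net, config)
}

#' Build any configured classifier
#'
#' Dispatches to [build_resnet()] or [build_modified_model()] by family.
#'
#' @param config A [model_config()].
#' @return A `seed_classifier`.
#' @export
build_classifier <- function(config) {
  if (config$family %in% names(.family_layout)) build_resnet(config)
  else build_modified_model(config)
}

#' @export
print.seed_classifier <- function(x, ...) {
  cat(sprintf("seed_classifier: %s, %d classes, input %dx%dx3, %s parameters\n",
              x$config$family, x$config$num_classes, x$config$input_size,
              x$config$input_size, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Census of a classifier's modules
#'
#' Counts module kinds in the network tree; used to verify the stated
#' composition of the modified families (e.g. the SE + deformable
#' variant has exactly two SE modules, one deformable convolution and
#' one fully connected layer).
#'
#' @param model A `seed_classifier`.
#' @return Named integer vector of module-kind counts.
#' @export
module_census <- function(model) {
  kinds <- vapply(collect_modules(model$net), function(m) m$kind, character(1))
  table(kinds)
}

#' Forward pass returning class probabilities
#'
#' @param model A `seed_classifier`.
#' @param x Input batch `(H, W, 3, N)`, already normalized, or a single
#'   `(H, W, 3)` image.
#' @param normalize If `TRUE`, applies the model's stored channel
#'   mean/sd normalization to raw 0-255 input first.
#' @return `(num_classes, N)` matrix of softmax probabilities.
#' @export
predict_classifier <- function(model, x, normalize = FALSE) {
  stopifnot(inherits(model, "seed_classifier"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (normalize) x <- normalize_batch(x, model$norm)
  logits <- model$net$fwd(x, training = FALSE)
  softmax_probs(logits)
}

normalize_batch <- function(x, norm) {
  for (ch in 1:3)
    x[, , ch, ] <- (x[, , ch, ] - norm$mean[ch]) / norm$sd[ch]
  x
}

# deep copy / restore of all parameters plus batch-norm running
# statistics (a best-epoch snapshot must carry both, or restored weights
# would run under statistics collected from later epochs)
snapshot_params <- function(root) {
  lapply(collect_modules(root), function(m)
    list(params = m$params,
         rm = if (m$kind == "batchnorm") m$running_mean,
         rv = if (m$kind == "batchnorm") m$running_var))
}
restore_params <- function(root, snap) {
  mods <- collect_modules(root)
  for (i in seq_along(mods)) {
    mods[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$rm)) {
      mods[[i]]$running_mean <- snap[[i]]$rm
      mods[[i]]$running_var <- snap[[i]]$rv
    }
  }
  invisible(NULL)
}

#' Save a classifier checkpoint
#'
#' Self-describing single-file checkpoint: weights, batch-norm running
#' statistics, the [model_config()] and the normalization constants.
#'
#' @param model A `seed_classifier`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  mods <- collect_modules(model$net)
  state <- list(config = model$config, norm = model$norm, classes = model$classes,
                params = lapply(mods, function(m) m$params),
                buffers = lapply(mods, function(m)
                  if (m$kind == "batchnorm")
                    list(mean = m$running_mean, var = m$running_var) else NULL))
  saveRDS(state, path)
  invisible(path)
}

#' Load a classifier checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `seed_classifier` with restored weights.
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  model <- build_classifier(state$config)
  mods <- collect_modules(model$net)
  stopifnot(length(mods) == length(state$params))
  for (i in seq_along(mods)) {
    mods[[i]]$params <- state$params[[i]]
    if (!is.null(state$buffers[[i]])) {
      mods[[i]]$running_mean <- state$buffers[[i]]$mean
      mods[[i]]$running_var <- state$buffers[[i]]$var
    }
  }
  model$norm <- state$norm
  model$classes <- state$classes
  model
}
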