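# Minimal reverse-mode CNN engine in vectorized base R.
#
# Feature maps are 4-D arrays (H, W, C, N). Convolution is computed as a
# sum over kernel taps of strided-slice GEMMs, which keeps every heavy
# operation inside BLAS. Each layer is a mutable environment (class
# "nn_module") with fwd(x, training) and bwd(dy); containers compose
# them. This engine exists because the attention/deformable residual
# classifiers are the package's core method and are trained end-to-end
# here.

new_module <- function(kind) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$params <- list()
  m$grads <- list()
  m$momentum_buf <- list()
  m$children <- list()
  class(m) <- "nn_module"
  m
}

# recursive collection of modules holding parameters
collect_modules <- function(m) {
  out <- list(m)
  for (ch in m$children) out <- c(out, collect_modules(ch))
  out
}

#' Number of trainable parameters of a classifier
#'
#' @param model A model from [build_resnet()] or relatives, or a raw
#'   `nn_module`.
#' @return Integer count of trainable scalars.
#' @export
n_parameters <- function(model) {
  root <- if (inherits(model, "seed_classifier")) model$net else model
  sum(vapply(collect_modules(root),
             function(m) sum(vapply(m$params, length, integer(1))), numeric(1)))
}

zero_grads <- function(root) {
  for (m in collect_modules(root))
    m$grads <- lapply(m$params, function(p) { p[] <- 0; p })  # keep exact shape
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- low-level ops ---------------------------------------------------------

pad_hw <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# forward convolution; returns y and the padded input for backward
conv2d_fwd <- function(x, W, b, stride, pad) {
  d <- dim(x); Cin <- d[3]; N <- d[4]
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  xp <- pad_hw(x, pad)
  Hout <- conv_out_dim(d[1], kh, stride, pad)
  Wout <- conv_out_dim(d[2], kw, stride, pad)
  M <- Hout * Wout * N
  ym <- matrix(0, M, Cout)
  for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
    rs <- seq.int(ki, by = stride, length.out = Hout)
    cs <- seq.int(kj, by = stride, length.out = Wout)
    xs <- xp[rs, cs, , , drop = FALSE]
    xm <- matrix(aperm(xs, c(1, 2, 4, 3)), M, Cin)
    ym <- ym + xm %*% matrix(W[ki, kj, , ], Cin, Cout)
  }
  ym <- ym + rep(b, each = M)
  y <- aperm(array(ym, c(Hout, Wout, N, Cout)), c(1, 2, 4, 3))
  list(y = y, xp = xp, Hout = Hout, Wout = Wout)
}

conv2d_bwd <- function(dy, xp, W, stride, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  Hout <- dim(dy)[1]; Wout <- dim(dy)[2]; N <- dim(dy)[4]
  M <- Hout * Wout * N
  dm <- matrix(aperm(dy, c(1, 2, 4, 3)), M, Cout)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(xp))
  for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
    rs <- seq.int(ki, by = stride, length.out = Hout)
    cs <- seq.int(kj, by = stride, length.out = Wout)
    xs <- xp[rs, cs, , , drop = FALSE]
    xm <- matrix(aperm(xs, c(1, 2, 4, 3)), M, Cin)
    dW[ki, kj, , ] <- crossprod(xm, dm)
    contrib <- dm %*% t(matrix(W[ki, kj, , ], Cin, Cout))
    ca <- aperm(array(contrib, c(Hout, Wout, N, Cin)), c(1, 2, 4, 3))
    dxp[rs, cs, , ] <- dxp[rs, cs, , , drop = FALSE] + ca
  }
  db <- colSums(dm)
  d <- dim(xp)
  dx <- if (pad > 0L)
    dxp[pad + seq_len(d[1] - 2L * pad), pad + seq_len(d[2] - 2L * pad), , , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

# --- layers ----------------------------------------------------------------

conv_module <- function(kh, kw, cin, cout, stride = 1L, pad = 0L, zero_init = FALSE) {
  m <- new_module("conv")
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$params$W <- if (zero_init) array(0, c(kh, kw, cin, cout))
                else he_init(c(kh, kw, cin, cout), kh * kw * cin)
  m$params$b <- numeric(cout)
  m$fwd <- function(x, training = TRUE) {
    r <- conv2d_fwd(x, m$params$W, m$params$b, m$stride, m$pad)
    m$cache <- r["xp"]
    r$y
  }
  m$bwd <- function(dy) {
    r <- conv2d_bwd(dy, m$cache$xp, m$params$W, m$stride, m$pad)
    m$grads$W <- m$grads$W + r$dW
    m$grads$b <- m$grads$b + r$db
    m$cache <- NULL
    r$dx
  }
  m
}

bn_module <- function(C, momentum = 0.1, eps = 1e-5) {
  m <- new_module("batchnorm")
  m$params$gamma <- rep(1, C); m$params$beta <- rep(0, C)
  m$running_mean <- rep(0, C); m$running_var <- rep(1, C)
  m$momentum <- momentum; m$eps <- eps
  m$fwd <- function(x, training = TRUE) {
    d <- dim(x); M <- d[1] * d[2] * d[4]; C <- d[3]
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), M, C)
    if (training) {
      mu <- colMeans(xm)
      xc <- xm - rep(mu, each = M)
      v <- colMeans(xc^2)
      m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
      m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * v
    } else {
      mu <- m$running_mean; v <- m$running_var
      xc <- xm - rep(mu, each = M)
    }
    inv <- 1 / sqrt(v + m$eps)
    xhat <- xc * rep(inv, each = M)
    ym <- xhat * rep(m$params$gamma, each = M) + rep(m$params$beta, each = M)
    if (training) m$cache <- list(xhat = xhat, inv = inv, dims = d)
    aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  }
  m$bwd <- function(dy) {
    d <- m$cache$dims; M <- d[1] * d[2] * d[4]; C <- d[3]
    dym <- matrix(aperm(dy, c(1, 2, 4, 3)), M, C)
    xhat <- m$cache$xhat; inv <- m$cache$inv
    m$grads$gamma <- m$grads$gamma + colSums(dym * xhat)
    m$grads$beta <- m$grads$beta + colSums(dym)
    dxhat <- dym * rep(m$params$gamma, each = M)
    # dx = inv/M * (M*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    s1 <- colSums(dxhat); s2 <- colSums(dxhat * xhat)
    dxm <- (dxhat - rep(s1 / M, each = M) - xhat * rep(s2 / M, each = M)) *
      rep(inv, each = M)
    m$cache <- NULL
    aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  }
  m
}

relu_module <- function() {
  m <- new_module("relu")
  m$fwd <- function(x, training = TRUE) {
    if (training) m$cache <- list(mask = x > 0)
    x * (x > 0)
  }
  m$bwd <- function(dy) {
    dx <- dy * m$cache$mask
    m$cache <- NULL
    dx
  }
  m
}

maxpool_module <- function(k = 3L, stride = 2L, pad = 1L) {
  m <- new_module("maxpool")
  m$k <- as.integer(k); m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    xp <- pad_hw(x, m$pad, value = -Inf)
    Hout <- conv_out_dim(d[1], m$k, m$stride, m$pad)
    Wout <- conv_out_dim(d[2], m$k, m$stride, m$pad)
    y <- array(-Inf, c(Hout, Wout, d[3], d[4]))
    arg <- array(0L, dim(y))
    tap <- 0L
    for (ki in seq_len(m$k)) for (kj in seq_len(m$k)) {
      tap <- tap + 1L
      rs <- seq.int(ki, by = m$stride, length.out = Hout)
      cs <- seq.int(kj, by = m$stride, length.out = Wout)
      xs <- xp[rs, cs, , , drop = FALSE]
      upd <- xs > y
      y[upd] <- xs[upd]
      arg[upd] <- tap
    }
    if (training) m$cache <- list(arg = arg, in_dim = d, pdim = dim(xp))
    y
  }
  m$bwd <- function(dy) {
    d <- m$cache$in_dim
    dxp <- array(0, m$cache$pdim)
    Hout <- dim(dy)[1]; Wout <- dim(dy)[2]
    tap <- 0L
    for (ki in seq_len(m$k)) for (kj in seq_len(m$k)) {
      tap <- tap + 1L
      rs <- seq.int(ki, by = m$stride, length.out = Hout)
      cs <- seq.int(kj, by = m$stride, length.out = Wout)
      sel <- m$cache$arg == tap
      if (!any(sel)) next
      dxp[rs, cs, , ] <- dxp[rs, cs, , , drop = FALSE] + dy * sel
    }
    m$cache <- NULL
    if (m$pad > 0L)
      dxp[m$pad + seq_len(d[1]), m$pad + seq_len(d[2]), , , drop = FALSE]
    else dxp
  }
  m
}

gap_module <- function() {
  m <- new_module("global_avgpool")
  m$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    if (training) m$cache <- list(d = d)
    y <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
    dim(y) <- c(d[3], d[4])
    y
  }
  m$bwd <- function(dy) {
    d <- m$cache$d
    m$cache <- NULL
    array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
  }
  m
}

dense_module <- function(fin, fout) {
  m <- new_module("dense")
  m$params$W <- he_init(c(fout, fin), fin)
  m$params$b <- numeric(fout)
  m$fwd <- function(x, training = TRUE) {
    if (training) m$cache <- list(x = x)
    m$params$W %*% x + m$params$b
  }
  m$bwd <- function(dy) {
    m$grads$W <- m$grads$W + dy %*% t(m$cache$x)
    m$grads$b <- m$grads$b + rowSums(dy)
    dx <- t(m$params$W) %*% dy
    m$cache <- NULL
    dx
  }
  m
}

sequential_module <- function(children) {
  m <- new_module("sequential")
  m$children <- children
  m$fwd <- function(x, training = TRUE) {
    for (ch in m$children) x <- ch$fwd(x, training)
    x
  }
  m$bwd <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$bwd(dy)
    dy
  }
  m
}

# softmax cross-entropy on logits (K x N); labels are 1-based integers
softmax_probs <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

cross_entropy <- function(logits, labels) {
  N <- ncol(logits)
  p <- softmax_probs(logits)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N)
}

# SGD with momentum and L2 weight decay (decoupled in the classical
# sense: decay added to the gradient before the momentum update)
sgd_step <- function(root, lr, momentum = 0.9, weight_decay = 0) {
  for (m in collect_modules(root)) {
    for (nm in names(m$params)) {
      g <- m$grads[[nm]] + weight_decay * m$params[[nm]]
      buf <- m$momentum_buf[[nm]]
      if (is.null(buf)) buf <- g else buf <- momentum * buf + g
      m$momentum_buf[[nm]] <- buf
      m$params[[nm]] <- m$params[[nm]] - lr * buf
    }
  }
  invisible(NULL)
}
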