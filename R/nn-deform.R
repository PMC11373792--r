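# Deformable convolution: each kernel tap samples the input at its
# regular grid position plus a learned fractional offset, via bilinear
# interpolation (zero beyond borders). Offsets are predicted by a
# companion convolution whose weights start at zero, so training begins
# at exact equivalence with a standard convolution.

#' Deformable convolution module
#'
#' Offsets are produced by an internal `kh x kw` convolution with
#' `2 * kh * kw` output channels (a (dy, dx) pair per tap, tap order
#' row-major over the kernel), zero-initialized. With all offsets zero
#' the output equals a standard convolution with the same weights; this
#' degenerate equivalence is the module's defining invariant.
#'
#' @param kh,kw Kernel height and width.
#' @param cin,cout Input and output channels.
#' @param stride,pad Convolution stride and zero padding.
#' @return An `nn_module`.
#' @export
deform_conv_module <- function(kh, kw, cin, cout, stride = 1L, pad = 1L) {
  m <- new_module("deform_conv")
  m$kh <- as.integer(kh); m$kw <- as.integer(kw)
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$params$W <- he_init(c(kh, kw, cin, cout), kh * kw * cin)
  m$params$b <- numeric(cout)
  m$children <- list(offset_conv = conv_module(kh, kw, cin, 2L * kh * kw,
                                               stride = stride, pad = pad,
                                               zero_init = TRUE))
  m$fwd <- function(x, training = TRUE) {
    deform_fwd(m, x, training)
  }
  m$bwd <- function(dy) deform_bwd(m, dy)
  m
}

# shared forward used by both the module and the functional interface
deform_fwd <- function(m, x, training = TRUE, offsets = NULL) {
  d <- dim(x); Cin <- d[3]; N <- d[4]
  kh <- m$kh; kw <- m$kw; Cout <- dim(m$params$W)[4]
  if (is.null(offsets)) offsets <- m$children$offset_conv$fwd(x, training)
  xp <- pad_hw(x, m$pad)
  Hp <- dim(xp)[1]; Wp <- dim(xp)[2]
  Hout <- conv_out_dim(d[1], kh, m$stride, m$pad)
  Wout <- conv_out_dim(d[2], kw, m$stride, m$pad)
  M <- Hout * Wout * N
  stopifnot(dim(offsets)[1] == Hout, dim(offsets)[2] == Wout,
            dim(offsets)[3] == 2L * kh * kw)
  xp_flat <- as.vector(xp)
  n_off <- rep(seq_len(N), each = Hout * Wout)        # (i,j,n) flattened order
  plane <- (n_off - 1L) * Hp * Wp * Cin
  chan_off <- (seq_len(Cin) - 1L) * Hp * Wp
  ym <- matrix(0, M, Cout)
  taps <- vector("list", kh * kw)
  tap <- 0L
  for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
    tap <- tap + 1L
    base_y <- (seq_len(Hout) - 1L) * m$stride + ki
    base_x <- (seq_len(Wout) - 1L) * m$stride + kj
    py <- array(0, c(Hout, Wout, N)); py[] <- base_y
    px <- array(0, c(Hout, Wout, N)); px[] <- rep(base_x, each = Hout)
    py <- as.vector(py) + as.vector(offsets[, , 2L * tap - 1L, ])
    px <- as.vector(px) + as.vector(offsets[, , 2L * tap, ])
    y0 <- floor(py); x0 <- floor(px)
    fy <- py - y0; fx <- px - x0
    corners <- list(
      list(y = y0,      x = x0,      w = (1 - fy) * (1 - fx)),
      list(y = y0 + 1L, x = x0,      w = fy * (1 - fx)),
      list(y = y0,      x = x0 + 1L, w = (1 - fy) * fx),
      list(y = y0 + 1L, x = x0 + 1L, w = fy * fx))
    Mt <- matrix(0, M, Cin)
    cvals <- vector("list", 4L)
    cidx <- vector("list", 4L)
    for (q in 1:4) {
      cy <- corners[[q]]$y; cx <- corners[[q]]$x
      valid <- cy >= 1 & cy <= Hp & cx >= 1 & cx <= Wp
      cys <- ifelse(valid, cy, 1); cxs <- ifelse(valid, cx, 1)
      base_idx <- cys + (cxs - 1) * Hp + plane
      idx <- outer(base_idx, chan_off, "+")
      vals <- matrix(xp_flat[idx], M, Cin) * valid    # column-major recycle
      cvals[[q]] <- vals
      cidx[[q]] <- list(idx = idx, valid = valid)
      Mt <- Mt + corners[[q]]$w * vals
    }
    ym <- ym + Mt %*% matrix(m$params$W[ki, kj, , ], Cin, Cout)
    if (training)
      taps[[tap]] <- list(Mt = Mt, cvals = cvals, cidx = cidx,
                          w = lapply(corners, `[[`, "w"), fy = fy, fx = fx)
  }
  ym <- ym + rep(m$params$b, each = M)
  if (training)
    m$cache <- list(taps = taps, d = d, pdim = dim(xp), Hout = Hout,
                    Wout = Wout, N = N)
  aperm(array(ym, c(Hout, Wout, N, Cout)), c(1, 2, 4, 3))
}

deform_bwd <- function(m, dy) {
  cc <- m$cache
  kh <- m$kh; kw <- m$kw
  Cin <- dim(m$params$W)[3]; Cout <- dim(m$params$W)[4]
  Hout <- cc$Hout; Wout <- cc$Wout; N <- cc$N
  M <- Hout * Wout * N
  dm <- matrix(aperm(dy, c(1, 2, 4, 3)), M, Cout)
  dxp_flat <- numeric(prod(cc$pdim))
  doff <- array(0, c(Hout, Wout, 2L * kh * kw, N))
  tap <- 0L
  for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
    tap <- tap + 1L
    tc <- cc$taps[[tap]]
    Wt <- matrix(m$params$W[ki, kj, , ], Cin, Cout)
    m$grads$W[ki, kj, , ] <- m$grads$W[ki, kj, , ] +
      array(crossprod(tc$Mt, dm), c(Cin, Cout))
    G <- dm %*% t(Wt)                                  # (M, Cin)
    # gradient to the input through each corner
    for (q in 1:4) {
      contrib <- G * tc$w[[q]] * tc$cidx[[q]]$valid
      agg <- rowsum(as.vector(contrib), group = as.vector(tc$cidx[[q]]$idx))
      tgt <- as.numeric(rownames(agg))
      dxp_flat[tgt] <- dxp_flat[tgt] + agg[, 1]
    }
    # gradient to the offsets through the bilinear weights
    v00 <- tc$cvals[[1]]; v10 <- tc$cvals[[2]]
    v01 <- tc$cvals[[3]]; v11 <- tc$cvals[[4]]
    fy <- tc$fy; fx <- tc$fx
    dvdy <- (1 - fx) * (v10 - v00) + fx * (v11 - v01)  # recycled per column
    dvdx <- (1 - fy) * (v01 - v00) + fy * (v11 - v10)
    doff[, , 2L * tap - 1L, ] <- array(rowSums(G * dvdy), c(Hout, Wout, N))
    doff[, , 2L * tap, ] <- array(rowSums(G * dvdx), c(Hout, Wout, N))
  }
  m$grads$b <- m$grads$b + colSums(dm)
  dx_off <- m$children$offset_conv$bwd(doff)
  d <- cc$d
  dxp <- array(dxp_flat, cc$pdim)
  dx <- if (m$pad > 0L)
    dxp[m$pad + seq_len(d[1]), m$pad + seq_len(d[2]), , , drop = FALSE]
  else dxp
  m$cache <- NULL
  dx + dx_off
}

#' Deformable convolution (functional form)
#'
#' Applies a deformable convolution with explicit kernel weights and
#' per-position offsets; used directly in tests and for the degenerate
#' zero-offset equivalence check.
#'
#' @param x Input map `(H, W, Cin, N)`.
#' @param W Kernel `(kh, kw, Cin, Cout)`.
#' @param b Bias, length `Cout`.
#' @param offsets `(Hout, Wout, 2*kh*kw, N)` array of (dy, dx) pairs per
#'   tap (row-major tap order), or `NULL` for all-zero offsets.
#' @param stride,pad Stride and zero padding.
#' @return Output map `(Hout, Wout, Cout, N)`.
#' @export
deformable_conv <- function(x, W, b = NULL, offsets = NULL, stride = 1L, pad = 1L) {
  kh <- dim(W)[1]; kw <- dim(W)[2]
  if (is.null(b)) b <- numeric(dim(W)[4])
  m <- new_module("deform_conv")
  m$kh <- kh; m$kw <- kw; m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$params$W <- W; m$params$b <- b
  if (is.null(offsets)) {
    Hout <- conv_out_dim(dim(x)[1], kh, stride, pad)
    Wout <- conv_out_dim(dim(x)[2], kw, stride, pad)
    offsets <- array(0, c(Hout, Wout, 2L * kh * kw, dim(x)[4]))
  }
  deform_fwd(m, x, training = FALSE, offsets = offsets)
}

#' Standard convolution (functional form)
#'
#' Plain strided convolution used as the reference in the zero-offset
#' deformable equivalence checks and available for feature extraction.
#'
#' @inheritParams deformable_conv
#' @return Output map `(Hout, Wout, Cout, N)`.
#' @export
standard_conv <- function(x, W, b = NULL, stride = 1L, pad = 1L) {
  if (is.null(b)) b <- numeric(dim(W)[4])
  conv2d_fwd(x, W, b, as.integer(stride), as.integer(pad))$y
}
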