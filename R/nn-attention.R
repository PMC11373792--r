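# Channel and channel+spatial attention modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# broadcast a (C, N) weight over the spatial dims of a (H, W, C, N) map
bcast_cn <- function(w, d) array(rep(as.vector(w), each = d[1] * d[2]), d)

#' Squeeze-and-excitation module
#'
#' Squeeze: global average pool per channel. Excitation: a C -> C/r -> C
#' bottleneck (ReLU between, sigmoid after). The input map is rescaled
#' channel-wise by the resulting weights, which lie in (0, 1), so the
#' output never exceeds the input in per-channel magnitude.
#'
#' @param C Number of channels.
#' @param reduction Channel-reduction ratio r (bottleneck width is
#'   `max(1, ceiling(C / r))`).
#' @return An `nn_module`.
#' @export
se_module <- function(C, reduction = 16L) {
  m <- new_module("se")
  Cr <- max(1L, ceiling(C / reduction))
  m$params$W1 <- he_init(c(Cr, C), C)
  m$params$b1 <- numeric(Cr)
  m$params$W2 <- he_init(c(C, Cr), Cr)
  m$params$b2 <- numeric(C)
  m$fwd <- function(x, training = TRUE) {
    d <- dim(x); HW <- d[1] * d[2]
    s <- colMeans(matrix(x, HW, d[3] * d[4]))      # squeeze
    dim(s) <- c(d[3], d[4])
    z <- m$params$W1 %*% s + m$params$b1
    a <- z * (z > 0)
    w <- sigmoid(m$params$W2 %*% a + m$params$b2)  # (C, N) in (0,1)
    if (training) m$cache <- list(x = x, s = s, z = z, a = a, w = w, d = d)
    x * bcast_cn(w, d)
  }
  m$bwd <- function(dy) {
    cc <- m$cache; d <- cc$d; HW <- d[1] * d[2]
    dx <- dy * bcast_cn(cc$w, d)
    dw <- colSums(matrix(dy * cc$x, HW, d[3] * d[4]))
    dim(dw) <- c(d[3], d[4])
    dv <- dw * cc$w * (1 - cc$w)                   # through sigmoid
    m$grads$W2 <- m$grads$W2 + dv %*% t(cc$a)
    m$grads$b2 <- m$grads$b2 + rowSums(dv)
    da <- t(m$params$W2) %*% dv
    dz <- da * (cc$z > 0)
    m$grads$W1 <- m$grads$W1 + dz %*% t(cc$s)
    m$grads$b1 <- m$grads$b1 + rowSums(dz)
    ds <- t(m$params$W1) %*% dz
    dx <- dx + bcast_cn(ds / HW, d)                # through the squeeze
    m$cache <- NULL
    dx
  }
  m
}

#' Convolutional block attention module (CBAM)
#'
#' Sequential channel-then-spatial attention. Channel attention: global
#' average- and max-pooled descriptors pass through a shared C -> C/r -> C
#' bottleneck, are summed and squashed by a sigmoid. Spatial attention:
#' channel-wise mean and max maps are stacked and convolved with a
#' `k x k` kernel, then squashed. Both stages rescale the map they
#' attend to; shapes are preserved.
#'
#' @param C Number of channels.
#' @param kernel Spatial-attention kernel size (odd; default 7).
#' @param reduction Channel-reduction ratio of the shared bottleneck.
#' @return An `nn_module`.
#' @export
cbam_module <- function(C, kernel = 7L, reduction = 16L) {
  if (kernel %% 2L == 0L) stop("CBAM spatial kernel must be odd")
  m <- new_module("cbam")
  Cr <- max(1L, ceiling(C / reduction))
  m$params$W1 <- he_init(c(Cr, C), C)
  m$params$b1 <- numeric(Cr)
  m$params$W2 <- he_init(c(C, Cr), Cr)
  m$params$b2 <- numeric(C)
  m$kernel <- as.integer(kernel)
  m$children <- list(sconv = conv_module(kernel, kernel, 2L, 1L,
                                         stride = 1L, pad = (kernel - 1L) %/% 2L))
  mlp_fwd <- function(s) {
    z <- m$params$W1 %*% s + m$params$b1
    a <- z * (z > 0)
    list(z = z, a = a, out = m$params$W2 %*% a + m$params$b2)
  }
  m$fwd <- function(x, training = TRUE) {
    d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    # ---- channel attention
    xm <- matrix(x, HW, C * N)
    savg <- colMeans(xm); dim(savg) <- c(C, N)
    arg_c <- max.col(t(xm), ties.method = "first")     # spatial argmax per (c, n)
    smax <- xm[cbind(arg_c, seq_len(C * N))]; dim(smax) <- c(C, N)
    fa <- mlp_fwd(savg); fm <- mlp_fwd(smax)
    att_c <- sigmoid(fa$out + fm$out)                  # (C, N)
    x1 <- x * bcast_cn(att_c, d)
    # ---- spatial attention
    x1p <- aperm(x1, c(3, 1, 2, 4))                    # (C, H, W, N)
    m2 <- matrix(x1p, C, HW * N)
    mmean <- colMeans(m2)
    arg_s <- max.col(t(m2), ties.method = "first")     # channel argmax per (h,w,n)
    mmax <- m2[cbind(arg_s, seq_len(HW * N))]
    cat2 <- array(0, c(d[1], d[2], 2L, N))
    cat2[, , 1L, ] <- array(mmean, c(d[1], d[2], N))
    cat2[, , 2L, ] <- array(mmax, c(d[1], d[2], N))
    sc <- m$children$sconv$fwd(cat2, training)
    att_s <- sigmoid(sc)                               # (H, W, 1, N)
    as4 <- array(0, d)                                 # broadcast over channels
    for (ch in seq_len(C)) as4[, , ch, ] <- att_s[, , 1L, ]
    y <- x1 * as4
    if (training)
      m$cache <- list(x = x, d = d, savg = savg, smax = smax, arg_c = arg_c,
                      fa = fa, fm = fm, att_c = att_c, x1 = x1,
                      arg_s = arg_s, att_s = att_s, as4 = as4)
    y
  }
  m$bwd <- function(dy) {
    cc <- m$cache; d <- cc$d; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    # ---- spatial attention backward
    dx1 <- dy * cc$as4
    datt_s <- array(rowSums(matrix(aperm(dy * cc$x1, c(1, 2, 4, 3)), HW * N, C)),
                    c(d[1], d[2], 1L, N))
    # note: aperm puts channel last so rowSums sums over channels
    dsc <- datt_s * cc$att_s * (1 - cc$att_s)
    dcat <- m$children$sconv$bwd(dsc)
    dmean <- dcat[, , 1L, ]; dmax <- dcat[, , 2L, ]
    dx1p_extra <- array(0, c(C, d[1], d[2], N))
    dx1p_extra[] <- rep(as.vector(dmean) / C, each = C)   # mean spreads evenly
    dmax_v <- as.vector(dmax)
    idx <- cc$arg_s + (seq_len(HW * N) - 1L) * C
    dx1p_extra[idx] <- dx1p_extra[idx] + dmax_v
    dx1 <- dx1 + aperm(dx1p_extra, c(2, 3, 1, 4))
    # ---- channel attention backward
    datt_c <- colSums(matrix(dx1 * cc$x, HW, C * N))
    dim(datt_c) <- c(C, N)
    dx <- dx1 * bcast_cn(cc$att_c, d)
    dv <- datt_c * cc$att_c * (1 - cc$att_c)
    mlp_bwd <- function(f, s, dv) {
      m$grads$W2 <- m$grads$W2 + dv %*% t(f$a)
      m$grads$b2 <- m$grads$b2 + rowSums(dv)
      da <- t(m$params$W2) %*% dv
      dz <- da * (f$z > 0)
      m$grads$W1 <- m$grads$W1 + dz %*% t(s)
      m$grads$b1 <- m$grads$b1 + rowSums(dz)
      t(m$params$W1) %*% dz
    }
    dsavg <- mlp_bwd(cc$fa, cc$savg, dv)
    dsmax <- mlp_bwd(cc$fm, cc$smax, dv)
    dx <- dx + bcast_cn(dsavg / HW, d)
    dxm_extra <- numeric(HW * C * N)
    idx2 <- cc$arg_c + (seq_len(C * N) - 1L) * HW
    dxm_extra[idx2] <- as.vector(dsmax)
    dx <- dx + array(dxm_extra, d)
    m$cache <- NULL
    dx
  }
  m
}
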