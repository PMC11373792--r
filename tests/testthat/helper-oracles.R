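# Independent oracles used across the test suite. These deliberately use
# different algorithms (and code paths) from the package implementation.

# exhaustive 256-level Otsu: scan every threshold, compute between-class
# variance from first principles
otsu_bruteforce <- function(values) {
  v <- as.integer(round(pmin(pmax(values, 0), 255)))
  best_t <- NA_integer_; best_var <- -Inf
  n <- length(v)
  for (t in 0:254) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (length(g0) == 0L || length(g1) == 0L) next
    w0 <- length(g0) / n; w1 <- length(g1) / n
    sb <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (sb > best_var + 1e-12) { best_var <- sb; best_t <- t }
  }
  best_t
}

# slow 8-connected component labelling by frontier flood fill
label_components_slow <- function(binary) {
  H <- nrow(binary); W <- ncol(binary)
  lab <- matrix(0L, H, W)
  remaining <- binary
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nxt <- 0L
  repeat {
    seed <- which(remaining)
    if (length(seed) == 0L) break
    nxt <- nxt + 1L
    frontier <- seed[1]
    remaining[frontier] <- FALSE
    lab[frontier] <- nxt
    while (length(frontier)) {
      r <- (frontier - 1L) %% H + 1L; c <- (frontier - 1L) %/% H + 1L
      nb <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        cand <- (cc[ok] - 1L) * H + rr[ok]
        nb <- c(nb, cand[remaining[cand]])
      }
      nb <- unique(nb)
      remaining[nb] <- FALSE
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  lab
}

# byte-level BIL serialization oracle: write the payload by explicit
# nested loops (line -> band -> sample), float64 little-endian
serialize_bil_manual <- function(a) {
  L <- dim(a)[1]; S <- dim(a)[2]; B <- dim(a)[3]
  out <- raw(0)
  con <- rawConnection(out, "wb")
  on.exit(close(con))
  for (l in seq_len(L)) for (b in seq_len(B))
    writeBin(as.double(a[l, , b]), con, size = 8, endian = "little")
  rawConnectionValue(con)
}

# random small seed crop for augmentation tests
random_crop <- function(size = 24L, label = "C1", seed = 1L) {
  set.seed(seed)
  structure(list(pixels = array(runif(size * size * 3) * 255, c(size, size, 3L)),
                 label = label,
                 provenance = list(scene_id = "s", component_id = 1L,
                                   transform = "original")),
            class = "seed_crop")
}

# draw an axis-aligned ellipse mask
ellipse_mask <- function(H, W, cy, cx, a, b) {
  rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= 1
}

expect_identical_array <- function(x, y, tol = 0) {
  if (tol == 0) testthat::expect_identical(x, y)
  else testthat::expect_lt(max(abs(x - y)), tol)
}
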