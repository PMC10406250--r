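# Independent brute-force oracles used across the suite.  These deliberately
# use dense matrices and index-by-index loops, never the package's fast paths.

# Dense lower-triangular Toeplitz matrix of the causal HRF convolution.
toeplitz_hrf <- function(kernel, nt) {
  L <- matrix(0, nt, nt)
  for (i in seq_len(nt)) {
    for (j in seq_len(i)) {
      k <- i - j + 1L
      if (k <= kernel$length) L[i, j] <- kernel$samples[k]
    }
  }
  L
}

# Index-by-index forward-difference gradient of a 4D array.
gradient_loop <- function(a, spacing = c(1, 1, 1, 1)) {
  d <- dim(a)
  out <- array(0, c(d, 4))
  for (ax in 1:4) {
    for (i1 in seq_len(d[1])) for (i2 in seq_len(d[2])) {
      for (i3 in seq_len(d[3])) for (i4 in seq_len(d[4])) {
        idx <- c(i1, i2, i3, i4)
        nxt <- idx
        nxt[ax] <- nxt[ax] + 1L
        val <- if (nxt[ax] > d[ax]) 0 else {
          (a[nxt[1], nxt[2], nxt[3], nxt[4]] -
             a[idx[1], idx[2], idx[3], idx[4]]) / spacing[ax]
        }
        out[i1, i2, i3, i4, ax] <- val
      }
    }
  }
  out
}

# 4D Neumann Laplacian stencil: sum over the 8 face neighbours (clamped to
# the boundary) minus the number of in-range neighbours times the center.
laplacian_stencil <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  for (i1 in seq_len(d[1])) for (i2 in seq_len(d[2])) {
    for (i3 in seq_len(d[3])) for (i4 in seq_len(d[4])) {
      idx <- c(i1, i2, i3, i4)
      acc <- 0
      nn <- 0L
      for (ax in 1:4) for (s in c(-1L, 1L)) {
        nb <- idx
        nb[ax] <- nb[ax] + s
        if (nb[ax] >= 1L && nb[ax] <= d[ax]) {
          acc <- acc + a[nb[1], nb[2], nb[3], nb[4]]
          nn <- nn + 1L
        }
      }
      out[i1, i2, i3, i4] <- acc - nn * a[idx[1], idx[2], idx[3], idx[4]]
    }
  }
  out
}

# Random symmetric PSD 4x4 matrix.
random_psd4 <- function() {
  A <- matrix(rnorm(16), 4, 4)
  crossprod(A)
}

# Pack a symmetric 4x4 matrix into the 10-component order used by the
# package: (11, 12, 13, 14, 22, 23, 24, 33, 34, 44).
pack10 <- function(M) {
  c(M[1, 1], M[1, 2], M[1, 3], M[1, 4], M[2, 2], M[2, 3], M[2, 4],
    M[3, 3], M[3, 4], M[4, 4])
}

unpack10 <- function(v) {
  M <- matrix(0, 4, 4)
  M[1, ] <- c(v[1], v[2], v[3], v[4])
  M[2, ] <- c(v[2], v[5], v[6], v[7])
  M[3, ] <- c(v[3], v[6], v[8], v[9])
  M[4, ] <- c(v[4], v[7], v[9], v[10])
  M
}

# Component matrix for a field of identical tensors on a given grid.
uniform_field <- function(M, grid) {
  comp <- matrix(rep(pack10(M), each = prod(grid)), prod(grid), 10)
  structure(comp, grid = grid, class = "tensor_field4d")
}

small_image <- function(d = c(4, 4, 4, 5), seed = 1) {
  set.seed(seed)
  array(rnorm(prod(d)), d)
}
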