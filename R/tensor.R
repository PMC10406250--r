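#' @useDynLib anisofmri, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# --- internal axis machinery -------------------------------------------------

# Apply f to a 4D array reshaped so that `axis` runs along rows of a matrix.
.along_axis <- function(a, axis, f) {
  d <- dim(a)
  perm <- c(axis, setdiff(seq_len(4L), axis))
  m <- aperm(a, perm)
  dim(m) <- c(d[axis], prod(d[-axis]))
  m <- f(m)
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

# Forward (left-to-right) first difference down matrix rows; trailing row 0.
.fwd_diff <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m * 0)
  rbind(m[-1L, , drop = FALSE] - m[-n, , drop = FALSE],
        matrix(0, 1L, ncol(m)))
}

# Backward (right-to-left) difference with zero-flux ends, the exact negative
# adjoint of .fwd_diff: the trailing flux sample is ignored (forward
# differencing pins it to zero) and there is no flux entering before the
# first sample.
.bwd_diff <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m * 0)
  q <- m
  q[n, ] <- 0
  q - rbind(matrix(0, 1L, ncol(m)), q[-n, , drop = FALSE])
}

# Reflect an integer index into 1..n (half-sample symmetric: ... 2 1 | 1 2 ...)
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period  # 0-based position in the tile
  ifelse(i < n, i + 1L, period - i)
}

# Dense 1D Gaussian smoothing matrix with reflect boundary, truncated at
# 4*sigma, kernel renormalized to unit sum after truncation.
.gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- as.integer(ceiling(4 * sigma))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- .reflect_index(i + seq(-r, r), n)
    for (j in seq_along(idx)) S[i, idx[j]] <- S[i, idx[j]] + w[j]
  }
  S
}

.check_image4d <- function(a, what = "image") {
  if (is.null(dim(a)) || length(dim(a)) != 4L) {
    stop(sprintf("'%s' must be a 4D array (x, y, z, t)", what))
  }
}

# --- gradient / divergence ---------------------------------------------------

#' 4D forward-difference gradient
#'
#' First differences along each of the four axes using a left-to-right
#' (forward) scheme with replicate-edge (Neumann) boundary: the last
#' difference along every axis is zero.  Differences are divided by the axis
#' spacing.
#'
#' @param image a 4D array `(nx, ny, nz, nt)`.
#' @param spacing positive spacings of the four axes; the default treats the
#'   grid in index space, which is the convention the flow parameters
#'   (`sigma_g`, step size) are expressed in.
#' @return An `(n_voxel x 4)` matrix with columns `(I_x, I_y, I_z, I_t)` and
#'   attribute `grid` holding `dim(image)` (voxels vary fastest along x).
#' @export
gradient4d <- function(image, spacing = c(1, 1, 1, 1)) {
  .check_image4d(image)
  if (length(spacing) != 4L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 4 positive scalars")
  }
  d <- dim(image)
  g <- matrix(0, prod(d), 4L)
  for (ax in 1:4) {
    g[, ax] <- as.numeric(.along_axis(image, ax, .fwd_diff)) / spacing[ax]
  }
  attr(g, "grid") <- d
  g
}

#' 4D backward-difference divergence
#'
#' Sums the backward (right-to-left) first difference of each flux component
#' along its own axis.  The boundary convention (no flux before the first
#' sample; the trailing flux sample, which [gradient4d()] pins to zero, is
#' dropped) makes `-divergence4d` the exact adjoint of [gradient4d()], and
#' `divergence4d(gradient4d(I))` the standard 4D Neumann Laplacian stencil.
#'
#' @param flux an `(n_voxel x 4)` matrix with a `grid` attribute as produced
#'   by [gradient4d()], or a 5D array `(nx, ny, nz, nt, 4)`.
#' @param spacing positive spacings of the four axes.
#' @return A 4D array of the flux divergence.
#' @export
divergence4d <- function(flux, spacing = c(1, 1, 1, 1)) {
  if (is.array(flux) && length(dim(flux)) == 5L) {
    d <- dim(flux)[1:4]
    flux <- matrix(flux, prod(d), 4L)
  } else {
    d <- attr(flux, "grid")
    if (is.null(d)) stop("'flux' must carry a 'grid' attribute or be 5D")
    if (!is.matrix(flux) || ncol(flux) != 4L || nrow(flux) != prod(d)) {
      stop("flux shape does not match its grid")
    }
  }
  if (length(spacing) != 4L || any(spacing <= 0)) {
    stop("'spacing' must be 4 positive scalars")
  }
  out <- array(0, dim = d)
  for (ax in 1:4) {
    comp <- array(flux[, ax], dim = d)
    out <- out + .along_axis(comp, ax, .bwd_diff) / spacing[ax]
  }
  out
}

# --- structure tensor --------------------------------------------------------

#' Gaussian-smoothed 4D structure tensor
#'
#' Per voxel, the outer product of the 4-gradient with itself divided by the
#' gradient magnitude, then each of the 10 unique components smoothed with a
#' 4D Gaussian of standard deviation `sigma_g` (voxel units, truncated at
#' 4 sigma, reflect boundary).  The result is symmetric by construction and
#' positive semi-definite up to smoothing round-off.
#'
#' @param grad gradient matrix from [gradient4d()].
#' @param sigma_g Gaussian smoothing standard deviation in voxels
#'   (`sigma_g = 0` skips smoothing).
#' @param epsilon guard added to the gradient-norm denominator so that
#'   zero-gradient voxels yield a zero tensor.
#' @param norm `"l2"` divides the outer product by `||grad||_2 + epsilon`
#'   (keeps edge-strength magnitude in the tensor); `"l2sq"` divides by
#'   `||grad||_2^2 + epsilon` (orientation-only tensor).
#' @return A `tensor_field4d`: an `(n_voxel x 10)` matrix of components in
#'   the order (11, 12, 13, 14, 22, 23, 24, 33, 34, 44) with attribute
#'   `grid`.
#' @export
structure_tensor <- function(grad, sigma_g = 1, epsilon = 1e-8,
                             norm = c("l2", "l2sq")) {
  norm <- match.arg(norm)
  if (!is.finite(sigma_g) || sigma_g < 0) stop("'sigma_g' must be >= 0")
  if (epsilon < 0) stop("'epsilon' must be >= 0")
  d <- attr(grad, "grid")
  if (is.null(d)) stop("'grad' must come from gradient4d()")
  gn <- sqrt(rowSums(grad^2))
  den <- (if (norm == "l2") gn else gn^2) + epsilon
  den[den == 0] <- 1  # zero gradient => zero numerator; avoid 0/0 when epsilon = 0
  pairs <- cbind(
    i = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L),
    j = c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L)
  )
  comp <- matrix(0, nrow(grad), 10L)
  for (c_idx in seq_len(10L)) {
    comp[, c_idx] <- grad[, pairs[c_idx, 1L]] * grad[, pairs[c_idx, 2L]] / den
  }
  if (sigma_g > 0) {
    smoothers <- lapply(1:4, function(ax) .gauss_matrix(d[ax], sigma_g))
    for (c_idx in seq_len(10L)) {
      a <- array(comp[, c_idx], dim = d)
      for (ax in 1:4) {
        S <- smoothers[[ax]]
        a <- .along_axis(a, ax, function(m) S %*% m)
      }
      comp[, c_idx] <- as.numeric(a)
    }
  }
  structure(comp, grid = d, sigma_g = sigma_g, class = "tensor_field4d")
}

#' Per-voxel eigendecomposition of a 4D tensor field
#'
#' Symmetric eigendecomposition of every voxel's 4x4 tensor.  Eigenvalues are
#' sorted in descending order; values in `[-tol, 0)` are clipped to zero,
#' while anything below `-tol` signals a corrupted tensor and raises an
#' error.
#'
#' @param field a `tensor_field4d` or any `(n x 10)` component matrix.
#' @param tol negative-eigenvalue tolerance.
#' @return A list of class `eigen_field4d` with `values` (`n x 4`,
#'   descending) and `vectors` (`n x 16`; `vectors[v, 4*(k-1) + i]` is the
#'   i-th entry of the k-th eigenvector) plus the `grid` attribute when
#'   present on the input.
#' @export
tensor_eigen <- function(field, tol = 1e-8) {
  comp <- unclass(field)
  attr(comp, "grid") <- NULL
  attr(comp, "sigma_g") <- NULL
  if (!is.matrix(comp) || ncol(comp) != 10L) {
    stop("'field' must be an (n x 10) tensor component matrix")
  }
  if (!all(is.finite(comp))) stop("non-finite tensor components")
  e <- eig4_field_cpp(comp)
  neg <- min(e$values)
  if (neg < -tol) {
    stop(sprintf("tensor has eigenvalue %.3e below -%g: corrupted field",
                 neg, tol))
  }
  e$values[e$values < 0] <- 0
  structure(list(values = e$values, vectors = e$vectors,
                 grid = attr(field, "grid")),
            class = "eigen_field4d")
}

#' Exponential eigenvalue remap for the steering tensor
#'
#' Maps each voxel's leading structure-tensor eigenvalue to a diffusivity:
#' `lambda1_new = exp(-(lambda1 / global_max)^2 / (2 * sigma_d^2))`, so
#' strong edges (ratio near 1) almost stop diffusion across them while flat
#' regions (ratio near 0) diffuse isotropically.  The remaining three
#' eigenvalues are set to 1 everywhere.  `global_max` is the maximum leading
#' eigenvalue over all voxels of the current image; a zero maximum (constant
#' image) is guarded by `epsilon`, making the remap total.
#'
#' @param eigs an `eigen_field4d` from [tensor_eigen()].
#' @param global_max the global maximum of the leading eigenvalue; defaults
#'   to `max(eigs$values[, 1])`.
#' @param sigma_d unitless width of the exponential remap.
#' @param epsilon positive guard replacing a zero `global_max`.
#' @return An `(n x 4)` matrix of remapped eigenvalues, all in `(0, 1]`,
#'   columns 2--4 identically 1.
#' @export
remap_eigenvalues <- function(eigs, global_max = NULL, sigma_d = 0.2,
                              epsilon = 1e-8) {
  if (!inherits(eigs, "eigen_field4d")) stop("'eigs' must be an eigen_field4d")
  if (!is.finite(sigma_d) || sigma_d <= 0) stop("'sigma_d' must be positive")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  lam1 <- eigs$values[, 1L]
  if (is.null(global_max)) global_max <- max(lam1)
  if (global_max < max(lam1)) {
    stop("'global_max' must dominate every per-voxel leading eigenvalue")
  }
  if (global_max <= 0) global_max <- epsilon
  out <- matrix(1, length(lam1), 4L)
  out[, 1L] <- exp(-(lam1 / global_max)^2 / (2 * sigma_d^2))
  out
}

#' Rebuild a tensor field from an eigensystem and new eigenvalues
#'
#' Computes `Q diag(lambda) Q^T` per voxel.  With the remapped spectrum from
#' [remap_eigenvalues()] the result is symmetric positive definite with all
#' eigenvalues in `(0, 1]`; when the leading remapped value is 1 the tensor
#' is the identity (fully isotropic diffusion).
#'
#' @param eigs an `eigen_field4d`.
#' @param values an `(n x 4)` matrix of eigenvalues matching `eigs$vectors`
#'   column order.
#' @return A `tensor_field4d` component matrix.
#' @export
rebuild_tensor <- function(eigs, values) {
  if (!inherits(eigs, "eigen_field4d")) stop("'eigs' must be an eigen_field4d")
  if (!is.matrix(values) || any(dim(values) != dim(eigs$values))) {
    stop("'values' must match the eigensystem dimensions")
  }
  comp <- rebuild4_field_cpp(values, eigs$vectors)
  structure(comp, grid = eigs$grid, class = "tensor_field4d")
}

#' Steering tensor of an image
#'
#' Convenience pipeline: gradient, Gaussian-smoothed structure tensor,
#' per-voxel eigendecomposition, exponential eigenvalue remap against the
#' global leading eigenvalue, spectral rebuild.  This is the anisotropic
#' diffusion tensor used by the regularization flow.
#'
#' @param image a 4D array.
#' @param sigma_g structure-tensor smoothing (voxels).
#' @param sigma_d remap width.
#' @param epsilon numeric guard for zero gradients / constant images.
#' @param spacing grid spacing for the gradient.
#' @param norm structure-tensor normalization, see [structure_tensor()].
#' @return A list with `field` (the steering `tensor_field4d`), `lambda1_max`
#'   (the global leading eigenvalue of the raw structure tensor) and
#'   `lambda1_new` (per-voxel remapped leading eigenvalue).
#' @export
steering_tensor <- function(image, sigma_g = 1, sigma_d = 0.2,
                            epsilon = 1e-8, spacing = c(1, 1, 1, 1),
                            norm = c("l2", "l2sq")) {
  g <- gradient4d(image, spacing)
  st <- structure_tensor(g, sigma_g = sigma_g, epsilon = epsilon,
                         norm = match.arg(norm))
  eigs <- tensor_eigen(st)
  lam_max <- max(eigs$values[, 1L])
  remapped <- remap_eigenvalues(eigs, global_max = lam_max,
                                sigma_d = sigma_d, epsilon = epsilon)
  list(field = rebuild_tensor(eigs, remapped),
       lambda1_max = lam_max,
       lambda1_new = remapped[, 1L])
}

# Multiply a tensor field (n x 10 components) with a gradient field (n x 4):
# per-voxel symmetric 4x4 matrix-vector product.
.tensor_matvec <- function(field, grad) {
  comp <- unclass(field)
  out <- matrix(0, nrow(grad), 4L)
  out[, 1L] <- comp[, 1L] * grad[, 1L] + comp[, 2L] * grad[, 2L] +
    comp[, 3L] * grad[, 3L] + comp[, 4L] * grad[, 4L]
  out[, 2L] <- comp[, 2L] * grad[, 1L] + comp[, 5L] * grad[, 2L] +
    comp[, 6L] * grad[, 3L] + comp[, 7L] * grad[, 4L]
  out[, 3L] <- comp[, 3L] * grad[, 1L] + comp[, 6L] * grad[, 2L] +
    comp[, 8L] * grad[, 3L] + comp[, 9L] * grad[, 4L]
  out[, 4L] <- comp[, 4L] * grad[, 1L] + comp[, 7L] * grad[, 2L] +
    comp[, 9L] * grad[, 3L] + comp[, 10L] * grad[, 4L]
  attr(out, "grid") <- attr(grad, "grid")
  out
}
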