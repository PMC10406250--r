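#' Construct a discrete HRF kernel
#'
#' An `hrf_kernel` holds the hemodynamic response function sampled causally at
#' the repetition time: `samples[1]` is the response at lag 0, `samples[2]` at
#' lag `tr`, and so on.  The kernel defines the linear operator `H` (causal
#' convolution along time, [apply_hrf()]) and its adjoint `H^T`
#' ([apply_hrf_adjoint()]).
#'
#' @param samples numeric vector of kernel values at lags `0, tr, 2*tr, ...`.
#'   Must be finite, non-empty, and contain at least one strictly positive
#'   value (a response must exist).
#' @param tr repetition time in seconds (sampling interval of the lag grid).
#' @return An object of class `hrf_kernel` with fields `samples`, `tr` and
#'   `length`.
#' @seealso [canonical_hrf()] for the default double-gamma shape,
#'   [read_hrf()] to load a kernel from a text file.
#' @export
hrf_kernel <- function(samples, tr) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("kernel must have at least one sample")
  if (!all(is.finite(samples))) stop("kernel samples must all be finite")
  if (!any(samples > 0)) stop("kernel must have at least one positive sample")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("'tr' must be a single positive number")
  }
  structure(
    list(samples = samples, tr = as.numeric(tr), length = length(samples)),
    class = "hrf_kernel"
  )
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf(
    "<hrf_kernel> %d samples at TR = %g s (span %g s), peak %g at lag %g s\n",
    x$length, x$tr, x$length * x$tr, max(x$samples),
    (which.max(x$samples) - 1L) * x$tr
  ))
  invisible(x)
}

#' Canonical double-gamma HRF
#'
#' Builds the canonical two-gamma hemodynamic response function on the TR lag
#' grid: a gamma density peaking around 5--6 s minus a scaled, delayed gamma
#' density modelling the post-stimulus undershoot.  Each sample is the
#' average of the continuous response over its TR bin (so even a single-bin
#' kernel captures the early response), and the kernel is normalized so its
#' peak value is exactly 1, which keeps the magnitude of the deconvolution
#' fidelity term comparable across TRs.
#'
#' @param tr repetition time in seconds.
#' @param duration total kernel support in seconds; the kernel has
#'   `ceiling(duration / tr)` samples.
#' @param peak_delay shape of the positive lobe gamma (seconds; mode at
#'   `peak_delay - 1` for unit rate).
#' @param undershoot_delay shape of the undershoot gamma (seconds).
#' @param undershoot_ratio relative amplitude of the undershoot.
#' @return An [hrf_kernel()].
#' @examples
#' h <- canonical_hrf(tr = 1)
#' h$length            # 32 samples
#' max(h$samples)      # 1
#' @export
canonical_hrf <- function(tr, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, undershoot_ratio = 1 / 6) {
  if (!is.finite(tr) || tr <= 0) stop("'tr' must be positive")
  if (!is.finite(duration) || duration < tr) {
    stop("'duration' must be at least one TR")
  }
  if (peak_delay <= 0 || undershoot_delay <= 0) stop("delays must be positive")
  n <- as.integer(ceiling(duration / tr))
  lag <- (seq_len(n) - 1L) * tr
  bin_mean <- function(shape) {
    (stats::pgamma(lag + tr, shape = shape, rate = 1) -
       stats::pgamma(lag, shape = shape, rate = 1)) / tr
  }
  h <- bin_mean(peak_delay) - undershoot_ratio * bin_mean(undershoot_delay)
  peak <- max(h)
  if (peak <= 0) stop("degenerate kernel: no positive response on the grid")
  hrf_kernel(h / peak, tr)
}

#' Read an HRF kernel from a single-column text file
#'
#' The file holds one kernel sample per line at TR spacing, lag 0 first.
#'
#' @param path path to the text file.
#' @param tr repetition time in seconds of the sampled kernel.
#' @return An [hrf_kernel()].
#' @export
read_hrf <- function(path, tr) {
  samples <- scan(path, what = numeric(), quiet = TRUE)
  hrf_kernel(samples, tr)
}

# Coerce a series / 4D array into an (n_voxel x n_time) matrix plus restore
# info.  Time is the last axis of a 4D array.
.as_time_matrix <- function(x) {
  if (is.null(dim(x))) {
    list(m = matrix(x, nrow = 1L), dim = NULL, n_time = length(x))
  } else if (length(dim(x)) == 4L) {
    d <- dim(x)
    list(m = matrix(x, nrow = prod(d[1:3]), ncol = d[4]), dim = d,
         n_time = d[4])
  } else if (length(dim(x)) == 2L) {
    list(m = x, dim = dim(x), n_time = ncol(x))
  } else {
    stop("expected a vector, an (n_voxel x n_time) matrix or a 4D array")
  }
}

.restore_shape <- function(m, info) {
  if (is.null(info$dim)) as.numeric(m) else array(m, dim = info$dim)
}

.check_kernel_tr <- function(kernel, tr) {
  if (!inherits(kernel, "hrf_kernel")) stop("'kernel' must be an hrf_kernel")
  if (!is.null(tr) && abs(kernel$tr - tr) > 1e-9 * max(kernel$tr, tr)) {
    stop(sprintf("kernel TR (%g s) does not match series TR (%g s)",
                 kernel$tr, tr))
  }
}

#' Apply the HRF operator H (causal temporal convolution)
#'
#' Convolves every voxel's time course with the HRF kernel, assuming zero
#' history before the first sample and truncating at the scan end:
#' `out[t] = sum_{k <= t} kernel[k] * x[t - k]`.  Purely temporal: spatial
#' voxels are processed independently, and the operator is linear.
#'
#' @param x a numeric time series, an `(n_voxel x n_time)` matrix (series in
#'   rows), or a 4D array with time as the fourth axis.
#' @param kernel an [hrf_kernel()].
#' @param tr optional repetition time of `x`; if given it must match
#'   `kernel$tr`.
#' @return Same shape as `x`.
#' @export
apply_hrf <- function(x, kernel, tr = NULL) {
  .check_kernel_tr(kernel, tr)
  info <- .as_time_matrix(x)
  m <- info$m
  nt <- info$n_time
  h <- kernel$samples
  out <- matrix(0, nrow(m), nt)
  for (k in seq_len(min(length(h), nt))) {
    cols <- k:nt
    out[, cols] <- out[, cols] + h[k] * m[, cols - k + 1L, drop = FALSE]
  }
  .restore_shape(out, info)
}

#' Apply the adjoint HRF operator H^T (anti-causal correlation)
#'
#' Exact adjoint of [apply_hrf()] under the standard inner product on the
#' fixed-length time axis; equivalent to convolution with the time-reversed
#' kernel: `out[t] = sum_k kernel[k] * x[t + k]`.
#'
#' @inheritParams apply_hrf
#' @return Same shape as `x`.
#' @export
apply_hrf_adjoint <- function(x, kernel, tr = NULL) {
  .check_kernel_tr(kernel, tr)
  info <- .as_time_matrix(x)
  m <- info$m
  nt <- info$n_time
  h <- kernel$samples
  out <- matrix(0, nrow(m), nt)
  for (k in seq_len(min(length(h), nt))) {
    cols <- 1L:(nt - k + 1L)
    out[, cols] <- out[, cols] + h[k] * m[, cols + k - 1L, drop = FALSE]
  }
  .restore_shape(out, info)
}
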