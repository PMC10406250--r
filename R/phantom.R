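# Synthetic BOLD phantom: block/spike activity-inducing signal scaled by a
# 3D amplitude map, two-stage additive Gaussian noise, HRF convolution.

#' Piecewise-constant (boxcar) activity-inducing signal
#'
#' Samples a sum of non-overlapping block events on the TR grid.  A sample at
#' time `t` is active for an event iff `onset <= t < offset` (half-open
#' convention), so a 100 s scan at TR 1 with one event from 20 to 60 s has
#' exactly 40 active samples.
#'
#' @param duration scan length in seconds.
#' @param tr repetition time in seconds.
#' @param events data frame with columns `onset`, `offset` (seconds) and
#'   optionally `amplitude` (default 1).
#' @return Numeric series of `round(duration / tr)` samples.
#' @export
boxcar_series <- function(duration, tr, events) {
  if (!is.finite(duration) || !is.finite(tr) || tr <= 0 || duration < tr) {
    stop("'duration' must be at least one positive TR")
  }
  n <- as.integer(round(duration / tr))
  t_grid <- (seq_len(n) - 1L) * tr
  u <- numeric(n)
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) return(u)
  events <- as.data.frame(events)
  if (is.null(events$amplitude)) events$amplitude <- 1
  if (any(events$onset < 0) || any(events$offset > duration) ||
      any(events$onset >= events$offset)) {
    stop("events must satisfy 0 <= onset < offset <= duration")
  }
  ord <- order(events$onset)
  events <- events[ord, , drop = FALSE]
  if (nrow(events) > 1L &&
      any(events$onset[-1L] < events$offset[-nrow(events)])) {
    stop("overlapping events are not allowed")
  }
  for (k in seq_len(nrow(events))) {
    act <- t_grid >= events$onset[k] & t_grid < events$offset[k]
    u[act] <- events$amplitude[k]
  }
  u
}

#' Spike (event-related) activity-inducing signal
#'
#' Zeros with single-sample impulses at the stated times.  Times off the TR
#' grid are snapped to the nearest sample with a warning.
#'
#' @param duration scan length in seconds.
#' @param tr repetition time.
#' @param times spike times in seconds, within `[0, duration)`.
#' @param amplitude impulse height (recycled over spikes).
#' @return Numeric series of `round(duration / tr)` samples.
#' @export
spike_series <- function(duration, tr, times, amplitude = 1) {
  if (!is.finite(duration) || !is.finite(tr) || tr <= 0 || duration < tr) {
    stop("'duration' must be at least one positive TR")
  }
  n <- as.integer(round(duration / tr))
  u <- numeric(n)
  if (length(times) == 0L) return(u)
  if (any(times < 0) || any(times >= duration)) {
    stop("spike times must lie within [0, duration)")
  }
  idx_exact <- times / tr
  idx <- as.integer(round(idx_exact))
  if (any(abs(idx_exact - idx) > 1e-9)) {
    warning("spike times off the TR grid were snapped to the nearest sample")
  }
  amplitude <- rep_len(amplitude, length(times))
  for (k in seq_along(idx)) u[idx[k] + 1L] <- u[idx[k] + 1L] + amplitude[k]
  u
}

#' Synthetic 3D activation amplitude map
#'
#' Sum of 3D Gaussian blobs, affinely rescaled so the minimum and maximum hit
#' the requested range exactly (default `[0, 3]`, the validation-map range).
#' A gray-matter mask is derived as the voxels exceeding 10% of the map peak.
#' This map is a synthetic stand-in for a scanner-simulated activation map:
#' it reproduces only the spatial amplitude pattern role.
#'
#' @param shape integer 3-vector of grid sizes.
#' @param blobs list of blobs, each `list(center = c(x, y, z)` voxel
#'   coordinates, `width =` isotropic standard deviation in voxels,
#'   `peak =` relative height`)`.
#' @param range length-2 output range (strictly increasing).
#' @return A list with `map` (3D array) and `gm_mask` (3D logical).
#' @export
activation_map <- function(shape, blobs, range = c(0, 3)) {
  if (length(shape) != 3L || any(shape < 1)) stop("'shape' must be 3 sizes")
  if (length(blobs) < 1L) stop("at least one blob is required")
  if (length(range) != 2L || !(range[2] > range[1])) {
    stop("'range' must be strictly increasing")
  }
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  m <- numeric(nrow(g))
  for (b in blobs) {
    d2 <- (g$x - b$center[1])^2 + (g$y - b$center[2])^2 + (g$z - b$center[3])^2
    peak <- if (is.null(b$peak)) 1 else b$peak
    m <- m + peak * exp(-d2 / (2 * b$width^2))
  }
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 1e-12 * max(1, abs(hi))) {
    stop("degenerate map: all values equal, cannot rescale")
  }
  m <- range[1] + (m - lo) / (hi - lo) * (range[2] - range[1])
  map <- array(m, dim = shape)
  list(map = map, gm_mask = map > 0.1 * max(map))
}

#' Specification of a synthetic fMRI phantom
#'
#' Bundles every parameter of the forward model: activity-inducing design
#' (block or spike), 3D amplitude map, the two noise stages, grid geometry
#' and the random seed.  The defaults are the validation conditions used
#' throughout the package: a 12x12x12 grid at 2 mm isotropic resolution,
#' 100 s at TR 1 s, one 40 s block from 20 to 60 s, a two-blob amplitude map
#' rescaled to `[0, 3]`, small model noise and moderate acquisition noise.
#'
#' @param shape 3D grid sizes.
#' @param voxel_size voxel edge lengths in mm.
#' @param tr repetition time in seconds.
#' @param duration scan length in seconds.
#' @param design either `list(type = "block", events = data.frame(onset,
#'   offset, amplitude))` or `list(type = "spike", times =, amplitude =)`.
#' @param sigma_m model-noise standard deviation (added to the scaled
#'   activity-inducing signal before HRF convolution).
#' @param sigma_a acquisition-noise standard deviation (added after HRF
#'   convolution).  Ignored when `target_psnr` is given.
#' @param target_psnr optional peak-SNR target in dB; when set, `sigma_a` is
#'   derived from the clean activity-related image at synthesis time via
#'   [noise_for_target_psnr()].
#' @param blobs amplitude-map blobs, see [activation_map()].
#' @param map_range amplitude-map output range.
#' @param seed integer seed driving both noise stages.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(12, 12, 12), voxel_size = c(2, 2, 2),
                         tr = 1, duration = 100,
                         design = list(
                           type = "block",
                           events = data.frame(onset = 20, offset = 60,
                                               amplitude = 1)),
                         sigma_m = 0.05, sigma_a = 0.3, target_psnr = NULL,
                         blobs = list(
                           list(center = c(4, 4, 6), width = 2, peak = 1),
                           list(center = c(9, 8, 7), width = 2.5, peak = 0.8)),
                         map_range = c(0, 3), seed = 1L) {
  if (duration < tr) stop("'duration' must be at least one TR")
  if (sigma_m < 0 || sigma_a < 0) stop("noise standard deviations must be >= 0")
  if (!design$type %in% c("block", "spike")) {
    stop("design type must be 'block' or 'spike'")
  }
  structure(
    list(shape = as.integer(shape), voxel_size = voxel_size, tr = tr,
         duration = duration, design = design, sigma_m = sigma_m,
         sigma_a = sigma_a, target_psnr = target_psnr, blobs = blobs,
         map_range = map_range, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Synthesize a 4D fMRI phantom
#'
#' Forward model, per voxel `v`: the noisy activity-inducing signal is
#' `u_n(v, .) = map(v) * u(.) + eps_m` with `eps_m ~ N(0, sigma_m^2)` i.i.d.;
#' the activity-related (noiseless BOLD) image is `x = H u_n`; the acquired
#' image is `y = x + eps_a` with `eps_a ~ N(0, sigma_a^2)` i.i.d.  Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param kernel HRF kernel; defaults to [canonical_hrf()] at the spec TR.
#' @return A list of class `synthetic_dataset` with `u` (ground-truth
#'   series), `u_n`, `x`, `y` (4D arrays), `map`, `gm_mask`, the achieved
#'   `sigma_a`, and the `spec`.
#' @export
synthesize_phantom <- function(spec, kernel = NULL) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  if (is.null(kernel)) kernel <- canonical_hrf(spec$tr)
  u <- switch(spec$design$type,
    block = boxcar_series(spec$duration, spec$tr, spec$design$events),
    spike = spike_series(spec$duration, spec$tr, spec$design$times,
                         if (is.null(spec$design$amplitude)) 1
                         else spec$design$amplitude)
  )
  am <- activation_map(spec$shape, spec$blobs, spec$map_range)
  nv <- prod(spec$shape)
  nt <- length(u)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  u_n <- outer(as.numeric(am$map), u) +
    matrix(stats::rnorm(nv * nt, sd = spec$sigma_m), nv, nt)
  x <- apply_hrf(u_n, kernel)
  sigma_a <- spec$sigma_a
  if (!is.null(spec$target_psnr)) {
    sigma_a <- noise_for_target_psnr(x, spec$target_psnr)
  }
  y <- x + matrix(stats::rnorm(nv * nt, sd = sigma_a), nv, nt)
  dim4 <- c(spec$shape, nt)
  structure(
    list(u = u,
         u_n = array(u_n, dim4),
         x = array(x, dim4),
         y = array(y, dim4),
         map = am$map, gm_mask = am$gm_mask,
         sigma_a = sigma_a, kernel = kernel, spec = spec),
    class = "synthetic_dataset"
  )
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 * log10(max(abs(clean)) / rms(noisy - clean))`.  A zero residual
#' yields `Inf`.
#'
#' @param clean,noisy arrays of identical shape.
#' @return pSNR in dB.
#' @export
psnr <- function(clean, noisy) {
  if (length(clean) != length(noisy)) stop("shapes do not match")
  rms <- sqrt(mean((noisy - clean)^2))
  if (rms == 0) return(Inf)
  20 * log10(max(abs(clean)) / rms)
}

#' Additive-noise level achieving a target pSNR
#'
#' Inverts the pSNR definition: returns the Gaussian noise standard deviation
#' whose expected root-mean-square residual gives the requested peak-SNR on
#' the given clean signal.
#'
#' @param clean the clean signal/image.
#' @param target_db finite target pSNR in dB.
#' @return Noise standard deviation.
#' @export
noise_for_target_psnr <- function(clean, target_db) {
  if (!is.finite(target_db)) stop("'target_db' must be finite")
  peak <- max(abs(clean))
  if (peak <= 0) stop("'clean' must be nonzero")
  peak / 10^(target_db / 20)
}
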