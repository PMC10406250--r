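# Validation metrics: voxel-wise Pearson correlation maps, RMSE summaries
# over gray-matter masks, spherical MNI ROIs.

.image_matrix <- function(image) {
  if (inherits(image, "fmri_image")) image <- image$data
  .check_image4d(image)
  d <- dim(image)
  list(m = matrix(image, prod(d[1:3]), d[4]), dim = d)
}

#' Voxel-wise Pearson correlation map
#'
#' Pearson correlation between every (masked) voxel's time course and a
#' reference series.  Voxels where either series has zero variance are
#' undefined (`NA`) and excluded from downstream means.
#'
#' @param image a 4D array or [fmri_image()].
#' @param reference numeric series of length `dim(image)[4]`.
#' @param mask optional 3D logical mask restricting the computation.
#' @return A list of class `corr_map`: `r` (3D array, `NA` outside the mask
#'   or where undefined), `defined` (3D logical), `reference` description.
#' @export
voxelwise_pearson <- function(image, reference, mask = NULL) {
  im <- .image_matrix(image)
  if (length(reference) != im$dim[4]) {
    stop("reference length must equal the image time dimension")
  }
  sel <- if (is.null(mask)) rep(TRUE, nrow(im$m)) else {
    if (!identical(dim(mask), im$dim[1:3])) stop("mask grid does not match")
    as.logical(mask)
  }
  r <- rep(NA_real_, nrow(im$m))
  ref_c <- reference - mean(reference)
  ref_ss <- sum(ref_c^2)
  if (ref_ss > 0) {
    m <- im$m[sel, , drop = FALSE]
    mc <- m - rowMeans(m)
    ss <- rowSums(mc^2)
    num <- as.numeric(mc %*% ref_c)
    rr <- rep(NA_real_, nrow(m))
    ok <- ss > 0
    rr[ok] <- num[ok] / sqrt(ss[ok] * ref_ss)
    r[sel] <- rr
  }
  defined <- !is.na(r)
  if (!any(defined)) {
    stop("all voxels undefined: no series with nonzero variance in the mask")
  }
  structure(
    list(r = array(r, im$dim[1:3]), defined = array(defined, im$dim[1:3])),
    class = "corr_map"
  )
}

#' MSE/RMSE summary against a ground truth
#'
#' Computes the per-voxel mean square error over time between a recovered
#' image and the truth (a shared series, broadcast to every voxel, or a full
#' 4D image), then summarizes over the mask: `rmse` is the square root of the
#' mean of the per-voxel MSEs and `mse_std_root` the square root of their
#' standard deviation.  The raw moments are returned as well.
#'
#' @param recovered a 4D array or [fmri_image()].
#' @param truth a series of length `nt` or a 4D array of matching shape.
#' @param mask optional 3D logical mask.
#' @param scale_map optional 3D amplitude map; when given, the truth series
#'   is scaled per voxel by the map before comparison (the forward-model
#'   ground truth of the phantom).
#' @return A list of class `metric_summary` with `rmse`, `mse_std_root`,
#'   `mse_mean`, `mse_std`, `n_voxels` and the per-voxel `mse` 3D array.
#' @export
mse_summary <- function(recovered, truth, mask = NULL, scale_map = NULL) {
  im <- .image_matrix(recovered)
  nv <- nrow(im$m); nt <- im$dim[4]
  if (is.null(dim(truth))) {
    if (length(truth) != nt) stop("truth series length must equal nt")
    tm <- matrix(truth, nv, nt, byrow = TRUE)
    if (!is.null(scale_map)) tm <- tm * as.numeric(scale_map)
  } else {
    tt <- .image_matrix(truth)
    if (!identical(tt$dim, im$dim)) stop("truth grid does not match")
    tm <- tt$m
  }
  sel <- if (is.null(mask)) rep(TRUE, nv) else as.logical(mask)
  if (!any(sel)) stop("empty mask")
  mse_vox <- rowMeans((im$m - tm)^2)
  vals <- mse_vox[sel]
  structure(
    list(rmse = sqrt(mean(vals)),
         mse_std_root = sqrt(stats::sd(vals)),
         mse_mean = mean(vals), mse_std = stats::sd(vals),
         n_voxels = sum(sel), mse = array(mse_vox, im$dim[1:3])),
    class = "metric_summary"
  )
}

#' Combined phantom recovery metrics
#'
#' Convenience summary for phantom experiments: RMSE moments plus the mean
#' and standard deviation of the voxel-wise Pearson correlation with the
#' ground-truth series, over the mask.
#'
#' @param recovered 4D array.
#' @param truth_series ground-truth activity-inducing series.
#' @param mask 3D logical mask (typically the gray-matter mask).
#' @return A list with `rmse`, `mse_std_root`, `r_mean`, `r_std`,
#'   `n_voxels`.
#' @export
phantom_metrics <- function(recovered, truth_series, mask = NULL) {
  ms <- mse_summary(recovered, truth_series, mask)
  cm <- voxelwise_pearson(recovered, truth_series, mask)
  rv <- cm$r[cm$defined & (if (is.null(mask)) TRUE else mask)]
  list(rmse = ms$rmse, mse_std_root = ms$mse_std_root,
       r_mean = mean(rv), r_std = stats::sd(rv), n_voxels = ms$n_voxels)
}

#' Spherical ROI in world (MNI) coordinates
#'
#' A voxel belongs to the ROI iff its world-space center, obtained by
#' applying the affine to its 0-based index, lies within `radius` mm of the
#' ROI center (inclusive).
#'
#' @param center world-space center, mm.
#' @param radius sphere radius, mm.
#' @param affine 4x4 voxel-to-world matrix.
#' @param dim integer 3-vector of grid sizes.
#' @return 3D logical mask; empty (with a warning) if the sphere misses the
#'   grid.
#' @export
build_spherical_roi <- function(center, radius, affine, dim) {
  if (radius <= 0) stop("'radius' must be positive")
  if (!identical(dim(affine), c(4L, 4L))) stop("'affine' must be 4x4")
  g <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1L,
                             j = seq_len(dim[2]) - 1L,
                             k = seq_len(dim[3]) - 1L))
  world <- cbind(g, 1) %*% t(affine)
  d2 <- (world[, 1] - center[1])^2 + (world[, 2] - center[2])^2 +
    (world[, 3] - center[3])^2
  roi <- array(d2 <= radius^2, dim = dim)
  if (!any(roi)) warning("ROI lies entirely outside the grid: empty mask")
  roi
}

#' Union of ROI masks
#'
#' @param ... 3D logical masks on the same grid.
#' @return Their voxel-wise union.
#' @export
roi_union <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1]]) && !is.array(masks[[1]])) {
    masks <- masks[[1]]
  }
  out <- masks[[1]]
  for (m in masks[-1]) {
    if (!identical(dim(m), dim(out))) stop("masks on different grids")
    out <- out | m
  }
  out
}

#' Mean correlation inside an ROI
#'
#' Arithmetic mean of the defined correlation values inside the ROI, with
#' the contributing voxel count.
#'
#' @param cmap a `corr_map` from [voxelwise_pearson()].
#' @param roi 3D logical mask.
#' @return A list with `mean_r` and `n_voxels`.
#' @export
roi_mean_correlation <- function(cmap, roi) {
  if (!inherits(cmap, "corr_map")) stop("'cmap' must be a corr_map")
  sel <- as.logical(roi) & cmap$defined
  if (!any(sel)) stop("empty intersection between ROI and defined voxels")
  list(mean_r = mean(cmap$r[sel]), n_voxels = sum(sel))
}

#' Unit-amplitude task regressor
#'
#' Piecewise-constant signal with unit amplitude while the task is performed
#' and zero elsewhere, on the TR grid (half-open blocks).
#'
#' @param duration scan length in seconds.
#' @param tr repetition time.
#' @param blocks data frame with `onset` and `offset` columns (seconds).
#' @return Numeric series.
#' @export
task_regressor <- function(duration, tr, blocks) {
  blocks <- as.data.frame(blocks)
  if (nrow(blocks) > 0L) blocks$amplitude <- 1
  boxcar_series(duration, tr, blocks)
}

#' Motor-task somatosensory ROI centers
#'
#' MNI coordinates (mm) of somatosensory homunculus landmarks used to build
#' per-task spherical ROIs: five finger sites per hand, three tongue sites
#' (bilateral), and one foot site per side.  Hand and foot ROIs follow the
#' contralateral motor convention (left-hemisphere sites, negative x, serve
#' the right-hand/right-foot tasks).
#'
#' @return A data frame with columns `task`, `location`, `x`, `y`, `z`.
#' @export
motor_roi_table <- function() {
  path <- system.file("extdata", "motor_rois.tsv", package = "anisofmri",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build grouped task ROI masks from a center table
#'
#' Builds one spherical ROI per table row and unions the rows of each task
#' into a single mask; when a gray-matter mask is supplied, the union is
#' intersected with it afterwards.
#'
#' @param table data frame with `task`, `x`, `y`, `z` columns (mm), e.g.
#'   [motor_roi_table()].
#' @param affine 4x4 voxel-to-world matrix.
#' @param dim grid sizes.
#' @param radius sphere radius in mm.
#' @param gm_mask optional 3D logical gray-matter mask.
#' @return Named list of 3D logical masks, one per task.
#' @export
task_roi_masks <- function(table, affine, dim, radius = 3, gm_mask = NULL) {
  tasks <- unique(table$task)
  out <- lapply(tasks, function(tk) {
    rows <- table[table$task == tk, , drop = FALSE]
    masks <- lapply(seq_len(nrow(rows)), function(i) {
      build_spherical_roi(c(rows$x[i], rows$y[i], rows$z[i]), radius,
                          affine, dim)
    })
    m <- roi_union(masks)
    if (!is.null(gm_mask)) m <- m & gm_mask
    m
  })
  names(out) <- tasks
  out
}
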