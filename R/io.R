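# NIfTI-1 input/output, preprocessing (linear detrend + z-normalization),
# run manifests.

#' A 4D fMRI image container
#'
#' Thin container carrying the value array, the repetition time and the
#' voxel-to-world affine.  All computations run in voxel index space; the
#' affine is carried through untouched for ROI construction and output.
#'
#' @param data 4D numeric array `(nx, ny, nz, nt)`.
#' @param tr repetition time in seconds.
#' @param affine 4x4 voxel-to-world matrix (default: scaled identity from
#'   `voxel_size`).
#' @param voxel_size voxel edge lengths in mm (used only for the default
#'   affine).
#' @return An object of class `fmri_image`.
#' @export
fmri_image <- function(data, tr, affine = NULL, voxel_size = c(2, 2, 2)) {
  .check_image4d(data, "data")
  if (!is.finite(tr) || tr <= 0) stop("'tr' must be positive")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(list(data = data, tr = tr, affine = affine), class = "fmri_image")
}

#' @export
print.fmri_image <- function(x, ...) {
  cat(sprintf("<fmri_image> %s, TR = %g s\n",
              paste(dim(x$data), collapse = "x"), x$tr))
  invisible(x)
}

#' @export
dim.fmri_image <- function(x) dim(x$data)

#' Read a 4D NIfTI-1 image
#'
#' The TR is taken from the NIfTI time-axis pixdim; a `tr` argument
#' overrides it (required when the header carries no usable TR).
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param tr optional TR override in seconds.
#' @return An [fmri_image()].
#' @export
read_fmri <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop(sprintf("expected a 4D image, got %dD: %s", length(dim(arr)), path))
  }
  hdr_tr <- RNifti::pixdim(img)
  hdr_tr <- if (length(hdr_tr) >= 4L) hdr_tr[4L] else NA_real_
  if (is.null(tr)) {
    if (!is.finite(hdr_tr) || hdr_tr <= 0) {
      stop("no usable TR in the NIfTI header; supply 'tr' explicitly")
    }
    tr <- hdr_tr
  }
  fmri_image(array(as.numeric(arr), dim(arr)), tr = tr,
             affine = unclass(RNifti::xform(img)))
}

#' Write a 4D image (or 3D map) as NIfTI-1
#'
#' @param image an [fmri_image()], or a plain 3D/4D array.
#' @param path output `.nii` or `.nii.gz` path.
#' @param tr repetition time (for plain 4D arrays).
#' @param affine voxel-to-world matrix (for plain arrays).
#' @return `path`, invisibly.
#' @export
write_fmri <- function(image, path, tr = NULL, affine = NULL) {
  if (inherits(image, "fmri_image")) {
    arr <- image$data
    tr <- image$tr
    affine <- image$affine
  } else {
    arr <- image
    if (is.null(affine)) affine <- diag(c(2, 2, 2, 1))
  }
  nim <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(nim)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (length(dim(arr)) == 4L) {
    if (is.null(tr)) stop("'tr' is required for 4D output")
    RNifti::pixdim(nim) <- c(vox, tr)
  } else {
    RNifti::pixdim(nim) <- vox
  }
  RNifti::qform(nim) <- structure(affine, code = 2L)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read a 3D binary mask
#'
#' @param path NIfTI file holding a 3D map; nonzero voxels are in the mask.
#' @return 3D logical array.
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L) stop("mask must be a 3D image")
  arr != 0
}

#' Detrend and z-normalize every voxel time course
#'
#' Per voxel: subtract the least-squares linear trend over time, then divide
#' by the residual standard deviation, yielding zero-mean, unit-variance
#' time courses.  Voxels whose residual is (numerically) zero after
#' detrending are left at zero and flagged.
#'
#' @param image an [fmri_image()] or 4D array.
#' @return Same container as the input, with a 3D logical attribute
#'   `flat_voxels` marking constant-after-detrend voxels.
#' @export
preprocess_fmri <- function(image) {
  arr <- if (inherits(image, "fmri_image")) image$data else image
  .check_image4d(arr)
  d <- dim(arr)
  nt <- d[4]
  if (nt < 3L) stop("at least 3 time points are required for detrending")
  m <- matrix(arr, prod(d[1:3]), nt)
  tt <- seq_len(nt)
  X <- cbind(1, tt - mean(tt))
  # residual-maker applied on the right: rows are series
  P <- X %*% solve(crossprod(X), t(X))
  res <- m - m %*% t(P)
  sds <- sqrt(rowSums(res^2) / (nt - 1L))
  flat <- sds <= 1e-12 * pmax(1, apply(abs(m), 1L, max))
  res[flat, ] <- 0
  res[!flat, ] <- res[!flat, , drop = FALSE] / sds[!flat]
  out <- array(res, d)
  flat3 <- array(flat, d[1:3])
  if (inherits(image, "fmri_image")) {
    image$data <- out
    attr(image, "flat_voxels") <- flat3
    image
  } else {
    attr(out, "flat_voxels") <- flat3
    out
  }
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the
#' subcommand, all configuration values, input/output paths, the seed and
#' the package version, as JSON.
#'
#' @param path output path.
#' @param command subcommand name.
#' @param params named list of parameters.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, params) {
  manifest <- list(
    tool = "anisofmri",
    version = as.character(utils::packageVersion("anisofmri")),
    command = command,
    params = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path manifest JSON path.
#' @return The manifest as a list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
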