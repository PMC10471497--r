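#' Construct a voxel stack
#'
#' A voxel stack holds per-subject voxel features (typically Jacobian
#' determinants of deformation fields) as a dense subjects x voxels matrix
#' restricted to a binary brain mask, together with the mask geometry and the
#' NIfTI affine, so volumes can be reassembled losslessly.
#'
#' @param data numeric matrix, subjects in rows, masked voxels in columns.
#' @param mask 3D logical (or 0/1) array; `sum(mask)` must equal `ncol(data)`.
#' @param affine 4x4 affine matrix carried through to NIfTI output
#'   (default identity).
#' @param subjects optional subject identifiers (default `1:nrow(data)`).
#' @return An object of class `voxel_stack` with elements `data`, `mask`,
#'   `dim`, `affine`, `subjects` and `voxel_index` (linear indices of masked
#'   voxels in the 3D grid, column order of `data`).
#' @export
voxel_stack <- function(data, mask, affine = diag(4), subjects = NULL) {
  data <- as.matrix(data)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  if (sum(mask) != ncol(data)) {
    stop("mask selects ", sum(mask), " voxels but data has ", ncol(data),
         " columns")
  }
  if (!all(is.finite(data))) stop("voxel data must be finite")
  if (is.null(subjects)) subjects <- seq_len(nrow(data))
  structure(
    list(data = data, mask = mask, dim = dim(mask), affine = affine,
         subjects = subjects, voxel_index = which(mask)),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  cat("voxel_stack:", nrow(x$data), "subjects x", ncol(x$data),
      "masked voxels on a", paste(x$dim, collapse = "x"), "grid\n")
  invisible(x)
}

#' @export
dim.voxel_stack <- function(x) dim(x$data)

#' Re-embed a per-voxel vector into the 3D grid
#'
#' @param stack a `voxel_stack` (supplies mask and geometry).
#' @param values numeric vector with one entry per masked voxel.
#' @param fill value used outside the mask (default `NA`).
#' @return A 3D array of dimension `stack$dim`.
#' @export
unmask <- function(stack, values, fill = NA_real_) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (length(values) != length(stack$voxel_index)) {
    stop("values must have one entry per masked voxel")
  }
  vol <- array(fill, dim = stack$dim)
  vol[stack$voxel_index] <- values
  vol
}

#' Ellipsoidal brain-like mask
#'
#' Default mask used by the synthetic generators: an ellipsoid inscribed in
#' the grid, mimicking the fact that a brain mask occupies roughly half of
#' the bounding box and leaves background voxels outside the analysis.
#'
#' @param shape integer vector of length 3, grid dimensions.
#' @param radius_frac fraction of each half-dimension used as semi-axis
#'   (default 0.9).
#' @return A 3D logical array.
#' @export
ellipsoid_mask <- function(shape = c(12L, 12L, 12L), radius_frac = 0.9) {
  stopifnot(length(shape) == 3L, all(shape >= 3L))
  centre <- (shape + 1) / 2
  semi <- radius_frac * (shape - 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                               z = seq_len(shape[3])))
  d2 <- ((idx[, 1] - centre[1]) / semi[1])^2 +
        ((idx[, 2] - centre[2]) / semi[2])^2 +
        ((idx[, 3] - centre[3]) / semi[3])^2
  array(d2 <= 1, dim = shape)
}
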