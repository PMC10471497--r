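#' Write a voxel stack as 4D NIfTI plus 3D mask
#'
#' @param stack a [voxel_stack()].
#' @param path output 4D image path (`.nii` or `.nii.gz`).
#' @param mask_path output mask path.
#' @return Invisibly, the two paths.
#' @export
write_voxel_stack <- function(stack, path, mask_path) {
  stopifnot(inherits(stack, "voxel_stack"))
  n <- nrow(stack$data)
  arr <- array(0, dim = c(stack$dim, n))
  for (i in seq_len(n)) {
    vol <- array(0, dim = stack$dim)
    vol[stack$voxel_index] <- stack$data[i, ]
    arr[, , , i] <- vol
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(stack$mask),
                                           dim = stack$dim)), mask_path)
  invisible(c(path, mask_path))
}

#' Read a 4D NIfTI image and mask into a voxel stack
#'
#' Validates that the mask is 3D, binary and on the image grid, then
#' extracts the subjects x masked-voxels matrix. Round-trips
#' [write_voxel_stack()] output losslessly.
#'
#' @param path 4D image path.
#' @param mask_path 3D mask path.
#' @return A [voxel_stack()].
#' @export
read_voxel_stack <- function(path, mask_path) {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img)
  if (length(di) != 4L) stop("image must be 4D")
  if (!identical(dim(msk)[1:3], di[1:3])) stop("mask grid mismatch")
  mv <- as.numeric(msk)
  if (!all(mv %in% c(0, 1))) stop("mask must be binary")
  mask <- array(mv == 1, dim = di[1:3])
  vidx <- which(mask)
  n <- di[4]
  dat <- matrix(NA_real_, n, length(vidx))
  for (i in seq_len(n)) {
    vol <- img[, , , i]
    dat[i, ] <- vol[vidx]
  }
  voxel_stack(dat, mask, affine = unclass(RNifti::xform(img)))
}

#' Write a per-voxel map (or several) as NIfTI
#'
#' @param stack a [voxel_stack()] supplying geometry.
#' @param values numeric vector (3D output) or matrix with one row per
#'   volume (4D output), columns = masked voxels.
#' @param path output path.
#' @param fill background value outside the mask (default 0).
#' @return Invisibly, `path`.
#' @export
write_map <- function(stack, values, path, fill = 0) {
  if (is.matrix(values)) {
    arr <- array(fill, dim = c(stack$dim, nrow(values)))
    for (i in seq_len(nrow(values))) {
      vol <- array(fill, dim = stack$dim)
      vol[stack$voxel_index] <- values[i, ]
      arr[, , , i] <- vol
    }
  } else {
    arr <- unmask(stack, values, fill = fill)
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a covariate table from delimited text
#'
#' Reads a TSV with a header, checks required columns and unique subject
#' ids, and excludes subjects with missing values in any model variable
#' (logging the count, as cohort analyses report their missing-data
#' exclusions).
#'
#' @param path TSV file path.
#' @param required character vector of required column names (besides
#'   `subject`).
#' @return data.frame of complete rows.
#' @export
read_covariates <- function(path, required = character()) {
  d <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!"subject" %in% names(d)) stop("missing required column: subject")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d$subject)) stop("duplicated subject id(s)")
  model_cols <- c("subject", required)
  keep <- complete.cases(d[, model_cols, drop = FALSE])
  if (any(!keep)) {
    message("excluded ", sum(!keep), " subject(s) with missing data")
    d <- d[keep, , drop = FALSE]
  }
  for (cl in required) {
    if (!is.numeric(d[[cl]]) && !is.factor(d[[cl]]) && !is.character(d[[cl]])) {
      stop("cannot interpret column '", cl, "'")
    }
  }
  rownames(d) <- NULL
  d
}

#' Write a covariate table as TSV
#'
#' @param d data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_covariates <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
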