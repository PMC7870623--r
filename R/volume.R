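#' Construct a knee MR volume
#'
#' A light container for a rank-3 intensity grid with physical voxel
#' spacing and an orientation tag.
#'
#' @param data numeric 3D array (rows x cols x slices), finite and
#'   non-negative.
#' @param spacing_mm length-3 numeric: physical size of a voxel along
#'   (row, col, slice), in millimetres; all positive.
#' @param orientation `"coronal"` or `"sagittal"`.
#' @return an object of class `knee_volume`.
#' @export
knee_volume <- function(data, spacing_mm, orientation = c("coronal", "sagittal")) {
  orientation <- match.arg(orientation)
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing_mm) == 3, all(spacing_mm > 0),
            all(is.finite(data)))
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 orientation = orientation),
            class = "knee_volume")
}

#' @export
print.knee_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<knee_volume> %d x %d x %d voxels, spacing %.3f x %.3f x %.2f mm, %s\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], x$orientation))
  invisible(x)
}

#' Write a volume (or label mask) as NIfTI
#'
#' @param vol a `knee_volume`, or a plain 3D array (then `spacing_mm` must
#'   be given).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing_mm voxel spacing when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing_mm = NULL) {
  if (inherits(vol, "knee_volume")) {
    dat <- vol$data; sp <- vol$spacing_mm
  } else {
    stopifnot(!is.null(spacing_mm))
    dat <- vol; sp <- spacing_mm
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @param orientation orientation tag to attach.
#' @return a `knee_volume` with spacing taken from the NIfTI header.
#' @export
read_volume <- function(path, orientation = c("coronal", "sagittal")) {
  orientation <- match.arg(orientation)
  img <- RNifti::readNifti(path)
  knee_volume(array(as.numeric(img), dim(img)),
              RNifti::pixdim(img)[1:3], orientation)
}
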