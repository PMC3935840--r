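#' Read a CT volume from a NIfTI file
#'
#' Reads a scalar 3-D image (NIfTI-1, optionally gzipped) into a
#' [CtVolume]. Values are promoted to doubles; any scale slope/intercept
#' stored in the header is applied by the reader, so the returned values are
#' attenuation in HU as stored. Orientation metadata are kept opaquely and
#' written back by [writeVolume()].
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [CtVolume].
#' @examples
#' vol <- new("CtVolume", values = array(0, c(5, 5, 5)),
#'            spacing = c(1, 1, 1))
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(vol, f)
#' identical(imgData(readVolume(f)), imgData(vol))
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("expected a 3-D scalar image, got ", length(d), "-D payload")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  vals <- array(as.double(img), dim = d)
  new("CtVolume", values = vals, spacing = as.double(sp),
      orientation = RNifti::niftiHeader(img))
}

#' Write a CT volume to a NIfTI file
#'
#' @param vol a [CtVolume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CtVolume"))
  img <- RNifti::asNifti(vol@values, reference = vol@orientation)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary tumor mask from a NIfTI file
#'
#' Values must be binary. A mask with two distinct values `{0, v}` (v > 0)
#' is coerced to logical by `> 0` thresholding with a warning, so
#' segmentations stored with other positive label values load. A mask with
#' more than two distinct values needs an explicit `label`, otherwise the
#' selection is ambiguous and an error is raised.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param label optional: keep voxels equal to this value and drop all
#'   others (for multi-label segmentations).
#' @return A [RoiMask].
#' @export
readMask <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("expected a 3-D scalar mask, got ", length(d), "-D payload")
  vals <- array(as.double(img), dim = d)
  uv <- sort(unique(as.vector(vals)))
  if (!is.null(label)) {
    bin <- vals == label
  } else if (length(uv) > 2L) {
    stop("mask has ", length(uv),
         " distinct values; pass `label` to select one")
  } else {
    if (!all(uv %in% c(0, 1)))
      warning("mask values {", paste(uv, collapse = ", "),
              "} coerced to binary by > 0 thresholding")
    bin <- vals > 0
  }
  sp <- RNifti::pixdim(img)[seq_len(3)]
  new("RoiMask", values = bin, spacing = as.double(sp))
}

#' Write a binary mask to a NIfTI file
#'
#' @param mask a [RoiMask].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "RoiMask"))
  img <- RNifti::asNifti(array(as.integer(mask@values),
                               dim = dim(mask@values)))
  RNifti::pixdim(img) <- mask@spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Extract the masked voxel sample from a volume
#'
#' Collects the attenuation values and grid coordinates of all
#' mask-foreground voxels. Volume and mask must be voxel-aligned: same grid
#' shape, spacings equal within 1e-4 mm (format rounding tolerance; no
#' resampling is performed).
#'
#' @param vol a [CtVolume].
#' @param mask a [RoiMask], voxel-aligned with `vol`.
#' @return A [VoxelSample]: HU values, (x, y, z) positions (1-based, x
#'   fastest), and the single-voxel volume in mm^3.
#' @examples
#' vol <- new("CtVolume", values = array(40, c(4, 4, 4)),
#'            spacing = c(0.7, 0.7, 5))
#' m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
#' mask <- new("RoiMask", values = m, spacing = c(0.7, 0.7, 5))
#' s <- extractRoiVoxels(vol, mask)
#' nVoxels(s)       # 8
#' voxelVolume(s)   # 2.45 mm^3
#' @export
extractRoiVoxels <- function(vol, mask) {
  stopifnot(is(vol, "CtVolume"), is(mask, "RoiMask"))
  if (!identical(dim(vol@values), dim(mask@values)))
    stop("volume and mask grid shapes differ")
  if (any(abs(vol@spacing - mask@spacing) > 1e-4))
    stop("volume and mask spacings differ by more than 1e-4 mm")
  fg <- which(mask@values)
  if (length(fg) == 0L) stop("mask has no foreground voxels")
  pos <- arrayInd(fg, dim(mask@values))
  colnames(pos) <- c("x", "y", "z")
  new("VoxelSample", hu = as.double(vol@values[fg]),
      positions = pos, dims = as.integer(dim(vol@values)),
      voxelVolume = prod(vol@spacing))
}
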