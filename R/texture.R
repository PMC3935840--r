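#' Quantize ROI voxels to discrete gray levels
#'
#' Resamples the segmented tumor's attenuation values to `nLevels` discrete
#' gray levels (default 16) by uniform binning over the ROI's own (min, max)
#' range: level = min(L, floor(L * (v - min) / (max - min)) + 1). This
#' reduces image noise and normalizes intensity across subjects by
#' clustering voxels of similar intensity. A flat ROI (max = min) maps every
#' voxel to level 1. Binning is per scan, per timepoint; a fixed HU window
#' can be imposed instead via `huRange`.
#'
#' @param sample a [VoxelSample].
#' @param nLevels number of gray levels L >= 2 (default 16).
#' @param huRange optional numeric(2) fixed (min, max) HU window to bin over
#'   instead of the ROI's own range; values outside are clamped to the end
#'   levels.
#' @return A [QuantizedRoi].
#' @export
quantizeRoi <- function(sample, nLevels = 16L, huRange = NULL) {
  stopifnot(is(sample, "VoxelSample"))
  L <- as.integer(nLevels)
  if (L < 2L) stop("nLevels must be >= 2")
  v <- sample@hu
  rng <- if (is.null(huRange)) range(v) else sort(as.double(huRange))
  lo <- rng[1]; hi <- rng[2]
  if (hi == lo) {
    lev <- rep(1L, length(v))
  } else {
    lev <- floor(L * (v - lo) / (hi - lo)) + 1
    lev <- as.integer(pmin(L, pmax(1L, lev)))
  }
  grid <- array(0L, dim = sample@dims)
  grid[sample@positions] <- lev
  new("QuantizedRoi", levels = grid, nLevels = L, huRange = c(lo, hi))
}

.connOffsets <- function(connectivity) {
  switch(connectivity,
    "26" = {
      o <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
      o[rowSums(abs(o)) > 0, , drop = FALSE]
    },
    "6" = rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1)),
    "8-2d" = {
      o <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = 0))
      o[rowSums(abs(o)) > 0, , drop = FALSE]
    },
    stop("unknown connectivity '", connectivity,
         "'; use '26', '6' or '8-2d'")
  )
}

#' Partition a quantized ROI into homogeneous zones
#'
#' Labels the maximal connected components of equal gray level: every
#' foreground voxel belongs to exactly one zone of voxels sharing its level
#' under the chosen neighborhood rule. Default is the full 26-neighborhood
#' in 3-D; "6" is face-connectivity and "8-2d" treats each axial slice
#' independently with in-plane 8-connectivity. Zones are defined on the
#' voxel lattice regardless of physical spacing.
#'
#' @param q a [QuantizedRoi].
#' @param connectivity "26" (default), "6" or "8-2d".
#' @return A list with `zones` (data.frame: `level`, `size` of each zone,
#'   in scan-order of first voxel), `labels` (integer array, 0 =
#'   background), `nVoxels` and `connectivity`.
#' @examples
#' # a uniform ROI is a single zone covering all its voxels
#' @export
labelZones <- function(q, connectivity = "26") {
  stopifnot(is(q, "QuantizedRoi"))
  off <- .connOffsets(connectivity)
  lab <- .labelZonesCpp(as.integer(q@levels), dim(q@levels),
                        matrix(as.integer(off), ncol = 3))
  nz <- attr(lab, "n_zones")
  labels <- array(as.integer(lab), dim = dim(q@levels))
  fg <- labels != 0L
  sizes <- tabulate(labels[fg], nbins = nz)
  lev <- integer(nz)
  lev[labels[fg]] <- q@levels[fg]
  list(zones = data.frame(level = lev, size = sizes),
       labels = labels,
       nVoxels = sum(fg),
       connectivity = connectivity)
}

#' Build the gray-level size-zone matrix
#'
#' M(m, n) counts the zones with quantized gray level m and size n voxels:
#' M(3, 5) = 6 means six homogeneous regions of level 3, each five voxels
#' large. The conservation identity sum n * M(m, n) = foreground voxel count
#' is checked on construction.
#'
#' @param zones the output of [labelZones()].
#' @param nLevels number of rows; defaults to the largest level present.
#' @return A [GLSZM].
#' @export
buildGLSZM <- function(zones, nLevels = NULL) {
  z <- zones$zones
  if (nrow(z) == 0L) stop("empty zone list")
  L <- if (is.null(nLevels)) max(z$level) else as.integer(nLevels)
  smax <- max(z$size)
  M <- table(factor(z$level, levels = seq_len(L)),
             factor(z$size, levels = seq_len(smax)))
  M <- matrix(as.numeric(M), nrow = L, ncol = smax,
              dimnames = list(seq_len(L), seq_len(smax)))
  new("GLSZM", counts = M, nVoxels = as.integer(zones$nVoxels),
      connectivity = zones$connectivity)
}

#' Intensity variability of a GLSZM
#'
#' Variability of zone counts across gray levels:
#' IV = sum_m (sum_n M(m, n))^2, the sum over gray levels of the squared
#' number of zones at that level (the size-zone "gray-level non-uniformity"
#' sum). Low values indicate a gray-level-homogeneous tumor; a uniform ROI
#' gives 1. Unnormalized by default; `normalized = TRUE` divides by the
#' total zone count.
#'
#' @param g a [GLSZM].
#' @param normalized divide by total zone count? Default FALSE.
#' @return The intensity variability.
#' @export
intensityVariability <- function(g, normalized = FALSE) {
  stopifnot(is(g, "GLSZM"))
  v <- sum(rowSums(g@counts)^2)
  if (normalized) v <- v / sum(g@counts)
  v
}

#' Size-zone variability of a GLSZM
#'
#' Variability of zone counts across zone sizes:
#' SZV = sum_n (sum_m M(m, n))^2, the sum over zone sizes of the squared
#' number of zones of that size (the "size-zone non-uniformity" sum). Low
#' values indicate uniformly sized zones; a uniform ROI gives 1.
#' Unnormalized by default.
#'
#' @param g a [GLSZM].
#' @param normalized divide by total zone count? Default FALSE.
#' @return The size-zone variability.
#' @export
sizeZoneVariability <- function(g, normalized = FALSE) {
  stopifnot(is(g, "GLSZM"))
  v <- sum(colSums(g@counts)^2)
  if (normalized) v <- v / sum(g@counts)
  v
}

#' Dump a GLSZM as a delimited table
#'
#' Debug output: rows = gray level m, columns = zone size n.
#'
#' @param g a [GLSZM].
#' @param path output path for a tab-delimited table.
#' @return `path`, invisibly.
#' @export
writeGLSZM <- function(g, path) {
  stopifnot(is(g, "GLSZM"))
  write.table(data.frame(level = rownames(g@counts), g@counts,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a zone label map as a NIfTI integer image
#'
#' Debug output pairing with [labelZones()]: each voxel carries its zone id.
#'
#' @param zones output of [labelZones()].
#' @param spacing voxel spacing (mm) to stamp on the image.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeZoneMap <- function(zones, spacing, path) {
  img <- RNifti::asNifti(zones$labels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}
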