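#' CtVolume: a 3-D CT attenuation grid
#'
#' Container for one CT volume: a 3-D array of attenuation values in
#' Hounsfield units (HU) plus the physical voxel spacing in mm. Orientation
#' metadata read from file is carried opaquely and written back on output.
#'
#' All modules share one coordinate convention: 1-based integer (x, y, z)
#' grid indices, x varying fastest (R array order).
#'
#' @slot values 3-D numeric array of attenuation (HU).
#' @slot spacing numeric(3), positive voxel edge lengths (mm) along (x, y, z).
#' @slot orientation opaque orientation metadata (NIfTI header fields or
#'   NULL); preserved on write.
#' @export
setClass("CtVolume",
  representation(values = "array", spacing = "numeric", orientation = "ANY"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            orientation = NULL))

setValidity("CtVolume", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3-D array")
  if (any(dim(v) < 1L)) return("grid must have >= 1 voxel per axis")
  if (!all(is.finite(v))) return("attenuation values must all be finite")
  s <- object@spacing
  if (length(s) != 3L || !all(is.finite(s)) || any(s <= 0))
    return("spacing must be three positive voxel edge lengths (mm)")
  TRUE
})

#' RoiMask: a binary tumor segmentation mask
#'
#' A 3-D binary grid voxel-aligned with its paired [CtVolume] (same shape,
#' same spacing). Foreground (TRUE) voxels delimit the tumor region of
#' interest.
#'
#' @slot values 3-D logical array.
#' @slot spacing numeric(3), voxel spacing in mm; must equal the paired
#'   volume's spacing.
#' @export
setClass("RoiMask",
  representation(values = "array", spacing = "numeric"),
  prototype(values = array(FALSE, c(1, 1, 1)), spacing = c(1, 1, 1)))

setValidity("RoiMask", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3-D array")
  if (!is.logical(v)) return("mask values must be logical")
  if (anyNA(v)) return("mask values must not contain NA")
  s <- object@spacing
  if (length(s) != 3L || !all(is.finite(s)) || any(s <= 0))
    return("spacing must be three positive voxel edge lengths (mm)")
  TRUE
})

#' VoxelSample: the masked voxel sample of one scan
#'
#' The attenuation values and grid coordinates of all mask-foreground voxels
#' of one scan, together with the physical volume of a single voxel. This is
#' the input to every feature computation.
#'
#' @slot hu numeric vector of attenuation values (HU), one per foreground
#'   voxel, in grid scan order (x fastest).
#' @slot positions integer matrix (n x 3) of 1-based (x, y, z) grid indices,
#'   rows aligned with `hu`.
#' @slot dims integer(3), shape of the originating grid.
#' @slot voxelVolume numeric scalar, mm^3 (product of spacings).
#' @export
setClass("VoxelSample",
  representation(hu = "numeric", positions = "matrix", dims = "integer",
                 voxelVolume = "numeric"))

setValidity("VoxelSample", function(object) {
  n <- length(object@hu)
  if (n < 1L) return("sample must contain >= 1 voxel")
  if (!all(is.finite(object@hu))) return("hu values must be finite")
  if (nrow(object@positions) != n || ncol(object@positions) != 3L)
    return("positions must be an n x 3 matrix aligned with hu")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be the 3-D shape of the source grid")
  if (length(object@voxelVolume) != 1L || !is.finite(object@voxelVolume) ||
      object@voxelVolume <= 0)
    return("voxelVolume must be a positive scalar (mm^3)")
  TRUE
})

#' QuantizedRoi: ROI voxels resampled to discrete gray levels
#'
#' The mask foreground re-expressed on a small number of discrete gray
#' levels (default 16) by uniform min-max binning of the ROI attenuation
#' values. Background voxels carry level 0.
#'
#' @slot levels 3-D integer array; 0 = background, 1..nLevels = foreground.
#' @slot nLevels integer, number of gray levels L (>= 2).
#' @slot huRange numeric(2), the (min, max) HU used for binning.
#' @export
setClass("QuantizedRoi",
  representation(levels = "array", nLevels = "integer", huRange = "numeric"))

setValidity("QuantizedRoi", function(object) {
  lv <- object@levels
  if (length(dim(lv)) != 3L) return("levels must be a 3-D array")
  L <- object@nLevels
  if (length(L) != 1L || L < 1L) return("nLevels must be a positive integer")
  fg <- lv[lv != 0L]
  if (length(fg) < 1L) return("quantized ROI must have >= 1 foreground voxel")
  if (any(fg < 1L | fg > L))
    return("every foreground voxel must carry a level in 1..nLevels")
  TRUE
})

#' GLSZM: the gray-level size-zone matrix
#'
#' Counts of homogeneous zones indexed by quantized gray level m (rows) and
#' zone size n in voxels (columns). A zone is a maximal connected set of
#' foreground voxels sharing one gray level under the chosen neighborhood
#' rule. Entry M(m, n) = number of zones with level m and size n; e.g.
#' M(3, 5) = 6 means six zones of gray level 3 and size 5 voxels. The
#' conservation identity sum_{m,n} n * M(m, n) = number of foreground voxels
#' is enforced by the validity method.
#'
#' @slot counts numeric matrix (L x maxZoneSize) of zone counts; rownames
#'   are gray levels "1".."L", colnames zone sizes "1".."maxZoneSize".
#' @slot nVoxels integer, foreground voxel count.
#' @slot connectivity character, the neighborhood rule ("26", "6" or "8-2d").
#' @export
setClass("GLSZM",
  representation(counts = "matrix", nVoxels = "integer",
                 connectivity = "character"))

setValidity("GLSZM", function(object) {
  M <- object@counts
  if (any(M < 0) || any(M != round(M)))
    return("zone counts must be nonnegative integers")
  if (sum(M) < 1) return("matrix must contain >= 1 zone")
  sizes <- as.numeric(colnames(M))
  if (ncol(M) > 0 && any(is.na(sizes)))
    return("colnames must be the zone sizes")
  tot <- sum(M %*% sizes)
  if (tot != object@nVoxels)
    return(sprintf(
      "conservation violated: sum n*M(m,n) = %d but nVoxels = %d",
      tot, object@nVoxels))
  if (!object@connectivity %in% c("26", "6", "8-2d"))
    return("connectivity must be one of '26', '6', '8-2d'")
  TRUE
})

#' ModelReport: per-arm statistical analysis report
#'
#' The full per-arm analysis output: univariate percent-change comparisons
#' by responder status, the screened variable set, the final backward-
#' stepwise logistic model (odds ratios per unit percent change, Wald 95%
#' CIs, p-values), and ROC results (AUC, Youden-optimal cutoff,
#' sensitivity/specificity), plus the conventions the run used.
#'
#' @slot arm character, treatment arm label.
#' @slot n named integer vector: responders / nonresponders in the arm.
#' @slot univariate data.frame: variable, mean/sd by responder status,
#'   Mann-Whitney p, test path used.
#' @slot screened character vector of variables passing the p < threshold
#'   univariate screen.
#' @slot model data.frame: retained variable, odds ratio, CI bounds, p.
#' @slot separation logical, TRUE if the logistic fit showed complete or
#'   quasi-complete separation (estimates unreliable).
#' @slot roc list per scored variable: auc, cutoff, direction, sensitivity,
#'   specificity.
#' @slot conventions named list echoing the run conventions (kurtosis type,
#'   percent-change denominator, connectivity, gray levels, thresholds,
#'   seeds, package version).
#' @export
setClass("ModelReport",
  representation(arm = "character", n = "integer", univariate = "data.frame",
                 screened = "character", model = "data.frame",
                 separation = "logical", roc = "list", conventions = "list"))

setValidity("ModelReport", function(object) {
  if (nrow(object@model) > 0) {
    ok <- with(object@model, is.na(or) | (ci_lo <= or & or <= ci_hi))
    if (!all(ok)) return("each CI must bracket its odds ratio")
  }
  for (r in object@roc) {
    if (!is.null(r$auc) && (r$auc < 0 || r$auc > 1))
      return("AUC must lie in [0, 1]")
    if (!is.null(r$sensitivity) &&
        (r$sensitivity < 0 || r$sensitivity > 100 ||
         r$specificity < 0 || r$specificity > 100))
      return("sensitivity/specificity must lie in [0, 100]")
  }
  TRUE
})
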