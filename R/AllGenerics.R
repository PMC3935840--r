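#' Accessors for image and texture containers
#'
#' `imgData()` returns the raw array of a [CtVolume], [RoiMask] or
#' [QuantizedRoi]; `voxelSpacing()` the (x, y, z) voxel edge lengths in mm;
#' `huValues()` the attenuation values of a [VoxelSample]; `voxelPositions()`
#' its (x, y, z) grid indices; `voxelVolume()` the single-voxel volume in
#' mm^3; `zoneCounts()` the GLSZM count matrix; `nVoxels()` the foreground
#' voxel count; `zoneConnectivity()` the neighborhood rule of a [GLSZM].
#'
#' @param x the object.
#' @return The slot value described above.
#' @name accessors
#' @aliases imgData voxelSpacing huValues voxelPositions voxelVolume
#'   zoneCounts nVoxels zoneConnectivity
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("huValues", function(x) standardGeneric("huValues"))
#' @rdname accessors
#' @export
setGeneric("voxelPositions", function(x) standardGeneric("voxelPositions"))
#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setGeneric("zoneCounts", function(x) standardGeneric("zoneCounts"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("zoneConnectivity", function(x) standardGeneric("zoneConnectivity"))

#' @rdname accessors
#' @export
setMethod("imgData", "CtVolume", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("imgData", "RoiMask", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("imgData", "QuantizedRoi", function(x) x@levels)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CtVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "RoiMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("huValues", "VoxelSample", function(x) x@hu)
#' @rdname accessors
#' @export
setMethod("voxelPositions", "VoxelSample", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("voxelVolume", "VoxelSample", function(x) x@voxelVolume)
#' @rdname accessors
#' @export
setMethod("zoneCounts", "GLSZM", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("nVoxels", "GLSZM", function(x) x@nVoxels)
#' @rdname accessors
#' @export
setMethod("nVoxels", "VoxelSample", function(x) length(x@hu))
#' @rdname accessors
#' @export
setMethod("zoneConnectivity", "GLSZM", function(x) x@connectivity)

setMethod("show", "CtVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CtVolume: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("RoiMask: %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(object@values)))
})

setMethod("show", "VoxelSample", function(object) {
  cat(sprintf(
    "VoxelSample: %d voxels, voxel volume %.4g mm^3, mean %.1f HU\n",
    length(object@hu), object@voxelVolume, mean(object@hu)))
})

setMethod("show", "QuantizedRoi", function(object) {
  cat(sprintf(
    "QuantizedRoi: %d gray levels over HU range [%.1f, %.1f], %d voxels\n",
    object@nLevels, object@huRange[1], object@huRange[2],
    sum(object@levels != 0L)))
})

setMethod("show", "GLSZM", function(object) {
  nz <- sum(object@counts)
  cat(sprintf(
    "GLSZM: %d zones over %d voxels (%s-connectivity), %d levels x sizes 1..%d\n",
    nz, object@nVoxels, object@connectivity, nrow(object@counts),
    ncol(object@counts)))
})

setMethod("show", "ModelReport", function(object) {
  cat(sprintf("ModelReport — arm %s (responders %d, nonresponders %d)\n",
              object@arm, object@n[["responder"]],
              object@n[["nonresponder"]]))
  cat("Univariate percent changes (mean±sd; Mann-Whitney p):\n")
  u <- object@univariate
  for (i in seq_len(nrow(u))) {
    cat(sprintf("  %-22s resp %8.1f±%-7.1f nonresp %8.1f±%-7.1f p=%.3f [%s]\n",
                u$variable[i], u$mean_responder[i], u$sd_responder[i],
                u$mean_nonresponder[i], u$sd_nonresponder[i], u$p[i],
                u$test[i]))
  }
  cat(sprintf("Screened (p < %.2f): %s\n",
              object@conventions$screen_threshold,
              paste(object@screened, collapse = ", ")))
  if (nrow(object@model) == 0) {
    cat("Final model: empty (all variables removed)\n")
  } else {
    cat("Final logistic model (per unit percent change):\n")
    m <- object@model
    for (i in seq_len(nrow(m))) {
      cat(sprintf("  %-22s OR %.3f (95%% CI %.3f, %.3f) p=%.3f\n",
                  m$variable[i], m$or[i], m$ci_lo[i], m$ci_hi[i], m$p[i]))
    }
  }
  if (isTRUE(object@separation))
    cat("  [degenerate fit: separation detected; estimates unreliable]\n")
  for (nm in names(object@roc)) {
    r <- object@roc[[nm]]
    cat(sprintf(
      "ROC %s: AUC %.3f, optimal cutoff %s %.3g (sens %.1f%%, spec %.1f%%)\n",
      nm, r$auc, if (r$direction == "lower") "<" else ">", r$cutoff,
      r$sensitivity, r$specificity))
  }
  invisible(object)
})
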