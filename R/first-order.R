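#' Tumor volume from a voxel sample
#'
#' Volume is the number of segmented voxels times the unit voxel volume,
#' converted to cm^3.
#'
#' @param sample a [VoxelSample].
#' @return Volume in cm^3.
#' @examples
#' # 1000 voxels of 1 mm^3 -> 1 cm^3
#' @export
computeVolume <- function(sample) {
  stopifnot(is(sample, "VoxelSample"))
  length(sample@hu) * sample@voxelVolume / 1000
}

#' Mean tumor density from attenuation
#'
#' Density is derived from the mean attenuation of all segmented voxels via
#' the linear CT convention rho = 1 + mean(HU)/1000 g/cm^3 (water = 0 HU ->
#' 1 g/cm^3; air = -1000 HU -> 0). A mean below -1000 HU would imply
#' negative density and raises an error.
#'
#' @param sample a [VoxelSample].
#' @return Density in g/cm^3.
#' @export
computeDensity <- function(sample) {
  stopifnot(is(sample, "VoxelSample"))
  mu <- mean(sample@hu)
  if (mu < -1000)
    stop("mean attenuation ", round(mu, 1),
         " HU < -1000 implies non-physical negative density")
  1 + mu / 1000
}

#' Tumor mass
#'
#' Mass in grams is tumor volume (cm^3) times mean tumor density (g/cm^3).
#'
#' @param volume volume in cm^3 (> 0).
#' @param density density in g/cm^3.
#' @return Mass in g.
#' @export
computeMass <- function(volume, density) {
  if (!is.finite(volume) || volume <= 0) stop("volume must be positive")
  volume * density
}

# centered moments m_k = mean((x - mean(x))^k)
.centralMoment <- function(x, k) mean((x - mean(x))^k)

#' Attenuation-histogram skewness
#'
#' Third standardized moment of the ROI attenuation values. Negative
#' skewness: values spread to the left of the mean (long left tail);
#' positive: to the right. By default population (biased) moments,
#' g1 = m3 / m2^(3/2); `type = "sample"` applies the usual small-sample
#' correction.
#'
#' @param sample a [VoxelSample] (or a bare numeric vector).
#' @param type "population" (default) or "sample".
#' @return Skewness, or `NA` (with attribute `undefined = TRUE`) when the
#'   voxel values have zero variance.
#' @export
computeSkewness <- function(sample, type = c("population", "sample")) {
  type <- match.arg(type)
  x <- if (is(sample, "VoxelSample")) sample@hu else as.double(sample)
  n <- length(x)
  if (n < 3L) stop("skewness needs >= 3 voxels")
  m2 <- .centralMoment(x, 2)
  if (m2 == 0) return(structure(NA_real_, undefined = TRUE))
  g1 <- .centralMoment(x, 3) / m2^1.5
  if (type == "sample") g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Attenuation-histogram kurtosis
#'
#' Fourth standardized moment of the ROI attenuation values: the
#' peakedness of the histogram (leptokurtic = sharper peak, platykurtic =
#' flatter). Default is the non-excess Pearson kurtosis on population
#' moments, m4 / m2^2 (Gaussian -> 3); `excess = TRUE` subtracts 3, and
#' `type = "sample"` applies the small-sample correction to the excess form
#' before any offset. The convention in use is echoed into every pipeline
#' report so percent-change comparisons are never convention-blind.
#'
#' @param sample a [VoxelSample] (or a bare numeric vector).
#' @param type "population" (default) or "sample".
#' @param excess subtract 3 (Gaussian -> 0)? Default FALSE.
#' @return Kurtosis, or `NA` (attribute `undefined = TRUE`) at zero variance.
#' @export
computeKurtosis <- function(sample, type = c("population", "sample"),
                            excess = FALSE) {
  type <- match.arg(type)
  x <- if (is(sample, "VoxelSample")) sample@hu else as.double(sample)
  n <- length(x)
  if (n < 4L) stop("kurtosis needs >= 4 voxels")
  m2 <- .centralMoment(x, 2)
  if (m2 == 0) return(structure(NA_real_, undefined = TRUE))
  k <- .centralMoment(x, 4) / m2^2
  if (type == "sample") {
    g2 <- k - 3
    k <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)) + 3
  }
  if (excess) k <- k - 3
  k
}

#' All seven per-scan features
#'
#' Computes the full feature vector of one scan: volume (cm^3), density
#' (g/cm^3), mass (g), histogram skewness and kurtosis (on raw HU values;
#' the 16-level resampling applies to texture only), and the two GLSZM
#' texture features, intensity variability and size-zone variability.
#'
#' @param sample a [VoxelSample].
#' @param nLevels gray levels for texture quantization (default 16).
#' @param connectivity zone neighborhood rule: "26" (default), "6" or
#'   "8-2d" (per-slice 8-neighborhood).
#' @param kurtosisType,skewnessType moment convention, "population"
#'   (default) or "sample".
#' @param kurtosisExcess subtract 3 from kurtosis? Default FALSE.
#' @return A one-row data.frame with columns volume_cm3, density_g_cm3,
#'   mass_g, skewness, kurtosis, intensity_variability,
#'   size_zone_variability.
#' @export
scanFeatures <- function(sample, nLevels = 16L, connectivity = "26",
                         kurtosisType = "population",
                         skewnessType = "population",
                         kurtosisExcess = FALSE) {
  stopifnot(is(sample, "VoxelSample"))
  vol <- computeVolume(sample)
  den <- computeDensity(sample)
  q <- quantizeRoi(sample, nLevels = nLevels)
  g <- buildGLSZM(labelZones(q, connectivity = connectivity))
  data.frame(
    volume_cm3 = vol,
    density_g_cm3 = den,
    mass_g = computeMass(vol, den),
    skewness = as.double(computeSkewness(sample, type = skewnessType)),
    kurtosis = as.double(computeKurtosis(sample, type = kurtosisType,
                                         excess = kurtosisExcess)),
    intensity_variability = intensityVariability(g),
    size_zone_variability = sizeZoneVariability(g)
  )
}
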