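# Gaussian random field on a 3-D grid: white noise smoothed by an FFT
# Gaussian kernel (sigma in voxels per axis), standardized to zero mean and
# unit variance over the grid. Circular wrap at the boundary is immaterial
# here because tumors sit inside a margin.
.gaussianField <- function(dims, sigmaVox) {
  wn <- array(rnorm(prod(dims)), dim = dims)
  if (all(sigmaVox <= 1e-8)) return(wn)
  kern1 <- function(n, s) {
    if (s <= 1e-8) return(c(1, rep(0, n - 1)))
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-d^2 / (2 * s^2))
    k / sum(k)
  }
  k3 <- outer(outer(kern1(dims[1], sigmaVox[1]), kern1(dims[2], sigmaVox[2])),
              kern1(dims[3], sigmaVox[3]))
  f <- Re(fft(fft(wn) * fft(k3), inverse = TRUE)) / prod(dims)
  (f - mean(f)) / sd(f)
}

.rnormClamped <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

#' Parameters of a synthetic tumor phantom
#'
#' An ellipsoid tumor with spatially correlated internal texture on a CT-like
#' grid. The attenuation model inside the mask is
#' `meanHU + textureSd * GRF(corrLength) + noiseSd * white noise`, with an
#' optional population of low-attenuation "necrotic pockets": the voxels in
#' the top `pocketFraction` of a second, smoother random field are shifted
#' down by `pocketDepth` HU. Small pocket fractions with deep pockets yield
#' the negatively skewed, leptokurtic attenuation histograms typical of
#' enhancing solid tumors with focal necrosis; growing the pocket fraction
#' emulates treatment-induced necrosis. Outside the mask the background is
#' lung-like (~ -800 HU).
#'
#' @param radii ellipsoid semi-axes (mm), length 3.
#' @param meanHU mean attenuation of solid tissue (HU).
#' @param textureSd marginal SD of the correlated texture field (HU).
#' @param corrLength spatial correlation length of the texture (mm).
#' @param noiseSd additive white-noise SD (HU).
#' @param spacing voxel spacing (mm), length 3.
#' @param pocketFraction fraction of tumor voxels in necrotic pockets
#'   (0 disables).
#' @param pocketDepth attenuation drop inside pockets (HU).
#' @param pocketCorrLength correlation length of the pocket field (mm).
#' @param background background attenuation (HU).
#' @param seed integer RNG seed; the phantom is a pure function of its
#'   parameters and this seed.
#' @return A `TumorPhantomParams` list.
#' @export
tumorPhantomParams <- function(radii = c(18, 16, 14), meanHU = 130,
                               textureSd = 45, corrLength = 3.5,
                               noiseSd = 10, spacing = c(1, 1, 3),
                               pocketFraction = 0.03, pocketDepth = 280,
                               pocketCorrLength = 6, background = -800,
                               seed = 1L) {
  stopifnot(length(radii) == 3, all(radii > 0), length(spacing) == 3,
            all(spacing > 0), textureSd >= 0, corrLength > 0, noiseSd >= 0,
            pocketFraction >= 0, pocketFraction < 1, pocketCorrLength > 0)
  structure(list(radii = as.double(radii), meanHU = as.double(meanHU),
                 textureSd = as.double(textureSd),
                 corrLength = as.double(corrLength),
                 noiseSd = as.double(noiseSd),
                 spacing = as.double(spacing),
                 pocketFraction = as.double(pocketFraction),
                 pocketDepth = as.double(pocketDepth),
                 pocketCorrLength = as.double(pocketCorrLength),
                 background = as.double(background),
                 seed = as.integer(seed)),
            class = "TumorPhantomParams")
}

#' Generate a synthetic tumor phantom
#'
#' Builds the CT volume and tumor mask described by
#' [tumorPhantomParams()]. The grid is sized to the ellipsoid plus a margin
#' of one correlation length (at least 3 voxels) per side. Deterministic:
#' the same parameters and seed give bit-identical output.
#'
#' @param params a [tumorPhantomParams()] object.
#' @param dims optional fixed grid size (voxels); errors if the ellipsoid
#'   does not fit.
#' @return list: `volume` ([CtVolume]), `mask` ([RoiMask]).
#' @export
generateTumor <- function(params, dims = NULL) {
  stopifnot(inherits(params, "TumorPhantomParams"))
  sp <- params$spacing
  rVox <- params$radii / sp
  margin <- pmax(3, ceiling(params$corrLength / sp) + 2)
  if (is.null(dims)) {
    dims <- as.integer(2 * ceiling(rVox) + 2 * margin + 1)
  } else {
    dims <- as.integer(dims)
    if (any(2 * rVox + 2 > dims))
      stop("ellipsoid exceeds the requested grid")
  }
  centre <- (dims + 1) / 2
  ax <- (seq_len(dims[1]) - centre[1]) * sp[1]
  ay <- (seq_len(dims[2]) - centre[2]) * sp[2]
  az <- (seq_len(dims[3]) - centre[3]) * sp[3]
  r2 <- outer(outer((ax / params$radii[1])^2, (ay / params$radii[2])^2, "+"),
              (az / params$radii[3])^2, "+")
  mask <- r2 <= 1
  if (!any(mask)) stop("ellipsoid contains no voxels at this spacing")
  set.seed(params$seed)
  vals <- array(params$background, dim = dims)
  tex <- .gaussianField(dims, params$corrLength / sp)
  inside <- params$meanHU + params$textureSd * tex[mask] +
    params$noiseSd * rnorm(sum(mask))
  if (params$pocketFraction > 0) {
    pf <- .gaussianField(dims, params$pocketCorrLength / sp)[mask]
    thr <- quantile(pf, 1 - params$pocketFraction, names = FALSE)
    inside[pf > thr] <- inside[pf > thr] - params$pocketDepth
  }
  vals[mask] <- inside
  list(volume = new("CtVolume", values = vals, spacing = sp,
                    orientation = NULL),
       mask = new("RoiMask", values = mask, spacing = sp))
}

#' A treatment effect on a tumor phantom
#'
#' Parametrizes how therapy transforms the phantom: the ellipsoid radii are
#' scaled by `volumeScale^(1/3)` (so tumor volume scales by `volumeScale`),
#' mean attenuation is shifted by `huShift`, and the texture is homogenized
#' by `homogenization`: macroscopic contrast (texture SD, necrotic pocket
#' contrast) is multiplied by it, the correlation length is divided by it,
#' and microscopic voxel noise by its square — response smooths fine-scale
#' heterogeneity faster than it shrinks gross contrast. Since level
#' quantization is per-scan min-max, the joint contrast scaling cancels in
#' the zone statistics; the zone structure responds through the correlation
#' length and through the noise-to-bin-width ratio, which falls linearly in
#' the factor. Values < 1 therefore produce fewer, larger, more uniform
#' zones while leaving histogram shape (skewness, kurtosis) roughly
#' invariant — the TKI-responder phenotype; values > 1 roughen the texture.
#' `pocketDelta` adds to the necrotic pocket fraction, emulating
#' treatment-induced necrosis spreading through the lesion (the
#' CCRT-responder histogram phenotype: flattened peak, shifted attenuation).
#'
#' @param volumeScale volume scale factor, in (0, 2] (nonresponders may
#'   grow).
#' @param huShift mean attenuation shift (HU).
#' @param homogenization texture homogenization factor, in (0, 2].
#' @param pocketDelta additive change to the pocket fraction.
#' @return A `TreatmentEffect` list.
#' @export
treatmentEffect <- function(volumeScale = 1, huShift = 0,
                            homogenization = 1, pocketDelta = 0) {
  stopifnot(volumeScale > 0, volumeScale <= 2,
            homogenization > 0, homogenization <= 2)
  structure(list(volumeScale = volumeScale, huShift = huShift,
                 homogenization = homogenization, pocketDelta = pocketDelta),
            class = "TreatmentEffect")
}

#' Apply a treatment effect to a phantom
#'
#' Regenerates the post-treatment tumor from the transformed parameters
#' (the post mask is a rescaled ellipsoid, not a deformation of the pre
#' mask — no registration machinery is involved). Deterministic per `seed`.
#'
#' @param params baseline [tumorPhantomParams()].
#' @param effect a [treatmentEffect()].
#' @param seed RNG seed for the post-treatment phantom.
#' @return list: `volume`, `mask`, and `params` (the post-treatment
#'   parameter set).
#' @export
applyTreatmentEffect <- function(params, effect, seed) {
  stopifnot(inherits(params, "TumorPhantomParams"),
            inherits(effect, "TreatmentEffect"))
  post <- params
  post$radii <- params$radii * effect$volumeScale^(1 / 3)
  post$meanHU <- params$meanHU + effect$huShift
  post$textureSd <- params$textureSd * effect$homogenization
  post$corrLength <- params$corrLength / effect$homogenization
  post$pocketDepth <- params$pocketDepth * effect$homogenization
  post$noiseSd <- params$noiseSd * effect$homogenization^2
  post$pocketFraction <- min(0.6, max(0, params$pocketFraction +
                                        effect$pocketDelta))
  post$seed <- as.integer(seed)
  out <- generateTumor(post)
  out$params <- post
  out
}

# group-level effect distributions: each entry mean/sd (+ clamp range)
.defaultEffectDistributions <- function() {
  list(
    TKI = list(
      responder = list(volumeScale = c(0.49, 0.20, 0.10, 1.20),
                       huShift = c(-95, 100),
                       homogenization = c(0.55, 0.12, 0.25, 0.90),
                       pocketDelta = c(0.01, 0.01, 0, 0.10)),
      nonresponder = list(volumeScale = c(0.58, 0.20, 0.10, 1.40),
                          huShift = c(-50, 90),
                          homogenization = c(1.05, 0.15, 0.70, 1.60),
                          pocketDelta = c(0.00, 0.01, 0, 0.10))),
    CCRT = list(
      responder = list(volumeScale = c(0.45, 0.30, 0.08, 1.30),
                       huShift = c(-85, 110),
                       homogenization = c(1.35, 0.25, 0.70, 2.00),
                       pocketDelta = c(0.20, 0.06, 0.05, 0.45)),
      nonresponder = list(volumeScale = c(0.86, 0.35, 0.15, 1.80),
                          huShift = c(-50, 110),
                          homogenization = c(1.00, 0.22, 0.50, 1.70),
                          pocketDelta = c(0.02, 0.02, 0, 0.10)))
  )
}

#' Configuration of a synthetic paired-tumor cohort
#'
#' Default group sizes mirror the modelled study: TKI arm 10 responders (4
#' of them near-complete) and 13 nonresponders; CCRT arm 12 responders (7
#' near-complete) and 16 nonresponders. Baseline phantoms have volumes of
#' roughly 20-30 cm^3 and solid-tissue attenuation (~130 HU, density ~1.13
#' g/cm^3). Effect distributions encode the arm-specific response
#' phenotypes: CCRT responders shrink strongly and accrue confluent necrosis
#' (histogram shift and flattening); TKI responders homogenize their texture
#' while both TKI groups shrink comparably, so size is not the
#' discriminating signal in that arm. Necrosis fractions are drawn uniformly
#' within the label-consistent interval (nonresponder <= 0.50 < responder;
#' near-complete > 0.90): necrosis here is a pathology-side label carrier,
#' not an imaging quantity.
#'
#' @param counts nested list per arm: `responder`, `nearComplete` (subset of
#'   responders), `nonresponder`.
#' @param effects nested list per arm/group of effect-parameter
#'   distributions, each `c(mean, sd)` or `c(mean, sd, lo, hi)`.
#' @param baseline list of baseline phantom distribution settings.
#' @param seed master seed; every per-patient seed derives from it.
#' @return A `CohortConfig` list.
#' @export
cohortConfig <- function(
    counts = list(TKI = list(responder = 10L, nearComplete = 4L,
                             nonresponder = 13L),
                  CCRT = list(responder = 12L, nearComplete = 7L,
                              nonresponder = 16L)),
    effects = .defaultEffectDistributions(),
    baseline = list(volumeLogMean = log(19), volumeLogSd = 0.55,
                    volumeRange = c(5, 80), meanHU = c(130, 25),
                    textureSd = c(45, 8), corrLength = c(3.5, 0.5),
                    noiseSd = 10, pocketFraction = c(0.01, 0.04),
                    pocketDepth = c(330, 40), spacing = c(1, 1, 3)),
    seed = 20140226L) {
  for (arm in names(counts)) {
    ct <- counts[[arm]]
    stopifnot(ct$responder >= 0, ct$nonresponder >= 0,
              ct$nearComplete >= 0, ct$nearComplete <= ct$responder)
  }
  structure(list(counts = counts, effects = effects, baseline = baseline,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

.sampleEffect <- function(dist) {
  g <- function(d) {
    lo <- if (length(d) >= 3) d[3] else -Inf
    hi <- if (length(d) >= 4) d[4] else Inf
    .rnormClamped(1, d[1], d[2], lo, hi)
  }
  treatmentEffect(volumeScale = g(dist$volumeScale),
                  huShift = g(dist$huShift),
                  homogenization = g(dist$homogenization),
                  pocketDelta = g(dist$pocketDelta))
}

#' Generate a synthetic paired pre/post-treatment cohort
#'
#' Draws per-patient baseline phantoms and group-specific treatment effects
#' from a [cohortConfig()], generates every pre and post tumor, and labels
#' each patient with a necrosis fraction consistent with its intended
#' response class. Fully reproducible: all per-patient seeds derive from the
#' master seed and are recorded in the manifest. If `dir` is given, NIfTI
#' volumes/masks, a metadata CSV and a JSON manifest — the exact inputs
#' [runPipeline()] consumes — are written there.
#'
#' @param config a [cohortConfig()].
#' @param dir optional output directory for NIfTI images + metadata +
#'   manifest.
#' @return A `SyntheticCohort`: list with `patients` (per-patient list of
#'   `pre`/`post` image pairs, parameters, effect, label, seeds),
#'   `metadata` (data.frame: patient_id, arm, necrosis_fraction,
#'   response_label), and `manifest` (seeds + parameters). When `dir` is
#'   given the manifest gains the file paths.
#' @export
generateCohort <- function(config = cohortConfig(), dir = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  roster <- list()
  for (arm in names(config$counts)) {
    ct <- config$counts[[arm]]
    lab <- c(rep("near_complete_responder", ct$nearComplete),
             rep("responder", ct$responder - ct$nearComplete),
             rep("nonresponder", ct$nonresponder))
    for (l in lab) roster[[length(roster) + 1]] <- list(arm = arm, label = l)
  }
  nPat <- length(roster)
  if (nPat == 0L) stop("zero-patient config")
  seeds <- sample.int(2^30, 2 * nPat)
  bl <- config$baseline
  patients <- vector("list", nPat)
  for (i in seq_len(nPat)) {
    arm <- roster[[i]]$arm
    label <- roster[[i]]$label
    necrosis <- switch(label,
      nonresponder = runif(1, 0.00, 0.50),
      responder = runif(1, 0.505, 0.90),
      near_complete_responder = runif(1, 0.905, 0.995))
    vol <- exp(rnorm(1, bl$volumeLogMean, bl$volumeLogSd)) # cm^3
    vol <- min(bl$volumeRange[2], max(bl$volumeRange[1], vol))
    shape <- exp(rnorm(2, 0, 0.12))
    r0 <- (3 * vol * 1000 / (4 * pi * shape[1] * shape[2]))^(1 / 3)
    params <- tumorPhantomParams(
      radii = r0 * c(shape[1], shape[2], 1),
      meanHU = rnorm(1, bl$meanHU[1], bl$meanHU[2]),
      textureSd = .rnormClamped(1, bl$textureSd[1], bl$textureSd[2], 15, 90),
      corrLength = .rnormClamped(1, bl$corrLength[1], bl$corrLength[2],
                                 2, 6),
      noiseSd = bl$noiseSd,
      spacing = bl$spacing,
      pocketFraction = runif(1, bl$pocketFraction[1], bl$pocketFraction[2]),
      pocketDepth = .rnormClamped(1, bl$pocketDepth[1], bl$pocketDepth[2],
                                  150, 400),
      seed = seeds[2 * i - 1])
    grp <- if (label == "nonresponder") "nonresponder" else "responder"
    effect <- .sampleEffect(config$effects[[arm]][[grp]])
    pre <- generateTumor(params)
    post <- applyTreatmentEffect(params, effect, seed = seeds[2 * i])
    patients[[i]] <- list(
      patient_id = sprintf("P%03d", i), arm = arm, label = label,
      necrosis_fraction = necrosis, params = params, effect = effect,
      pre = pre, post = post,
      seeds = c(pre = seeds[2 * i - 1], post = seeds[2 * i]))
  }
  metadata <- data.frame(
    patient_id = vapply(patients, `[[`, "", "patient_id"),
    arm = vapply(patients, `[[`, "", "arm"),
    necrosis_fraction = vapply(patients, `[[`, 0, "necrosis_fraction"),
    response_label = vapply(patients, `[[`, "", "label"))
  manifest <- list(
    master_seed = config$seed,
    package_version = as.character(packageVersion("neoresponse")),
    patients = lapply(patients, function(p) {
      list(patient_id = p$patient_id, arm = p$arm,
           necrosis_fraction = p$necrosis_fraction,
           response_label = p$label,
           seeds = as.list(p$seeds),
           effect = unclass(p$effect),
           params = unclass(p$params))
    }))
  cohort <- structure(list(patients = patients, metadata = metadata,
                           manifest = manifest),
                      class = "SyntheticCohort")
  if (!is.null(dir)) writeCohort(cohort, dir)
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Emits per-patient pre/post NIfTI volumes and masks, `metadata.csv`, and
#' `manifest.json` (seeds, parameters, file paths) under `dir`.
#'
#' @param cohort a `SyntheticCohort` from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- lapply(cohort$patients, function(p) {
    base <- file.path(dir, p$patient_id)
    f <- list(pre_volume = paste0(base, "_pre.nii.gz"),
              pre_mask = paste0(base, "_pre_mask.nii.gz"),
              post_volume = paste0(base, "_post.nii.gz"),
              post_mask = paste0(base, "_post_mask.nii.gz"))
    writeVolume(p$pre$volume, f$pre_volume)
    writeMask(p$pre$mask, f$pre_mask)
    writeVolume(p$post$volume, f$post_volume)
    writeMask(p$post$mask, f$post_mask)
    f
  })
  man <- cohort$manifest
  for (i in seq_along(man$patients)) man$patients[[i]]$files <-
    lapply(files[[i]], basename)
  write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
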