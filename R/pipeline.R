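#' Run configuration for the end-to-end pipeline
#'
#' Houses every convention and threshold of a run: gray levels for texture
#' quantization, zone connectivity, moment conventions, the percent-change
#' denominator (fixed at |pre|), the univariate screening threshold, the
#' likelihood-ratio removal probability, the exact Mann-Whitney group-size
#' switch, and the master seed. All of it is echoed into every report so
#' downstream comparisons are never convention-blind.
#'
#' @param manifest path to a cohort `manifest.json` (as written by
#'   [generateCohort()]), or NULL when analyzing in-memory objects.
#' @param outDir output directory for reports and tables, or NULL.
#' @param nLevels gray levels (default 16).
#' @param connectivity zone neighborhood ("26", "6", "8-2d").
#' @param kurtosisType,skewnessType "population" (default) or "sample".
#' @param kurtosisExcess subtract 3 from kurtosis? Default FALSE.
#' @param screenThreshold univariate screen (default 0.50).
#' @param removal LR removal probability (default 0.10).
#' @param exactMax exact Mann-Whitney switch (default 12).
#' @param seed master seed echoed into provenance.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(manifest = NULL, outDir = NULL, nLevels = 16L,
                      connectivity = "26", kurtosisType = "population",
                      skewnessType = "population", kurtosisExcess = FALSE,
                      screenThreshold = 0.50, removal = 0.10,
                      exactMax = 12L, seed = 1L) {
  stopifnot(nLevels >= 2, screenThreshold > 0, screenThreshold < 1,
            removal > 0, removal < 1)
  structure(list(manifest = manifest, outDir = outDir,
                 nLevels = as.integer(nLevels), connectivity = connectivity,
                 kurtosisType = kurtosisType, skewnessType = skewnessType,
                 kurtosisExcess = kurtosisExcess,
                 screenThreshold = screenThreshold, removal = removal,
                 exactMax = as.integer(exactMax), seed = as.integer(seed)),
            class = "RunConfig")
}

.featureNames <- c("volume_cm3", "density_g_cm3", "mass_g", "skewness",
                   "kurtosis", "intensity_variability",
                   "size_zone_variability")

.scanRow <- function(vol, mask, config) {
  s <- extractRoiVoxels(vol, mask)
  scanFeatures(s, nLevels = config$nLevels,
               connectivity = config$connectivity,
               kurtosisType = config$kurtosisType,
               skewnessType = config$skewnessType,
               kurtosisExcess = config$kurtosisExcess)
}

#' Extract the per-scan feature table of an in-memory cohort
#'
#' One row per patient and timepoint with the seven quantitative features.
#'
#' @param cohort a `SyntheticCohort` (or any list with the same shape).
#' @param config a [runConfig()] carrying the extraction conventions.
#' @return data.frame: patient_id, timepoint (pre/post), then the feature
#'   columns.
#' @export
extractCohortFeatures <- function(cohort, config = runConfig()) {
  rows <- lapply(cohort$patients, function(p) {
    pre <- .scanRow(p$pre$volume, p$pre$mask, config)
    post <- .scanRow(p$post$volume, p$post$mask, config)
    cbind(data.frame(patient_id = rep(p$patient_id, 2),
                     timepoint = c("pre", "post")),
          rbind(pre, post))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Extract features for a cohort stored on disk
#'
#' Reads every patient's pre/post volume + mask named in a cohort manifest
#' and computes the per-scan feature table.
#'
#' @param manifestPath path to `manifest.json`.
#' @param config a [runConfig()].
#' @return list: `features` (data.frame as in [extractCohortFeatures()]),
#'   `metadata` (patient_id, arm, necrosis_fraction, response_label).
#' @export
extractFeatures <- function(manifestPath, config = runConfig()) {
  man <- jsonlite::read_json(manifestPath)
  dir <- dirname(manifestPath)
  rows <- list()
  meta <- list()
  for (p in man$patients) {
    fp <- function(k) file.path(dir, p$files[[k]])
    for (f in p$files) if (!file.exists(file.path(dir, f)))
      stop("missing image file: ", f)
    pre <- .scanRow(readVolume(fp("pre_volume")), readMask(fp("pre_mask")),
                    config)
    post <- .scanRow(readVolume(fp("post_volume")),
                     readMask(fp("post_mask")), config)
    rows[[length(rows) + 1]] <-
      cbind(data.frame(patient_id = rep(p$patient_id, 2),
                       timepoint = c("pre", "post")),
            rbind(pre, post))
    meta[[length(meta) + 1]] <- data.frame(
      patient_id = p$patient_id, arm = p$arm,
      necrosis_fraction = p$necrosis_fraction,
      response_label = p$response_label)
  }
  list(features = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}

#' Per-patient percent changes from a feature table
#'
#' Joins the pre and post rows of each patient and computes the percent
#' change of every feature under the |pre| denominator convention.
#'
#' @param features feature table from [extractCohortFeatures()] /
#'   [extractFeatures()].
#' @return data.frame: patient_id plus `pct_<feature>` columns (NA where
#'   the baseline is zero).
#' @export
percentChangeTable <- function(features) {
  pre <- features[features$timepoint == "pre", , drop = FALSE]
  post <- features[features$timepoint == "post", , drop = FALSE]
  post <- post[match(pre$patient_id, post$patient_id), , drop = FALSE]
  if (anyNA(post$patient_id)) stop("every patient needs a pre and a post row")
  out <- data.frame(patient_id = pre$patient_id)
  for (v in .featureNames) {
    out[[paste0("pct_", v)]] <- percentChange(pre[[v]], post[[v]])
  }
  out
}

.conventionBlock <- function(config) {
  list(gray_levels = config$nLevels, connectivity = config$connectivity,
       kurtosis = paste0(config$kurtosisType,
                         if (config$kurtosisExcess) "-excess" else
                           "-nonexcess"),
       skewness = config$skewnessType,
       percent_change_denominator = "abs(pre)",
       screen_threshold = config$screenThreshold,
       removal_probability = config$removal,
       exact_test_max_group = config$exactMax,
       seed = config$seed,
       package_version = as.character(packageVersion("neoresponse")))
}

#' Analyze one treatment arm
#'
#' The full statistical procedure on one arm's percent changes: univariate
#' responder-vs-nonresponder comparisons of every feature (Mann-Whitney),
#' the p < threshold screen, backward-stepwise logistic regression with LR
#' removal, and ROC with Youden-optimal cutoffs — on each retained
#' variable's raw percent change and, when at least one variable is
#' retained, on the fitted model's linear predictor.
#'
#' @param pct percent-change table for the arm (rows = patients).
#' @param responder logical vector aligned with `pct` rows.
#' @param arm arm label for the report.
#' @param config a [runConfig()].
#' @return A [ModelReport-class] object.
#' @export
analyzeArm <- function(pct, responder, arm, config = runConfig()) {
  responder <- as.logical(responder)
  if (sum(responder) < 2L || sum(!responder) < 2L)
    stop("arm ", arm, " has < 2 patients in a class")
  vars <- paste0("pct_", .featureNames)
  vars <- intersect(vars, names(pct))
  uni <- do.call(rbind, lapply(vars, function(v) {
    x <- pct[[v]]
    ok <- !is.na(x)
    if (sum(ok & responder) < 1L || sum(ok & !responder) < 1L) {
      return(data.frame(variable = v, mean_responder = NA, sd_responder = NA,
                        mean_nonresponder = NA, sd_nonresponder = NA,
                        p = NA, test = "undefined"))
    }
    mw <- mannWhitneyTest(x[ok & responder], x[ok & !responder],
                          exactMax = config$exactMax)
    data.frame(variable = v,
               mean_responder = mean(x[ok & responder]),
               sd_responder = sd(x[ok & responder]),
               mean_nonresponder = mean(x[ok & !responder]),
               sd_nonresponder = sd(x[ok & !responder]),
               p = mw$p, test = mw$method)
  }))
  scr <- univariateScreen(pct[vars], responder,
                          threshold = config$screenThreshold,
                          exactMax = config$exactMax)
  df <- cbind(pct[vars], responder = responder)
  if (length(scr$screened) > 0) {
    fitres <- fitLogisticBackward(df, "responder", scr$screened,
                                  removal = config$removal)
  } else {
    fitres <- list(model = data.frame(variable = character(0),
                                      or = numeric(0), ci_lo = numeric(0),
                                      ci_hi = numeric(0), p = numeric(0)),
                   retained = character(0), removed = character(0),
                   separation = FALSE, fit = NULL)
  }
  roc <- list()
  for (v in fitres$retained) {
    roc[[v]] <- rocAnalysis(pct[[v]], responder, direction = "auto")
  }
  if (!is.null(fitres$fit)) {
    lp <- as.numeric(predict(fitres$fit, newdata = df, type = "link"))
    roc[["model_linear_predictor"]] <-
      rocAnalysis(lp, responder, direction = "higher")
  }
  new("ModelReport", arm = arm,
      n = c(responder = sum(responder), nonresponder = sum(!responder)),
      univariate = uni, screened = scr$screened, model = fitres$model,
      separation = fitres$separation, roc = roc,
      conventions = .conventionBlock(config))
}

#' Analyze a whole cohort arm by arm
#'
#' Arms are analyzed independently end-to-end. An arm with fewer than two
#' patients in either response class is skipped with a message, not an
#' error.
#'
#' @param features per-scan feature table.
#' @param metadata patient metadata (patient_id, arm, and either
#'   necrosis_fraction or response_label).
#' @param config a [runConfig()].
#' @return Named list of [ModelReport-class] per analyzable arm, with
#'   attribute `pct` (the percent-change table joined to metadata).
#' @export
analyzeCohort <- function(features, metadata, config = runConfig()) {
  pct <- percentChangeTable(features)
  m <- metadata[match(pct$patient_id, metadata$patient_id), , drop = FALSE]
  if (!is.null(m$response_label)) {
    lab <- factor(m$response_label,
                  levels = c("nonresponder", "responder",
                             "near_complete_responder"))
  } else {
    lab <- classifyPathologicResponse(m$necrosis_fraction)
  }
  responder <- isResponder(lab)
  reports <- list()
  for (arm in unique(m$arm)) {
    sel <- m$arm == arm
    if (sum(responder[sel]) < 2L || sum(!responder[sel]) < 2L) {
      message("arm ", arm, " skipped: < 2 patients in a response class")
      next
    }
    reports[[arm]] <- analyzeArm(pct[sel, , drop = FALSE], responder[sel],
                                 arm = arm, config = config)
  }
  attr(reports, "pct") <- cbind(pct, arm = m$arm, responder = responder)
  reports
}

.reportToList <- function(report) {
  list(arm = report@arm, n = as.list(report@n),
       univariate = report@univariate, screened = report@screened,
       model = report@model, separation = report@separation,
       roc = lapply(report@roc, function(r) r[c("auc", "cutoff", "direction",
                                                "sensitivity",
                                                "specificity")]),
       conventions = report@conventions)
}

#' Serialize per-arm reports to JSON
#'
#' @param reports output of [analyzeCohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReports <- function(reports, path) {
  jsonlite::write_json(lapply(reports, .reportToList), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Run the full pipeline from a cohort manifest
#'
#' End-to-end orchestration: read every patient's images, extract the seven
#' features per scan, compute percent changes, analyze each arm
#' (univariate comparisons, screening, backward logistic model, ROC), and —
#' when `config$outDir` is set — write `features.csv`,
#' `percent_changes.csv`, `reports.json` and a human-readable `report.txt`.
#' Runs are deterministic given the manifest: re-running the same config on
#' the same cohort produces byte-identical outputs.
#'
#' @param config a [runConfig()] with `manifest` set.
#' @return list: `features`, `metadata`, `pct`, `reports`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"), !is.null(config$manifest))
  ext <- extractFeatures(config$manifest, config)
  reports <- analyzeCohort(ext$features, ext$metadata, config)
  pct <- attr(reports, "pct")
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(ext$features, file.path(config$outDir, "features.csv"),
              row.names = FALSE)
    write.csv(pct, file.path(config$outDir, "percent_changes.csv"),
              row.names = FALSE)
    writeReports(reports, file.path(config$outDir, "reports.json"))
    txt <- file.path(config$outDir, "report.txt")
    con <- file(txt, open = "wt")
    sink(con)
    on.exit({ sink(); close(con) }, add = TRUE)
    cat("neoresponse pipeline report\n")
    cat("conventions:\n")
    cv <- .conventionBlock(config)
    for (nm in names(cv)) cat(sprintf("  %s: %s\n", nm, cv[[nm]]))
    for (r in reports) { cat("\n"); show(r) }
  }
  list(features = ext$features, metadata = ext$metadata, pct = pct,
       reports = reports)
}
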