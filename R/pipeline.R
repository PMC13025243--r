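# End-to-end runs: manifest -> feature table -> TI / contrast / correlation
# reports, with a serializable configuration whose defaults reproduce the
# standard portable-EEG chain (0.5-70 Hz band-pass, 50 Hz notch, 2 s epochs,
# default artifact thresholds, eight canonical bands, all-channel mean
# aggregation, natural-log TI).

#' Default run configuration
#'
#' @param manifest data.frame with columns `subject, condition, path`
#'   (EDF or delimited text recordings)
#' @param outDir optional output directory; when set, runs write their
#'   resolved config and outputs beside each other
#' @param ... overrides for any config entry (fLow, fHigh, mains, notch,
#'   epochS, artifact, bands, aggregate, channels, variant, conditionA,
#'   conditionB, fdrQ, seed, covariatesPath, textFs, textUnitScale)
#' @return list of class `runConfig`
#' @export
runConfig <- function(manifest = NULL, outDir = NULL, ...) {
  cfg <- list(
    manifest = manifest,
    outDir = outDir,
    fLow = 0.5, fHigh = 70,
    mains = 50, notch = TRUE,
    epochS = 2.0,
    artifact = artifactOptions(),
    bands = defaultBands(),
    aggregate = "mean", channels = NULL,
    variant = "standard",
    conditionA = "prayer", conditionB = "relaxation",
    fdrQ = 0.05,
    seed = 1,
    covariatesPath = NULL,
    textFs = 250, textUnitScale = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "runConfig")
}

#' Serialize / restore a run configuration
#'
#' Plain-text YAML round trip; every run writes its resolved config beside
#' its outputs so a run is reproducible from the config file alone.
#'
#' @param config a [runConfig()]
#' @param path file path
#' @return `writeRunConfig`: the path invisibly; `readRunConfig`: the config
#' @export
writeRunConfig <- function(config, path) {
  ser <- unclass(config)
  ser$artifact <- unclass(ser$artifact)
  ser$bands <- as.list(ser$bands)
  if (!is.null(ser$manifest)) ser$manifest <- as.list(ser$manifest)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  ser <- yaml::read_yaml(path)
  ser$bands <- as.data.frame(ser$bands, stringsAsFactors = FALSE)
  if (!is.null(ser$manifest))
    ser$manifest <- as.data.frame(ser$manifest, stringsAsFactors = FALSE)
  ser$artifact <- do.call(artifactOptions, ser$artifact[
    c("absAmpThresh", "ptpAmpThresh", "emgZThresh", "emgBand")])
  cfg <- do.call(runConfig, c(list(manifest = ser$manifest,
                                   outDir = ser$outDir),
                              ser[setdiff(names(ser),
                                          c("manifest", "outDir"))]))
  cfg
}

readRecordingAuto <- function(path, subject, condition, config) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    readEDF(path, subjectId = subject, condition = condition)
  else
    readTextRecording(path, fs = config$textFs,
                      unitScale = config$textUnitScale,
                      subjectId = subject, condition = condition)
}

#' Extract band-power features for every manifest recording
#'
#' Per recording: band-pass, notch, epoch, artifact screening, Hann
#' periodogram PSD, band integration. Per-block rejection fractions are
#' attached as `attr(, "rejection_log")` and every excluded epoch count is
#' messaged, never dropped silently. Unreadable inputs are collected in
#' `attr(, "failures")`; the run fails only if every input fails.
#'
#' @param config a [runConfig()] with a manifest
#' @return long band-power data.frame (one row per subject x condition x
#'   channel x band); written to `outDir/features.tsv` when `outDir` is set
#' @export
runExtract <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  man <- config$manifest
  if (is.null(man) || !nrow(man)) stop("config has no input manifest")
  tables <- list()
  rejLog <- list()
  failures <- list()
  for (i in seq_len(nrow(man))) {
    res <- tryCatch({
      rec <- readRecordingAuto(man$path[i], man$subject[i],
                               man$condition[i], config)
      rec <- applyBandpass(rec, config$fLow, config$fHigh)
      if (isTRUE(config$notch)) rec <- applyNotch(rec, config$mains)
      ep <- segmentEpochs(rec, config$epochS)
      ep <- rejectArtifacts(ep, config$artifact)
      message(sprintf("extract %s/%s: %d/%d epochs rejected (%.1f%%)",
                      man$subject[i], man$condition[i],
                      sum(!retainedMask(ep)), nEpochs(ep),
                      100 * fractionRejected(ep)))
      psd <- computePSD(ep)
      tab <- bandPowerTable(psd, bands = config$bands,
                            lowpassCorner = config$fHigh,
                            notchFreq = if (isTRUE(config$notch))
                              config$mains else NA)
      list(tab = tab,
           rej = data.frame(subject = man$subject[i],
                            condition = man$condition[i],
                            n_epochs = nEpochs(ep),
                            n_rejected = sum(!retainedMask(ep)),
                            fraction_rejected = fractionRejected(ep),
                            stringsAsFactors = FALSE))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(path = man$path[i], error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      tables[[length(tables) + 1L]] <- res$tab
      rejLog[[length(rejLog) + 1L]] <- res$rej
    }
  }
  if (!length(tables))
    stop("run failure: every input failed (first error: ",
         failures[[1]]$error, ")")
  out <- do.call(rbind, tables)
  attr(out, "rejection_log") <- do.call(rbind, rejLog)
  if (length(failures)) {
    attr(out, "failures") <- do.call(rbind, failures)
    warning("partial failure: ", length(failures), " input(s) unreadable",
            call. = FALSE)
  }
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeFeatureTable(out, file.path(config$outDir, "features.tsv"))
    utils::write.table(attr(out, "rejection_log"),
                       file.path(config$outDir, "rejection_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeRunConfig(config, file.path(config$outDir, "run_config.yaml"))
  }
  out
}

#' Analyze a feature table: TI, condition contrast, correlation families
#'
#' Chains channel aggregation, TI computation for the configured variant,
#' the paired condition contrast (skipped with a notice when only one
#' condition is present), and — when a covariate table is configured — the
#' TI x covariate Pearson family with BH-FDR flags.
#'
#' @param config a [runConfig()]
#' @param features band-power data.frame from [runExtract()] or
#'   [readFeatureTable()]
#' @return list: `ti` (per subject x condition), `contrast` (or `NULL`),
#'   `correlations` (or `NULL`); writes TSVs and the report when `outDir`
#'   is set
#' @export
runAnalyze <- function(config, features) {
  stopifnot(inherits(config, "runConfig"))
  agg <- aggregateChannels(features, method = config$aggregate,
                           channels = config$channels)
  ti <- computeTI(agg, variant = config$variant)

  contrast <- NULL
  conds <- unique(ti$condition)
  if (all(c(config$conditionA, config$conditionB) %in% conds)) {
    contrast <- pairedContrast(ti, a = config$conditionA,
                               b = config$conditionB)
  } else if (length(conds) < 2L) {
    message("analyze: single condition present; contrast skipped")
  } else {
    stop("pairing error: conditions ", config$conditionA, "/",
         config$conditionB, " not both present (found: ",
         paste(conds, collapse = ", "), ")")
  }

  correlations <- NULL
  if (!is.null(config$covariatesPath)) {
    cov <- readCovariates(config$covariatesPath)
    tiA <- ti[ti$condition == config$conditionA, c("subject", "ti")]
    merged <- merge(cov, tiA, by = "subject")
    correlations <- pearsonMatrix(merged[, setdiff(names(merged), "subject"),
                                         drop = FALSE],
                                  familyId = "ti_covariates", q = config$fdrQ)
  }

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    tiOut <- ti
    utils::write.table(tiOut, file.path(config$outDir, "ti.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    descr <- split(ti$ti, ti$condition)
    renderReport(descr,
                 if (is.null(correlations)) list() else correlations,
                 contrast, config$outDir,
                 runMeta = list(variant = ti$variant[1],
                                fdr_q = config$fdrQ, seed = config$seed,
                                bands = paste(config$bands$band,
                                              collapse = "|")))
  }
  list(ti = ti, contrast = contrast, correlations = correlations)
}
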