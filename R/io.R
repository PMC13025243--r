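# EDF (European Data Format) read/write, delimited-text ingest, and the long
# feature-table serialization. All readers convert to the package's canonical
# unit (microvolts) on ingest.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")  # left-justified, space padded
}

edfNum <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2, width = -1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edfPad(s, width)
}

#' Write a recording to an EDF file
#'
#' Minimal EDF writer: one data record per second, all signals at the
#' recording's sampling rate, 16-bit samples scaled to a symmetric per-channel
#' physical range in microvolts. A trailing partial second is dropped (EDF
#' records are whole seconds).
#'
#' @param rec an [EEGRecording-class]
#' @param path output file path
#' @return the path, invisibly
#' @seealso [readEDF()]
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate (1-s records)")
  fs <- as.integer(round(fs))
  x <- sampleMatrix(rec)
  ns <- nrow(x)
  nrec <- ncol(x) %/% fs
  if (nrec < 1L) stop("recording shorter than one EDF record (1 s)")
  if (ncol(x) %% fs != 0L)
    warning("trailing partial second dropped when writing EDF", call. = FALSE)
  x <- x[, seq_len(nrec * fs), drop = FALSE]

  physMax <- pmax(apply(abs(x), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8),
    edfPad(subjectId(rec), 80),
    edfPad(paste("condition:", conditionLabel(rec)), 80),
    edfPad("01.01.20", 8), edfPad("00.00.00", 8),
    edfPad(256 * (1 + ns), 8),
    edfPad("", 44),
    edfPad(nrec, 8),
    edfPad("1", 8),
    edfPad(ns, 4)
  )
  sig <- paste0(
    paste(vapply(channelLabels(rec), edfPad, "", width = 16), collapse = ""),
    paste(rep(edfPad("", 80), ns), collapse = ""),
    paste(rep(edfPad("uV", 8), ns), collapse = ""),
    paste(vapply(-physMax, edfNum, "", width = 8), collapse = ""),
    paste(vapply(physMax, edfNum, "", width = 8), collapse = ""),
    paste(rep(edfPad("-32768", 8), ns), collapse = ""),
    paste(rep(edfPad("32767", 8), ns), collapse = ""),
    paste(rep(edfPad("BP:0.5-70Hz", 80), ns), collapse = ""),
    paste(rep(edfPad(fs, 8), ns), collapse = ""),
    paste(rep(edfPad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)

  # re-read the serialized physical max so the scaling used for the digital
  # samples matches the header to full header precision
  physMaxHdr <- as.numeric(vapply(physMax, edfNum, "", width = 8))
  dig <- matrix(0L, ns, ncol(x))
  for (i in seq_len(ns)) {
    d <- round(x[i, ] / physMaxHdr[i] * 32767)
    dig[i, ] <- as.integer(pmax(pmin(d, 32767), -32768))
  }
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

edfReadField <- function(raw, offset, width, n = 1L) {
  out <- character(n)
  for (i in seq_len(n)) {
    from <- offset + (i - 1L) * width + 1L
    out[i] <- trimws(rawToChar(raw[from:(from + width - 1L)]))
  }
  out
}

#' Read an EDF/EDF+ file
#'
#' Parses the 16-bit EDF format, converts samples to microvolts using the
#' physical-dimension header field (uV assumed canonical; mV and V are
#' rescaled; any other unit passes through with `meta$unit_warning` set), and
#' requires all signals to share one sampling rate.
#'
#' @param path EDF file
#' @param subjectId,condition optional tags; defaults are taken from the EDF
#'   patient and recording identification fields
#' @return an [EEGRecording-class]
#' @export
readEDF <- function(path, subjectId = NULL, condition = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 256L) stop("EDF format error: truncated fixed header")
  nrec <- as.integer(edfReadField(raw, 236, 8))
  recDur <- as.numeric(edfReadField(raw, 244, 8))
  ns <- as.integer(edfReadField(raw, 252, 4))
  if (is.na(ns) || ns < 1L)
    stop("EDF format error: invalid 'number of signals' header field")
  if (length(raw) < 256L * (1L + ns))
    stop("EDF format error: truncated signal header")
  sh <- 256L
  labels <- edfReadField(raw, sh, 16, ns);            sh <- sh + 16L * ns
  sh <- sh + 80L * ns                                  # transducer
  physDim <- edfReadField(raw, sh, 8, ns);            sh <- sh + 8L * ns
  physMin <- as.numeric(edfReadField(raw, sh, 8, ns)); sh <- sh + 8L * ns
  physMax <- as.numeric(edfReadField(raw, sh, 8, ns)); sh <- sh + 8L * ns
  digMin <- as.numeric(edfReadField(raw, sh, 8, ns));  sh <- sh + 8L * ns
  digMax <- as.numeric(edfReadField(raw, sh, 8, ns));  sh <- sh + 8L * ns
  sh <- sh + 80L * ns                                  # prefiltering
  spr <- as.integer(edfReadField(raw, sh, 8, ns))

  if (length(unique(spr)) != 1L)
    stop("EDF format error: heterogeneous 'samples per record' header field (",
         paste(spr, collapse = ", "),
         "); all signals must share one sampling rate")
  fs <- spr[1] / recDur

  hdrBytes <- 256L * (1L + ns)
  dat <- readBin(raw[(hdrBytes + 1L):length(raw)], "integer",
                 n = nrec * ns * spr[1], size = 2L, endian = "little")
  if (length(dat) < nrec * ns * spr[1])
    stop("EDF format error: data section shorter than header declares")
  # records are [sig1 block, sig2 block, ...]; reshape to channels x time
  arr <- array(dat, dim = c(spr[1], ns, nrec))
  x <- matrix(0, ns, spr[1] * nrec)
  for (i in seq_len(ns)) x[i, ] <- as.numeric(arr[, i, ])

  meta <- list(source = path)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (i in seq_len(ns))
    x[i, ] <- (x[i, ] - digMin[i]) * scale[i] + physMin[i]
  unitFactor <- vapply(physDim, function(u) {
    switch(tolower(u), "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6,
           NA_real_)
  }, 0)
  if (anyNA(unitFactor)) {
    meta$unit_warning <- paste("unknown physical dimension:",
                               paste(unique(physDim[is.na(unitFactor)]),
                                     collapse = ", "))
    warning(meta$unit_warning, " (values passed through unscaled)",
            call. = FALSE)
    unitFactor[is.na(unitFactor)] <- 1
  }
  x <- x * unitFactor

  if (is.null(subjectId)) {
    subjectId <- edfReadField(raw, 8, 80)
    if (!nzchar(subjectId)) subjectId <- "unknown"
  }
  if (is.null(condition)) {
    recId <- edfReadField(raw, 88, 80)
    condition <- if (grepl("^condition: ", recId))
      sub("^condition: ", "", recId) else "unknown"
  }
  rownames(x) <- labels
  checkMontage(labels)
  EEGRecording(x, fs = fs, subjectId = subjectId, condition = condition,
               meta = meta)
}

#' Read a recording from delimited text
#'
#' One column per channel with a header row of channel labels, one row per
#' sample; tab or comma separated (auto-detected). Values are multiplied by
#' `unitScale` to reach microvolts.
#'
#' @param path TSV/CSV file
#' @param fs sampling rate in Hz
#' @param unitScale multiplier taking stored values to microvolts (e.g. `1e6`
#'   for volt-scaled data)
#' @param subjectId,condition tags for the returned recording
#' @return an [EEGRecording-class]
#' @export
readTextRecording <- function(path, fs, unitScale = 1,
                              subjectId = "s1", condition = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("parse error: no data rows")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  labels <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  ncolExp <- length(labels)
  body <- strsplit(lines[-1], sep, fixed = TRUE)
  lens <- lengths(body)
  if (any(lens != ncolExp))
    stop("parse error: ragged row at row ", which(lens != ncolExp)[1])
  vals <- suppressWarnings(as.numeric(unlist(body, use.names = FALSE)))
  if (anyNA(vals)) {
    badRow <- (which(is.na(vals))[1] - 1L) %/% ncolExp + 1L
    stop("parse error: non-numeric cell at row ", badRow)
  }
  x <- t(matrix(vals, nrow = ncolExp))
  rownames(x) <- NULL
  x <- t(x) * unitScale          # channels x time
  rownames(x) <- labels
  EEGRecording(x, fs = fs, subjectId = subjectId, condition = condition,
               meta = list(source = path))
}

featureCols <- c("subject", "condition", "channel", "band", "power_uv2",
                 "relative_power", "log_power", "low_confidence")

#' Write a band-power feature table
#'
#' Long-format TSV with columns `subject, condition, channel, band, power_uv2`
#' plus any of `relative_power`, `log_power`, `low_confidence`. Numeric cells
#' are serialized at full double precision so a write/read round trip is
#' bit-exact.
#'
#' @param table band-power data.frame (internal `power` column maps to
#'   `power_uv2` on disk)
#' @param path output TSV path
#' @return the path, invisibly
#' @export
writeFeatureTable <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("feature table must be a non-empty data.frame")
  out <- table
  if ("power" %in% names(out))
    names(out)[names(out) == "power"] <- "power_uv2"
  keep <- intersect(featureCols, names(out))
  out <- out[, keep, drop = FALSE]
  for (j in names(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.17g", out[[j]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a band-power feature table
#'
#' @param path TSV written by [writeFeatureTable()]
#' @return data.frame with internal column names (`power` for `power_uv2`)
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  unknown <- setdiff(names(tab), featureCols)
  if (length(unknown))
    stop("feature-table format error: unknown column(s): ",
         paste(unknown, collapse = ", "))
  req <- c("subject", "condition", "channel", "band", "power_uv2")
  missingCols <- setdiff(req, names(tab))
  if (length(missingCols))
    stop("feature-table format error: missing column(s): ",
         paste(missingCols, collapse = ", "))
  names(tab)[names(tab) == "power_uv2"] <- "power"
  for (j in c("power", "relative_power", "log_power"))
    if (j %in% names(tab)) tab[[j]] <- as.numeric(tab[[j]])
  if ("low_confidence" %in% names(tab))
    tab$low_confidence <- as.logical(tab$low_confidence)
  tab
}

#' Read a per-subject covariate table
#'
#' Tab- or comma-separated, one row per subject (`subject` column), named
#' numeric covariates (anxiety, personality scores, ...). Missing cells are
#' the literal sentinel `NA` and drive pairwise deletion downstream.
#'
#' @param path TSV/CSV file
#' @return data.frame keyed by unique `subject`
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  l1 <- readLines(path, n = 1)
  sep <- if (grepl("\t", l1)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  if (!"subject" %in% names(tab))
    stop("covariate-table format error: missing 'subject' column")
  if (anyDuplicated(tab$subject))
    stop("covariate-table format error: duplicate subject keys")
  tab
}

#' Write a covariate table
#'
#' @param table data.frame with a `subject` column
#' @param path output TSV path
#' @return the path, invisibly
#' @export
writeCovariates <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n")
  invisible(path)
}
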