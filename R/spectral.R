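# PSD estimation and band power extraction.
#
# Estimator: per retained epoch, demean, multiply by a periodic Hann window,
# FFT, one-sided periodogram compensated by the mean squared window value so
# that the integral of the density over [0, Nyquist] equals the time-domain
# variance; densities are averaged across the non-overlapping epochs (a
# Welch estimate with zero overlap, matching the segmentation exactly).

# one-sided Hann periodogram of a single epoch vector -> density in uV^2/Hz
hannDensity <- function(v, fs) {
  n <- length(v)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)  # periodic Hann
  v <- (v - mean(v)) * w
  X <- stats::fft(v)
  nf <- n %/% 2 + 1L
  p <- (Mod(X[seq_len(nf)])^2) / (fs * sum(w^2))
  # double interior bins for the one-sided spectrum
  if (nf > 2L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  if (n %% 2 == 1L) p[nf] <- 2 * p[nf]  # odd n: last bin is not Nyquist
  list(freqs = (0:(nf - 1L)) * fs / n, density = p)
}

# integrate a density vector over [fLow, fHigh) on bin centres,
# excluding the DC and Nyquist bins
bandPowerFromDensity <- function(density, freqs, fLow, fHigh) {
  df <- freqs[2] - freqs[1]
  sel <- freqs >= fLow & freqs < fHigh
  sel[1] <- FALSE
  sel[length(sel)] <- FALSE
  sum(density[sel]) * df
}

#' Average power spectral density over retained epochs
#'
#' @param epochs an [EpochSet-class] with at least one retained epoch
#' @return a [PSDEstimate-class]; frequency step is `1 / epochS` (0.5 Hz for
#'   2 s epochs)
#' @examples
#' rec <- EEGRecording(matrix(sin(2 * pi * 10 * (0:4999) / 250), 1,
#'                            dimnames = list("Cz", NULL)), fs = 250)
#' psd <- computePSD(segmentEpochs(rec))
#' integrateBand(psd, 8, 12)  # ~ A^2 / 2 = 0.5
#' @export
computePSD <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  keep <- which(epochs@retained)
  if (!length(keep))
    stop("no clean epochs: all epochs were rejected for ",
         subjectId(epochs), "/", conditionLabel(epochs))
  fs <- samplingRate(epochs)
  nch <- dim(epochs@epochs)[2]
  nsamp <- dim(epochs@epochs)[3]
  nf <- nsamp %/% 2 + 1L
  acc <- matrix(0, nch, nf)
  freqs <- NULL
  for (e in keep) {
    for (ch in seq_len(nch)) {
      d <- hannDensity(epochs@epochs[e, ch, ], fs)
      acc[ch, ] <- acc[ch, ] + d$density
      freqs <- d$freqs
    }
  }
  acc <- acc / length(keep)
  rownames(acc) <- channelLabels(epochs)
  new("PSDEstimate", freqs = freqs, density = acc,
      nEpochsAveraged = length(keep), epochS = epochs@epochS, fs = fs,
      subjectId = subjectId(epochs), condition = conditionLabel(epochs))
}

#' Integrate a PSD over a frequency band
#'
#' Sums density times bin width over bins whose centre frequency `f`
#' satisfies `fLow <= f < fHigh` (half-open: a bin at exactly the upper edge
#' belongs to the next band). DC and Nyquist bins never contribute.
#'
#' @param psd a [PSDEstimate-class]
#' @param fLow,fHigh band edges in Hz; alternatively pass a one-row band
#'   definition as `fLow`
#' @return named numeric vector of band power per channel, microvolts^2
#' @export
integrateBand <- function(psd, fLow, fHigh = NULL) {
  stopifnot(is(psd, "PSDEstimate"))
  if (is.data.frame(fLow)) {
    fHigh <- fLow$f_high[1]
    fLow <- fLow$f_low[1]
  }
  nyq <- max(psd@freqs)
  if (fLow < 0 || fHigh > nyq + 1e-9)
    stop("parameter error: band [", fLow, ", ", fHigh,
         ") outside the PSD grid [0, ", nyq, "]")
  apply(psd@density, 1, bandPowerFromDensity, freqs = psd@freqs,
        fLow = fLow, fHigh = fHigh)
}

#' Build a long band-power table from PSD estimates
#'
#' One row per (subject, condition, channel, band). High-frequency rows are
#' flagged low-confidence when the band contains the low-pass corner or the
#' notch frequency recorded in the source metadata (e.g. high gamma 45-70 Hz
#' under a 50 Hz notch and 70 Hz low-pass), mirroring the practice of
#' retaining high-gamma estimates only when recording quality permits.
#'
#' @param psds a [PSDEstimate-class] or list of them (each tagged with
#'   subject/condition)
#' @param bands band definition data.frame, default [defaultBands()]; bands
#'   must be non-overlapping under half-open semantics
#' @param lowpassCorner,notchFreq corners used to set the low-confidence
#'   flag; defaults assume the standard 0.5-70 Hz / 50 Hz chain
#' @return data.frame: `subject, condition, channel, band, power,
#'   low_confidence`
#' @export
bandPowerTable <- function(psds, bands = defaultBands(),
                           lowpassCorner = 70, notchFreq = 50) {
  if (is(psds, "PSDEstimate")) psds <- list(psds)
  checkBandsNonOverlapping(bands)
  rows <- vector("list", length(psds))
  for (i in seq_along(psds)) {
    psd <- psds[[i]]
    pw <- matrix(0, nrow(psd@density), nrow(bands))
    for (b in seq_len(nrow(bands)))
      pw[, b] <- integrateBand(psd, bands$f_low[b], bands$f_high[b])
    corners <- c(lowpassCorner, notchFreq)
    lowConf <- vapply(seq_len(nrow(bands)), function(b)
      any(!is.na(corners) & corners >= bands$f_low[b] &
            corners < bands$f_high[b]), TRUE)
    rows[[i]] <- data.frame(
      subject = subjectId(psd), condition = conditionLabel(psd),
      channel = rep(channelLabels(psd), times = nrow(bands)),
      band = rep(bands$band, each = nrow(psd@density)),
      power = as.vector(pw),
      low_confidence = rep(lowConf, each = nrow(psd@density)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Add relative band power
#'
#' `RP_i = P_i / sum(P)` over an explicit set of included bands, computed per
#' (subject, condition, channel). Relative powers over the included bands sum
#' to one for every key; rows for bands outside the included set get `NA`.
#'
#' @param table band-power data.frame from [bandPowerTable()]
#' @param includedBands band names forming the normalization denominator;
#'   default = all bands present
#' @return the table with a `relative_power` column; the number of included
#'   bands is recorded in `attr(, "n_bands_included")`
#' @export
relativePower <- function(table, includedBands = unique(table$band)) {
  stopifnot(is.data.frame(table), "power" %in% names(table))
  key <- interaction(table$subject, table$condition, table$channel,
                     drop = TRUE)
  table$relative_power <- NA_real_
  inc <- table$band %in% includedBands
  for (k in levels(key)) {
    sel <- key == k & inc
    have <- table$band[sel]
    if (!setequal(have, includedBands) || anyDuplicated(have))
      stop("included band(s) missing for key ", k, ": ",
           paste(setdiff(includedBands, have), collapse = ", "))
    tot <- sum(table$power[sel])
    if (tot <= 0)
      stop("undefined-ratio error: zero total power for key ", k)
    table$relative_power[sel] <- table$power[sel] / tot
  }
  attr(table, "n_bands_included") <- length(includedBands)
  table
}

#' Log-transform band powers
#'
#' EEG power distributions are right-skewed; a log transform stabilizes
#' variance before parametric modelling.
#'
#' @param table band-power data.frame
#' @param base log base, `exp(1)` (default) or `10`
#' @return the table with a `log_power` column
#' @export
logTransform <- function(table, base = exp(1)) {
  stopifnot(is.data.frame(table), "power" %in% names(table))
  if (any(table$power <= 0))
    stop("domain error: log transform requires strictly positive powers")
  table$log_power <- log(table$power, base = base)
  table
}
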