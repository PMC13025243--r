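# Filtering, epoching and artifact screening.
#
# All filters are applied forward and backward (zero phase) so band power is
# not distorted by group delay. Edges are protected by odd-reflection padding
# before the double pass.

# autoregressive continuation of a signal tail: fits an AR model to the
# boundary segment and extrapolates `p` samples, giving a spectrally
# consistent pad (a sinusoid continues exactly; noise continues as
# stationary noise of the same colour)
arExtend <- function(tail, p, orderMax = 16L) {
  m <- mean(tail)
  z <- tail - m
  if (stats::sd(z) < .Machine$double.eps) return(rep(m, p))
  fit <- tryCatch(stats::ar(z, aic = TRUE,
                            order.max = min(orderMax, length(z) - 1L),
                            method = "burg"),
                  error = function(e) NULL)
  if (is.null(fit) || fit$order == 0L) return(rep(m, p))
  co <- fit$ar
  m_ord <- fit$order
  buf <- c(z[(length(z) - m_ord + 1L):length(z)], numeric(p))
  for (k in seq_len(p))
    buf[m_ord + k] <- sum(co * buf[(m_ord + k - 1L):k][seq_len(m_ord)])
  buf[(m_ord + 1L):(m_ord + p)] + m
}

# Forward-backward filter with edge padding to absorb filter transients.
# Odd (point) reflection continues trends and suits high/low-pass stages.
# The narrow notch instead needs a spectrally consistent continuation: any
# waveform discontinuity at the data/pad junction makes its high-Q resonance
# ring back into the data, so the pad is an AR extrapolation of the boundary.
zerophase <- function(filt, x, padLen, type = c("odd", "ar")) {
  type <- match.arg(type)
  n <- length(x)
  p <- min(max(3L, as.integer(padLen)), n - 1L)
  if (type == "odd") {
    pre <- 2 * x[1] - x[(p + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - p)]
  } else {
    seg <- min(n, max(4L * p, 64L))
    post <- arExtend(x[(n - seg + 1L):n], p)
    pre <- rev(arExtend(rev(x[1:seg]), p))
  }
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(p + 1L):(p + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass (second-order high-pass cascaded with a
#' second-order low-pass), applied forward and backward per channel. The
#' low-pass digital corner is widened to compensate for the squared magnitude
#' response of the double pass, so the zero-phase response stays within 1 dB
#' of unity over `[2 * fLow, 0.9 * fHigh]` while attenuation at `fLow / 5`
#' and at Nyquist exceeds 20 dB. Defaults implement the 0.5-70 Hz acquisition
#' band used for portable eyes-closed EEG.
#'
#' @param rec an [EEGRecording-class]
#' @param fLow high-pass corner in Hz
#' @param fHigh low-pass corner in Hz (must be below Nyquist)
#' @return a filtered [EEGRecording-class]; `meta$bandpass` records the corners
#' @export
applyBandpass <- function(rec, fLow = 0.5, fHigh = 70) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (!(fLow > 0 && fLow < fHigh))
    stop("parameter error: need 0 < fLow < fHigh")
  if (fHigh >= fs / 2)
    stop("parameter error: fHigh (", fHigh, ") must be below Nyquist (",
         fs / 2, ")")
  # widen the low-pass corner so the double-pass response is < 1 dB down at
  # 0.9 * fHigh: for a 2nd-order Butterworth, (0.9 fHigh / fc)^4 <= 10^0.05 - 1
  k <- 0.9 / (10^0.05 - 1)^0.25
  fcU <- min(fHigh * k, 0.995 * fs / 2)
  hp <- signal::butter(2, fLow / (fs / 2), type = "high")
  lp <- signal::butter(2, fcU / (fs / 2), type = "low")
  x <- sampleMatrix(rec)
  padHp <- ceiling(3 * fs / fLow)
  padLp <- ceiling(3 * fs / fcU)
  for (i in seq_len(nrow(x))) {
    v <- zerophase(hp, x[i, ], padHp)
    x[i, ] <- zerophase(lp, v, padLp)
  }
  meta <- rec@meta
  meta$bandpass <- c(fLow, fHigh)
  initialize(rec, samples = x, meta = meta)
}

#' Zero-phase mains notch filter
#'
#' Second-order IIR notch (quality factor `q`, default 30) at the mains
#' frequency, applied forward and backward. Attenuation at the mains frequency
#' is complete to numerical precision while the zero-phase response stays
#' within 3 dB at +/- 3 Hz.
#'
#' @param rec an [EEGRecording-class]
#' @param mains mains frequency in Hz (50 in Europe, 60 elsewhere)
#' @param q notch quality factor (centre frequency / -3 dB bandwidth)
#' @return a filtered [EEGRecording-class]; `meta$notch` records the frequency
#' @export
applyNotch <- function(rec, mains = 50, q = 30) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (!(mains > 0 && mains < fs / 2))
    stop("parameter error: mains frequency must lie in (0, Nyquist)")
  w0 <- 2 * pi * mains / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  filt <- signal::Arma(b = b, a = a)
  x <- sampleMatrix(rec)
  pad <- ceiling(3 * fs * q / mains)
  for (i in seq_len(nrow(x)))
    x[i, ] <- zerophase(filt, x[i, ], pad, type = "ar")
  meta <- rec@meta
  meta$notch <- mains
  initialize(rec, samples = x, meta = meta)
}

#' Segment a recording into non-overlapping epochs
#'
#' Contiguous, non-overlapping epochs from the start of the recording; a
#' trailing partial segment is discarded. At 250 Hz and the default 2 s this
#' yields 500-sample epochs and 0.5 Hz spectral resolution, aligning bin
#' centres with all canonical band edges.
#'
#' @param rec an [EEGRecording-class]
#' @param epochS epoch length in seconds
#' @return an [EpochSet-class] with all epochs retained
#' @export
segmentEpochs <- function(rec, epochS = 2.0) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  nsamp <- round(epochS * fs)
  if (nsamp < 2L) stop("parameter error: epoch too short")
  x <- sampleMatrix(rec)
  nep <- ncol(x) %/% nsamp
  if (nep < 1L)
    stop("empty-set error: recording (", duration(rec),
         " s) shorter than one epoch (", epochS, " s)")
  ep <- array(0, dim = c(nep, nrow(x), nsamp))
  for (e in seq_len(nep))
    ep[e, , ] <- x[, ((e - 1L) * nsamp + 1L):(e * nsamp), drop = FALSE]
  new("EpochSet", epochs = ep, fs = fs, epochS = epochS,
      channelLabels = channelLabels(rec),
      retained = rep(TRUE, nep), rejectionReason = rep("none", nep),
      subjectId = subjectId(rec), condition = conditionLabel(rec),
      meta = rec@meta)
}

#' Artifact-screening options
#'
#' Deterministic replacements for visual artifact screening: an absolute
#' amplitude rule, a peak-to-peak rule, and a high-frequency (EMG) power rule
#' scored as a robust z against the median/MAD of each channel's per-epoch
#' high-frequency power over the whole recording block.
#'
#' @param absAmpThresh absolute amplitude threshold in microvolts
#' @param ptpAmpThresh peak-to-peak threshold in microvolts
#' @param emgZThresh robust z-score threshold for high-frequency power
#' @param emgBand two-element Hz vector delimiting the EMG band; the upper
#'   edge is capped at 0.96 * Nyquist at use time
#' @return list of class `artifactOptions`
#' @export
artifactOptions <- function(absAmpThresh = 100, ptpAmpThresh = 200,
                            emgZThresh = 3.0, emgBand = c(30, 110)) {
  if (absAmpThresh <= 0 || ptpAmpThresh <= 0 || emgZThresh <= 0)
    stop("parameter error: artifact thresholds must be positive")
  structure(list(absAmpThresh = absAmpThresh, ptpAmpThresh = ptpAmpThresh,
                 emgZThresh = emgZThresh, emgBand = emgBand),
            class = "artifactOptions")
}

#' Flag artifact-contaminated epochs
#'
#' An epoch is flagged `"amplitude"` if any channel exceeds the absolute or
#' peak-to-peak amplitude threshold, and `"emg"` if the robust z-score of its
#' high-frequency power — median/MAD across the block's epochs, per channel,
#' scored on the log scale where power is variance-stabilized — exceeds the
#' EMG threshold on any channel. Amplitude takes precedence when both rules
#' fire. Epoch data are never altered, only the retention mask and reasons.
#'
#' @param epochs an [EpochSet-class]
#' @param opts an [artifactOptions()] list
#' @param overrides optional integer vector (or data.frame with an
#'   `epoch_index` column) of manually rejected epoch indices, flagged
#'   `"manual"` for parity with human screening
#' @return the [EpochSet-class] with updated mask and reasons
#' @export
rejectArtifacts <- function(epochs, opts = artifactOptions(),
                            overrides = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  if (nEpochs(epochs) < 1L) stop("empty-set error: no epochs")
  fs <- samplingRate(epochs)
  ne <- nEpochs(epochs)
  nch <- dim(epochs@epochs)[2]
  reason <- epochs@rejectionReason

  emgLow <- opts$emgBand[1]
  emgHigh <- min(opts$emgBand[2], 0.96 * fs / 2)
  if (emgLow >= emgHigh)
    stop("parameter error: EMG band collapsed below Nyquist cap")

  hf <- matrix(0, ne, nch)
  ampHit <- logical(ne)
  for (e in seq_len(ne)) {
    seg <- epochs@epochs[e, , , drop = FALSE]
    dim(seg) <- dim(epochs@epochs)[2:3]
    ampHit[e] <- any(abs(seg) > opts$absAmpThresh) ||
      any(apply(seg, 1, function(v) diff(range(v))) > opts$ptpAmpThresh)
    for (ch in seq_len(nch)) {
      d <- hannDensity(seg[ch, ], fs)
      hf[e, ch] <- bandPowerFromDensity(d$density, d$freqs, emgLow, emgHigh)
    }
  }
  # robust z on log power: per-epoch band power is multiplicative
  # (chi-square-like), so the log scale is where a Gaussian z is calibrated
  emgHit <- logical(ne)
  for (ch in seq_len(nch)) {
    lh <- log(pmax(hf[, ch], 1e-300))
    med <- stats::median(lh)
    spread <- stats::mad(lh)
    if (spread <= 0) next
    z <- (lh - med) / spread
    emgHit <- emgHit | (z > opts$emgZThresh)
  }

  reason[emgHit & reason == "none"] <- "emg"
  reason[ampHit] <- "amplitude"
  if (!is.null(overrides)) {
    idx <- if (is.data.frame(overrides)) overrides$epoch_index else overrides
    idx <- as.integer(idx)
    if (any(idx < 1L | idx > ne))
      stop("parameter error: override epoch index out of range")
    reason[idx] <- "manual"
  }
  retained <- reason == "none"
  if (!any(retained))
    warning("no clean epochs remain after artifact screening", call. = FALSE)
  initialize(epochs, retained = retained, rejectionReason = reason)
}

#' Concatenate retained epochs back into a continuous matrix
#'
#' Inverse of [segmentEpochs()] restricted to the retained (or all) epochs;
#' useful for verifying that segmentation is lossless over the analyzed
#' portion of a recording.
#'
#' @param epochs an [EpochSet-class]
#' @param retainedOnly concatenate only retained epochs?
#' @return channels x time matrix
#' @export
concatenateEpochs <- function(epochs, retainedOnly = FALSE) {
  keep <- if (retainedOnly) which(epochs@retained) else seq_len(nEpochs(epochs))
  if (!length(keep)) stop("no clean epochs")
  nsamp <- dim(epochs@epochs)[3]
  nch <- dim(epochs@epochs)[2]
  out <- matrix(0, nch, length(keep) * nsamp)
  for (j in seq_along(keep))
    out[, ((j - 1L) * nsamp + 1L):(j * nsamp)] <- epochs@epochs[keep[j], , ]
  rownames(out) <- channelLabels(epochs)
  out
}
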