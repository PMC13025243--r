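#' Multichannel EEG recording
#'
#' Container for one continuous block of scalp EEG: a channels x time sample
#' matrix in microvolts, the sampling rate, and subject/condition tags.
#' Channel labels live in the rownames of the sample matrix and follow the
#' 10-20 naming scheme (the 8-channel portable montage used throughout is
#' Fz, C3, Cz, C4, Pz, PO7, Oz, PO8 at 250 Hz).
#'
#' @slot samples numeric matrix, channels x time, microvolts; rownames are
#'   channel labels
#' @slot fs sampling rate in Hz (positive scalar)
#' @slot subjectId subject identifier
#' @slot condition condition label, e.g. "prayer" or "relaxation"
#' @slot meta free-form list (device, session, applied filters, unit warnings)
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    subjectId = "character",
    condition = "character",
    meta = "list"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive finite number")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  if (is.null(rownames(object@samples)) ||
      any(!nzchar(rownames(object@samples))))
    msg <- c(msg, "samples must carry channel labels as rownames")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples contain non-finite values")
  if (length(object@subjectId) != 1L || length(object@condition) != 1L)
    msg <- c(msg, "subjectId and condition must be single strings")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples channels x time numeric matrix in microvolts
#' @param fs sampling rate in Hz
#' @param channelLabels channel names; defaults to `rownames(samples)`
#' @param subjectId subject identifier
#' @param condition condition label
#' @param meta free-form metadata list
#' @return an [EEGRecording-class] object
#' @examples
#' rec <- EEGRecording(matrix(rnorm(500), 1, dimnames = list("Cz", NULL)),
#'                     fs = 250)
#' duration(rec)
#' @export
EEGRecording <- function(samples, fs, channelLabels = rownames(samples),
                         subjectId = "s1", condition = "unknown",
                         meta = list()) {
  samples <- as.matrix(samples)
  if (is.null(channelLabels))
    stop("channel labels are required (rownames or channelLabels=)")
  if (length(channelLabels) != nrow(samples))
    stop("number of channel labels (", length(channelLabels),
         ") does not match number of sample rows (", nrow(samples), ")")
  rownames(samples) <- channelLabels
  new("EEGRecording", samples = samples, fs = as.numeric(fs),
      subjectId = as.character(subjectId),
      condition = as.character(condition), meta = meta)
}

#' @describeIn EEGRecording sampling rate in Hz
#' @param x an EEGRecording
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @describeIn EEGRecording channel labels
#' @export
setMethod("channelLabels", "EEGRecording", function(x) rownames(x@samples))

#' @describeIn EEGRecording subject id
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)

#' @describeIn EEGRecording condition label
#' @export
setMethod("conditionLabel", "EEGRecording", function(x) x@condition)

#' @describeIn EEGRecording sample matrix (channels x time, microvolts)
#' @export
setMethod("sampleMatrix", "EEGRecording", function(x) x@samples)

#' @describeIn EEGRecording duration in seconds
#' @export
setMethod("duration", "EEGRecording", function(x) ncol(x@samples) / x@fs)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", object@subjectId, "/", object@condition, "\n")
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              duration(object)))
  cat("  channels:", paste(channelLabels(object), collapse = ", "), "\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

#' Segmented EEG epochs with artifact-screening state
#'
#' Non-overlapping, contiguous fixed-length segments of a recording, together
#' with the per-epoch retention mask and rejection reasons filled in by
#' [rejectArtifacts()].
#'
#' @slot epochs numeric array, epoch x channel x sample, microvolts
#' @slot fs sampling rate in Hz
#' @slot epochS epoch length in seconds
#' @slot channelLabels channel names
#' @slot retained logical retention mask, one per epoch
#' @slot rejectionReason per-epoch label: "none", "amplitude", "emg", "manual"
#' @slot subjectId subject identifier
#' @slot condition condition label
#' @slot meta metadata carried over from the source recording
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    epochs = "array",
    fs = "numeric",
    epochS = "numeric",
    channelLabels = "character",
    retained = "logical",
    rejectionReason = "character",
    subjectId = "character",
    condition = "character",
    meta = "list"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    msg <- c(msg, "epochs must be a 3-d array (epoch x channel x sample)")
  else {
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "channel dimension does not match channelLabels")
    if (d[3] != round(object@epochS * object@fs))
      msg <- c(msg, "sample dimension does not match epochS * fs")
    if (length(object@retained) != d[1])
      msg <- c(msg, "retained mask length must equal epoch count")
    if (length(object@rejectionReason) != d[1])
      msg <- c(msg, "rejectionReason length must equal epoch count")
  }
  bad <- setdiff(unique(object@rejectionReason),
                 c("none", "amplitude", "emg", "manual"))
  if (length(bad))
    msg <- c(msg, paste("unknown rejection reason:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn EpochSet epoch count
#' @param x an EpochSet
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[1])

#' @describeIn EpochSet sampling rate in Hz
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @describeIn EpochSet channel labels
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)

#' @describeIn EpochSet subject id
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)

#' @describeIn EpochSet condition label
#' @export
setMethod("conditionLabel", "EpochSet", function(x) x@condition)

#' @describeIn EpochSet logical retention mask
#' @export
setMethod("retainedMask", "EpochSet", function(x) x@retained)

#' @describeIn EpochSet per-epoch rejection reasons
#' @export
setMethod("rejectionReasons", "EpochSet", function(x) x@rejectionReason)

#' @describeIn EpochSet fraction of epochs not retained
#' @export
setMethod("fractionRejected", "EpochSet",
          function(x) sum(!x@retained) / length(x@retained))

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet:", object@subjectId, "/", object@condition, "\n")
  cat(sprintf("  %d epochs of %.2g s (%d channels @ %g Hz)\n",
              nEpochs(object), object@epochS, dim(object@epochs)[2],
              object@fs))
  cat(sprintf("  retained %d/%d (fraction rejected %.3f)\n",
              sum(object@retained), nEpochs(object),
              fractionRejected(object)))
})

#' Averaged power spectral density estimate
#'
#' One-sided PSD averaged across retained epochs (Hann-windowed, non-overlapping
#' periodogram average). The density is variance-calibrated: integrating it
#' over 0 to Nyquist recovers the mean per-epoch signal variance.
#'
#' @slot freqs frequency grid in Hz, 0 to fs/2, step 1/epochS
#' @slot density channels x frequency matrix, microvolt^2 per Hz
#' @slot nEpochsAveraged number of retained epochs averaged
#' @slot epochS epoch length in seconds
#' @slot fs sampling rate in Hz
#' @slot subjectId subject identifier
#' @slot condition condition label
#' @exportClass PSDEstimate
setClass("PSDEstimate",
  representation(
    freqs = "numeric",
    density = "matrix",
    nEpochsAveraged = "integer",
    epochS = "numeric",
    fs = "numeric",
    subjectId = "character",
    condition = "character"
  )
)

setValidity("PSDEstimate", function(object) {
  msg <- character()
  if (ncol(object@density) != length(object@freqs))
    msg <- c(msg, "density columns must match frequency grid")
  if (any(object@density < 0))
    msg <- c(msg, "density must be non-negative everywhere")
  if (is.null(rownames(object@density)))
    msg <- c(msg, "density must carry channel labels as rownames")
  if (length(msg)) msg else TRUE
})

#' @describeIn PSDEstimate sampling rate in Hz
#' @param x a PSDEstimate
#' @export
setMethod("samplingRate", "PSDEstimate", function(x) x@fs)

#' @describeIn PSDEstimate channel labels
#' @export
setMethod("channelLabels", "PSDEstimate", function(x) rownames(x@density))

#' @describeIn PSDEstimate subject id
#' @export
setMethod("subjectId", "PSDEstimate", function(x) x@subjectId)

#' @describeIn PSDEstimate condition label
#' @export
setMethod("conditionLabel", "PSDEstimate", function(x) x@condition)

setMethod("show", "PSDEstimate", function(object) {
  cat("PSDEstimate:", object@subjectId, "/", object@condition, "\n")
  cat(sprintf("  %d channels, %d frequency bins (0-%g Hz, df = %g Hz)\n",
              nrow(object@density), length(object@freqs),
              max(object@freqs), object@freqs[2] - object@freqs[1]))
  cat(sprintf("  averaged over %d epochs of %g s\n",
              object@nEpochsAveraged, object@epochS))
})
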