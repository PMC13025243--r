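#' @import methods
NULL

#' Sampling rate accessor
#'
#' @param x an [EEGRecording-class], [EpochSet-class] or [PSDEstimate-class]
#' @return sampling rate in Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel label accessor
#'
#' @param x an object carrying channel labels
#' @return character vector of 10-20 electrode names, in source order
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Subject identifier accessor
#'
#' @param x an object tagged with a subject
#' @return subject id string
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Condition label accessor
#'
#' @param x an object tagged with a recording condition
#' @return condition label string (e.g. "prayer", "relaxation")
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' Sample matrix accessor
#'
#' @param x an [EEGRecording-class]
#' @return channels x time numeric matrix in microvolts
#' @export
setGeneric("sampleMatrix", function(x) standardGeneric("sampleMatrix"))

#' Recording duration
#'
#' @param x an [EEGRecording-class]
#' @return duration in seconds
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Number of epochs
#'
#' @param x an [EpochSet-class]
#' @return integer epoch count
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Retention mask accessor
#'
#' @param x an [EpochSet-class]
#' @return logical vector, one entry per epoch
#' @export
setGeneric("retainedMask", function(x) standardGeneric("retainedMask"))

#' Per-epoch rejection reasons
#'
#' @param x an [EpochSet-class]
#' @return character vector: "none", "amplitude", "emg" or "manual"
#' @export
setGeneric("rejectionReasons", function(x) standardGeneric("rejectionReasons"))

#' Fraction of rejected epochs
#'
#' @param x an [EpochSet-class]
#' @return proportion of epochs not retained, in \[0, 1\]
#' @export
setGeneric("fractionRejected", function(x) standardGeneric("fractionRejected"))
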