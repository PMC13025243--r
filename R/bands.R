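#' Canonical EEG band definitions
#'
#' The eight-band scheme used throughout: delta (1-4), theta (4-7), low alpha
#' (8-10), high alpha (10-12), low beta (13-20), high beta (20-30), low gamma
#' (30-45) and high gamma (45-70 Hz). Intervals are half-open
#' `[fLow, fHigh)`: a spectral bin sitting exactly on an upper edge belongs to
#' the next band. Note the scheme deliberately leaves gaps at \[7,8) and
#' \[12,13) Hz; [bridgeGaps()] extends theta and high alpha over them for
#' sensitivity analyses.
#'
#' @param bridgeGaps logical; if `TRUE`, theta is extended to 8 Hz and high
#'   alpha to 13 Hz so the band set tiles 1-70 Hz without holes
#' @return data.frame with columns `band`, `f_low`, `f_high`
#' @examples
#' defaultBands()
#' @export
defaultBands <- function(bridgeGaps = FALSE) {
  b <- data.frame(
    band  = c("delta", "theta", "alpha_low", "alpha_high",
              "beta_low", "beta_high", "gamma_low", "gamma_high"),
    f_low  = c(1,  4,  8, 10, 13, 20, 30, 45),
    f_high = c(4,  7, 10, 12, 20, 30, 45, 70),
    stringsAsFactors = FALSE
  )
  if (bridgeGaps) {
    b$f_high[b$band == "theta"] <- 8
    b$f_high[b$band == "alpha_high"] <- 13
  }
  b
}

#' Define a frequency band
#'
#' @param band band name (canonical or user-defined)
#' @param fLow lower edge in Hz (inclusive)
#' @param fHigh upper edge in Hz (exclusive)
#' @return one-row data.frame in the [defaultBands()] layout
#' @export
bandDefinition <- function(band, fLow, fHigh) {
  if (!is.numeric(fLow) || !is.numeric(fHigh) || fLow < 0 || fLow >= fHigh)
    stop("band edges must satisfy 0 <= fLow < fHigh")
  data.frame(band = as.character(band), f_low = fLow, f_high = fHigh,
             stringsAsFactors = FALSE)
}

# half-open overlap check; stops on overlap
checkBandsNonOverlapping <- function(bands) {
  b <- bands[order(bands$f_low), , drop = FALSE]
  if (nrow(b) > 1L && any(b$f_high[-nrow(b)] > b$f_low[-1L] + 1e-12))
    stop("band definitions overlap under half-open [f_low, f_high) semantics")
  invisible(TRUE)
}

#' Standard 10-20 montage check
#'
#' Advisory validation of channel labels against the 10-20/10-10 scalp naming
#' scheme. Non-standard labels produce a warning, never an error, so
#' nonstandard montages still flow through the pipeline keyed by label.
#'
#' @param labels character vector of channel labels
#' @return invisibly, the labels not recognised as 10-20/10-10 names
#' @export
checkMontage <- function(labels) {
  standard <- c(
    "Fp1", "Fp2", "Fpz", "AF3", "AF4", "AF7", "AF8", "AFz",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT7", "FT8",
    "T7", "T8", "T3", "T4", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP7", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "T5", "T6",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2",
    "A1", "A2", "M1", "M2"
  )
  unknown <- setdiff(labels, standard)
  if (length(unknown))
    warning("non-10-20 channel labels: ", paste(unknown, collapse = ", "),
            " (advisory only)", call. = FALSE)
  invisible(unknown)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream seed below 2^31 from a base seed and small indices.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in seq_along(idx))
    s <- (s * 48271 + as.double(idx[k]) * 7919 + k) %% 2147483647
  as.integer(s)
}
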