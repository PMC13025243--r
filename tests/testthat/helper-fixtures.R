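# fixtures are built in code; no binary files

toneRecording <- function(freq, amp = 2, durS = 300, fs = 250, nch = 1,
                          phase = 0, subject = "s1", condition = "test") {
  t <- (0:(round(durS * fs) - 1)) / fs
  v <- amp * sin(2 * pi * freq * t + phase)
  x <- matrix(rep(v, each = nch), nrow = nch)
  rownames(x) <- paste0("ch", seq_len(nch))
  EEGRecording(x, fs = fs, subjectId = subject, condition = condition)
}

noiseRecording <- function(sd = 2, durS = 300, fs = 250, nch = 1, seed = 1,
                           subject = "s1", condition = "test") {
  set.seed(seed)
  x <- matrix(rnorm(nch * round(durS * fs), sd = sd), nrow = nch)
  rownames(x) <- paste0("ch", seq_len(nch))
  EEGRecording(x, fs = fs, subjectId = subject, condition = condition)
}

# printed group-mean band powers used as a single pseudo-subject
pseudoSubjectTable <- function(withDelta = TRUE) {
  bands <- c("theta", "alpha_low", "alpha_high", "beta_low", "beta_high")
  pows <- c(3849.94, 5469.42, 4729.73, 2109.69, 1415.47)
  if (withDelta) {
    bands <- c("delta", bands)
    pows <- c(9327.87, pows)
  }
  data.frame(subject = "mean39", condition = "pooled", channel = "mean:all",
             band = bands, power = pows, stringsAsFactors = FALSE)
}

# independent brute-force statement of the BH step-up definition
bhOracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0L) rej[o[seq_len(k)]] <- TRUE
  rej
}
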