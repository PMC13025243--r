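test_that("PSD is variance-calibrated (Parseval) and zero for zero input", {
  zero <- EEGRecording(matrix(0, 1, 5000, dimnames = list("Cz", NULL)), 250)
  psd <- computePSD(segmentEpochs(zero))
  expect_true(all(psd@density == 0))
  expect_equal(psd@freqs[2] - psd@freqs[1], 0.5)

  rec <- noiseRecording(sd = 2, durS = 300, seed = 2)
  ep <- segmentEpochs(rec)
  psd <- computePSD(ep)
  df <- psd@freqs[2] - psd@freqs[1]
  total <- sum(psd@density) * df
  meanVar <- mean(apply(ep@epochs[, 1, ], 1, var))
  expect_equal(total, meanVar, tolerance = 0.01)
  expect_equal(total, 4, tolerance = 0.05)
})

test_that("a pure tone integrates to A^2/2 in its band and nowhere else", {
  rec <- toneRecording(15, amp = 2, durS = 300)
  psd <- computePSD(segmentEpochs(rec))
  expect_equal(unname(integrateBand(psd, 13, 20)), 2, tolerance = 0.02)
  expect_lt(unname(integrateBand(psd, 4, 7)), 1e-10)
  # density concentrated within the Hann main lobe around 15 Hz
  expect_gt(unname(integrateBand(psd, 14.5, 15.6)) / 2, 0.99)
})

test_that("band integration uses half-open bins and is exactly additive", {
  # hand-built PSD: unit density on the 4.0 Hz bin only
  dens <- matrix(0, 1, 251, dimnames = list("Cz", NULL))
  freqs <- seq(0, 125, by = 0.5)
  dens[1, which(freqs == 4.0)] <- 1
  psd <- new("PSDEstimate", freqs = freqs, density = dens,
             nEpochsAveraged = 1L, epochS = 2, fs = 250,
             subjectId = "s", condition = "c")
  expect_equal(unname(integrateBand(psd, 4, 7)), 0.5)   # density * df
  expect_equal(unname(integrateBand(psd, 1, 4)), 0)
  expect_error(integrateBand(psd, 100, 140), "outside the PSD grid")

  rec <- noiseRecording(durS = 60, seed = 3)
  p <- computePSD(segmentEpochs(rec))
  expect_identical(integrateBand(p, 4, 7) + integrateBand(p, 7, 13),
                   integrateBand(p, 4, 13))
})

test_that("a 7.5 Hz tone falls into the canonical band-scheme gap", {
  rec <- toneRecording(7.5, amp = 2, durS = 60)
  psd <- computePSD(segmentEpochs(rec))
  tone <- 2                                          # A^2/2
  expect_lt(unname(integrateBand(psd, 4, 7)) / tone, 0.05)
  expect_lt(unname(integrateBand(psd, 8, 10)) / tone, 0.25)
  expect_gt(unname(integrateBand(psd, 7, 8)) / tone, 0.6)
})

test_that("band tables have one row per key x band with confidence flags", {
  spec <- studySimSpec(nSubjects = 1, blockS = 20, seed = 4)
  rec <- simulateRecording(spec, 1, "prayer")$recording
  psd <- computePSD(segmentEpochs(rec))
  tab <- bandPowerTable(psd)
  expect_equal(nrow(tab), 8 * 8)
  expect_true(all(tab$power >= 0))
  flagged <- unique(tab$band[tab$low_confidence])
  expect_identical(flagged, "gamma_high")   # contains the 50 Hz notch & 70 Hz corner

  overlap <- rbind(bandDefinition("a", 1, 5), bandDefinition("b", 4, 8))
  expect_error(bandPowerTable(psd, bands = overlap), "overlap")

  one <- bandPowerTable(computePSD(segmentEpochs(noiseRecording(durS = 10))))
  expect_equal(nrow(one), 8)
})

test_that("relative power normalizes to one over the included bands", {
  # the printed broad-band group means as one pseudo-subject
  broad <- data.frame(
    subject = "mean39", condition = "pooled", channel = "mean:all",
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    power = c(9327.87, 3849.94, 4985.45, 1792.57, 693.70))
  rp <- relativePower(broad)
  expect_equal(sum(rp$relative_power), 1, tolerance = 1e-9)
  expect_equal(rp$relative_power[rp$band == "theta"], 0.18644,
               tolerance = 5e-5)   # printed to five decimals

  single <- broad[1, ]
  expect_equal(relativePower(single)$relative_power, 1)
  two <- broad[1:2, ]; two$power <- c(3, 3)
  expect_equal(relativePower(two)$relative_power, c(0.5, 0.5))

  zero <- broad; zero$power <- 0
  expect_error(relativePower(zero), "undefined-ratio")
  expect_error(relativePower(broad[-2, ], includedBands = broad$band),
               "missing")
})

test_that("log transform is monotone and rejects non-positive power", {
  tab <- pseudoSubjectTable()
  expect_equal(logTransform(tab[tab$power == 3849.94, ])$log_power,
               log(3849.94))
  one <- tab[1, ]; one$power <- 1
  expect_equal(logTransform(one)$log_power, 0)
  one$power <- 100
  expect_equal(logTransform(one, base = 10)$log_power, 2)
  expect_identical(order(logTransform(tab)$log_power), order(tab$power))
  one$power <- 0
  expect_error(logTransform(one), "domain error")
})

test_that("band-power spread shrinks like one over the square root of epochs", {
  spread <- function(nEpochs, seeds) {
    vapply(seeds, function(s) {
      x <- makeBandSignal(8, 10, 5, nEpochs * 2, 250, seed = s)
      rec <- EEGRecording(matrix(x, 1, dimnames = list("Cz", NULL)), 250)
      unname(integrateBand(computePSD(segmentEpochs(rec)), 8, 10))
    }, 0)
  }
  s32 <- sd(spread(32, 1:50))
  s128 <- sd(spread(128, 1:50))
  expect_equal(s32 / s128, 2, tolerance = 0.2)
})
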