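test_that("band-pass removes drift and preserves the pass band", {
  drift <- toneRecording(0.05, amp = 100, durS = 60)
  out <- applyBandpass(drift)
  expect_lt(sqrt(mean(sampleMatrix(out)^2)), 10)

  mid <- toneRecording(10, amp = 2, durS = 60)
  out <- applyBandpass(mid)
  expect_equal(sd(sampleMatrix(out)) / sd(sampleMatrix(mid)), 1,
               tolerance = 0.05)
  # < 1 dB ripple at 0.9 * fHigh
  hi <- toneRecording(63, amp = 2, durS = 60)
  ratio <- sd(sampleMatrix(applyBandpass(hi))) / sd(sampleMatrix(hi))
  expect_gt(20 * log10(ratio), -1)
  # >= 20 dB attenuation at fLow / 5
  lo <- toneRecording(0.1, amp = 2, durS = 120)
  ratio <- sd(sampleMatrix(applyBandpass(lo))) / sd(sampleMatrix(lo))
  expect_lt(20 * log10(ratio), -20)

  expect_error(applyBandpass(mid, 0.5, 130), "Nyquist")
  expect_error(applyBandpass(mid, 10, 5), "fLow < fHigh")
})

test_that("filtering is linear and near-idempotent", {
  rec <- noiseRecording(durS = 30, seed = 4)
  f1 <- sampleMatrix(applyBandpass(rec))
  scaled <- initialize(rec, samples = sampleMatrix(rec) * 3.7)
  f2 <- sampleMatrix(applyBandpass(scaled))
  expect_equal(f2, 3.7 * f1, tolerance = 1e-9)
  # second application changes almost nothing in the pass band interior
  twice <- sampleMatrix(applyBandpass(applyBandpass(rec)))
  expect_equal(sd(twice) / sd(f1), 1, tolerance = 0.1)
})

test_that("notch removes mains and spares neighbours, 50 or 60 Hz", {
  mains <- toneRecording(50, amp = 10, durS = 60, phase = 0.7)
  out <- applyNotch(mains)
  expect_lt(sqrt(2) * sd(sampleMatrix(out)), 0.4)
  near <- toneRecording(47, amp = 1, durS = 60)
  ratio <- sd(sampleMatrix(applyNotch(near))) / sd(sampleMatrix(near))
  expect_equal(ratio, 1, tolerance = 0.3)
  us <- toneRecording(60, amp = 10, durS = 60)
  out60 <- applyNotch(us, mains = 60)
  expect_lt(sqrt(2) * sd(sampleMatrix(out60)), 0.4)
  expect_error(applyNotch(us, mains = 130), "Nyquist")
})

test_that("epoch segmentation floors to whole epochs and is lossless", {
  rec <- noiseRecording(durS = 300)
  ep <- segmentEpochs(rec)
  expect_equal(nEpochs(ep), 150)
  expect_equal(dim(ep@epochs)[3], 500)
  ep2 <- segmentEpochs(noiseRecording(durS = 301))
  expect_equal(nEpochs(ep2), 150)          # trailing second discarded
  # five-minute block at 250 Hz: 150 epochs of 500 samples
  expect_equal(dim(ep@epochs)[c(1, 3)], c(150L, 500L))
  # concatenation recovers the analyzed portion exactly
  expect_identical(concatenateEpochs(ep),
                   sampleMatrix(rec)[, 1:(150 * 500), drop = FALSE])
  expect_error(segmentEpochs(noiseRecording(durS = 1)), "empty-set")
})

test_that("clean recordings pass screening; injected spikes are flagged exactly", {
  spec <- studySimSpec(nSubjects = 1, blockS = 300, seed = 21)
  rec <- simulateRecording(spec, 1, "relaxation")$recording
  clean <- rejectArtifacts(segmentEpochs(rec))
  expect_equal(sum(rejectionReasons(clean) == "amplitude"), 0)
  expect_lte(fractionRejected(clean), 0.05)

  inj <- injectArtifacts(rec, spikeRate = 0.1, emgRate = 0, seed = 6)
  expect_equal(nrow(inj$log), 15)
  ep <- rejectArtifacts(segmentEpochs(inj$recording))
  expect_setequal(which(rejectionReasons(ep) == "amplitude"),
                  inj$log$epoch_index)
  expect_equal(fractionRejected(ep),
               sum(!retainedMask(ep)) / nEpochs(ep))
})

test_that("EMG bursts are flagged by the high-frequency power rule", {
  spec <- studySimSpec(nSubjects = 1, blockS = 300, seed = 22)
  rec <- simulateRecording(spec, 1, "prayer")$recording
  inj <- injectArtifacts(rec, spikeRate = 0, emgRate = 0.1, seed = 7)
  ep <- rejectArtifacts(segmentEpochs(inj$recording))
  flagged <- which(!retainedMask(ep))
  expect_gte(mean(inj$log$epoch_index %in% flagged), 0.95)
  fp <- setdiff(flagged, inj$log$epoch_index)
  expect_lte(length(fp) / (nEpochs(ep) - nrow(inj$log)), 0.05)
})

test_that("amplitude screening is idempotent on the retained subset", {
  spec <- studySimSpec(nSubjects = 1, blockS = 120, seed = 23)
  rec <- simulateRecording(spec, 1, "prayer")$recording
  inj <- injectArtifacts(rec, spikeRate = 0.1, emgRate = 0, seed = 8)
  ep <- rejectArtifacts(segmentEpochs(inj$recording))
  keptSignal <- concatenateEpochs(ep, retainedOnly = TRUE)
  rec2 <- EEGRecording(keptSignal, fs = samplingRate(ep))
  ep2 <- rejectArtifacts(segmentEpochs(rec2))
  expect_equal(sum(rejectionReasons(ep2) == "amplitude"), 0)
})

test_that("manual overrides and degenerate cases are handled", {
  rec <- noiseRecording(durS = 20, seed = 30)
  ep <- rejectArtifacts(segmentEpochs(rec), overrides = c(2L, 5L))
  expect_equal(which(rejectionReasons(ep) == "manual"), c(2L, 5L))
  expect_false(any(retainedMask(ep)[c(2, 5)]))

  hot <- toneRecording(10, amp = 500, durS = 10)
  expect_warning(epAll <- rejectArtifacts(segmentEpochs(hot)),
                 "no clean epochs")
  expect_error(computePSD(epAll), "no clean epochs")
  expect_error(artifactOptions(absAmpThresh = -1), "positive")
})
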