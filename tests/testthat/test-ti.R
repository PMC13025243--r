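test_that("channel aggregation reduces per-channel powers as requested", {
  tab <- data.frame(subject = "s", condition = "c",
                    channel = rep(c("Cz", "Pz"), each = 2),
                    band = rep(c("theta", "beta_low"), 2),
                    power = c(2, 1, 4, 1))
  agg <- aggregateChannels(tab)
  expect_equal(agg$power[agg$band == "theta"], 3)
  aggM <- aggregateChannels(tab, method = "median")
  expect_equal(aggM$power[aggM$band == "theta"], 3)
  same <- tab; same$power <- 5
  expect_true(all(aggregateChannels(same)$power == 5))
  expect_error(aggregateChannels(tab, channels = character(0)), "empty")
  expect_error(aggregateChannels(tab, channels = "Oz"), "not in table")
})

test_that("posterior-subset aggregation sees a planted posterior alpha gradient", {
  spec <- studySimSpec(nSubjects = 1, blockS = 60, seed = 12)
  gains <- matrix(1, 8, 8,
                  dimnames = list(names(spec$bandPowerMeans),
                                  spec$channelLabels))
  post <- c("Pz", "PO7", "Oz", "PO8")
  gains[c("alpha_low", "alpha_high"), post] <- 2.5
  rec <- simulateRecording(spec, 1, "relaxation", channelGains = gains)$recording
  tab <- bandPowerTable(computePSD(segmentEpochs(rec)))
  all8 <- aggregateChannels(tab)
  sub4 <- aggregateChannels(tab, channels = post)
  aLowAll <- all8$power[all8$band == "alpha_low"]
  aLowPost <- sub4$power[sub4$band == "alpha_low"]
  expect_gt(aLowPost, aLowAll)
})

test_that("TI reproduces the printed group-mean plug-in values", {
  tab <- pseudoSubjectTable()
  ti <- computeTI(tab)$ti
  tiD <- computeTI(tab, variant = "delta_augmented")$ti
  # hand arithmetic on the printed means
  expect_equal(ti, log(14049.09 / 3525.16), tolerance = 1e-6)
  expect_equal(tiD, log(23376.96 / 3525.16), tolerance = 1e-6)
  # the plug-ins sit within 0.05 of the printed participant means
  expect_lt(abs(ti - 1.36), 0.05)
  expect_lt(abs(tiD - 1.87), 0.05)
})

test_that("TI obeys its log-ratio identities", {
  tab <- pseudoSubjectTable()
  base <- computeTI(tab)$ti
  doubled <- tab
  num <- doubled$band %in% c("theta", "alpha_low", "alpha_high")
  doubled$power[num] <- doubled$power[num] * 2
  expect_equal(computeTI(doubled)$ti - base, log(2), tolerance = 1e-12)

  equal <- tab
  equal$power <- ifelse(num, 1, 1.5)   # 3 numerator vs 2 denominator bands
  equal$power[equal$band == "delta"] <- 7
  expect_equal(computeTI(equal)$ti, 0, tolerance = 1e-12)

  # delta augmentation adds exactly log(1 + Pd / numerator)
  ti <- computeTI(tab)$ti
  tiD <- computeTI(tab, variant = "delta_augmented")$ti
  expect_equal(tiD - ti, log(1 + 9327.87 / 14049.09), tolerance = 1e-12)
  expect_gte(tiD, ti)
})

test_that("TI is monotone in numerator and denominator band powers", {
  tab <- pseudoSubjectTable()
  base <- computeTI(tab)$ti
  for (b in c("theta", "alpha_low", "alpha_high")) {
    up <- tab; up$power[up$band == b] <- up$power[up$band == b] * 1.1
    expect_gt(computeTI(up)$ti, base)
  }
  for (b in c("beta_low", "beta_high")) {
    up <- tab; up$power[up$band == b] <- up$power[up$band == b] * 1.1
    expect_lt(computeTI(up)$ti, base)
  }
})

test_that("absolute and relative powers give identical TI", {
  spec <- studySimSpec(nSubjects = 2, blockS = 30, seed = 13)
  rec <- simulateRecording(spec, 1, "prayer")$recording
  agg <- aggregateChannels(bandPowerTable(computePSD(segmentEpochs(rec))))
  rel <- relativePower(agg)
  tiAbs <- computeTI(agg)$ti
  tiRel <- computeTI(rel, powerColumn = "relative_power")$ti
  expect_lt(abs(tiAbs - tiRel), 1e-12)
})

test_that("TI input validation is explicit", {
  tab <- pseudoSubjectTable()
  expect_error(computeTI(tab[tab$band != "theta", ]), "missing band")
  neg <- tab; neg$power[2] <- -1
  expect_error(computeTI(neg), "domain error")
  multi <- rbind(tab, transform(tab, channel = "Cz"))
  expect_error(computeTI(multi), "aggregateChannels")
  expect_error(computeTI(pseudoSubjectTable(withDelta = FALSE),
                         variant = "delta_augmented"), "missing band")
  # exploratory reduced ratios are available but tagged
  expect_match(computeTI(tab, variant = "theta_beta")$variant, "theta_beta")
})

test_that("paired contrast reproduces the d = t/sqrt(n) convention", {
  z <- as.numeric(scale(1:39))
  diffs <- 2.18 / sqrt(39) + z          # mean 2.18/sqrt(39), sd exactly 1
  a <- stats::setNames(diffs, paste0("s", 1:39))
  b <- stats::setNames(rep(0, 39), paste0("s", 1:39))
  pc <- pairedContrast(a, b)
  expect_equal(pc$t, 2.18, tolerance = 1e-12)
  expect_equal(pc$df, 38)
  expect_equal(round(pc$d, 2), 0.35)
  expect_equal(round(pc$d_lo, 2), 0.03)
  expect_equal(round(pc$d_hi, 2), 0.67)
  # cross-check t and p against the reference implementation
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(pc$t, unname(tt$statistic))
  expect_equal(pc$p, tt$p.value)
  expect_true(pc$d_lo <= pc$d && pc$d <= pc$d_hi)
  expect_equal(sign(pc$d), sign(pc$t))
})

test_that("paired contrast degenerate and error cases", {
  x <- stats::setNames(c(1.2, 1.5, 1.1, 1.9), paste0("s", 1:4))
  same <- pairedContrast(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$d, 0)
  expect_error(pairedContrast(x, x + 0.5), "degenerate")
  y <- x; names(y) <- paste0("q", 1:4)
  expect_error(pairedContrast(x, y), "alignment")
  expect_error(pairedContrast(x[1:2], x[1:2]), "at least 3")
})

test_that("the simulator's planted condition effect is analytic in TI", {
  spec <- studySimSpec(nSubjects = 3, blockS = 8, seed = 14,
                       conditionEffect = 0.25)
  a <- simulateRecording(spec, 2, "prayer")
  b <- simulateRecording(spec, 2, "relaxation")
  expect_equal(attr(a$truth, "ti_true") - attr(b$truth, "ti_true"),
               log(1.25), tolerance = 1e-12)
  null <- studySimSpec(nSubjects = 3, blockS = 8, seed = 14,
                       conditionEffect = 0)
  a0 <- simulateRecording(null, 2, "prayer")
  b0 <- simulateRecording(null, 2, "relaxation")
  expect_equal(attr(a0$truth, "ti_true"), attr(b0$truth, "ti_true"))
})
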