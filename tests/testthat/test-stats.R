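test_that("descriptives match hand arithmetic and handle missings", {
  d <- describeValues(c(1, 2, 3, 4))
  expect_equal(d$mean, 2.5)
  expect_equal(d$sd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(d$median, 2.5)
  expect_equal(d$skewness, 0)
  expect_equal(d$min, 1); expect_equal(d$max, 4)

  d2 <- describeValues(c(5, NA, 7))
  expect_equal(d2$n, 2)
  expect_equal(d2$mean, 6)

  dc <- describeValues(rep(3, 10))
  expect_equal(dc$sd, 0)
  expect_true(dc$constant)
  expect_true(is.na(dc$skewness))

  expect_error(describeValues(c(1, NA)), "insufficient-data")
})

test_that("shape statistics use the SPSS small-sample formulas", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (n in c(8, 25, 120)) {
    x <- rlnorm(n)
    d <- describeValues(x)
    expect_equal(d$skewness, e1071::skewness(x, type = 2), tolerance = 1e-12)
    expect_equal(d$excess_kurtosis, e1071::kurtosis(x, type = 2),
                 tolerance = 1e-12)
  }
})

test_that("BH step-up matches its definition exhaustively up to permutation", {
  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 1.0)
  for (len in 1:8) {
    combos <- utils::combn(length(grid) + len - 1L, len)
    # multiset enumeration: all non-decreasing index vectors
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j] - seq_len(len) + 1L
      p <- grid[idx]
      expect_identical(bhFDR(p)$reject, bhOracle(p),
                       info = paste(p, collapse = ","))
    }
  }
  # permutation equivariance closes the gap to the full vector space
  set.seed(32)
  for (r in 1:200) {
    p <- sample(grid, 8, replace = TRUE)
    o <- sample(8)
    expect_identical(bhFDR(p)$reject[o], bhFDR(p[o])$reject)
  }
})

test_that("BH flags and adjusted p agree with the reference implementation", {
  res <- bhFDR(c(0.001, 0.02, 0.03, 0.04, 0.5), q = 0.05)
  expect_identical(res$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bhFDR(rep(1, 6))$reject))
  expect_true(bhFDR(0.04)$reject)            # m = 1 reduces to the threshold
  expect_error(bhFDR(c(0.2, 1.2)), "domain error")

  set.seed(33)
  for (r in 1:100) {
    p <- runif(sample(1:20, 1))
    res <- bhFDR(p)
    expect_equal(res$padj, p.adjust(p, method = "BH"))
    expect_identical(res$reject, unname(p.adjust(p, "BH") <= 0.05))
    # monotone: any p below a rejected p is rejected too
    if (any(res$reject))
      expect_true(all(res$reject[p <= max(p[res$reject])]))
  }
})

test_that("pairwise-deletion Pearson families report r, p, n and flags", {
  set.seed(34)
  x <- rnorm(40)
  df <- data.frame(a = x, b = -x, c = x + rnorm(40))
  df$a[3] <- NA                      # one missing value -> n = 39 for pairs with a
  rep <- pearsonMatrix(df, familyId = "t")
  expect_equal(rep$r["a", "a"], 1)
  expect_equal(rep$r["a", "b"], -1)
  expect_equal(rep$n["a", "b"], 39)
  expect_equal(rep$n["b", "c"], 40)
  expect_true(all(abs(rep$r) <= 1, na.rm = TRUE))
  expect_equal(rep$r, t(rep$r))
  expect_true(rep$fdr_flags["a", "b"])

  # sampling-distribution check: rho = 0.6, n = 500
  set.seed(35)
  z <- rnorm(500)
  w <- 0.6 * z + sqrt(1 - 0.36) * rnorm(500)
  r <- pearsonMatrix(data.frame(z = z, w = w))$r["z", "w"]
  expect_gt(r, 0.52); expect_lt(r, 0.67)

  # pairs with < 3 complete cases are unavailable, not fabricated
  df2 <- data.frame(u = c(1, 2, NA, NA, NA), v = c(NA, NA, 1, 2, 3),
                    w = 1:5)
  rep2 <- pearsonMatrix(df2)
  expect_true(is.na(rep2$r["u", "v"]))
  expect_false(is.na(rep2$r["v", "w"]))
})

test_that("correlations are invariant to joint row permutation only", {
  set.seed(36)
  df <- as.data.frame(matrix(rnorm(200), 50, 4))
  base <- pearsonMatrix(df)$r
  perm <- sample(50)
  expect_equal(pearsonMatrix(df[perm, ])$r, base)
  broken <- as.data.frame(lapply(df, sample))
  mOff <- function(m) mean(abs(m[lower.tri(m)]))
  expect_lt(mOff(pearsonMatrix(broken)$r), mOff(base) + 0.15)
})

test_that("reports mark nominal-only and FDR-surviving pairs distinctly", {
  set.seed(37)
  n <- 39
  z <- rnorm(n)
  df <- data.frame(strong = z, strong2 = z + 0.3 * rnorm(n),
                   weak = 0.33 * z + rnorm(n), null1 = rnorm(n),
                   null2 = rnorm(n), null3 = rnorm(n))
  rep <- pearsonMatrix(df, familyId = "mix")
  dir <- file.path(tempdir(), "report-test")
  files <- renderReport(list(ti = z), rep, NULL, dir,
                        runMeta = list(seed = 37))
  tab <- utils::read.table(file.path(dir, "correlations_mix.tsv"),
                           sep = "\t", header = TRUE, check.names = FALSE,
                           comment.char = "")
  cells <- unlist(tab[-1])
  expect_true(any(grepl("\\*\\*#", cells)))            # FDR-surviving
  full <- utils::read.table(file.path(dir, "correlations_mix_full.tsv"),
                            sep = "\t", header = TRUE)
  expect_true(all(c("r", "p", "n", "p_adj", "fdr_significant") %in%
                    names(full)))
  nominalOnly <- full$p < 0.05 & !full$fdr_significant
  if (any(nominalOnly)) {
    # nominal-only pairs carry the star but not the FDR marker
    expect_true(any(grepl("\\*$", cells)))
  }
  expect_true(file.exists(file.path(dir, "run_metadata.tsv")))
  expect_message(renderReport(list(), list(), NULL, dir), "omitted")
})
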