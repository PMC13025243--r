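# Descriptives, correlation families with pairwise deletion, and
# Benjamini-Hochberg FDR control.

#' Descriptive statistics with SPSS-convention shape measures
#'
#' Mean, sample SD (n-1), median, range, adjusted Fisher-Pearson skewness
#' (G1) and excess kurtosis (G2) — the small-sample-adjusted formulas SPSS
#' reports. Missing values are dropped and `n` counts non-missing values
#' only. For a constant vector the shape statistics are undefined: they are
#' returned as `NA` with `constant = TRUE`, not an error.
#'
#' @param values numeric vector, may contain `NA`
#' @return one-row data.frame: `n, mean, sd, median, min, max, skewness,
#'   excess_kurtosis, constant`
#' @export
describeValues <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2L) stop("insufficient-data error: need at least 2 values")
  m <- mean(x)
  s <- stats::sd(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  constant <- s == 0
  if (constant || n < 3L) {
    G1 <- NA_real_
  } else {
    g1 <- m3 / m2^1.5
    G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  if (constant || n < 4L) {
    G2 <- NA_real_
  } else {
    g2 <- m4 / m2^2 - 3
    G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  data.frame(n = n, mean = m, sd = s, median = stats::median(x),
             min = min(x), max = max(x), skewness = G1,
             excess_kurtosis = G2, constant = constant)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q` within one declared family of tests.
#' Adjusted p-values are reported alongside the rejection flags; both derive
#' from the same step-up pass, and the flags are monotone in p.
#'
#' @param p vector of p-values in \[0, 1\]
#' @param q target false discovery rate (default 0.05)
#' @return list: `reject` (logical, original order), `padj`, `q`
#' @examples
#' bhFDR(c(0.001, 0.02, 0.03, 0.04, 0.5))$reject
#' @export
bhFDR <- function(p, q = 0.05) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("domain error: p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (m == 0L) return(list(reject = logical(0), padj = numeric(0), q = q))
  o <- order(p)
  ps <- p[o]
  # step-up: largest i with p_(i) <= i q / m; reject 1..i
  crit <- ps <= seq_len(m) * q / m
  k <- if (any(crit)) max(which(crit)) else 0L
  rejSorted <- seq_len(m) <= k
  # adjusted values: running minimum of m p_(i) / i from the top
  padjSorted <- rev(cummin(rev(pmin(m * ps / seq_len(m), 1))))
  reject <- logical(m)
  padj <- numeric(m)
  reject[o] <- rejSorted
  padj[o] <- padjSorted
  list(reject = reject, padj = padj, q = q)
}

#' Pairwise-deletion Pearson correlation family with FDR flags
#'
#' Pearson r for every variable pair using pairwise-complete observations,
#' two-tailed p from the t transform on `n_ij - 2` degrees of freedom, a
#' matrix of per-pair complete-case counts, and Benjamini-Hochberg FDR flags
#' computed over the family (all off-diagonal pairs of this table) at level
#' `q`. Pairs with fewer than 3 complete cases are reported as `NA`, never
#' fabricated.
#'
#' @param data data.frame of numeric columns (missing cells allowed)
#' @param familyId label for this correlation family (one table = one family)
#' @param q FDR level
#' @return list of class `correlationReport`: `r`, `p`, `n`, `padj`,
#'   `fdr_flags` matrices plus `family_id` and `q`
#' @export
pearsonMatrix <- function(data, familyId = "family", q = 0.05) {
  stopifnot(is.data.frame(data))
  num <- vapply(data, is.numeric, TRUE)
  data <- data[, num, drop = FALSE]
  v <- names(data)
  k <- length(v)
  if (k < 2L) stop("need at least two numeric variables")
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(v, v))
  diag(r) <- 1
  diag(nmat) <- colSums(!is.na(data))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- stats::complete.cases(data[[i]], data[[j]])
      nij <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nij
      if (nij < 3L) next
      rij <- stats::cor(data[[i]][ok], data[[j]][ok])
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        pij <- 0
      } else {
        tij <- rij * sqrt((nij - 2) / (1 - rij^2))
        pij <- 2 * stats::pt(-abs(tij), df = nij - 2)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  lower <- which(lower.tri(p), arr.ind = TRUE)
  pv <- p[lower]
  ok <- !is.na(pv)
  flags <- padj <- matrix(NA, k, k, dimnames = list(v, v))
  if (any(ok)) {
    fdr <- bhFDR(pv[ok], q = q)
    fl <- rep(NA, length(pv)); fl[ok] <- fdr$reject
    pa <- rep(NA_real_, length(pv)); pa[ok] <- fdr$padj
    for (idx in seq_len(nrow(lower))) {
      i <- lower[idx, 1]; j <- lower[idx, 2]
      flags[i, j] <- flags[j, i] <- fl[idx]
      padj[i, j] <- padj[j, i] <- pa[idx]
    }
  }
  structure(list(r = r, p = p, n = nmat, padj = padj, fdr_flags = flags,
                 family_id = familyId, q = q),
            class = "correlationReport")
}

#' @export
print.correlationReport <- function(x, digits = 3, ...) {
  cat("Correlation family:", x$family_id, "(BH-FDR q =", x$q, ")\n")
  print(round(x$r, digits))
  nrej <- sum(x$fdr_flags[lower.tri(x$fdr_flags)], na.rm = TRUE)
  cat(nrej, "pair(s) FDR-significant\n")
  invisible(x)
}

# lower-triangle display matrix with nominal (*/**) and FDR (#) markers
formatCorrelationTable <- function(rep) {
  k <- nrow(rep$r)
  v <- rownames(rep$r)
  out <- matrix("", k, k, dimnames = list(v, v))
  for (i in seq_len(k)) {
    out[i, i] <- "-"
    if (i > 1) for (j in seq_len(i - 1)) {
      if (is.na(rep$r[i, j])) { out[i, j] <- "NA"; next }
      mark <- if (is.na(rep$p[i, j])) ""
        else if (rep$p[i, j] < 0.01) "**"
        else if (rep$p[i, j] < 0.05) "*" else ""
      fdr <- if (isTRUE(rep$fdr_flags[i, j])) "#" else ""
      out[i, j] <- paste0(sprintf("%.3f", rep$r[i, j]), mark, fdr)
    }
  }
  out
}

#' Write the study report tables
#'
#' Writes TSV tables mirroring a standard descriptives / correlation /
#' contrast layout: per-variable descriptive statistics, one
#' lower-triangle correlation table per family (nominal significance marked
#' `*`/`**`, FDR-surviving pairs additionally marked `#`, with a full numeric
#' r/p/adjusted-p companion table), the paired contrast, and a run-metadata
#' block. Empty sections are omitted with a message.
#'
#' @param descriptives named list of numeric vectors, or a data.frame whose
#'   columns are described one by one
#' @param correlations a `correlationReport` or list of them
#' @param contrast one-row data.frame from [pairedContrast()] (or `NULL`)
#' @param dir output directory (created if needed)
#' @param runMeta named list written to `run_metadata.tsv` (band set,
#'   thresholds, seed, package version, ...)
#' @return character vector of files written, invisibly
#' @export
renderReport <- function(descriptives, correlations, contrast, dir,
                         runMeta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  if (is.data.frame(descriptives))
    descriptives <- as.list(descriptives)
  if (length(descriptives)) {
    desc <- do.call(rbind, lapply(names(descriptives), function(nm) {
      d <- describeValues(descriptives[[nm]])
      cbind(variable = nm, d)
    }))
    f <- file.path(dir, "descriptives.tsv")
    utils::write.table(desc, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  } else message("report: no descriptives; section omitted")

  if (inherits(correlations, "correlationReport"))
    correlations <- list(correlations)
  for (rep in correlations) {
    if (is.null(rep) || !nrow(rep$r)) {
      message("report: empty correlation family; section omitted")
      next
    }
    disp <- formatCorrelationTable(rep)
    f <- file.path(dir, paste0("correlations_", rep$family_id, ".tsv"))
    utils::write.table(cbind(variable = rownames(disp), disp), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    lower <- which(lower.tri(rep$r), arr.ind = TRUE)
    longTab <- data.frame(
      var1 = rownames(rep$r)[lower[, 1]],
      var2 = colnames(rep$r)[lower[, 2]],
      r = rep$r[lower], p = rep$p[lower], n = rep$n[lower],
      p_adj = rep$padj[lower], fdr_significant = rep$fdr_flags[lower])
    f2 <- file.path(dir, paste0("correlations_", rep$family_id, "_full.tsv"))
    utils::write.table(longTab, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f, f2)
  }

  if (!is.null(contrast) && nrow(contrast)) {
    f <- file.path(dir, "contrast.tsv")
    utils::write.table(contrast, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  } else message("report: no contrast; section omitted")

  meta <- c(list(package = "eegti",
                 version = as.character(utils::packageVersion("eegti")),
                 date = format(Sys.time(), "%Y-%m-%d")), runMeta)
  metaTab <- data.frame(key = names(meta),
                        value = vapply(meta, function(v)
                          paste(format(v), collapse = ","), ""))
  f <- file.path(dir, "run_metadata.tsv")
  utils::write.table(metaTab, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
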