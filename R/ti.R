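# The Transcendence Index: a log-ratio spectral composite contrasting
# internally oriented theta-alpha activity with externally oriented beta
# activity, plus the within-subject condition contrast.

#' Aggregate band powers across channels
#'
#' Reduces per-channel band powers to one value per (subject, condition,
#' band). The default is the mean over all channels, the least-assumptive
#' reduction when no topographic hypothesis is in play; a posterior subset
#' (`c("Pz", "PO7", "Oz", "PO8")`) is a natural alternative for alpha-weighted
#' analyses. Derived columns (`relative_power`, `log_power`) are dropped:
#' recompute them after aggregation.
#'
#' @param table band-power data.frame from [bandPowerTable()]
#' @param method `"mean"` or `"median"`
#' @param channels optional channel subset; default all channels present
#' @return aggregated data.frame with `channel` set to a subset tag
#' @export
aggregateChannels <- function(table, method = c("mean", "median"),
                              channels = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), "power" %in% names(table))
  if (!is.null(channels)) {
    if (!length(channels))
      stop("parameter error: empty channel subset")
    missing <- setdiff(channels, unique(table$channel))
    if (length(missing))
      stop("parameter error: channel(s) not in table: ",
           paste(missing, collapse = ", "))
    table <- table[table$channel %in% channels, , drop = FALSE]
    tag <- paste0(method, ":", paste(sort(channels), collapse = "+"))
  } else {
    tag <- paste0(method, ":all")
  }
  f <- if (method == "mean") mean else stats::median
  agg <- stats::aggregate(power ~ subject + condition + band, data = table,
                          FUN = f)
  if ("low_confidence" %in% names(table)) {
    lc <- stats::aggregate(low_confidence ~ subject + condition + band,
                           data = table, FUN = any)
    agg <- merge(agg, lc, by = c("subject", "condition", "band"))
  }
  agg$channel <- tag
  agg[, c("subject", "condition", "channel", "band", "power",
          intersect("low_confidence", names(agg)))]
}

tiBands <- function(variant) {
  num <- c("theta", "alpha_low", "alpha_high")
  if (variant == "delta_augmented") num <- c("delta", num)
  list(num = num, den = c("beta_low", "beta_high"))
}

#' Compute the Transcendence Index
#'
#' `TI = log((P_theta + P_alpha_low + P_alpha_high) / (P_beta_low +
#' P_beta_high))`, natural log by default. The delta-augmented variant adds
#' delta power to the numerator, capturing slower components of internal
#' orientation at the cost of vigilance/drift sensitivity. Because the index
#' is a ratio, it is identical whether absolute or relative band powers are
#' supplied (the normalizer cancels) and invariant to any global amplitude
#' scaling of the recording.
#'
#' The table must hold one row per (subject, condition, band): aggregate
#' channels first with [aggregateChannels()].
#'
#' @param table aggregated band-power data.frame
#' @param variant `"standard"` for (theta+alpha)/beta, `"delta_augmented"` to
#'   add delta to the numerator; `"theta_beta"` and `"alpha_beta"` are
#'   clearly-labelled exploratory reduced ratios with no validation claims
#' @param logBase base of the logarithm applied to the composite ratio
#' @param powerColumn which column to use, `"power"` (absolute, default) or
#'   `"relative_power"`
#' @return data.frame: `subject, condition, ti, variant` where `variant` tags
#'   the formula, log base and aggregation for provenance
#' @examples
#' tab <- data.frame(subject = "mean39", condition = "pooled",
#'                   channel = "mean:all",
#'                   band = c("theta", "alpha_low", "alpha_high",
#'                            "beta_low", "beta_high"),
#'                   power = c(3849.94, 5469.42, 4729.73, 2109.69, 1415.47))
#' computeTI(tab)$ti  # 1.3827
#' @export
computeTI <- function(table, variant = c("standard", "delta_augmented",
                                         "theta_beta", "alpha_beta"),
                      logBase = exp(1), powerColumn = "power") {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(table))
  if (!powerColumn %in% names(table))
    stop("column '", powerColumn, "' not present in table")
  bands <- switch(variant,
    standard = tiBands("standard"),
    delta_augmented = tiBands("delta_augmented"),
    theta_beta = list(num = "theta", den = c("beta_low", "beta_high")),
    alpha_beta = list(num = c("alpha_low", "alpha_high"),
                      den = c("beta_low", "beta_high")))
  need <- c(bands$num, bands$den)

  keys <- unique(table[, c("subject", "condition")])
  if (length(unique(table$channel)) > 1L)
    stop("table has multiple channels per key; run aggregateChannels() first")
  ti <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- table$subject == keys$subject[i] &
      table$condition == keys$condition[i]
    sub <- table[sel, , drop = FALSE]
    missing <- setdiff(need, sub$band)
    if (length(missing))
      stop("missing band(s) for ", keys$subject[i], "/", keys$condition[i],
           ": ", paste(missing, collapse = ", "))
    p <- sub[[powerColumn]][match(need, sub$band)]
    if (any(!is.finite(p)) || any(p <= 0))
      stop("domain error: non-positive or missing band power for ",
           keys$subject[i], "/", keys$condition[i])
    num <- sum(p[seq_along(bands$num)])
    den <- sum(p[-seq_along(bands$num)])
    ti[i] <- log(num / den, base = logBase)
  }
  tag <- sprintf("%s|log=%s|agg=%s", variant,
                 if (isTRUE(all.equal(logBase, exp(1)))) "e" else
                   format(logBase),
                 if (length(unique(table$channel)) == 1L)
                   table$channel[1] else "mixed")
  out <- data.frame(subject = keys$subject, condition = keys$condition,
                    ti = ti, variant = tag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Within-subject paired contrast of TI between conditions
#'
#' Paired t-test on within-subject differences (condition `a` minus `b`),
#' two-tailed p from the t distribution on n-1 degrees of freedom, paired
#' Cohen's d computed as `d = t / sqrt(n)` with the normal-approximation 95
#' percent interval `d +/- 1.96 * sqrt(1/n + d^2 / (2n))`.
#'
#' @param ti either a TI data.frame from [computeTI()] (then give `a` and
#'   `b`), or a named numeric vector of per-subject values for condition A
#' @param b second condition label, or named numeric vector for condition B
#' @param a first condition label (ignored when vectors are supplied)
#' @return one-row data.frame: `n, t, df, p, d, d_lo, d_hi, mean_diff`
#' @examples
#' x <- c(s1 = 1.5, s2 = 1.2, s3 = 1.8, s4 = 1.4)
#' pairedContrast(x, x - c(0.2, 0.1, 0.3, 0.15))
#' @export
pairedContrast <- function(ti, b, a = NULL) {
  if (is.data.frame(ti)) {
    if (is.null(a)) stop("give both condition labels a= and b=")
    xa <- ti$ti[ti$condition == a]
    names(xa) <- ti$subject[ti$condition == a]
    xb <- ti$ti[ti$condition == b]
    names(xb) <- ti$subject[ti$condition == b]
  } else {
    xa <- ti
    xb <- b
  }
  if (is.null(names(xa)) || is.null(names(xb)))
    stop("alignment error: per-subject values must be named by subject")
  if (!setequal(names(xa), names(xb)))
    stop("alignment error: subject sets differ between conditions")
  xb <- xb[names(xa)]
  n <- length(xa)
  if (n < 3L) stop("need at least 3 subjects for the paired contrast")
  d <- xa - xb
  if (all(d == 0)) {
    tstat <- 0
    p <- 1
  } else if (stats::sd(d) == 0) {
    stop("degenerate-case error: zero-variance nonzero differences")
  } else {
    tstat <- mean(d) / (stats::sd(d) / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  cohend <- tstat / sqrt(n)
  se <- sqrt(1 / n + cohend^2 / (2 * n))
  data.frame(n = n, t = tstat, df = n - 1, p = p, d = cohend,
             d_lo = cohend - 1.96 * se, d_hi = cohend + 1.96 * se,
             mean_diff = mean(d))
}
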