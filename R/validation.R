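# Agreement and comparison statistics between a reference modality
# (ground truth / singleplex) and mIF-derived calls.

#' Spearman rank correlation
#'
#' Rank correlation with mid-rank ties. The p-value is exact (sum of squared
#' rank differences distribution) for n < 10 without ties, and otherwise uses
#' the t approximation `t = r * sqrt((n-2)/(1-r^2))` with n-2 degrees of
#' freedom; the switchover at n = 10 is a documented implementation choice.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list (r_s, p, n, method). A constant vector yields `r_s = NA` with
#'   method `"undefined"`.
#' @export
spearman_rank <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r_s = NA_real_, p = NA_real_, n = n, method = "undefined"))
  rx <- rank(x); ry <- rank(y)
  r <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n < 10 && !ties) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = TRUE))
    p <- ct$p.value
    method <- "exact"
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(r_s = unname(r), p = min(1, p), n = n, method = method)
}

#' Bland-Altman agreement
#'
#' Differences `d = x - y`; bias is `mean(d)` and the 95% limits of agreement
#' are `bias +/- 1.96 * sd(d)` (sample sd, n-1 denominator). Per-point flags
#' mark differences inside the limits.
#'
#' @param x,y paired measurements, n >= 2.
#' @return list (bias, loa_low, loa_high, within_loa, sd_d, n).
#' @export
bland_altman <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 2) stop("need n >= 2")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  list(bias = bias, loa_low = loa_low, loa_high = loa_high,
       within_loa = d >= loa_low & d <= loa_high, sd_d = s, n = n)
}

#' Mann-Whitney U test
#'
#' U from rank sums with mid-rank ties. Exact p (Wilcoxon rank-sum
#' distribution) when `min(n1, n2) <= 8` and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y nonempty numeric vectors.
#' @return list (U, p, n1, n2, method). U is reported for `x`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U <- min(U1, n1 * n2 - U1)
  ties <- anyDuplicated(c(x, y)) > 0
  if (min(n1, n2) <= 8 && !ties) {
    # pwilcox gives P(U_x <= q) under H0
    p <- 2 * pwilcox(U, n1, n2)
    method <- "exact"
  } else {
    nt <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - sum(nt^3 - nt) /
                              ((n1 + n2) * (n1 + n2 - 1)))
    z <- (abs(U1 - mu) - 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-z)
    method <- "normal-approximation"
  }
  list(U = unname(U1), p = min(1, max(0, p)), n1 = n1, n2 = n2, method = method)
}

#' Paired t test
#'
#' Classical paired t on differences with a two-tailed p from the t
#' distribution, df = n-1. Zero-variance differences with nonzero mean are
#' reported as `t = +/-Inf`, `p = 0` with `degenerate = TRUE`.
#'
#' @param x,y paired numeric vectors, n >= 2.
#' @return list (t, p, df, mean_d, degenerate).
#' @export
paired_t <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 2) stop("need n >= 2")
  d <- x - y
  md <- mean(d); s <- sd(d)
  if (s == 0) {
    if (md == 0) return(list(t = 0, p = 1, df = n - 1, mean_d = 0, degenerate = TRUE))
    return(list(t = sign(md) * Inf, p = 0, df = n - 1, mean_d = md,
                degenerate = TRUE))
  }
  tstat <- md / (s / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1), df = n - 1,
       mean_d = md, degenerate = FALSE)
}

#' Positivity-difference criterion
#'
#' Flags paired units where the reference and test percent-positive values
#' differ by more than 10 percentage points (less than 90% accuracy of
#' obtaining a similar result), and summarises flagged units per marker.
#'
#' @param paired data.frame with columns `unit`, `marker`, `reference`, `test`
#'   (percentages in 0-100).
#' @param limit flag threshold in percentage points.
#' @return list (`flags` data.frame with `flagged` column, `summary` per
#'   marker counts).
#' @export
positivity_criterion <- function(paired, limit = 10) {
  stopifnot(all(c("unit", "marker", "reference", "test") %in% names(paired)))
  if (any(paired$reference < 0 | paired$reference > 100 |
          paired$test < 0 | paired$test > 100))
    stop("percentages must lie in [0, 100]")
  fl <- paired
  fl$difference <- fl$reference - fl$test
  fl$flagged <- abs(fl$difference) > limit
  sm <- do.call(rbind, lapply(split(fl, fl$marker), function(g)
    data.frame(marker = g$marker[1], n_units = nrow(g),
               n_flagged = sum(g$flagged), stringsAsFactors = FALSE)))
  rownames(sm) <- NULL
  list(flags = fl, summary = sm)
}

#' Panel validation against a reference modality
#'
#' Builds per-unit, per-marker percent-positivity pairs from reference and
#' test call tables, then per marker runs Spearman rank correlation,
#' Bland-Altman agreement and the 10-percentage-point positivity criterion.
#' The verdict is `"validated"` when the correlation is significant (p < 0.05,
#' r_s > 0) and the bias lies within the limits-of-agreement half-width; both
#' LoA readings (per-point coverage and bias magnitude) are reported.
#'
#' @param truth_calls,mif_calls data.frames with a `unit` column plus one
#'   logical column per marker (cell rows).
#' @param markers markers to validate (default: shared logical columns).
#' @param alpha significance level.
#' @return data.frame, one row per marker, plus attribute `pairs`.
#' @export
validate_panel <- function(truth_calls, mif_calls, markers = NULL,
                           alpha = 0.05) {
  if (is.null(markers))
    markers <- setdiff(intersect(names(truth_calls), names(mif_calls)), "unit")
  units <- sort(unique(truth_calls$unit))
  if (!setequal(units, unique(mif_calls$unit)))
    stop("reference and test tables must cover the same unit set")
  pct <- function(df, m) vapply(units, function(u)
    100 * mean(df[[m]][df$unit == u]), 0)
  pairs <- do.call(rbind, lapply(markers, function(m)
    data.frame(unit = units, marker = m, reference = pct(truth_calls, m),
               test = pct(mif_calls, m), stringsAsFactors = FALSE)))
  res <- do.call(rbind, lapply(markers, function(m) {
    pm <- pairs[pairs$marker == m, ]
    if (length(units) < 3)
      return(data.frame(marker = m, r_s = NA, p = NA, bias = NA,
                        loa_low = NA, loa_high = NA, n_flagged = NA,
                        prop_within_loa = NA, verdict = "insufficient units",
                        stringsAsFactors = FALSE))
    sp <- spearman_rank(pm$reference, pm$test)
    ba <- bland_altman(pm$reference, pm$test)
    pc <- positivity_criterion(pm)
    half <- 1.96 * ba$sd_d
    validated <- !is.na(sp$r_s) && sp$p < alpha && sp$r_s > 0 &&
      abs(ba$bias) <= half
    data.frame(marker = m, r_s = sp$r_s, p = sp$p, bias = ba$bias,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               n_flagged = sum(pc$flags$flagged),
               prop_within_loa = mean(ba$within_loa),
               verdict = if (validated) "validated" else "not validated",
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "pairs") <- pairs
  attr(res, "note") <- "no multiple-testing correction applied"
  res
}
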