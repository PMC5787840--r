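#' Relative water content
#'
#' `RWC = (FW - DW) / (SW - DW) * 100`, the standard leaf-hydration measure
#' from fresh (FW), saturated (SW) and dry (DW) weights. Vectorized;
#' invariant to the weight unit. Requires `0 < DW <= FW <= SW` with
#' `SW > DW`; violations are an error.
#'
#' @param fw,sw,dw Fresh, saturated and dry weights (same unit).
#' @return RWC percent in `[0, 100]`.
#' @export
compute_rwc <- function(fw, sw, dw) {
  if (any(fw <= 0) || any(sw <= 0) || any(dw <= 0))
    stop("weights must be positive")
  if (any(sw == dw))
    stop("SW == DW: saturated and dry weight equal (division by zero)")
  if (any(dw > fw) || any(fw > sw))
    stop("weight ordering violated: need DW <= FW <= SW")
  (fw - dw) / (sw - dw) * 100
}

#' Read leaf-weight records
#'
#' TSV with columns `sample_id`, `cultivar`, `day`, `fw`, `sw`, `dw`;
#' weight invariants are checked at parse and the computed `rwc` column is
#' appended.
#'
#' @param path TSV path or an equivalent data.frame.
#' @return Data frame with an `rwc` column.
#' @export
read_rwc_records <- function(path) {
  df <- if (is.data.frame(path)) path else read_tsv_strict(path)
  req <- c("sample_id", "cultivar", "day", "fw", "sw", "dw")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("RWC table missing columns: ", paste(missing_cols, collapse = ", "))
  df$rwc <- compute_rwc(df$fw, df$sw, df$dw)
  df
}

#' Express an RWC time series as percent of day 0
#'
#' @param values RWC values.
#' @param days Matching day labels; day 0 (the minimum day) must be present
#'   with a positive value.
#' @return Numeric vector: `value(d) * 100 / value(day 0)`; day 0 maps
#'   to 100.
#' @export
rwc_percent_of_day0 <- function(values, days) {
  if (length(values) != length(days)) stop("values and days differ in length")
  i0 <- which(days == min(days))
  if (length(i0) != 1L) stop("need exactly one day-0 value")
  if (min(days) != 0) stop("day 0 missing from series")
  if (values[i0] <= 0) stop("day-0 value must be positive")
  values * 100 / values[i0]
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When there are no ties and `n + m` is at most
#' `exact_limit`, the p-value is exact, obtained by enumerating all
#' `choose(n + m, n)` assignments of ranks to the first sample; otherwise
#' midranks and a normal approximation with tie-corrected variance are used.
#' The `exact` flag of the result records which path ran.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Largest `n + m` for which the exact enumeration is
#'   attempted (default 12).
#' @return Object of class `mw_test`: `statistic` (U for `x`), `p_value`,
#'   `exact`, `n`, `m`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks under ties
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n + m <= exact_limit) {
    combos <- utils::combn(n + m, n)
    u_all <- colSums(combos) - n * (n + 1) / 2
    p <- 2 * min(mean(u_all <= u), mean(u_all >= u))
    p <- min(p, 1)
    exact <- TRUE
  } else {
    nm <- n + m
    tie_tab <- table(pooled)
    sigma2 <- n * m / 12 * ((nm + 1) - sum(tie_tab^3 - tie_tab) /
                              (nm * (nm - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (u - n * m / 2) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  structure(list(statistic = u, p_value = p, exact = exact, n = n, m = m),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test: U = %g, n = %d, m = %d, p = %.4g (%s)\n",
              x$statistic, x$n, x$m, x$p_value,
              if (x$exact) "exact enumeration" else "normal approximation"))
  invisible(x)
}
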