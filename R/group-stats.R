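# Group-level inference for paired adaptation designs: paired t with dz,
# 2x2 repeated-measures ANOVA via within-subject contrasts, simple main
# effects, effect-size conversions, noncentral-t power mathematics and
# Tukey-fence outlier flagging.

effect_report <- function(effect, kind, statistic, df1, df2, p,
                          effect_size, effect_size_type) {
  data.frame(effect = effect, kind = kind, statistic = statistic,
             df1 = df1, df2 = df2, p = p, effect_size = effect_size,
             effect_size_type = effect_size_type,
             stringsAsFactors = FALSE)
}

#' Paired t test with dz
#'
#' Two-tailed paired t test on per-participant values, reported with the
#' standardized paired effect size dz = mean(d) / sd(d), where sd uses the
#' unbiased (n - 1) denominator. Identical vectors return the degenerate
#' zero report (t = 0, p = 1, dz = 0); constant non-zero differences make
#' the statistic undefined and raise an error.
#'
#' @param x,y Paired numeric vectors (same participants, same order),
#'   length >= 2.
#' @param effect Label for the report row.
#' @return A one-row data frame: `effect`, `kind = "t"`, `statistic`,
#'   `df1` (NA), `df2 = n - 1`, `p`, `effect_size` (dz),
#'   `effect_size_type = "dz"`.
#' @export
#' @examples
#' paired_t(c(2, 4, 5, 9), c(1, 2, 2, 5))
paired_t <- function(x, y, effect = "paired difference") {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0))
      return(effect_report(effect, "t", 0, NA_real_, n - 1, 1, 0, "dz"))
    stop("zero variance of paired differences: t statistic undefined",
         call. = FALSE)
  }
  tt <- t.test(x, y, paired = TRUE)
  effect_report(effect, "t", unname(tt$statistic), NA_real_, n - 1,
                tt$p.value, mean(d) / sd(d), "dz")
}

#' Convert a paired t statistic to dz
#'
#' For a paired design, `dz = t / sqrt(n)`.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs (>= 2).
#' @return dz.
#' @export
dz_from_t <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

#' Convert a 1-df within-subject F to dz
#'
#' For a contrast F on (1, n - 1) degrees of freedom, `F = t^2`, so
#' `dz = sqrt(F / df2)`.
#'
#' @param f F statistic (>= 0).
#' @param df2 Error degrees of freedom (n - 1).
#' @return dz (non-negative; the contrast's direction is not recoverable
#'   from F).
#' @export
dz_from_F <- function(f, df2) {
  stopifnot(f >= 0, df2 >= 1)
  sqrt(f / df2)
}

#' Partial eta squared from a 1-df F
#'
#' For a single-df within-subject effect, partial eta squared equals
#' `F / (F + df2)`.
#'
#' @inheritParams dz_from_F
#' @return Partial eta squared in `[0, 1)`.
#' @export
eta2_from_F <- function(f, df2) {
  stopifnot(f >= 0, df2 >= 1)
  f / (f + df2)
}

.contrast_F <- function(d, effect) {
  n <- length(d)
  if (sd(d) == 0) {
    if (all(d == 0))
      return(effect_report(effect, "F", 0, 1, n - 1, 1, 0, "partial_eta_sq"))
    stop("zero variance of contrast scores: F statistic undefined",
         call. = FALSE)
  }
  tstat <- mean(d) / (sd(d) / sqrt(n))
  fstat <- tstat^2
  effect_report(effect, "F", fstat, 1, n - 1,
                pf(fstat, 1, n - 1, lower.tail = FALSE),
                eta2_from_F(fstat, n - 1), "partial_eta_sq")
}

.cell_means_2x2 <- function(data, value, participant, factor_a, factor_b) {
  for (col in c(value, participant, factor_a, factor_b))
    if (!col %in% names(data))
      stop(sprintf("column '%s' not found", col), call. = FALSE)
  a_lev <- sort(unique(as.character(data[[factor_a]])))
  b_lev <- sort(unique(as.character(data[[factor_b]])))
  if (length(a_lev) != 2L || length(b_lev) != 2L)
    stop("both factors must have exactly 2 levels", call. = FALSE)
  m <- tapply(data[[value]],
              list(factor(as.character(data[[participant]])),
                   factor(as.character(data[[factor_a]]), levels = a_lev),
                   factor(as.character(data[[factor_b]]), levels = b_lev)),
              mean)
  if (any(is.na(m)))
    stop("incomplete design: every participant needs a value in all 4 cells",
         call. = FALSE)
  m
}

#' 2x2 repeated-measures ANOVA via within-subject contrasts
#'
#' Each effect of a fully within-subject 2x2 design is a single-df paired
#' contrast on per-participant difference scores: its F equals the square
#' of the corresponding paired t and is reported on (1, n - 1) degrees of
#' freedom with partial eta squared `F / (F + df2)`.
#'
#' @param data Long data frame, one row per participant x cell.
#' @param value Name of the response column.
#' @param participant Name of the participant id column.
#' @param factor_a,factor_b Names of the two within-subject factor columns
#'   (2 levels each; levels are taken in sorted order).
#' @return A three-row data frame (main effect of each factor, then the
#'   interaction) in the [paired_t()] report schema with `kind = "F"`.
#' @export
rm_anova_2x2 <- function(data, value = "pss", participant = "participant",
                         factor_a = "congruency", factor_b = "condition") {
  m <- .cell_means_2x2(data, value, participant, factor_a, factor_b)
  a_main <- (m[, 1, 1] + m[, 1, 2]) / 2 - (m[, 2, 1] + m[, 2, 2]) / 2
  b_main <- (m[, 1, 1] + m[, 2, 1]) / 2 - (m[, 1, 2] + m[, 2, 2]) / 2
  inter <- (m[, 1, 1] - m[, 1, 2]) - (m[, 2, 1] - m[, 2, 2])
  rbind(.contrast_F(a_main, paste0("main:", factor_a)),
        .contrast_F(b_main, paste0("main:", factor_b)),
        .contrast_F(inter, paste0("interaction:", factor_a, "x", factor_b)))
}

#' Simple main effects in a 2x2 within-subject design
#'
#' Tests the effect of `test_factor` separately within each level of
#' `within_factor`, as a paired contrast on that level's two cells:
#' F = t^2 on (1, n - 1) degrees of freedom, i.e. the per-level error
#' term, not a pooled one.
#'
#' @inheritParams rm_anova_2x2
#' @param test_factor Factor whose effect is tested.
#' @param within_factor Factor whose levels stratify the test.
#' @param within_level Level(s) of `within_factor` to test; `NULL` (the
#'   default) tests every level. Unknown levels raise an error.
#' @return One report row per tested level.
#' @export
simple_main_effects <- function(data, value = "pss",
                                participant = "participant",
                                test_factor = "condition",
                                within_factor = "congruency",
                                within_level = NULL) {
  m <- .cell_means_2x2(data, value, participant, within_factor, test_factor)
  levels_w <- dimnames(m)[[2]]
  if (is.null(within_level)) within_level <- levels_w
  bad <- setdiff(within_level, levels_w)
  if (length(bad))
    stop(sprintf("unknown level '%s' of factor '%s'", bad[1L], within_factor),
         call. = FALSE)
  out <- lapply(within_level, function(lev) {
    d <- m[, lev, 1] - m[, lev, 2]
    .contrast_F(d, sprintf("simple:%s within %s=%s",
                           test_factor, within_factor, lev))
  })
  do.call(rbind, out)
}

#' Power of a two-tailed paired t test
#'
#' Exact noncentral-t power: with `n` pairs and standardized paired effect
#' dz, the test statistic is noncentral t with df = n - 1 and
#' noncentrality `dz * sqrt(n)`; power is the probability of exceeding the
#' two-tailed critical value.
#'
#' @param dz Standardized mean of paired differences.
#' @param n Number of pairs (>= 2).
#' @param alpha Two-tailed significance level (default 0.05).
#' @return Achieved power in (0, 1). At dz = 0 this equals alpha.
#' @export
#' @examples
#' power_paired(0.66, 20)  # about 0.80
power_paired <- function(dz, n, alpha = 0.05) {
  stopifnot(all(n >= 2), alpha > 0, alpha < 1)
  df <- n - 1
  tcrit <- qt(1 - alpha / 2, df)
  ncp <- dz * sqrt(n)
  pt(-tcrit, df, ncp) + pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Minimal detectable paired effect size
#'
#' Inverts [power_paired()] in dz by root bracketing on (0, 10).
#'
#' @param n Number of pairs.
#' @param alpha Two-tailed significance level.
#' @param power Target power.
#' @return The dz at which the paired t test attains the target power.
#' @export
#' @examples
#' min_detectable_dz(20)  # about 0.66
min_detectable_dz <- function(n, alpha = 0.05, power = 0.80) {
  stopifnot(n >= 2, power > alpha, power < 1)
  f <- function(d) power_paired(d, n, alpha) - power
  if (f(10) < 0)
    stop("no detectable effect size below dz = 10 for this design",
         call. = FALSE)
  uniroot(f, c(1e-9, 10), tol = 1e-9)$root
}

#' Required sample size for a paired t test
#'
#' Smallest number of pairs at which the two-tailed paired t test reaches
#' the target power for a given dz, by upward iteration on exact
#' noncentral-t power.
#'
#' @param dz Standardized paired effect size (> 0).
#' @param alpha Two-tailed significance level.
#' @param power Target power.
#' @param max_n Search cap; exceeding it raises an error.
#' @return Integer sample size.
#' @export
#' @examples
#' required_n(0.56)  # 28
required_n <- function(dz, alpha = 0.05, power = 0.80, max_n = 1e5) {
  stopifnot(dz > 0, power > alpha, power < 1)
  for (n in 2:max_n)
    if (power_paired(dz, n, alpha) >= power) return(as.integer(n))
  stop(sprintf("required n exceeds the cap of %d", as.integer(max_n)),
       call. = FALSE)
}

#' Tukey-fence outlier flags
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles
#' computed by linear interpolation (`stats::quantile` type 7).
#'
#' @param values Numeric vector, length >= 4.
#' @return Logical vector of flags.
#' @export
tukey_outliers <- function(values) {
  if (length(values) < 4L) stop("need at least 4 values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}
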