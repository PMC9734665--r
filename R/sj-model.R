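# Two-criterion observer model for simultaneity judgments.
#
# An observer judges an audiovisual pair "simultaneous" when the test SOA
# falls between two decision criteria on the SOA axis. With criterion
# positions blurred by Gaussian noise, the probability of a simultaneous
# response is the difference of two cumulative Gaussians. SOA is signed in
# milliseconds; negative values mean the auditory stimulus came first.

#' Two-criterion observer parameters
#'
#' Container for the four parameters of the two-criterion simultaneity
#' judgment model: the low (audio-lead side) and high (visual-lead side)
#' decision criteria on the SOA axis, and the Gaussian slope scale attached
#' to each criterion.
#'
#' @param c_low Low criterion position (ms). Must not exceed `c_high`.
#' @param c_high High criterion position (ms).
#' @param sigma_low Positive slope scale of the low criterion (ms).
#' @param sigma_high Positive slope scale of the high criterion (ms).
#'
#' @return An object of class `criterion_params`.
#' @seealso [prob_simultaneous()], [pss()], [sj_window()]
#' @export
#' @examples
#' p <- criterion_params(-180, 260, 90, 90)
#' pss(p)       # 40
#' sj_window(p) # 440
criterion_params <- function(c_low, c_high, sigma_low, sigma_high) {
  vals <- c(c_low, c_high, sigma_low, sigma_high)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals)))
    stop("criterion parameters must be four finite numbers", call. = FALSE)
  if (sigma_low <= 0 || sigma_high <= 0)
    stop("sigma_low and sigma_high must be positive", call. = FALSE)
  if (c_low > c_high)
    stop("c_low must not exceed c_high", call. = FALSE)
  structure(
    list(c_low = as.numeric(c_low), c_high = as.numeric(c_high),
         sigma_low = as.numeric(sigma_low), sigma_high = as.numeric(sigma_high)),
    class = "criterion_params"
  )
}

#' @export
print.criterion_params <- function(x, ...) {
  cat(sprintf(
    "Two-criterion observer: c_low = %.2f ms, c_high = %.2f ms, sigma_low = %.2f, sigma_high = %.2f\n",
    x$c_low, x$c_high, x$sigma_low, x$sigma_high))
  cat(sprintf("  PSS = %.2f ms, window = %.2f ms\n", pss(x), sj_window(x)))
  invisible(x)
}

#' Single cumulative-Gaussian parameters
#'
#' Parameters of the two-parameter null model: one criterion and one slope
#' scale, giving a monotone response probability over SOA. Used as the
#' simpler nested model in the participant screen.
#'
#' @param criterion Criterion position on the SOA axis (ms); stored as `c`.
#' @param sigma Positive slope scale (ms).
#' @return An object of class `single_cdf_params`.
#' @seealso [prob_single()], [fit_single_cdf()]
#' @export
single_cdf_params <- function(criterion, sigma) {
  if (!is.numeric(criterion) || !is.numeric(sigma) ||
      length(criterion) != 1L || length(sigma) != 1L ||
      !is.finite(criterion) || !is.finite(sigma))
    stop("parameters must be finite numbers", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  structure(list(c = as.numeric(criterion), sigma = as.numeric(sigma)),
            class = "single_cdf_params")
}

#' Probability of a simultaneous response under the two-criterion model
#'
#' The response probability is the difference of two cumulative Gaussians,
#' `pnorm((c_high - soa)/sigma_high) - pnorm((c_low - soa)/sigma_low)`,
#' clipped into `[eps, 1 - eps]`. With `c_low < c_high` the curve is
#' unimodal, tending to 0 at both SOA extremes with its peak between the
#' criteria. When the slope scales differ the raw difference can be slightly
#' negative in one tail; clipping keeps the value a valid probability.
#'
#' @param params A [criterion_params()] object.
#' @param soa Numeric vector of SOAs (ms; negative = auditory first).
#' @param eps Clipping constant applied to both tails (default `1e-6`).
#' @return Numeric vector of probabilities in `[eps, 1 - eps]`.
#' @export
#' @examples
#' p <- criterion_params(-200, 200, 100, 100)
#' prob_simultaneous(p, 0)   # pnorm(2) - pnorm(-2), about 0.9545
prob_simultaneous <- function(params, soa, eps = 1e-6) {
  if (!inherits(params, "criterion_params"))
    stop("params must be a criterion_params object", call. = FALSE)
  p <- pnorm((params$c_high - soa) / params$sigma_high) -
       pnorm((params$c_low  - soa) / params$sigma_low)
  pmin(pmax(p, eps), 1 - eps)
}

#' Probability of a simultaneous response under the single-CDF model
#'
#' One cumulative Gaussian over SOA: `pnorm((soa - c)/sigma)`, monotone
#' increasing in SOA. This is the two-parameter null model used to screen
#' out participants whose data the two-criterion model does not fit better
#' than a monotone curve.
#'
#' @param params A [single_cdf_params()] object.
#' @param soa Numeric vector of SOAs (ms).
#' @return Numeric vector of probabilities.
#' @export
prob_single <- function(params, soa) {
  if (!inherits(params, "single_cdf_params"))
    stop("params must be a single_cdf_params object", call. = FALSE)
  pnorm((soa - params$c) / params$sigma)
}

#' Point of subjective simultaneity
#'
#' The PSS is the midpoint of the two decision criteria,
#' `(c_high + c_low)/2`. A positive PSS means visual-lead SOAs are more
#' often judged simultaneous than audio-lead SOAs.
#'
#' @param x A [criterion_params()] object, or a fitted model object that
#'   carries one (see [fit_criterion_model()], [fit_scaled_gaussian()]).
#' @return PSS in ms.
#' @export
pss <- function(x) UseMethod("pss")

#' @export
pss.criterion_params <- function(x) (x$c_high + x$c_low) / 2

#' @export
pss.sj_fit <- function(x) pss(x$params)

#' @export
pss.scaled_gaussian_params <- function(x) x$mu

#' @export
pss.scaled_gaussian_fit <- function(x) x$params$mu

#' Window of subjective simultaneity
#'
#' The distance between the two decision criteria, `c_high - c_low`: the
#' width of the SOA range an observer tends to judge simultaneous. The
#' fitter's ordering constraint guarantees a non-negative window.
#'
#' @inheritParams pss
#' @return Window width in ms.
#' @export
sj_window <- function(x) UseMethod("sj_window")

#' @export
sj_window.criterion_params <- function(x) x$c_high - x$c_low

#' @export
sj_window.sj_fit <- function(x) sj_window(x$params)

#' Per-SOA binomial response cells
#'
#' One row per SOA level with the number of trials `n` and the number of
#' simultaneous responses `k`. This is the aggregated form in which SJ data
#' enter the likelihood.
#'
#' @param soa Distinct signed SOA values (ms).
#' @param n Trial counts (scalar recycled, or one per SOA), each >= 1.
#' @param k Simultaneous-response counts, `0 <= k <= n`.
#' @return A data frame of class `binomial_cells` with columns
#'   `soa`, `n`, `k`.
#' @export
binomial_cells <- function(soa, n, k) {
  if (!is.numeric(soa) || !is.numeric(n) || !is.numeric(k))
    stop("soa, n and k must be numeric", call. = FALSE)
  if (length(n) == 1L) n <- rep(n, length(soa))
  if (length(soa) != length(n) || length(soa) != length(k))
    stop("soa, n and k must have equal length", call. = FALSE)
  if (anyDuplicated(soa)) stop("SOA levels must be distinct", call. = FALSE)
  if (any(n < 1) || any(n != round(n)) || any(k != round(k)))
    stop("n and k must be whole numbers with n >= 1", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]", call. = FALSE)
  structure(
    data.frame(soa = as.numeric(soa), n = as.integer(round(n)),
               k = as.integer(round(k))),
    class = c("binomial_cells", "data.frame")
  )
}

as_binomial_cells <- function(x) {
  if (inherits(x, "binomial_cells")) return(x)
  if (is.data.frame(x) && all(c("soa", "n", "k") %in% names(x)))
    return(binomial_cells(x$soa, x$n, x$k))
  stop("cannot interpret input as binomial cells (need columns soa, n, k)",
       call. = FALSE)
}

#' Binomial log-likelihood of per-SOA response counts
#'
#' Sum over cells of `k*log(p) + (n - k)*log(1 - p)`. The additive binomial
#' coefficient is omitted throughout the package; it cancels in every
#' deviance difference. The `0 * log(0) = 0` convention applies, so the
#' saturated likelihood of cells with `k = 0` or `k = n` is finite.
#'
#' @param cells A [binomial_cells()] object (or data frame with `soa`, `n`,
#'   `k`).
#' @param p Per-cell probabilities in `[0, 1]`, same length as `nrow(cells)`.
#' @return The log-likelihood (a scalar; `-Inf` if a positive count meets a
#'   zero probability).
#' @export
binom_loglik <- function(cells, p) {
  cells <- as_binomial_cells(cells)
  if (length(p) != nrow(cells))
    stop("need one probability per cell", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  xlogp <- function(x, pr) {
    out <- numeric(length(x))
    pos <- x > 0
    out[pos] <- x[pos] * log(pr[pos])
    out
  }
  sum(xlogp(cells$k, p) + xlogp(cells$n - cells$k, 1 - p))
}

#' Saturated log-likelihood
#'
#' Log-likelihood of the model that fits every cell's empirical proportion
#' exactly; the reference point of the deviance.
#'
#' @inheritParams binom_loglik
#' @return Scalar log-likelihood.
#' @export
saturated_loglik <- function(cells) {
  cells <- as_binomial_cells(cells)
  binom_loglik(cells, cells$k / cells$n)
}

#' Deviance of a fitted model
#'
#' `2 * (saturated log-likelihood - model log-likelihood)`. Non-negative up
#' to numerical tolerance, zero when the model reproduces the empirical
#' proportions exactly. Differences in deviance between nested fits equal
#' the likelihood-ratio statistic and are unaffected by the omitted
#' binomial coefficient.
#'
#' @inheritParams binom_loglik
#' @param log_likelihood The fitted model's log-likelihood on the same
#'   cells, as returned by [binom_loglik()].
#' @return Scalar deviance.
#' @export
sj_deviance <- function(cells, log_likelihood) {
  2 * (saturated_loglik(cells) - log_likelihood)
}
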