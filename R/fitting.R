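# Maximum-likelihood fitting of the observer models.
#
# Both models are fitted on the unconstrained scale
#   theta = (c_low, log(c_high - c_low), log sigma_low, log sigma_high)
# (criterion ordering and positive scales by construction), by bounded
# quasi-Newton (L-BFGS-B) with an analytic gradient from several
# deterministic starts. The best start wins; non-convergence is reported,
# never silently dropped.

#' Fitting configuration
#'
#' @param eps Probability clipping constant used inside the likelihood
#'   (default `1e-6`).
#' @param reltol Relative convergence tolerance on the objective
#'   (default `1e-8`).
#' @param maxit Maximum optimizer iterations per start.
#' @param alpha Significance level of the nested-model screen.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(eps = 1e-6, reltol = 1e-8, maxit = 500L, alpha = 0.05) {
  stopifnot(eps > 0, eps < 0.5, reltol > 0, maxit >= 1, alpha > 0, alpha < 1)
  structure(list(eps = eps, reltol = reltol, maxit = as.integer(maxit),
                 alpha = alpha),
            class = "fit_config")
}

# ---- four-parameter model ---------------------------------------------------

.criterion_unpack <- function(theta) {
  c_low <- theta[1L]
  c_high <- c_low + exp(theta[2L])
  list(c_low = c_low, c_high = c_high,
       sigma_low = exp(theta[3L]), sigma_high = exp(theta[4L]))
}

.criterion_negll <- function(theta, soa, k, n, eps) {
  q <- .criterion_unpack(theta)
  p <- pnorm((q$c_high - soa) / q$sigma_high) -
       pnorm((q$c_low  - soa) / q$sigma_low)
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

.criterion_negll_grad <- function(theta, soa, k, n, eps) {
  q <- .criterion_unpack(theta)
  w <- q$c_high - q$c_low
  zh <- (q$c_high - soa) / q$sigma_high
  zl <- (q$c_low  - soa) / q$sigma_low
  p_raw <- pnorm(zh) - pnorm(zl)
  clipped <- p_raw < eps | p_raw > 1 - eps
  p <- pmin(pmax(p_raw, eps), 1 - eps)
  dldp <- k / p - (n - k) / (1 - p)
  dldp[clipped] <- 0  # objective is flat where the probability is clipped
  ph <- dnorm(zh); pl <- dnorm(zl)
  dp_dch <- ph / q$sigma_high
  dp_dcl <- -pl / q$sigma_low
  g <- c(
    sum(dldp * (dp_dch + dp_dcl)),   # c_low shifts both criteria
    sum(dldp * dp_dch) * w,          # log-width moves c_high only
    sum(dldp * pl * zl),             # log sigma_low
    sum(dldp * (-ph * zh))           # log sigma_high
  )
  -g
}

# Deterministic start grid: criterion pairs at +/- 1/3 and +/- 2/3 of the
# SOA span, each slope scale at 1/4 or 1/2 span, plus one moment-based
# start treating the response mass over SOA as a density.
.criterion_starts <- function(cells) {
  soa <- cells$soa
  span <- diff(range(soa))
  mid <- mean(range(soa))
  starts <- list()
  for (w in c(1 / 3, 2 / 3))
    for (sl in c(1 / 4, 1 / 2))
      for (sh in c(1 / 4, 1 / 2))
        starts[[length(starts) + 1L]] <-
          c(mid - w * span, log(2 * w * span), log(sl * span), log(sh * span))
  mass <- cells$k / cells$n
  if (sum(mass) > 0) {
    wt <- mass / sum(mass)
    mu <- sum(wt * soa)
    s <- sqrt(max(sum(wt * (soa - mu)^2), (span / 20)^2))
    starts[[length(starts) + 1L]] <- c(mu - s, log(2 * s), log(s / 2), log(s / 2))
  }
  starts
}

# Bounded quasi-Newton (L-BFGS-B) from every start; parameters beyond a few
# SOA spans are unidentifiable from the sampled range, so the box doubles
# as an identifiability constraint. The winner gets one polish restart
# (fresh Hessian), which also clears runs stopped at maxit on a plateau.
.run_starts <- function(starts, fn, gr, config, lower, upper, ...) {
  ctrl <- list(factr = config$reltol / .Machine$double.eps,
               maxit = config$maxit)
  best <- NULL
  for (theta0 in starts) {
    theta0 <- pmin(pmax(theta0, lower), upper)
    opt <- tryCatch(
      optim(theta0, fn, gr = gr, ..., method = "L-BFGS-B",
            lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.null(best)) {
    polished <- tryCatch(
      optim(best$par, fn, gr = gr, ..., method = "L-BFGS-B",
            lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (!is.null(polished)) {
      improved <- polished$value < best$value - 1e-10 * (1 + abs(best$value))
      if (improved) best <- polished
      else if (best$convergence != 0L && polished$convergence == 0L)
        best$convergence <- 0L  # stationary: restart confirms the optimum
    }
  }
  best
}

#' Fit the four-parameter two-criterion model
#'
#' Maximum-likelihood fit of the difference-of-two-cumulative-Gaussians
#' model to per-SOA binomial counts, using multi-start BFGS on a
#' reparameterized scale that enforces `c_low <= c_high` and positive
#' slope scales. All-zero or all-`n` response data cannot identify the
#' model and are returned flagged as non-converged.
#'
#' @param cells A [binomial_cells()] object with at least 4 distinct SOA
#'   levels.
#' @param config A [fit_config()].
#' @return An object of class `sj_fit`: `params` ([criterion_params()]),
#'   `log_likelihood`, `deviance`, `converged`, `n_parameters = 4`,
#'   `n_starts_used`, and the `cells` the fit was computed on.
#' @seealso [fit_single_cdf()], [model_comparison()]
#' @export
#' @examples
#' truth <- criterion_params(-150, 250, 60, 60)
#' soa <- c(-350, -250, -150, -100, -50, 0, 50, 100, 150, 250, 350)
#' set.seed(1)
#' k <- rbinom(length(soa), 20, prob_simultaneous(truth, soa))
#' fit <- fit_criterion_model(binomial_cells(soa, 20, k))
#' pss(fit)
fit_criterion_model <- function(cells, config = fit_config()) {
  cells <- as_binomial_cells(cells)
  if (length(unique(cells$soa)) < 4L)
    stop("need at least 4 distinct SOA levels", call. = FALSE)
  degenerate <- all(cells$k == 0L) || all(cells$k == cells$n)
  starts <- .criterion_starts(cells)
  span <- diff(range(cells$soa))
  mid <- mean(range(cells$soa))
  lower <- c(mid - 4 * span, log(span / 100), log(span / 100), log(span / 100))
  upper <- c(mid + 4 * span, log(6 * span), log(5 * span), log(5 * span))
  best <- .run_starts(starts, .criterion_negll, .criterion_negll_grad, config,
                      lower = lower, upper = upper,
                      soa = cells$soa, k = cells$k, n = cells$n,
                      eps = config$eps)
  if (is.null(best))
    stop("all optimizer starts failed for the four-parameter model",
         call. = FALSE)
  q <- .criterion_unpack(best$par)
  params <- criterion_params(q$c_low, q$c_high, q$sigma_low, q$sigma_high)
  ll <- -best$value
  structure(
    list(params = params, log_likelihood = ll,
         deviance = sj_deviance(cells, ll),
         converged = best$convergence == 0L && !degenerate,
         n_parameters = 4L, n_starts_used = length(starts), cells = cells),
    class = "sj_fit")
}

# ---- two-parameter model ----------------------------------------------------

.single_negll <- function(theta, soa, k, n, eps) {
  z <- (soa - theta[1L]) / exp(theta[2L])
  p <- pmin(pmax(pnorm(z), eps), 1 - eps)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

.single_negll_grad <- function(theta, soa, k, n, eps) {
  s <- exp(theta[2L])
  z <- (soa - theta[1L]) / s
  p_raw <- pnorm(z)
  clipped <- p_raw < eps | p_raw > 1 - eps
  p <- pmin(pmax(p_raw, eps), 1 - eps)
  dldp <- k / p - (n - k) / (1 - p)
  dldp[clipped] <- 0
  phi <- dnorm(z)
  -c(sum(dldp * (-phi / s)), sum(dldp * (-phi * z)))
}

#' Fit the two-parameter single-CDF model
#'
#' Maximum-likelihood fit of a single cumulative Gaussian over SOA: the
#' simpler model nested (as a limiting case) in the two-criterion model,
#' used as the null of the participant screen.
#'
#' @inheritParams fit_criterion_model
#' @return An `sj_fit` with `params` a [single_cdf_params()] and
#'   `n_parameters = 2`.
#' @export
fit_single_cdf <- function(cells, config = fit_config()) {
  cells <- as_binomial_cells(cells)
  if (length(unique(cells$soa)) < 4L)
    stop("need at least 4 distinct SOA levels", call. = FALSE)
  degenerate <- all(cells$k == 0L) || all(cells$k == cells$n)
  span <- diff(range(cells$soa))
  mid <- mean(range(cells$soa))
  starts <- list()
  for (dc in c(-1 / 3, 0, 1 / 3))
    for (s in c(1 / 4, 1 / 2))
      starts[[length(starts) + 1L]] <- c(mid + dc * span, log(s * span))
  starts[[length(starts) + 1L]] <- c(mid, log(2 * span))
  # probit-regression start: linear fit of qnorm(proportion) on SOA
  prop <- pmin(pmax(cells$k / cells$n, 0.02), 0.98)
  co <- stats::coef(stats::lm(qnorm(prop) ~ cells$soa))
  if (is.finite(co[2L]) && co[2L] > 0)
    starts[[length(starts) + 1L]] <- c(-co[1L] / co[2L], log(1 / co[2L]))
  lower <- c(mid - 5 * span, log(span / 100))
  upper <- c(mid + 5 * span, log(10 * span))
  best <- .run_starts(starts, .single_negll, .single_negll_grad, config,
                      lower = lower, upper = upper,
                      soa = cells$soa, k = cells$k, n = cells$n,
                      eps = config$eps)
  if (is.null(best))
    stop("all optimizer starts failed for the two-parameter model",
         call. = FALSE)
  ll <- -best$value
  structure(
    list(params = single_cdf_params(best$par[1L], exp(best$par[2L])),
         log_likelihood = ll, deviance = sj_deviance(cells, ll),
         converged = best$convergence == 0L && !degenerate,
         n_parameters = 2L, n_starts_used = length(starts), cells = cells),
    class = "sj_fit")
}

#' @export
print.sj_fit <- function(x, ...) {
  cat(sprintf("%d-parameter SJ model fit (%s)\n", x$n_parameters,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  cat(sprintf("  log-likelihood %.4f, deviance %.4f, %d starts\n",
              x$log_likelihood, x$deviance, x$n_starts_used))
  invisible(x)
}

# ---- nested-model screen ----------------------------------------------------

#' Compare the four- and two-parameter fits
#'
#' Deviance difference between the nested fits. A participant's data are
#' considered adequately unimodal when the drop in deviance from the
#' two-parameter to the four-parameter model exceeds the chi-square
#' critical value at 2 degrees of freedom (5.991 at `alpha = 0.05`).
#'
#' @param fit4 Four-parameter `sj_fit`.
#' @param fit2 Two-parameter `sj_fit` on the identical cells.
#' @param alpha Significance level (default 0.05).
#' @return A list: `delta_deviance`, `critical_value`, `passes`, `alpha`.
#' @export
model_comparison <- function(fit4, fit2, alpha = 0.05) {
  if (!inherits(fit4, "sj_fit") || !inherits(fit2, "sj_fit"))
    stop("both arguments must be sj_fit objects", call. = FALSE)
  if (fit4$n_parameters != 4L || fit2$n_parameters != 2L)
    stop("expected a four-parameter and a two-parameter fit", call. = FALSE)
  if (!isTRUE(all.equal(as.data.frame(fit4$cells), as.data.frame(fit2$cells))))
    stop("fits were computed on different cells", call. = FALSE)
  delta <- fit2$deviance - fit4$deviance
  crit <- qchisq(1 - alpha, df = 2)
  list(delta_deviance = delta, critical_value = crit,
       passes = delta > crit, alpha = alpha)
}

#' Screen participants on the nested-model deviance criterion
#'
#' A participant is retained only when the four-parameter model beats the
#' two-parameter model (deviance difference above the 2-df chi-square
#' critical value) in every fitted condition cell. The full audit trail is
#' returned; nothing is dropped silently.
#'
#' @param comparisons Data frame with columns `participant`, `condition`,
#'   optionally `congruency`, and `delta_deviance` (one row per fitted
#'   cell; see [model_comparison()]).
#' @param alpha Significance level (default 0.05).
#' @return A data frame with one row per input cell, plus `critical_value`,
#'   `passes` (cell-level) and `retained` (participant-level, TRUE iff all
#'   of that participant's cells pass).
#' @export
screen_participants <- function(comparisons, alpha = 0.05) {
  req <- c("participant", "condition", "delta_deviance")
  if (!all(req %in% names(comparisons)))
    stop("comparisons must contain columns participant, condition, delta_deviance",
         call. = FALSE)
  crit <- qchisq(1 - alpha, df = 2)
  out <- as.data.frame(comparisons)
  if (nrow(out) == 0L) {
    out$critical_value <- numeric(0)
    out$passes <- logical(0)
    out$retained <- logical(0)
    return(out)
  }
  key <- if ("congruency" %in% names(out))
    interaction(out$condition, out$congruency, drop = TRUE) else out$condition
  tab <- table(out$participant, key)
  if (any(tab != 1L))
    stop("every participant needs exactly one comparison per condition cell",
         call. = FALSE)
  out$critical_value <- crit
  out$passes <- out$delta_deviance > crit
  retained_by <- tapply(out$passes, out$participant, all)
  out$retained <- as.logical(retained_by[as.character(out$participant)])
  rownames(out) <- NULL
  out
}

# ---- scaled-Gaussian re-analysis --------------------------------------------

.gauss_negll <- function(theta, soa, k, n, eps) {
  a <- stats::plogis(theta[1L])
  sd_ <- exp(theta[3L])
  p <- a * exp(-(soa - theta[2L])^2 / (2 * sd_^2))
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

#' Fit a scaled Gaussian to the response proportions
#'
#' Alternative PSS analysis: binomial maximum-likelihood fit of
#' `p(simultaneous) = amplitude * exp(-(soa - mu)^2 / (2 * sd^2))` with
#' `amplitude` constrained to (0, 1]. The location `mu` is reported as the
#' alternative PSS estimate.
#'
#' @param cells A [binomial_cells()] object with at least 3 distinct SOA
#'   levels.
#' @param config A [fit_config()].
#' @return An object of class `scaled_gaussian_fit` with `params` (class
#'   `scaled_gaussian_params`: `amplitude`, `mu`, `sd`), `log_likelihood`,
#'   `deviance`, `converged`, `n_parameters = 3`, `n_starts_used`, `cells`.
#' @export
fit_scaled_gaussian <- function(cells, config = fit_config()) {
  cells <- as_binomial_cells(cells)
  if (length(unique(cells$soa)) < 3L)
    stop("need at least 3 distinct SOA levels", call. = FALSE)
  degenerate <- all(cells$k == 0L) || all(cells$k == cells$n)
  soa <- cells$soa
  span <- diff(range(soa))
  mid <- mean(range(soa))
  mass <- cells$k / cells$n
  mu0 <- if (sum(mass) > 0) sum(soa * mass / sum(mass)) else mid
  starts <- list()
  for (a0 in c(0.7, 0.95))
    for (m0 in unique(c(mu0, mid)))
      for (s0 in c(span / 4, span / 2))
        starts[[length(starts) + 1L]] <- c(stats::qlogis(a0), m0, log(s0))
  lower <- c(stats::qlogis(1e-4), mid - 4 * span, log(span / 100))
  upper <- c(stats::qlogis(1 - 1e-6), mid + 4 * span, log(5 * span))
  best <- .run_starts(starts, .gauss_negll, NULL, config,
                      lower = lower, upper = upper,
                      soa = soa, k = cells$k, n = cells$n, eps = config$eps)
  if (is.null(best))
    stop("all optimizer starts failed for the scaled-Gaussian model",
         call. = FALSE)
  ll <- -best$value
  params <- structure(
    list(amplitude = stats::plogis(best$par[1L]), mu = best$par[2L],
         sd = exp(best$par[3L])),
    class = "scaled_gaussian_params")
  structure(
    list(params = params, log_likelihood = ll,
         deviance = sj_deviance(cells, ll),
         converged = best$convergence == 0L && !degenerate,
         n_parameters = 3L, n_starts_used = length(starts), cells = cells),
    class = "scaled_gaussian_fit")
}
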