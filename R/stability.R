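# Dilution-corrected RT-DNA half-life estimation.
#
# After washing out the inducer, the qPCR fold change of RT-DNA decays by
# two processes: first-order degradation (rate constant k) and dilution by
# cell growth and division. Growth is captured by a logistic fit of the
# OD600 curve; the fold-change model is
#   C(t) = 1 + A * exp(-k t) * OD(t_ref) / OD(t)
# where the OD ratio is the dilution factor and the "+1" floor is the
# plasmid contribution to the inside amplicon (fold change never drops
# below the plasmid-only background). A fitted k indistinguishable from
# zero means the decay is pure dilution: the half-life is beyond the
# assay's detection limit.

# below this rate the half-life exceeds ~11,500 h: beyond detection
K_DETECTION_LIMIT <- 1e-6

#' Logistic growth curve
#'
#' `OD(t) = od_max / (1 + exp(-r * (t - t0)))`: `od_max` is the plateau,
#' `r` the growth rate (1/min) and `t0` the midpoint time (minutes).
#'
#' @param t time(s), minutes (vectorized).
#' @param od_max plateau OD600 (> 0).
#' @param r growth rate, 1/min (> 0).
#' @param t0 midpoint, minutes.
#' @return OD600 value(s).
#' @export
logistic_od <- function(t, od_max, r, t0) {
  if (inherits(od_max, "logistic_fit")) {
    fit <- od_max
    od_max <- fit$od_max; r <- fit$r; t0 <- fit$t0
  }
  assert_number(od_max, "od_max", positive = TRUE)
  assert_number(r, "r", positive = TRUE)
  od_max / (1 + exp(-r * (t - t0)))
}

#' Fit a logistic growth curve to OD600 readings
#'
#' Least-squares fit of (od_max, r, t0) by Levenberg-Marquardt with
#' self-derived starting values; deterministic given the data.
#'
#' @param times sampling times, minutes, strictly increasing (>= 4 points).
#' @param od OD600 readings (> 0).
#' @return a `logistic_fit`: `od_max`, `r`, `t0`, `rss`, `times`, `od`.
#' @export
fit_logistic <- function(times, od) {
  if (is.data.frame(times)) { od <- times$od600; times <- times$time_min }
  if (length(times) < 4L)
    stop("need at least 4 points to fit a logistic curve", call. = FALSE)
  if (length(od) != length(times) || any(diff(times) <= 0) || any(od <= 0))
    stop("times must be strictly increasing and od > 0", call. = FALSE)
  if (stats::sd(od) < 1e-8 * mean(od) || stats::cor(times, od) <= 0)
    stop("degenerate growth curve: no increasing trend to fit",
         call. = FALSE)
  od_max0 <- max(od) * 1.05
  frac <- pmin(pmax(od / od_max0, 1e-6), 1 - 1e-6)
  lin <- stats::lm(stats::qlogis(frac) ~ times)
  r0 <- max(unname(stats::coef(lin)[2]), 1e-4)
  t0_0 <- -unname(stats::coef(lin)[1]) / r0
  fit <- minpack.lm::nls.lm(
    par = c(od_max0, r0, t0_0),
    lower = c(max(od) * 0.5, 1e-6, -Inf), upper = c(Inf, Inf, Inf),
    fn = function(p) od - logistic_od(times, p[1], p[2], p[3]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  structure(list(od_max = fit$par[1], r = fit$par[2], t0 = fit$par[3],
                 rss = fit$deviance, times = times, od = od),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic growth: OD_max = %.4g, r = %.4g /min, t0 = %.4g min (rss %.3g)\n",
    x$od_max, x$r, x$t0, x$rss))
  invisible(x)
}

#' Dilution-corrected decay model for RT-DNA fold change
#'
#' `C(t) = 1 + A * exp(-k t) * OD(t_ref) / OD(t)`. With `k = 0` the decrease
#' is pure growth dilution; C is always >= 1 (plasmid background floor).
#'
#' @param t time(s), minutes.
#' @param a amplitude (fold change above background at `t = 0` with no
#'   dilution); >= 0.
#' @param k degradation rate constant, 1/min (>= 0).
#' @param logistic a `logistic_fit` describing the culture's growth.
#' @param t_ref reference time (minutes) of the dilution ratio, normally the
#'   first sampling time of the decay series. Distinct from the logistic
#'   midpoint `t0`.
#' @return fold-change value(s).
#' @export
decay_curve <- function(t, a, k, logistic, t_ref) {
  assert_number(a, "a", nonneg = TRUE)
  assert_number(k, "k", nonneg = TRUE)
  stopifnot(inherits(logistic, "logistic_fit"))
  od_ref <- logistic_od(t_ref, logistic)
  1 + a * exp(-k * t) * od_ref / logistic_od(t, logistic)
}

new_decay_fit <- function(a, k, rss, k_fixed, t_ref) {
  structure(list(a = a, k = k, half_life = half_life(k), rss = rss,
                 k_fixed = k_fixed, t_ref = t_ref), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  hl <- if (is.infinite(x$half_life)) "beyond detection limit (Inf)" else
    sprintf("%.4g min", x$half_life)
  cat(sprintf("decay fit%s: A = %.4g, k = %.4g /min, half-life %s, rss %.3g\n",
              if (x$k_fixed) " (k fixed)" else "", x$a, x$k, hl, x$rss))
  invisible(x)
}

#' Fit the dilution-corrected decay model to a fold-change time series
#'
#' Least squares over `(A, k)` with `k` bounded in `k_bounds`; started from a
#' small grid of fixed k values to avoid local minima, best residual wins.
#' A fitted `k` below the detection threshold (1e-6/min) yields an infinite
#' half-life ("beyond the detection limit").
#'
#' @param times sampling times, minutes, strictly increasing (>= 3 points);
#'   or a data.frame with `time_min`, `fold_change`.
#' @param fold_change fold-change values (> 0).
#' @param logistic a `logistic_fit` on a matching time base.
#' @param k_bounds lower/upper bounds for k, 1/min (default `c(0, 1)`).
#' @param t_ref reference time for the dilution ratio (default first
#'   sampling time).
#' @return a `decay_fit`: `a`, `k`, `half_life` (minutes, possibly `Inf`),
#'   `rss`, `k_fixed = FALSE`, `t_ref`.
#' @export
fit_decay <- function(times, fold_change = NULL, logistic,
                      k_bounds = c(0, 1), t_ref = NULL) {
  if (is.data.frame(times)) {
    fold_change <- times$fold_change; times <- times$time_min
  }
  if (length(times) < 3L)
    stop("need at least 3 points to fit the decay model", call. = FALSE)
  if (length(fold_change) != length(times) || any(diff(times) <= 0) ||
      any(fold_change <= 0))
    stop("times must be strictly increasing and fold_change > 0",
         call. = FALSE)
  stopifnot(inherits(logistic, "logistic_fit"))
  t_ref <- t_ref %||% times[1]
  a0 <- max(fold_change[1] - 1, 1e-3)
  best <- NULL
  for (k0 in c(1e-4, log(2) / 30, 0.1)) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = c(a0, min(max(k0, k_bounds[1]), k_bounds[2])),
      lower = c(0, k_bounds[1]), upper = c(Inf, k_bounds[2]),
      fn = function(p) fold_change - decay_curve(times, p[1], p[2],
                                                 logistic, t_ref),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance - 1e-12) best <- fit
  }
  if (is.null(best)) stop("decay fit failed to converge", call. = FALSE)
  new_decay_fit(best$par[1], best$par[2], best$deviance, FALSE, t_ref)
}

#' Refit the decay model with a fixed half-life
#'
#' Fixes `k = ln(2) / half_life_min` (or 0 for an infinite half-life) and
#' fits the amplitude A alone, which is linear and solved in closed form
#' (clamped at A >= 0). The residual sum of squares is reported for model
#' comparison against the free fit.
#'
#' @param times,fold_change,logistic,t_ref as in [fit_decay()].
#' @param half_life_min imposed half-life, minutes (> 0, may be `Inf`).
#' @return a `decay_fit` with `k_fixed = TRUE`.
#' @export
fixed_k_refit <- function(times, fold_change = NULL, logistic,
                          half_life_min, t_ref = NULL) {
  if (is.data.frame(times)) {
    fold_change <- times$fold_change; times <- times$time_min
  }
  if (half_life_min <= 0)
    stop("`half_life_min` must be > 0", call. = FALSE)
  stopifnot(inherits(logistic, "logistic_fit"))
  t_ref <- t_ref %||% times[1]
  k <- if (is.infinite(half_life_min)) 0 else log(2) / half_life_min
  g <- exp(-k * times) * logistic_od(t_ref, logistic) /
    logistic_od(times, logistic)
  a <- max(sum(g * (fold_change - 1)) / sum(g^2), 0)
  rss <- sum((fold_change - (1 + a * g))^2)
  new_decay_fit(a, k, rss, TRUE, t_ref)
}

#' Half-life from a first-order rate constant
#'
#' @param k degradation rate constant, 1/min (>= 0).
#' @return `ln(2) / k` in minutes; `Inf` when `k` is below the detection
#'   threshold of 1e-6/min.
#' @export
half_life <- function(k) {
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  if (k < K_DETECTION_LIMIT) Inf else log(2) / k
}
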