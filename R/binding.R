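# Global equilibrium binding fits of fluorogen titrations.
#
# A fluorogenic aptamer at total concentration At binds its fluorogen
# (total Bt) with dissociation constant Kd; when Kd is comparable to the
# reagent concentrations, ligand depletion matters and the bound fraction is
# the root of a quadratic in the complex concentration (the tight-binding
# isotherm). Titration series of different constructs measured against the
# same fluorogen stock share the plateaus C0/C1 and the stock concentration
# Bt; Bt is fitted under a tight box to absorb stock-concentration error.

#' Quadratic tight-binding isotherm
#'
#' `F = C1 * ((At + Bt + Kd) - sqrt((At + Bt + Kd)^2 - 4 At Bt)) / (2 Bt)
#'  + C0`. The radicand is clamped at zero to absorb floating-point
#' negatives at the saturation boundary. Continuous and non-decreasing in
#' `at`; `F(0) = C0`; `F -> C0 + C1` as `at -> Inf`.
#'
#' @param at total DNA concentration(s), uM (vectorized).
#' @param c0 lower fluorescence plateau (arbitrary units).
#' @param c1 fluorescence amplitude (upper plateau minus lower; >= 0).
#' @param bt total fluorogen concentration, uM (> 0).
#' @param kd dissociation constant, uM (>= 0).
#' @return fluorescence, same length as `at`.
#' @examples
#' isotherm(1, c0 = 0, c1 = 100, bt = 1, kd = 1)  # 100 * (3 - sqrt(5)) / 2
#' @export
isotherm <- function(at, c0, c1, bt, kd) {
  assert_number(at, "at", nonneg = TRUE)
  assert_number(bt, "bt", positive = TRUE)
  assert_number(kd, "kd", nonneg = TRUE)
  s <- at + bt + kd
  rad <- pmax(s^2 - 4 * at * bt, 0)
  c1 * (s - sqrt(rad)) / (2 * bt) + c0
}

# shared parameter vector layout: c0, c1, bt, log10(kd) per series
global_residuals <- function(theta, split_data) {
  c0 <- theta[1]; c1 <- theta[2]; bt <- theta[3]
  unlist(lapply(seq_along(split_data), function(s) {
    d <- split_data[[s]]
    d$fluorescence - isotherm(d$at_uM, c0, c1, bt, 10^theta[3 + s])
  }), use.names = FALSE)
}

split_series <- function(series) {
  need <- c("construct", "at_uM", "fluorescence")
  stopifnot(is.data.frame(series), all(need %in% names(series)))
  split(series, factor(series$construct, levels = unique(series$construct)))
}

#' Globally fit the tight-binding isotherm to one or more titration series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) over shared
#' `C0`, `C1`, `Bt` and one `Kd` per series, with `Bt` constrained to
#' `bt_nominal * (1 +/- bt_box)` and `Kd` fitted on a log10 scale. Because
#' the isotherm is weakly identifiable when `Kd` far exceeds the titrated
#' range, the fit is multi-started with `Kd` drawn log-uniformly from
#' 0.01-100 uM; the start with the lowest residual sum of squares wins
#' (ties go to the earliest start). Deterministic given `seed`.
#'
#' @param series data.frame with columns `construct`, `bt_nominal_uM`,
#'   `at_uM`, `fluorescence`; every construct needs >= 4 points and a
#'   consistent `bt_nominal_uM`.
#' @param bt_box relative half-width of the Bt constraint box (default 0.2).
#' @param n_starts number of multi-starts (default 8).
#' @param seed RNG seed for the starts.
#' @return a `binding_fit`: `shared` (named c0/c1/bt estimates), `per_series`
#'   (data.frame: construct, kd_uM, ci_low, ci_high — CIs are `NA` until
#'   [bootstrap_ci()] is run), `rss`, `n_points`, `flags` (per-series
#'   `kd_unidentifiable` when the fitted amplitude is negligible), plus the
#'   data and internals needed for bootstrapping.
#' @export
fit_global <- function(series, bt_box = 0.2, n_starts = 8L, seed = 1L) {
  sp <- split_series(series)
  m <- length(sp)
  npts <- vapply(sp, nrow, integer(1))
  if (any(npts < 4L))
    stop("every titration series needs at least 4 points", call. = FALSE)
  bt_nom <- unique(series$bt_nominal_uM)
  if (length(bt_nom) != 1L)
    stop("`bt_nominal_uM` must be consistent across series", call. = FALSE)
  assert_number(bt_nom, "bt_nominal_uM", positive = TRUE)
  n_total <- sum(npts)
  if (n_total <= 3L + m)
    stop("fewer data points than free parameters", call. = FALSE)

  f <- series$fluorescence
  lower <- c(-Inf, 0, bt_nom * (1 - bt_box), rep(-4, m))
  upper <- c(Inf, Inf, bt_nom * (1 + bt_box), rep(4, m))
  kd_starts <- with_seed(seed,
    matrix(stats::runif(n_starts * m, log10(0.01), log10(100)),
           nrow = n_starts))

  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- c(min(f), max(f) - min(f), bt_nom, kd_starts[s, ])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = global_residuals, split_data = sp,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance - 1e-12) best <- fit
  }
  if (is.null(best))
    stop("global isotherm fit failed to converge from any start",
         call. = FALSE)

  theta <- best$par
  kd <- 10^theta[3 + seq_len(m)]
  # with a negligible amplitude the isotherm is flat and Kd means nothing
  amp_floor <- 1e-6 * max(abs(f), 1)
  flags <- rep(theta[2] < amp_floor, m)
  per <- data.frame(construct = names(sp), kd_uM = kd, ci_low = NA_real_,
                    ci_high = NA_real_, kd_unidentifiable = flags,
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  structure(list(
    shared = c(c0 = theta[1], c1 = theta[2], bt = theta[3]),
    shared_ci = NULL,
    per_series = per,
    rss = best$deviance,
    n_points = n_total,
    bt_nominal = bt_nom, bt_box = bt_box,
    data = series, theta = theta, lower = lower, upper = upper),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("global isotherm fit: %d series, %d points, rss %.4g\n",
              nrow(x$per_series), x$n_points, x$rss))
  cat(sprintf("  shared: C0 = %.4g, C1 = %.4g, Bt = %.4g uM (box %g%%)\n",
              x$shared["c0"], x$shared["c1"], x$shared["bt"],
              100 * x$bt_box))
  for (i in seq_len(nrow(x$per_series))) {
    p <- x$per_series[i, ]
    ci <- if (is.na(p$ci_low)) "" else
      sprintf(" (95%% CI %.3g, %.3g)", p$ci_low, p$ci_high)
    cat(sprintf("  %s: Kd = %.4g uM%s%s\n", p$construct, p$kd_uM, ci,
                if (p$kd_unidentifiable) " [unidentifiable]" else ""))
  }
  invisible(x)
}

#' Predicted fluorescence from a binding fit
#'
#' @param object a `binding_fit`.
#' @param ... unused.
#' @return fitted fluorescence for every row of the fitted data.
#' @export
fitted.binding_fit <- function(object, ...) {
  sp <- split_series(object$data)
  th <- object$theta
  unlist(lapply(seq_along(sp), function(s)
    isotherm(sp[[s]]$at_uM, th[1], th[2], th[3], 10^th[3 + s])),
    use.names = FALSE)
}

#' Residual-resampling bootstrap confidence intervals for a binding fit
#'
#' Resamples the fit residuals with replacement onto the fitted curve,
#' refits each pseudo-dataset (starting from the point estimate), and takes
#' percentile intervals. Reproducible under `seed`.
#'
#' @param fit a `binding_fit` from [fit_global()].
#' @param B number of bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return the fit, with `per_series$ci_low`/`ci_high` filled in and
#'   `shared_ci` set to a 2-row matrix of interval bounds for c0/c1/bt.
#' @export
bootstrap_ci <- function(fit, B = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "binding_fit"))
  if (B < 100L) stop("`B` must be >= 100", call. = FALSE)
  sp0 <- split_series(fit$data)
  fhat <- fitted(fit)
  # fitted() returns values in series order; rebuild in that order
  ord_data <- do.call(rbind, sp0)
  resid <- ord_data$fluorescence - fhat
  m <- nrow(fit$per_series)
  draws <- with_seed(seed,
    matrix(sample.int(length(resid), length(resid) * B, replace = TRUE),
           ncol = B))
  boot <- matrix(NA_real_, nrow = B, ncol = 3L + m)
  for (b in seq_len(B)) {
    fb <- fhat + resid[draws[, b]]
    spb <- sp0
    off <- 0L
    for (s in seq_along(spb)) {
      nb <- nrow(spb[[s]])
      spb[[s]]$fluorescence <- fb[off + seq_len(nb)]
      off <- off + nb
    }
    rb <- tryCatch(
      minpack.lm::nls.lm(par = fit$theta, lower = fit$lower,
                         upper = fit$upper, fn = global_residuals,
                         split_data = spb,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(rb)) boot[b, ] <- rb$par
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  a <- (1 - level) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  fit$shared_ci <- qs[, 1:3, drop = FALSE]
  colnames(fit$shared_ci) <- c("c0", "c1", "bt")
  rownames(fit$shared_ci) <- c("low", "high")
  fit$per_series$ci_low <- 10^qs[1, 3 + seq_len(m)]
  fit$per_series$ci_high <- 10^qs[2, 3 + seq_len(m)]
  fit$bootstrap <- list(B = B, used = nrow(boot), seed = seed, level = level)
  fit
}
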