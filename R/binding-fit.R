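# Normalization of competition/binding readouts and least-squares fitting
# of Hill-type and cooperative Michaelis-Menten models to
# concentration-response curves.

#' Hill inhibition model
#'
#' `R(x) = R_max - (R_max - R_min) * x^h / (K^h + x^h)`: response falls
#' from `R_max` to `R_min` with half-maximal inhibition at `x = K`.
#'
#' @param x concentration (same unit as `K`).
#' @param K half-maximal inhibitory concentration.
#' @param h Hill coefficient.
#' @param R_max,R_min upper and lower plateaus.
#' @return Model response.
#' @export
hill_inhibition <- function(x, K, h, R_max, R_min) {
  R_max - (R_max - R_min) * x^h / (K^h + x^h)
}

#' Hill activation model
#'
#' `R(x) = R_min + (R_max - R_min) * x^h / (K^h + x^h)`.
#'
#' @inheritParams hill_inhibition
#' @export
hill_activation <- function(x, K, h, R_max, R_min) {
  R_min + (R_max - R_min) * x^h / (K^h + x^h)
}

#' Cooperative Michaelis-Menten model
#'
#' `v(x) = V_max * x^n / (K^n + x^n)`: enzyme activity rising from zero
#' to `V_max`, half-maximal at the activator concentration `K`, with
#' cooperativity exponent `n`.
#'
#' @param x activator concentration.
#' @param K half-maximal activating concentration.
#' @param n cooperativity exponent.
#' @param V_max maximal activity.
#' @export
coop_mm <- function(x, K, n, V_max) {
  V_max * x^n / (K^n + x^n)
}

#' Normalize emission readouts against an untreated control
#'
#' @param treated,untreated emission counts (untreated must be positive).
#' @return List with `ratio` (treated/untreated) and `log2_ratio`.
#' @export
normalize_emission <- function(treated, untreated) {
  if (any(untreated <= 0)) stopf("untreated emission must be > 0")
  ratio <- treated / untreated
  list(ratio = ratio, log2_ratio = log2(ratio))
}

#' @noRd
validate_curve <- function(curve, min_points) {
  if (!all(c("x", "y") %in% names(curve)))
    stopf("curve needs columns x and y")
  if (any(!is.finite(curve$x)) || any(curve$x <= 0))
    stopf("concentrations must be finite and strictly positive")
  if (length(curve$x) != length(curve$y))
    stopf("x and y lengths differ")
  if (nrow(curve) < min_points)
    stopf("need at least %d points for fitting", min_points)
  curve[order(curve$x), , drop = FALSE]
}

# Multi-start bounded Levenberg-Marquardt driver shared by all models.
# `predict_fn(pars, x)` evaluates the model at a named parameter vector.
# nls.lm is driven directly on the residual function: formula-based nls
# front-ends reject exact zero-residual optima ("singular gradient"),
# which noiseless round-trips legitimately reach.
#' @noRd
fit_multistart <- function(curve, predict_fn, starts, lower, upper,
                           weights = NULL) {
  sw <- if (is.null(weights)) rep(1, nrow(curve)) else sqrt(weights)
  resid_fn <- function(p) sw * (curve$y - predict_fn(p, curve$x))
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  for (st in starts) {
    p0 <- unlist(st)
    out <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(par = p0, fn = resid_fn,
                                          lower = lower[names(p0)],
                                          upper = upper[names(p0)],
                                          control = ctrl)),
      error = function(e) NULL)
    if (is.null(out)) next
    rss <- out$deviance
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(par = out$par, rss = rss, hessian = out$hessian,
                   fitted = predict_fn(out$par, curve$x))
  }
  best
}

# back-transform the internal log-K parameter (`lK`) to the reported
# concentration scale; SE by the delta method
#' @noRd
make_fit_result <- function(model, best, curve, amplitude_ok,
                            k_name = "K") {
  if (is.null(best)) {
    return(structure(list(model = model, estimate = NULL, se = NULL,
                          rss = NA_real_, converged = FALSE,
                          n_points = nrow(curve)),
                     class = "cam_fit"))
  }
  est <- best$par
  dof <- max(1, nrow(curve) - length(est))
  se <- tryCatch(
    stats::setNames(sqrt(diag(solve(best$hessian)) * best$rss / dof),
                    names(est)),
    error = function(e)
      stats::setNames(rep(NA_real_, length(est)), names(est)))
  if ("lK" %in% names(est)) {
    K <- exp(est[["lK"]])
    est <- c(stats::setNames(K, k_name), est[names(est) != "lK"])
    se <- c(stats::setNames(K * se[["lK"]], k_name),
            se[names(se) != "lK"])
  }
  structure(list(model = model, estimate = est, se = se, rss = best$rss,
                 converged = amplitude_ok(est), n_points = nrow(curve),
                 fitted = best$fitted),
            class = "cam_fit")
}

#' @export
print.cam_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s), RSS = %s\n", x$model,
              if (x$converged) "converged" else "NOT converged",
              format(x$rss, digits = 4)))
  if (!is.null(x$estimate)) {
    tab <- data.frame(estimate = x$estimate, se = x$se)
    print(tab, digits = 4)
  }
  invisible(x)
}

#' @noRd
default_starts <- function(curve, h_grid = c(0.5, 1, 2, 4), extra = NULL) {
  ks <- seq(log(min(curve$x)), log(max(curve$x)), length.out = 5)
  starts <- list()
  for (k in ks) for (h in h_grid)
    starts[[length(starts) + 1]] <- c(list(lK = k, h = h), extra)
  lapply(starts, function(s) lapply(s, as.numeric))
}

#' Fit the Hill inhibition model to a competition curve
#'
#' Unweighted iterative least squares (optionally weighted by `1/y_err^2`)
#' with a multi-start strategy: log-spaced half-maximal concentrations
#' crossed with Hill coefficients 0.5, 1, 2 and 4. The half-maximal
#' concentration is fitted on the log scale (well-scaled gradients over
#' decades of concentration) and reported as `K` with a delta-method
#' standard error; `K` is bounded to `[x_min/100, x_max*100]` and `h` to
#' `(0, 10]`. Standard errors come from the Jacobian-based covariance of
#' the best fit. The fit is flagged
#' unconverged when no start converges or the fitted amplitude
#' `R_max - R_min` is not positive (model/direction mismatch).
#'
#' @param curve data frame with columns `x` (concentration, ascending,
#'   positive) and `y` (response); optional `y_err`.
#' @param fix_h optional fixed Hill coefficient (e.g. 1); default floats h.
#' @param weighted use `1/y_err^2` weights when `y_err` is present.
#' @return A `cam_fit`: `model`, `estimate` (`K`, `h`, `R_max`, `R_min`),
#'   `se`, `rss`, `converged`, `n_points`.
#' @export
fit_hill_inhibition <- function(curve, fix_h = NULL, weighted = FALSE) {
  curve <- validate_curve(curve, 4)
  lo <- c(lK = log(min(curve$x) / 100), h = 1e-2,
          R_max = -Inf, R_min = -Inf)
  hi <- c(lK = log(max(curve$x) * 100), h = 10, R_max = Inf, R_min = Inf)
  extra <- list(R_max = max(curve$y), R_min = min(curve$y))
  starts <- default_starts(curve, extra = extra)
  if (!is.null(fix_h)) {
    starts <- unique(lapply(starts, function(s) { s$h <- NULL; s }))
    lo <- lo[c("lK", "R_max", "R_min")]
    hi <- hi[c("lK", "R_max", "R_min")]
    pf <- function(p, x) hill_inhibition(x, exp(p[["lK"]]), fix_h,
                                         p[["R_max"]], p[["R_min"]])
  } else {
    pf <- function(p, x) hill_inhibition(x, exp(p[["lK"]]), p[["h"]],
                                         p[["R_max"]], p[["R_min"]])
  }
  w <- if (weighted && !is.null(curve$y_err)) 1 / curve$y_err^2 else NULL
  best <- fit_multistart(curve, pf, starts, lo, hi, w)
  make_fit_result("hill_inhibition", best, curve,
                  function(est) est[["R_max"]] > est[["R_min"]])
}

#' Fit the Hill activation model to a binding or response curve
#'
#' Same fitting strategy as [fit_hill_inhibition()]; the reported `K` is
#' the half-maximal activating concentration (e.g. Ca50 for free-Ca2+
#' titrations) and `h` the Hill coefficient.
#'
#' @inheritParams fit_hill_inhibition
#' @return A `cam_fit` with `estimate` (`K`, `h`, `R_max`, `R_min`).
#' @export
fit_hill_activation <- function(curve, fix_h = NULL, weighted = FALSE) {
  curve <- validate_curve(curve, 4)
  lo <- c(lK = log(min(curve$x) / 100), h = 1e-2,
          R_max = -Inf, R_min = -Inf)
  hi <- c(lK = log(max(curve$x) * 100), h = 10, R_max = Inf, R_min = Inf)
  extra <- list(R_max = max(curve$y), R_min = min(curve$y))
  starts <- default_starts(curve, extra = extra)
  if (!is.null(fix_h)) {
    starts <- unique(lapply(starts, function(s) { s$h <- NULL; s }))
    lo <- lo[c("lK", "R_max", "R_min")]
    hi <- hi[c("lK", "R_max", "R_min")]
    pf <- function(p, x) hill_activation(x, exp(p[["lK"]]), fix_h,
                                         p[["R_max"]], p[["R_min"]])
  } else {
    pf <- function(p, x) hill_activation(x, exp(p[["lK"]]), p[["h"]],
                                         p[["R_max"]], p[["R_min"]])
  }
  w <- if (weighted && !is.null(curve$y_err)) 1 / curve$y_err^2 else NULL
  best <- fit_multistart(curve, pf, starts, lo, hi, w)
  make_fit_result("hill_activation", best, curve,
                  function(est) est[["R_max"]] > est[["R_min"]])
}

#' Fit the cooperative Michaelis-Menten model to an activity curve
#'
#' @inheritParams fit_hill_inhibition
#' @return A `cam_fit` with `estimate` (`K`, `n`, `V_max`).
#' @export
fit_coop_mm <- function(curve, weighted = FALSE) {
  curve <- validate_curve(curve, 5)
  lo <- c(lK = log(min(curve$x) / 100), n = 1e-2, V_max = -Inf)
  hi <- c(lK = log(max(curve$x) * 100), n = 10, V_max = Inf)
  ks <- seq(log(min(curve$x)), log(max(curve$x)), length.out = 5)
  starts <- list()
  for (k in ks) for (n0 in c(0.5, 1, 2, 4))
    starts[[length(starts) + 1]] <- list(lK = k, n = n0,
                                         V_max = max(curve$y))
  w <- if (weighted && !is.null(curve$y_err)) 1 / curve$y_err^2 else NULL
  pf <- function(p, x) coop_mm(x, exp(p[["lK"]]), p[["n"]], p[["V_max"]])
  best <- fit_multistart(curve, pf, starts, lo, hi, w)
  make_fit_result("coop_mm", best, curve,
                  function(est) est[["V_max"]] > 0)
}
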