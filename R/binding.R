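## Fluorescence-quenching analysis. Two linearised models:
##   Stern-Volmer:       F0/F = 1 + Ksv [Q]
##   double-logarithmic: log10(F0/F - 1) = log10(Ka) + n log10([Q])
## Both are fitted by ordinary least squares on the linearised form, the
## standard treatment of steady-state quenching titrations.

# Coefficient of determination without summary.lm's perfect-fit warning;
# a zero-variance response fitted exactly counts as r2 = 1.
r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  if (ss_tot == 0) return(if (ss_res <= .Machine$double.eps) 1 else 0)
  min(max(1 - ss_res / ss_tot, 0), 1)
}

#' Construct a fluorescence titration series
#'
#' @param f0 Quencher-free fluorescence intensity (a.u.), positive.
#' @param q Quencher concentrations (mol/L), strictly increasing,
#'   nonnegative, length >= 3.
#' @param f Fluorescence intensities (a.u.) at each concentration, positive,
#'   same length as `q`.
#' @return A list of class `titration_series` with elements `f0`, `q`, `f`.
#' @seealso [stern_volmer_fit()], [double_log_fit()], [gen_titration()]
#' @export
titration_series <- function(f0, q, f) {
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0) {
    stop_input("f0 must be a single positive number")
  }
  if (length(q) != length(f)) stop_input("q and f must have the same length")
  if (length(q) < 3L) stop_input("titration needs at least 3 points")
  if (any(q < 0)) stop_input("q must be nonnegative")
  if (any(diff(q) <= 0)) stop_input("q must be strictly increasing")
  if (any(!is.finite(f)) || any(f <= 0)) stop_input("f must be strictly positive")
  structure(list(f0 = f0, q = as.numeric(q), f = as.numeric(f)),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat("Fluorescence titration:", length(x$q), "points, F0 =", x$f0, "\n")
  cat("[Q] from", format(min(x$q)), "to", format(max(x$q)), "mol/L\n")
  invisible(x)
}

#' Predicted Stern-Volmer quenching ratio
#'
#' The ratio `F0/F = 1 + Ksv [Q]` implied by dynamic (collisional)
#' quenching with constant `ksv`.
#'
#' @param ksv Stern-Volmer constant (L/mol), nonnegative.
#' @param q Quencher concentration(s) (mol/L), nonnegative.
#' @return Numeric vector of dimensionless F0/F ratios.
#' @examples
#' predict_quench(7.6e6, 1e-6)  # 8.6
#' @export
predict_quench <- function(ksv, q) {
  if (any(ksv < 0)) stop_input("ksv must be nonnegative")
  if (any(q < 0)) stop_input("q must be nonnegative")
  1 + ksv * q
}

#' Fit the Stern-Volmer quenching model
#'
#' Ordinary least squares of `y = F0/F` against `x = [Q]` with a free
#' intercept; the slope is the Stern-Volmer constant Ksv (L/mol). The
#' intercept is reported rather than forced to 1 so departures from the
#' ideal model (baseline drift, inner-filter effects — no inner-filter
#' correction is applied) are visible: on ideal data it is 1.
#'
#' @param series A [titration_series()].
#' @return An object of class `quenching_fit` with elements `ksv`,
#'   `intercept`, `r2`, `n_points` and the underlying `lm` fit. `coef()`
#'   returns `(intercept, ksv)`; `predict()` returns fitted F0/F at new
#'   concentrations; `residuals()` returns OLS residuals.
#' @examples
#' ser <- gen_titration(titration_design(noise_cv = 0), "stern_volmer", seed = 1)
#' stern_volmer_fit(ser)
#' @export
stern_volmer_fit <- function(series) {
  if (!inherits(series, "titration_series")) {
    stop_input("series must be a titration_series")
  }
  if (length(series$q) < 3L) stop_input("need at least 3 points to fit")
  if (stats::var(series$q) == 0) stop_input("zero variance in q: cannot fit a slope")
  y <- series$f0 / series$f
  fit <- stats::lm(y ~ q, data = data.frame(q = series$q, y = y))
  structure(list(
    ksv = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = r_squared(fit, y),
    n_points = length(series$q),
    lm = fit, series = series
  ), class = "quenching_fit")
}

#' @export
coef.quenching_fit <- function(object, ...) {
  c(intercept = object$intercept, ksv = object$ksv)
}

#' @export
predict.quenching_fit <- function(object, q = object$series$q, ...) {
  object$intercept + object$ksv * q
}

#' @export
residuals.quenching_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
print.quenching_fit <- function(x, ...) {
  cat("Stern-Volmer fit (", x$n_points, " points)\n", sep = "")
  cat("  Ksv       =", format(x$ksv, digits = 6), "L/mol\n")
  cat("  intercept =", format(x$intercept, digits = 6),
      "(1 under ideal quenching)\n")
  cat("  R^2       =", format(x$r2, digits = 6), "\n")
  invisible(x)
}

#' Fit the double-logarithmic binding model
#'
#' Ordinary least squares of `log10(F0/F - 1)` on `log10([Q])`: the
#' intercept estimates `log10(Ka)` and the slope the number of binding
#' sites `n`. Points with `F0/F - 1 <= 0` (no measurable quenching, outside
#' the log domain) or `[Q] = 0` are excluded, counted, and reported — never
#' dropped silently.
#'
#' @param series A [titration_series()].
#' @return An object of class `binding_fit` with elements `lg_ka`, `ka`
#'   (`= 10^lg_ka`), `n_sites`, `r2`, `n_points_used`, `excluded` (indices)
#'   and the underlying `lm`. `coef()` returns `(lg_ka, n_sites)`.
#' @examples
#' des <- titration_design(ka_true = 1.43e6, n_true = 1, noise_cv = 0)
#' double_log_fit(gen_titration(des, "binding_site", seed = 1))
#' @export
double_log_fit <- function(series) {
  if (!inherits(series, "titration_series")) {
    stop_input("series must be a titration_series")
  }
  ratio <- series$f0 / series$f - 1
  usable <- ratio > 0 & series$q > 0
  excluded <- which(!usable)
  if (sum(usable) < 3L) {
    stop_input("fewer than 3 usable points after excluding indices {%s} (F0/F - 1 <= 0 or q = 0)",
               paste(excluded, collapse = ", "))
  }
  lx <- log10(series$q[usable])
  ly <- log10(ratio[usable])
  if (stats::var(lx) == 0) stop_input("zero variance in log10(q): cannot fit a slope")
  fit <- stats::lm(ly ~ lx, data = data.frame(lx = lx, ly = ly))
  lg_ka <- unname(stats::coef(fit)[1L])
  structure(list(
    lg_ka = lg_ka,
    ka = 10^lg_ka,
    n_sites = unname(stats::coef(fit)[2L]),
    r2 = r_squared(fit, ly),
    n_points_used = sum(usable),
    excluded = excluded,
    lm = fit, series = series
  ), class = "binding_fit")
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(lg_ka = object$lg_ka, n_sites = object$n_sites)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Double-logarithmic binding fit (", x$n_points_used, " of ",
      x$n_points_used + length(x$excluded), " points used)\n", sep = "")
  cat("  Ka      =", format(x$ka, digits = 6), "L/mol  (lgKa =",
      format(x$lg_ka, digits = 6), ")\n")
  cat("  n sites =", format(x$n_sites, digits = 6), "\n")
  cat("  R^2     =", format(x$r2, digits = 6), "\n")
  if (length(x$excluded)) {
    cat("  excluded point indices:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
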