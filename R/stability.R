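## Environmental-stability sweeps: particle size (or count rate) tracked
## across temperature ramps, pH series, storage days or freeze-thaw cycles.
## The summaries are deliberately simple — endpoint change and full
## max-minus-min range — because both readings of "the size changed by X nm"
## occur in practice; they are reported side by side.

#' Construct a stability sweep series
#'
#' @param x Swept variable values, strictly monotone (increasing or
#'   decreasing, so heating and cooling ramps both qualify), length >= 2.
#' @param y Positive responses (nm for Z-average, kcps for count rate),
#'   same length as `x`.
#' @param axis One of `"temperature_C"`, `"pH"`, `"day"`.
#' @param ylabel Response label, e.g. `"z_ave_nm"`.
#' @param label Optional system label (e.g. which colloid the sweep
#'   belongs to), used by [compare_sweeps()].
#' @return A list of class `sweep_series`.
#' @export
sweep_series <- function(x, y, axis = c("temperature_C", "pH", "day"),
                         ylabel = "z_ave_nm", label = NULL) {
  axis <- match.arg(axis)
  if (length(x) != length(y)) stop_input("x and y must have the same length")
  if (length(x) < 2L) stop_input("sweep needs at least 2 points")
  d <- diff(x)
  if (!(all(d > 0) || all(d < 0))) stop_input("x must be strictly monotone")
  if (any(!is.finite(y)) || any(y <= 0)) stop_input("y must be strictly positive")
  structure(list(axis = axis, x = as.numeric(x), y = as.numeric(y),
                 ylabel = ylabel, label = label),
            class = "sweep_series")
}

#' @export
print.sweep_series <- function(x, ...) {
  cat("Stability sweep", if (!is.null(x$label)) paste0("'", x$label, "'") else "",
      "over", x$axis, "(", length(x$x), "points ),", x$ylabel, "\n")
  cat("  x:", format(x$x[1L]), "->", format(x$x[length(x$x)]),
      "  y range:", format(min(x$y)), "-", format(max(x$y)), "\n")
  invisible(x)
}

#' Delta and range metrics of a stability sweep
#'
#' Summarises how much the response moved across the sweep:
#' `endpoint_delta = |y_last - y_first|` and `range = max(y) - min(y)`,
#' together with the extreme values and the x positions where they occur.
#' `range >= endpoint_delta` always, and both are invariant under
#' reversing the sweep direction.
#'
#' @param series A [sweep_series()].
#' @return A list with elements `endpoint_delta`, `range`, `min`, `max`,
#'   `argmin_x`, `argmax_x`.
#' @examples
#' s <- sweep_series(x = c(10, 40, 70), y = c(300, 320, 338))
#' sweep_delta(s)$endpoint_delta  # 38
#' @export
sweep_delta <- function(series) {
  if (!inherits(series, "sweep_series")) stop_input("series must be a sweep_series")
  y <- series$y
  list(
    endpoint_delta = abs(y[length(y)] - y[1L]),
    range = max(y) - min(y),
    min = min(y),
    max = max(y),
    argmin_x = series$x[which.min(y)],
    argmax_x = series$x[which.max(y)]
  )
}

#' Response window over a pH sweep
#'
#' The minimum, maximum and span (`max - min`) of the response across a pH
#' series; errors on any other axis so temperature or storage sweeps are
#' not summarised under the wrong heading.
#'
#' @param series A [sweep_series()] with `axis = "pH"`.
#' @return A list with elements `y_min`, `y_max`, `span`.
#' @export
ph_window <- function(series) {
  if (!inherits(series, "sweep_series")) stop_input("series must be a sweep_series")
  if (series$axis != "pH") {
    stop_input("ph_window requires a pH sweep (axis is '%s')", series$axis)
  }
  list(y_min = min(series$y), y_max = max(series$y),
       span = max(series$y) - min(series$y))
}

#' Compare the stability of two sweeps
#'
#' Computes [sweep_delta()] metrics for two series measured over the same
#' axis and response, and flags the one with the smaller range as the more
#' stable system. The x grids need not match; the comparison is
#' metric-level only (no interpolation).
#'
#' @param a,b [sweep_series()] objects with matching `axis` and `ylabel`.
#' @return A list of class `sweep_comparison` with `metrics_a`,
#'   `metrics_b`, `label_a`, `label_b` and `more_stable` (the label of the
#'   smaller-range series, or `"tie"`).
#' @export
compare_sweeps <- function(a, b) {
  if (!inherits(a, "sweep_series") || !inherits(b, "sweep_series")) {
    stop_input("both arguments must be sweep_series objects")
  }
  if (a$axis != b$axis) {
    stop_input("axis mismatch: '%s' vs '%s'", a$axis, b$axis)
  }
  if (a$ylabel != b$ylabel) {
    stop_input("response mismatch: '%s' vs '%s'", a$ylabel, b$ylabel)
  }
  ma <- sweep_delta(a)
  mb <- sweep_delta(b)
  la <- a$label %||% "a"
  lb <- b$label %||% "b"
  more_stable <- if (ma$range < mb$range) la else if (mb$range < ma$range) lb else "tie"
  structure(list(metrics_a = ma, metrics_b = mb, label_a = la, label_b = lb,
                 more_stable = more_stable),
            class = "sweep_comparison")
}

#' @export
print.sweep_comparison <- function(x, ...) {
  cat("Sweep comparison:", x$label_a, "vs", x$label_b, "\n")
  cat(sprintf("  %s: endpoint delta %.4g, range %.4g\n",
              x$label_a, x$metrics_a$endpoint_delta, x$metrics_a$range))
  cat(sprintf("  %s: endpoint delta %.4g, range %.4g\n",
              x$label_b, x$metrics_b$endpoint_delta, x$metrics_b$range))
  cat("  more stable (smaller range):", x$more_stable, "\n")
  invisible(x)
}
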