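#' Poincare SD1/SD2 of a per-breath metric series
#'
#' In a Poincare plot each value `x[n]` is plotted against its immediate
#' successor `x[n+1]`. The dispersion of the cloud perpendicular to the
#' identity line is SD1 (breath-to-breath, short-term variation); the
#' dispersion parallel to it is SD2 (long-term variation). With the rotated
#' coordinates `d = (x[n+1] - x[n])/sqrt(2)` and `s = (x[n+1] + x[n])/sqrt(2)`,
#' SD1 and SD2 are the sample standard deviations (denominator
#' `n_pairs - 1`) of `d` and `s`. Both coordinates are taken about their own
#' mean, so a constant offset of the series changes neither statistic.
#'
#' For a stationary AR(1) series with coefficient `phi` and marginal variance
#' `sigma_x^2`, the closed forms are `SD1 = sigma_x * sqrt(1 - phi)` and
#' `SD2 = sigma_x * sqrt(1 + phi)`; white noise gives SD1 = SD2.
#'
#' @param series Ordered numeric vector of per-breath values (length >= 3,
#'   all finite).
#' @param label Free-text label for the series (e.g. `"PIP"`).
#' @param segments Optional vector (same length) identifying contiguous
#'   analyzed segments; lag-1 pairs are formed only within a segment, never
#'   across a gap between protocol windows, since values separated by an
#'   unanalyzed gap are not immediate successors. Every segment still
#'   contributes its pairs to one pooled SD1/SD2.
#' @return A `poincare_result`: list with `sd1`, `sd2`, `n_pairs`,
#'   `series_label`.
#' @export
poincare_sd <- function(series, label = "", segments = NULL) {
  series <- as.numeric(series)
  if (length(series) < 3L) {
    stop("argument error: Poincare analysis needs a series of length >= 3")
  }
  if (any(!is.finite(series))) {
    stop("data error: non-finite value in series at index ",
         which(!is.finite(series))[1L])
  }
  if (is.null(segments)) segments <- rep(1L, length(series))
  if (length(segments) != length(series)) {
    stop("argument error: segments must match the series length")
  }
  keep <- segments[-length(segments)] == segments[-1L]
  x_n <- series[-length(series)][keep]
  x_n1 <- series[-1L][keep]
  if (length(x_n) < 2L) {
    stop("argument error: fewer than 2 lag-1 pairs after segment gating")
  }
  d <- (x_n1 - x_n) / sqrt(2)
  s <- (x_n1 + x_n) / sqrt(2)
  structure(list(sd1 = stats::sd(d), sd2 = stats::sd(s),
                 n_pairs = length(d), series_label = label),
            class = "poincare_result")
}

#' @export
print.poincare_result <- function(x, ...) {
  cat(sprintf("<poincare_result>%s SD1 = %.4g, SD2 = %.4g (%d lag-1 pairs)\n",
              if (nzchar(x$series_label)) paste0(" ", x$series_label, ":") else "",
              x$sd1, x$sd2, x$n_pairs))
  invisible(x)
}

#' Poincare scatter of a per-breath series
#'
#' Base-graphics lag-1 scatter (`x[n]` vs `x[n+1]`) with the identity line,
#' annotated with SD1/SD2.
#'
#' @inheritParams poincare_sd
#' @param ... Passed to [plot()].
#' @return The [poincare_sd()] result, invisibly.
#' @export
poincare_plot <- function(series, label = "", segments = NULL, ...) {
  res <- poincare_sd(series, label = label, segments = segments)
  n <- length(series)
  graphics::plot(series[-n], series[-1L],
                 xlab = expression(x[n]), ylab = expression(x[n + 1]),
                 main = sprintf("%s  SD1 = %.3g, SD2 = %.3g",
                                label, res$sd1, res$sd2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(res)
}
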