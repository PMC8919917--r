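#' Exact two-sided Wilcoxon signed-rank p by sign-flip enumeration
#'
#' Zero differences are dropped (standard signed-rank convention) and the
#' remaining absolute differences are midranked, so ties still get an exact
#' p-value. All 2^m sign assignments are enumerated for m <= `max_enum`;
#' above that the test falls back to [stats::wilcox.test()].
#'
#' @param d Numeric vector of paired differences.
#' @param max_enum Largest m enumerated exactly (default 15, i.e. 32768
#'   sign patterns).
#' @return List with `statistic` (V, sum of ranks of positive differences),
#'   `p_value`, `exact` (logical), `n_nonzero`.
#' @keywords internal
wilcoxon_signed_rank <- function(d, max_enum = 15L) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(list(statistic = 0, p_value = 1, exact = TRUE,
                           n_nonzero = 0L))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (m <= max_enum) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    vs <- as.vector(signs %*% r)
    p_ge <- mean(vs >= v - 1e-12)
    p_le <- mean(vs <= v + 1e-12)
    p <- min(1, 2 * min(p_ge, p_le))
    list(statistic = v, p_value = p, exact = TRUE, n_nonzero = m)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE,
                                              correct = TRUE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         exact = FALSE, n_nonzero = m)
  }
}

#' Normality-gated paired comparison
#'
#' The paired battery for a crossover design: a Shapiro-Wilk test on the
#' paired differences `d = a - b` decides the main test — a two-tailed paired
#' Student's t-test when the differences look normal (Shapiro p >= `alpha`),
#' otherwise a two-tailed exact Wilcoxon signed-rank test. Both the gate p
#' and the final p are returned. If every difference is exactly zero the
#' comparison is degenerate: `p_value = 1` with a warning flag rather than a
#' failure, since identical inputs are a reachable case. If the differences
#' are constant but nonzero, Shapiro-Wilk is undefined and the signed-rank
#' test is used with `normality_p = NA`.
#'
#' @param a,b Per-subject values, aligned by index, equal length >= 3.
#' @param alpha Significance level; also the normality-gate level.
#' @return A `paired_comparison` list: `test_used` (`"paired_t"`,
#'   `"wilcoxon_signed_rank"` or `"degenerate"`), `normality_p`, `statistic`,
#'   `p_value`, `n`, `alpha`, `degenerate` flag, `exact` (signed-rank only).
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("argument error: groups must be aligned by subject (equal length)")
  }
  n <- length(a)
  if (n < 3L) stop("argument error: paired comparison needs n >= 3")
  if (anyNA(a) || anyNA(b)) stop("data error: NA values in paired data")
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are exactly zero; degenerate comparison")
    return(structure(list(test_used = "degenerate", normality_p = NA_real_,
                          statistic = NA_real_, p_value = 1, n = n,
                          alpha = alpha, degenerate = TRUE, exact = NA),
                     class = "paired_comparison"))
  }
  if (stats::sd(d) == 0) {
    wr <- wilcoxon_signed_rank(d)
    return(structure(list(test_used = "wilcoxon_signed_rank",
                          normality_p = NA_real_, statistic = wr$statistic,
                          p_value = wr$p_value, n = n, alpha = alpha,
                          degenerate = FALSE, exact = wr$exact),
                     class = "paired_comparison"))
  }
  sw <- stats::shapiro.test(d)$p.value
  if (sw >= alpha) {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(test_used = "paired_t", normality_p = sw,
                statistic = unname(tt$statistic), p_value = tt$p.value,
                n = n, alpha = alpha, degenerate = FALSE, exact = NA)
  } else {
    wr <- wilcoxon_signed_rank(d)
    res <- list(test_used = "wilcoxon_signed_rank", normality_p = sw,
                statistic = wr$statistic, p_value = wr$p_value,
                n = n, alpha = alpha, degenerate = FALSE, exact = wr$exact)
  }
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> n = %d, %s: statistic = %s, p = %.4g",
              x$n, x$test_used,
              if (is.na(x$statistic)) "NA" else format(x$statistic, digits = 4),
              x$p_value))
  if (!is.na(x$normality_p)) {
    cat(sprintf(" (Shapiro-Wilk gate p = %.4g)", x$normality_p))
  }
  cat("\n")
  invisible(x)
}

#' Two-tailed Mann-Whitney U comparison of independent groups
#'
#' Exact p when the combined sample size is at most 20 and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction. Implemented through [stats::wilcox.test()]; the
#' statistic reported is U for the first group.
#'
#' @param g1,g2 Numeric vectors, both non-empty.
#' @return List with `U`, `p_value`, `exact`, `n1`, `n2`.
#' @export
unpaired_compare <- function(g1, g2) {
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(g1) == 0L || length(g2) == 0L) {
    stop("argument error: both groups must be non-empty")
  }
  ties <- any(duplicated(c(g1, g2)))
  exact <- (length(g1) + length(g2) <= 20L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g2, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact,
       n1 = length(g1), n2 = length(g2))
}

#' Two-sided power of the paired t-test at given n
#'
#' Noncentral-t power: with `n` paired differences of mean `delta` and SD
#' `sigma_d`, the t statistic has a noncentral t distribution with `n - 1`
#' degrees of freedom and noncentrality `delta/sigma_d * sqrt(n)`; power is
#' the probability of exceeding the central-t two-sided critical value.
#'
#' @param n Number of pairs (>= 2).
#' @param delta Mean paired difference (> 0, measurement units).
#' @param sigma_d SD of the paired differences (> 0, same units).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
paired_t_power <- function(n, delta, sigma_d, alpha = 0.05) {
  stopifnot(n >= 2, delta > 0, sigma_d > 0, alpha > 0, alpha < 1)
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  ncp <- delta / sigma_d * sqrt(n)
  1 - stats::pt(crit, df = n - 1, ncp = ncp) +
    stats::pt(-crit, df = n - 1, ncp = ncp)
}

#' Paired-design sample size by noncentral-t iteration
#'
#' Smallest integer `n >= 2` such that a two-sided one-sample t-test on the
#' paired differences attains the requested power, iterating
#' [paired_t_power()] upward over n. The noncentral-t formulation (not the
#' normal approximation) is used throughout.
#'
#' @inheritParams paired_t_power
#' @param power Required power, in (0, 1).
#' @param n_max Safety cap on the iteration.
#' @return The required number of pairs (integer).
#' @export
paired_sample_size <- function(delta, sigma_d, power = 0.8, alpha = 0.05,
                               n_max = 1e6) {
  stopifnot(delta > 0, sigma_d > 0, power > 0, power < 1,
            alpha > 0, alpha < 1)
  n <- 2L
  while (n <= n_max) {
    if (paired_t_power(n, delta, sigma_d, alpha) >= power) return(n)
    n <- n + 1L
  }
  stop("sample size exceeds n_max = ", n_max)
}

#' Overall lung injury score
#'
#' Histological scoring of ventilator-induced lung injury grades four
#' metrics — alveolar congestion, hemorrhage, leukocyte infiltration and
#' alveolar wall thickness — each on a 0-4 scale (0 normal to 4 very severe,
#' half grades allowed); the overall score is their arithmetic mean.
#'
#' @param congestion,hemorrhage,leukocyte_infiltration,wall_thickness
#'   Grades in `[0, 4]`.
#' @return List of the four grades plus `overall`.
#' @export
vili_overall <- function(congestion, hemorrhage, leukocyte_infiltration,
                         wall_thickness) {
  g <- c(congestion = congestion, hemorrhage = hemorrhage,
         leukocyte_infiltration = leukocyte_infiltration,
         wall_thickness = wall_thickness)
  if (any(!is.finite(g)) || any(g < 0) || any(g > 4)) {
    stop("argument error: every grade must lie in [0, 4]")
  }
  c(as.list(g), list(overall = mean(g)))
}

#' Lung wet-to-dry weight ratio
#'
#' Ratio of tissue wet weight to dry weight (after drying to constant
#' weight); an index of pulmonary edema.
#'
#' @param wet_mg,dry_mg Tissue weights in mg; `dry_mg > 0`. A wet weight
#'   below the dry weight is physically implausible and triggers a warning,
#'   not an error.
#' @return List with `wet_mg`, `dry_mg`, `ratio`.
#' @export
wet_dry <- function(wet_mg, dry_mg) {
  if (!is.finite(dry_mg) || dry_mg <= 0) {
    stop("argument error: dry weight must be positive")
  }
  if (wet_mg < dry_mg) {
    warning("wet weight below dry weight; check the measurements")
  }
  list(wet_mg = wet_mg, dry_mg = dry_mg, ratio = wet_mg / dry_mg)
}
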