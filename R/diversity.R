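#' Per-sample metabolite diversity and total signal
#'
#' Metabolite diversity is the number of features detected (intensity > 0)
#' in a sample — the working proxy for the accumulation of new, mostly
#' low-abundance molecular species with age. Total signal is the column sum.
#' Both are computed per sample and returned alongside the sample metadata.
#'
#' @param t A [feature_table()].
#' @return A tibble (`diversity_series`) with one row per sample: `sample`,
#'   `diet`, `age_days`, `replicate`, `detected_count`, `total_signal`.
#' @export
diversity_series <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  out <- t$samples
  out$detected_count <- as.integer(colSums(t$intensities > 0))
  out$total_signal <- colSums(t$intensities)
  out
}

#' Per-sample count of detected features
#' @inheritParams diversity_series
#' @return Named integer vector of detected counts per sample.
#' @export
count_detected <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  colSums(t$intensities > 0)
}

#' Per-sample total signal
#' @inheritParams diversity_series
#' @return Named numeric vector of column sums.
#' @export
total_signal <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  colSums(t$intensities)
}

#' Least-squares polynomial trend through replicate points
#'
#' Fits an ordinary least-squares polynomial of the requested degree through
#' all replicate points (not replicate means), as used for drawing the
#' diversity and delay trend lines (cubic and quadratic respectively).
#'
#' @param x Predictor (ages), one value per observation.
#' @param y Response values.
#' @param degree Polynomial degree (2 or 3 in the pipeline; any >= 1 works).
#' @return A list of class `poly_trend` with `coefficients` (intercept
#'   first), `fitted`, `residuals`, `degree`, and `fun`, a vectorized
#'   evaluator of the fitted polynomial.
#' @export
fit_polynomial_trend <- function(x, y, degree = 3) {
  stopifnot(length(x) == length(y), degree >= 1)
  if (length(unique(x)) < degree + 1) {
    abort(sprintf("need at least %d distinct x values for a degree-%d fit.",
                  degree + 1, degree))
  }
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  cf <- unname(coef(fit))
  structure(
    list(coefficients = cf,
         fitted = unname(fit$fitted.values),
         residuals = unname(fit$residuals),
         degree = degree,
         fun = function(t) {
           vapply(t, function(ti) sum(cf * ti^(0:degree)), numeric(1))
         }),
    class = "poly_trend"
  )
}

#' Repeated-measures ANOVA on a diet's diversity series
#'
#' Tests whether detected counts change with age, with age as the within
#' factor and the replicate collection series as the subject — the same
#' one-way within-subject ANOVA used in the per-feature screen
#' ([rm_anova_feature()]).
#'
#' @param series A [diversity_series()] restricted to one diet (or with a
#'   single diet present).
#' @param response Column to test (default `detected_count`).
#' @return A tibble with `statistic` (F), `p_value`, `df1`, `df2`.
#' @export
diversity_age_anova <- function(series, response = "detected_count") {
  if (length(unique(series$diet)) != 1) {
    abort("`series` must contain exactly one diet; filter first.")
  }
  wide <- pivot_wider(series[, c("age_days", "replicate", response)],
                      names_from = "replicate", values_from = all_of(response))
  wide <- arrange(wide, .data$age_days)
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(m)) abort("unbalanced design: missing (age, replicate) cells.")
  res <- rm_anova_feature(m)
  tibble(statistic = res$statistic, p_value = res$p_value,
         df1 = res$df[1], df2 = res$df[2])
}

#' Plateau age of a fitted cubic trend
#'
#' The age at which the fitted diversity trend levels off: the smallest root
#' of the fitted derivative inside the observed age range at which the
#' curvature is negative. Reading the plateau off the fit (rather than the
#' raw-count argmax) is robust to replicate noise.
#'
#' @param trend A degree-3 [fit_polynomial_trend()] result, or a length-4
#'   coefficient vector (intercept first).
#' @param age_range Length-2 numeric: the observed age range.
#' @return The plateau age in days, or `NA_real_` if the fitted derivative
#'   has no such root in range.
#' @export
plateau_age <- function(trend, age_range) {
  cf <- if (inherits(trend, "poly_trend")) trend$coefficients else trend
  if (length(cf) != 4) abort("plateau_age needs a cubic (degree-3) fit.")
  dcf <- c(cf[2], 2 * cf[3], 3 * cf[4])   # derivative coefficients
  if (all(abs(dcf) < 1e-14)) return(NA_real_)
  roots <- polyroot(dcf)
  roots <- Re(roots[abs(Im(roots)) < 1e-8])
  roots <- roots[roots >= age_range[1] & roots <= age_range[2]]
  curv <- 2 * cf[3] + 6 * cf[4] * roots
  roots <- roots[curv < 0]
  if (!length(roots)) NA_real_ else min(roots)
}

#' Diversity, trend, and plateau summary per diet
#'
#' Convenience wrapper running [diversity_series()], the cubic trend of
#' detected counts over age (through all replicate points), the plateau-age
#' estimate, and the diversity repeated-measures ANOVA for each diet.
#'
#' @param t A [feature_table()].
#' @return A list with `series` (tibble), `trend` (named list of
#'   `poly_trend` per diet), and `summary` (tibble per diet: plateau age,
#'   ANOVA F and p, total-signal slope).
#' @export
diversity_analysis <- function(t) {
  series <- diversity_series(t)
  diets <- unique(series$diet)
  trend <- list()
  rows <- list()
  for (d in diets) {
    s <- series[series$diet == d, ]
    tr <- fit_polynomial_trend(s$age_days, s$detected_count, degree = 3)
    trend[[d]] <- tr
    an <- diversity_age_anova(s)
    slope <- coef(lm(total_signal ~ age_days, data = s))[[2]]
    rows[[d]] <- tibble(
      diet = d,
      plateau_age = plateau_age(tr, range(s$age_days)),
      statistic = an$statistic, p_value = an$p_value,
      total_signal_slope = slope
    )
  }
  list(series = series, trend = trend, summary = list_rbind(rows))
}
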