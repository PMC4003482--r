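#' Gompertz survivorship
#'
#' Survival function of the Gompertz mortality model with hazard
#' \eqn{h(t) = a e^{bt}}: \eqn{S(t) = \exp\{-(a/b)(e^{bt} - 1)\}}.
#'
#' @param t Vector of ages (days).
#' @param a Baseline hazard per day (> 0).
#' @param b Hazard growth rate per day (> 0).
#' @return Survival probabilities at `t`.
#' @export
gompertz_survival <- function(t, a, b) {
  stopifnot(a > 0, b > 0)
  exp(-(a / b) * expm1(b * t))
}

#' Mean lifespan implied by Gompertz parameters
#'
#' Numerically integrates the survival function over \eqn{[0, \infty)}.
#'
#' @inheritParams gompertz_survival
#' @return Mean lifespan in days.
#' @export
gompertz_mean <- function(a, b) {
  # integrate to the age where S(t) ~ 1e-14 (finite bound keeps the
  # quadrature stable in the exponential limit b -> 0)
  upper <- log1p(32.2 * b / a) / b
  integrate(gompertz_survival, 0, upper, a = a, b = b,
            rel.tol = 1e-10, abs.tol = 1e-10)$value
}

#' Calibrate the Gompertz baseline hazard to a target mean lifespan
#'
#' With the hazard doubling rate `b` held fixed (a single printed mean
#' lifespan gives one constraint, so only one parameter is identifiable),
#' finds `a` by 1-D root finding so that the numerically integrated mean of
#' the survival curve equals `target_mean_days` within 0.05 days.
#'
#' @param target_mean_days Target mean lifespan (days, > 0).
#' @param b_fixed Fixed hazard growth rate per day (default 0.1).
#' @return A list with elements `a`, `b`, and `mean_days` (the achieved
#'   integrated mean), of class `gompertz_params`.
#' @export
calibrate_gompertz <- function(target_mean_days, b_fixed = 0.1) {
  stopifnot(target_mean_days > 0, b_fixed > 0)
  f <- function(log10_a) gompertz_mean(10^log10_a, b_fixed) - target_mean_days
  root <- tryCatch(
    uniroot(f, lower = -12, upper = 2, tol = 1e-12),
    error = function(e) abort("no Gompertz baseline hazard in the search bracket reproduces the target mean.")
  )
  a <- 10^root$root
  achieved <- gompertz_mean(a, b_fixed)
  if (abs(achieved - target_mean_days) > 0.05) {
    abort("Gompertz calibration did not converge to within 0.05 days.")
  }
  structure(list(a = a, b = b_fixed, mean_days = achieved),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("<gompertz_params> a = %.4g /d, b = %.3g /d, mean lifespan = %.2f d\n",
              x$a, x$b, x$mean_days))
  invisible(x)
}

#' Simulate a cohort's death times under a Gompertz model
#'
#' Death times are drawn i.i.d. by inverse-CDF sampling:
#' \eqn{T = b^{-1}\log\{1 - (b/a)\log U\}} for \eqn{U \sim} Uniform(0,1).
#'
#' @param params A `gompertz_params` object (see [calibrate_gompertz()]).
#' @param n_flies Cohort size (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `lifespan_sim` with `death_times` (days,
#'   continuous), `curve` (tibble `day`, `fraction_alive`; see
#'   [lifespan_curve()]) and `cohort_size`.
#' @export
simulate_lifespan <- function(params, n_flies, seed = NULL) {
  stopifnot(inherits(params, "gompertz_params"), n_flies >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  u <- runif(n_flies)
  death_times <- log1p(-(params$b / params$a) * log(u)) / params$b
  structure(
    list(death_times = death_times,
         curve = lifespan_curve(death_times),
         cohort_size = n_flies),
    class = "lifespan_sim"
  )
}

#' Empirical survivorship curve from death times
#'
#' @param death_times Numeric vector of ages at death (days).
#' @return A tibble with columns `day` (0 .. last death, integer grid) and
#'   `fraction_alive` (fraction of the cohort with death time > day).
#' @export
lifespan_curve <- function(death_times) {
  stopifnot(length(death_times) >= 1, all(death_times >= 0))
  days <- 0:ceiling(max(death_times))
  frac <- vapply(days, function(d) mean(death_times > d), numeric(1))
  tibble(day = days, fraction_alive = frac)
}

#' Mean lifespan of a cohort followed to extinction
#'
#' @param death_times Numeric vector of ages at death (>= 1 value).
#' @return Arithmetic mean age at death (days).
#' @export
mean_lifespan <- function(death_times) {
  if (!length(death_times)) abort("empty cohort.")
  mean(death_times)
}

#' Log-rank test between two fully observed cohorts
#'
#' Standard log-rank chi-square (1 df) comparing the survival experience of
#' two cohorts followed to death (no censoring), computed with
#' [survival::survdiff()].
#'
#' @param deaths_a,deaths_b Numeric vectors of death times for the two cohorts.
#' @return A tibble with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
log_rank_test <- function(deaths_a, deaths_b) {
  if (!length(deaths_a) || !length(deaths_b)) abort("empty cohort.")
  time <- c(deaths_a, deaths_b)
  grp <- rep(c("A", "B"), c(length(deaths_a), length(deaths_b)))
  if (length(unique(time)) == 1L || identical(sort(deaths_a), sort(deaths_b))) {
    # survdiff is undefined/degenerate when the pooled experience is identical
    sd_fit <- tryCatch(
      survival::survdiff(survival::Surv(time, rep(1, length(time))) ~ grp),
      error = function(e) NULL
    )
    if (is.null(sd_fit) || !is.finite(sd_fit$chisq)) {
      return(tibble(statistic = 0, p_value = 1))
    }
    return(tibble(statistic = sd_fit$chisq,
                  p_value = stats::pchisq(sd_fit$chisq, 1, lower.tail = FALSE)))
  }
  sd_fit <- survival::survdiff(survival::Surv(time, rep(1, length(time))) ~ grp)
  tibble(statistic = sd_fit$chisq,
         p_value = stats::pchisq(sd_fit$chisq, 1, lower.tail = FALSE))
}

#' Deaths per inter-observation interval of a survivorship curve
#'
#' @param curve Tibble/data frame with `day` (increasing) and
#'   `fraction_alive` (non-increasing, starting at its maximum).
#' @param cohort_size Number of individuals the curve describes.
#' @return A tibble with `day_start`, `day_end` and `deaths` per interval.
#'   Deaths sum to `cohort_size * (1 - final fraction)`.
#' @export
deaths_per_interval <- function(curve, cohort_size) {
  stopifnot(cohort_size >= 1)
  curve <- arrange(as_tibble(curve), .data$day)
  if (any(diff(curve$fraction_alive) > 1e-12)) {
    abort("fraction_alive must be non-increasing.")
  }
  dec <- -diff(curve$fraction_alive)
  tibble(day_start = curve$day[-nrow(curve)],
         day_end = curve$day[-1],
         deaths = cohort_size * dec)
}
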