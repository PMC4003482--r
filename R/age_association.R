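#' One-way repeated-measures ANOVA for a single feature
#'
#' Age is the within factor; the replicate collection series is the subject
#' followed across ages. The total sum of squares decomposes as
#' \eqn{SS_{total} = SS_{age} + SS_{subject} + SS_{residual}} and
#' \eqn{F = MS_{age} / MS_{residual}} on \eqn{(a-1, (a-1)(s-1))} degrees of
#' freedom. No sphericity correction is applied. If the residual sum of
#' squares vanishes while the age effect does not, the fit is exact and the
#' p-value is 0 with an infinite-F sentinel; a constant response gives
#' F = 0, p = 1.
#'
#' @param values Numeric matrix, ages x replicates (balanced, finite).
#' @return A list with `statistic` (F), `p_value`, `df` (length 2), and `ss`
#'   (named vector: age, subject, residual).
#' @export
rm_anova_feature <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (ages x replicates).")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite and balanced (no missing cells).")
  }
  a <- nrow(values); s <- ncol(values)
  if (a < 2 || s < 2) abort("need at least 2 ages and 2 replicates.")
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  ss_age <- s * sum((rowMeans(values) - gm)^2)
  ss_subj <- a * sum((colMeans(values) - gm)^2)
  ss_res <- max(ss_total - ss_age - ss_subj, 0)
  df <- c(a - 1, (a - 1) * (s - 1))
  tol <- 1e-12 * max(ss_total, 1)
  if (ss_age <= tol) {
    return(list(statistic = 0, p_value = 1, df = df,
                ss = c(age = ss_age, subject = ss_subj, residual = ss_res)))
  }
  if (ss_res <= tol) {
    return(list(statistic = Inf, p_value = 0, df = df,
                ss = c(age = ss_age, subject = ss_subj, residual = ss_res)))
  }
  f <- (ss_age / df[1]) / (ss_res / df[2])
  list(statistic = f, p_value = pf(f, df[1], df[2], lower.tail = FALSE),
       df = df, ss = c(age = ss_age, subject = ss_subj, residual = ss_res))
}

# vectorized RM-ANOVA across the rows of a features x samples matrix.
# `age` and `replicate` index the columns; design must be balanced.
rm_anova_rows <- function(m, age, replicate) {
  ages <- sort(unique(age)); reps <- sort(unique(replicate))
  a <- length(ages); s <- length(reps)
  if (ncol(m) != a * s) abort("unbalanced design.")
  age_ind <- outer(age, ages, "==") * 1
  rep_ind <- outer(replicate, reps, "==") * 1
  if (any(colSums(age_ind) != s) || any(colSums(rep_ind) != a)) {
    abort("unbalanced design.")
  }
  gm <- rowMeans(m)
  ss_total <- rowSums((m - gm)^2)
  age_means <- (m %*% age_ind) / s
  rep_means <- (m %*% rep_ind) / a
  ss_age <- s * rowSums((age_means - gm)^2)
  ss_subj <- a * rowSums((rep_means - gm)^2)
  ss_res <- pmax(ss_total - ss_age - ss_subj, 0)
  df1 <- a - 1; df2 <- (a - 1) * (s - 1)
  tol <- 1e-12 * pmax(ss_total, 1)
  f <- (ss_age / df1) / (ss_res / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  f[ss_age <= tol] <- 0; p[ss_age <= tol] <- 1
  exact <- ss_res <= tol & ss_age > tol
  f[exact] <- Inf; p[exact] <- 0
  tibble(statistic = f, p_value = p)
}

#' Per-feature repeated-measures ANOVA screen for one diet
#'
#' Applies [rm_anova_feature()] to every eligible feature of one diet's
#' samples. Only features detected in all of the diet's samples are
#' eligible: a feature registering 0 in at least one sample belongs to the
#' detection-diversity analysis, not the intensity screen, and is flagged
#' `eligible = FALSE` rather than tested. Tests run on log10 intensities.
#'
#' @param t A [feature_table()] (normalized recommended).
#' @param diet Diet label to screen.
#' @param alpha Significance threshold on the p-value (default 0.0014, the
#'   calibrated metabolite threshold; use 0.0013 for transcript matrices).
#' @return A tibble with one row per feature: `feature`, `diet`, `eligible`,
#'   `statistic`, `p_value`, `significant` (`p < alpha`).
#' @export
rm_anova_table <- function(t, diet, alpha = 0.0014) {
  stopifnot(inherits(t, "feature_table"), alpha > 0, alpha < 1)
  td <- filter_diet(t, diet)
  m <- td$intensities
  eligible <- rowSums(m == 0) == 0
  if (!any(eligible)) abort("no eligible features (every feature has a non-detect).")
  res <- rm_anova_rows(log10(m[eligible, , drop = FALSE]),
                       td$samples$age_days, td$samples$replicate)
  out <- tibble(
    feature = rownames(m), diet = diet, eligible = eligible,
    statistic = NA_real_, p_value = NA_real_
  )
  out$statistic[eligible] <- res$statistic
  out$p_value[eligible] <- res$p_value
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  attr(out, "alpha") <- alpha
  out
}

#' Calibrate the significance threshold at the error-rate knee
#'
#' Operationalizes threshold selection "at the transition between linear and
#' exponential rise in error rate": over a log-spaced grid of candidate
#' thresholds \eqn{\alpha} from \eqn{1/m} to `cap`, the expected false
#' positives are \eqn{E(\alpha) = \alpha m}, the realized discoveries
#' \eqn{R(\alpha) = \#\{p \le \alpha\}}, and the estimated error rate
#' \eqn{\widehat{FDR}(\alpha) = E(\alpha)/\max(R(\alpha), 1)}. The knee is
#' the grid point maximizing the perpendicular distance to the chord joining
#' the curve's endpoints in \eqn{(\log_{10}\alpha, \log_{10}\widehat{FDR})}
#' space. On signal-free input (error rate near 1 everywhere) the cap is
#' returned with `no_signal = TRUE`.
#'
#' @param pvalues At least 100 p-values in (0, 1].
#' @param cap Upper bound on the returned threshold (default 0.05).
#' @param grid_n Number of grid points (default 100).
#' @return A list with `alpha` (the calibrated threshold), `no_signal`,
#'   and `grid` (tibble: `alpha`, `discoveries`, `fdr_hat`, `knee_distance`).
#' @export
calibrate_threshold <- function(pvalues, cap = 0.05, grid_n = 100) {
  pvalues <- pvalues[!is.na(pvalues)]
  m <- length(pvalues)
  if (m < 100) abort("threshold calibration needs at least 100 p-values.")
  if (any(pvalues <= 0 | pvalues > 1)) {
    # exact-fit sentinels (p = 0) carry no calibration information
    pvalues <- pmin(pmax(pvalues, .Machine$double.xmin), 1)
  }
  alphas <- 10^seq(log10(1 / m), log10(cap), length.out = grid_n)
  disc <- vapply(alphas, function(a) sum(pvalues <= a), numeric(1))
  fdr_hat <- alphas * m / pmax(disc, 1)
  x <- log10(alphas); y <- log10(fdr_hat)
  x0 <- x[1]; y0 <- y[1]; x1 <- x[grid_n]; y1 <- y[grid_n]
  chord <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  d <- abs((y1 - y0) * x - (x1 - x0) * y + x1 * y0 - y1 * x0) / max(chord, 1e-12)
  grid <- tibble(alpha = alphas, discoveries = disc, fdr_hat = fdr_hat,
                 knee_distance = d)
  no_signal <- median(fdr_hat) > 0.5
  alpha_star <- if (no_signal) cap else alphas[which.max(d)]
  list(alpha = min(alpha_star, cap), no_signal = no_signal, grid = grid)
}

#' Plug-in false discovery rate at a threshold
#'
#' The \eqn{\pi_0 = 1} plug-in estimator
#' \eqn{\widehat{FDR} = \alpha m / \#\{p \le \alpha\}} (conservative: all
#' tests assumed null when estimating false positives).
#'
#' @param pvalues Vector of p-values.
#' @param alpha Threshold in (0, 1).
#' @return The estimated FDR, or `NA_real_` when there are no discoveries.
#' @export
plug_in_fdr <- function(pvalues, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  pvalues <- pvalues[!is.na(pvalues)]
  r <- sum(pvalues <= alpha)
  if (r == 0) return(NA_real_)
  alpha * length(pvalues) / r
}

#' Cross-diet overlap of significant features
#'
#' @param res_a,res_b [rm_anova_table()] results for the two diets over the
#'   same feature universe.
#' @return A list with `counts` (tibble: `a_only`, `both`, `b_only`),
#'   `both_features` (ids significant in both diets, the input to the
#'   trajectory analysis), and `labels` (per-feature overlap label).
#' @export
diet_overlap <- function(res_a, res_b) {
  if (!identical(res_a$feature, res_b$feature)) {
    abort("results must cover the same feature universe in the same order.")
  }
  sa <- res_a$significant; sb <- res_b$significant
  label <- dplyr::case_when(
    sa & sb ~ "both",
    sa & !sb ~ "a_only",
    !sa & sb ~ "b_only",
    .default = "neither"
  )
  list(
    counts = tibble(a_only = sum(sa & !sb), both = sum(sa & sb),
                    b_only = sum(!sa & sb)),
    both_features = res_a$feature[sa & sb],
    labels = tibble(feature = res_a$feature, overlap = label)
  )
}

#' Age-association screen across both diets
#'
#' Runs the per-feature repeated-measures ANOVA screen for each diet,
#' optionally auto-calibrates the threshold at the error-rate knee, reports
#' the plug-in FDR, and computes the cross-diet overlap.
#'
#' @param t A [feature_table()].
#' @param alpha Significance threshold (ignored when `auto_calibrate`).
#' @param auto_calibrate Calibrate the threshold from the pooled p-value
#'   distribution with [calibrate_threshold()].
#' @param diets Diets to screen (default: all in the table, first two used
#'   for the overlap).
#' @return An object of class `age_assoc`: list with `results` (per-feature
#'   tibble over diets), `alpha`, `fdr` (per diet), `overlap` (see
#'   [diet_overlap()]), `calibration` (if requested).
#' @export
age_assoc_screen <- function(t, alpha = 0.0014, auto_calibrate = FALSE,
                             diets = unique(t$samples$diet)) {
  stopifnot(length(diets) >= 1)
  calibration <- NULL
  if (auto_calibrate) {
    pooled <- unlist(lapply(diets, function(d) {
      r <- rm_anova_table(t, d, alpha = 0.5)
      r$p_value[r$eligible]
    }))
    calibration <- calibrate_threshold(pooled)
    alpha <- calibration$alpha
  }
  res <- lapply(diets, function(d) rm_anova_table(t, d, alpha = alpha))
  names(res) <- diets
  fdr <- vapply(res, function(r) plug_in_fdr(r$p_value[r$eligible], alpha),
                numeric(1))
  overlap <- if (length(diets) >= 2) diet_overlap(res[[1]], res[[2]]) else NULL
  structure(
    list(results = list_rbind(res), alpha = alpha, fdr = fdr,
         overlap = overlap, calibration = calibration, diets = diets),
    class = "age_assoc"
  )
}

#' @export
print.age_assoc <- function(x, ...) {
  cat(sprintf("<age_assoc> alpha = %.2g\n", x$alpha))
  print(glance(x))
  invisible(x)
}

#' Tidy per-feature screen results
#' @param x An `age_assoc` object.
#' @param ... Unused.
#' @return The per-feature results tibble.
#' @method tidy age_assoc
#' @export
tidy.age_assoc <- function(x, ...) x$results

#' One-row summary of an age-association screen
#' @param x An `age_assoc` object.
#' @param ... Unused.
#' @return A tibble with one row per diet: features tested, significant
#'   count and fraction, plug-in FDR, and (when two diets were screened)
#'   the size of the cross-diet overlap.
#' @method glance age_assoc
#' @export
glance.age_assoc <- function(x, ...) {
  out <- x$results |>
    group_by(.data$diet) |>
    summarise(
      n_features = n(),
      n_eligible = sum(.data$eligible),
      n_significant = sum(.data$significant),
      frac_significant = sum(.data$significant) / n(),
      .groups = "drop"
    )
  out$alpha <- x$alpha
  out$fdr <- unname(x$fdr[out$diet])
  out$n_overlap <- if (!is.null(x$overlap)) x$overlap$counts$both else NA_integer_
  out
}
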