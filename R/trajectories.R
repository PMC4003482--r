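#' Replicate-averaged age trajectories
#'
#' Averages replicates per (feature, diet, age) to produce each feature's
#' age trajectory in each diet. For intensity trajectories the default is to
#' average log10 values (the scale on which the screen and the clustering
#' operate); `transform = "identity"` averages raw intensities, the input
#' for fold-change analytics.
#'
#' @param t A [feature_table()].
#' @param features Feature ids to keep (default all). For `"log10"` every
#'   kept feature must be strictly positive in all samples.
#' @param transform `"log10"` or `"identity"`.
#' @return A `trajectory_matrix`: list with `values` (named list per diet of
#'   features x ages matrices), `ages`, `features`, `scaling = "none"`,
#'   `transform`.
#' @export
average_replicates <- function(t, features = NULL,
                               transform = c("log10", "identity")) {
  stopifnot(inherits(t, "feature_table"))
  transform <- arg_match(transform)
  features <- features %||% feature_ids(t)
  missing_f <- setdiff(features, feature_ids(t))
  if (length(missing_f)) abort("unknown features requested.")
  m <- t$intensities[features, , drop = FALSE]
  if (transform == "log10") {
    if (any(m == 0)) {
      abort("log10 trajectories require strictly positive intensities; exclude zero-containing features first.")
    }
    m <- log10(m)
  }
  ages <- sort(unique(t$samples$age_days))
  diets <- unique(t$samples$diet)
  values <- lapply(diets, function(d) {
    sel <- t$samples$diet == d
    sub <- m[, sel, drop = FALSE]
    age <- t$samples$age_days[sel]
    reps <- table(age)
    if (length(unique(reps)) != 1) abort("unbalanced replicates within a diet.")
    out <- sapply(ages, function(a) rowMeans(sub[, age == a, drop = FALSE]))
    out <- matrix(out, nrow = length(features),
                  dimnames = list(features, paste0("age_", ages)))
    out
  })
  names(values) <- diets
  structure(
    list(values = values, ages = ages, features = features,
         scaling = "none", transform = transform),
    class = "trajectory_matrix"
  )
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("<trajectory_matrix> %d features x %d ages, diets: %s, scaling: %s\n",
              length(x$features), length(x$ages),
              paste(names(x$values), collapse = ", "), x$scaling))
  invisible(x)
}

#' Tidy a trajectory matrix into long format
#' @param x A `trajectory_matrix`.
#' @param ... Unused.
#' @return Tibble with `feature`, `diet`, `age_days`, `value`.
#' @method tidy trajectory_matrix
#' @export
tidy.trajectory_matrix <- function(x, ...) {
  list_rbind(imap(x$values, function(m, d) {
    tibble(feature = rep(rownames(m), ncol(m)),
           diet = d,
           age_days = rep(x$ages, each = nrow(m)),
           value = as.vector(m))
  }))
}

row_zscore <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)          # sample sd, n - 1
  sweep(sweep(m, 1, mu, "-"), 1, sdv, "/")
}

#' Z-score trajectories within or across diets
#'
#' `within_diet` scaling z-scores each feature's trajectory separately in
#' each diet (every row gets mean 0, unit sample variance per diet),
#' removing inter-diet level differences so only shapes remain.
#' `across_diets` scaling z-scores each feature's concatenated two-diet
#' trajectory, preserving level differences between diets as opposite-sign
#' per-diet means. Constant rows cannot be scaled and are excluded (ids
#' recorded in `$excluded`).
#'
#' @param m A `trajectory_matrix` with `scaling == "none"`.
#' @param mode `"within_diet"` or `"across_diets"`.
#' @return A scaled `trajectory_matrix` with an `excluded` element.
#' @export
scale_trajectories <- function(m, mode = c("within_diet", "across_diets")) {
  stopifnot(inherits(m, "trajectory_matrix"))
  mode <- arg_match(mode)
  tol <- 1e-12
  if (mode == "within_diet") {
    sds <- lapply(m$values, function(v) apply(v, 1, sd))
    constant <- Reduce(`|`, lapply(sds, function(s) s <= tol))
  } else {
    cat_m <- do.call(cbind, m$values)
    constant <- apply(cat_m, 1, sd) <= tol
  }
  excluded <- m$features[constant]
  keep <- !constant
  values <- lapply(m$values, function(v) v[keep, , drop = FALSE])
  if (!sum(keep)) abort("all rows are constant; nothing to scale.")
  if (mode == "within_diet") {
    values <- lapply(values, row_zscore)
  } else {
    cat_m <- do.call(cbind, values)
    cat_m <- row_zscore(cat_m)
    idx <- split(seq_len(ncol(cat_m)),
                 rep(seq_along(values), vapply(values, ncol, 1L)))
    values <- map2(values, idx, function(v, i) {
      out <- cat_m[, i, drop = FALSE]
      dimnames(out) <- dimnames(v)
      out
    })
  }
  structure(
    list(values = values, ages = m$ages, features = m$features[keep],
         scaling = mode, transform = m$transform, excluded = excluded),
    class = "trajectory_matrix"
  )
}

pearson_rows <- function(a, b) {
  az <- row_zscore(a); bz <- row_zscore(b)
  rowSums(az * bz) / (ncol(a) - 1)
}

#' Per-feature Pearson correlation between the two diets' trajectories
#'
#' For each matched feature, the Pearson correlation between its
#' replicate-averaged age trajectory in the two diets. Features with a
#' constant trajectory in either diet (undefined correlation) are excluded
#' and flagged.
#'
#' @param m A `trajectory_matrix` containing exactly two diets.
#' @param features Optional subset of feature ids.
#' @return A tibble `feature`, `r`, with attributes `median_r` and
#'   `excluded` (constant-trajectory ids).
#' @export
diet_pair_correlations <- function(m, features = NULL) {
  stopifnot(inherits(m, "trajectory_matrix"), length(m$values) == 2)
  features <- features %||% m$features
  a <- m$values[[1]][features, , drop = FALSE]
  b <- m$values[[2]][features, , drop = FALSE]
  if (ncol(a) < 3) abort("need at least 3 ages for trajectory correlations.")
  tol <- 1e-12
  const <- apply(a, 1, sd) <= tol | apply(b, 1, sd) <= tol
  r <- pearson_rows(a[!const, , drop = FALSE], b[!const, , drop = FALSE])
  out <- tibble(feature = features[!const], r = unname(r))
  attr(out, "median_r") <- median(out$r)
  attr(out, "excluded") <- features[const]
  out
}

#' Cross-diet trajectory concordance with a re-pairing permutation null
#'
#' The statistic is the median of the matched-pair Pearson correlations
#' between the two diets' feature trajectories. The null distribution
#' re-pairs features at random (permuting feature identity in the second
#' diet) and recomputes the median; the p-value is
#' \eqn{(1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) / (n_{perm} + 1)}.
#' With `exact = TRUE` (feasible for ~7 or fewer features) all pairings are
#' enumerated and the p-value is the exact proportion of pairings whose
#' median is at least the observed one.
#'
#' @param m A `trajectory_matrix` with exactly two diets.
#' @param features Optional subset of matched feature ids (>= 10 for the
#'   sampled test; any number >= 2 with `exact = TRUE`).
#' @param n_perm Number of random re-pairings (>= 1).
#' @param seed Optional seed for the re-pairings.
#' @param exact Enumerate all pairings instead of sampling.
#' @return A list of class `concordance_test` with `observed_median_r`,
#'   `p_value`, `n_perm`, `null_medians`, and `correlations` (the matched
#'   per-feature tibble).
#' @export
permutation_concordance <- function(m, features = NULL, n_perm = 1999,
                                    seed = NULL, exact = FALSE) {
  stopifnot(inherits(m, "trajectory_matrix"), length(m$values) == 2)
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  corr <- diet_pair_correlations(m, features)
  feats <- corr$feature
  n <- length(feats)
  if (!exact && n < 10) abort("need >= 10 matched features for the sampled test.")
  if (exact && n > 8) abort("exact enumeration is limited to 8 features.")
  az <- row_zscore(m$values[[1]][feats, , drop = FALSE])
  bz <- row_zscore(m$values[[2]][feats, , drop = FALSE])
  k <- ncol(az) - 1
  obs <- median(rowSums(az * bz) / k)
  med_for <- function(perm) median(rowSums(az * bz[perm, , drop = FALSE]) / k)
  if (exact) {
    perms <- permutations_of(n)
    null_medians <- vapply(perms, med_for, numeric(1))
    p <- mean(null_medians >= obs - 1e-12)
    n_perm <- length(null_medians)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    null_medians <- vapply(seq_len(n_perm), function(i) med_for(sample.int(n)),
                           numeric(1))
    p <- (1 + sum(null_medians >= obs - 1e-12)) / (n_perm + 1)
  }
  structure(
    list(observed_median_r = obs, p_value = p, n_perm = n_perm,
         null_medians = null_medians, correlations = corr, exact = exact),
    class = "concordance_test"
  )
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(permutations_of(n - 1), function(p) c(i, (seq_len(n)[-i])[p]))
  }))
}

#' @export
print.concordance_test <- function(x, ...) {
  cat(sprintf(
    "<concordance_test> median matched r = %.3f, p = %.4g (%s, %d pairings)\n",
    x$observed_median_r, x$p_value,
    if (x$exact) "exact" else "sampled", x$n_perm))
  invisible(x)
}

#' Tidy the per-feature concordance correlations
#' @param x A `concordance_test`.
#' @param ... Unused.
#' @return The matched per-feature correlation tibble.
#' @method tidy concordance_test
#' @export
tidy.concordance_test <- function(x, ...) x$correlations

#' One-row concordance test summary
#' @param x A `concordance_test`.
#' @param ... Unused.
#' @return A one-row tibble: observed median r, p-value, pairings.
#' @method glance concordance_test
#' @export
glance.concordance_test <- function(x, ...) {
  tibble(observed_median_r = x$observed_median_r, p_value = x$p_value,
         n_perm = x$n_perm, exact = x$exact)
}

#' Correlation of feature trajectories with the survivorship curve
#'
#' Pearson correlation between each feature's trajectory and the fraction
#' alive, linearly interpolated at the sampled ages. Trajectories tracking
#' mortality closely (|r| above the flag threshold) are flagged as
#' lifespan-correlated.
#'
#' @param m A `trajectory_matrix`.
#' @param lifespan Tibble with `diet`, `day`, `fraction_alive`.
#' @param diet Which diet's trajectories and curve to use.
#' @param strong_threshold Absolute-correlation flag threshold (default 0.75).
#' @return A tibble `feature`, `r`, `strong` per feature.
#' @export
lifespan_correlation <- function(m, lifespan, diet, strong_threshold = 0.75) {
  stopifnot(inherits(m, "trajectory_matrix"))
  curve <- lifespan[lifespan$diet == diet, ]
  if (!nrow(curve)) abort(paste0("no survivorship curve for diet '", diet, "'."))
  if (min(m$ages) > max(curve$day) || max(m$ages) < min(curve$day)) {
    abort("sampled ages fall outside the survivorship curve's support.")
  }
  surv <- approx(curve$day, curve$fraction_alive, xout = m$ages, rule = 2)$y
  v <- m$values[[diet]]
  if (sd(surv) <= 1e-12) abort("survivorship is constant over the sampled ages.")
  sz <- (surv - mean(surv)) / sd(surv)
  vz <- row_zscore(v)
  r <- as.vector(vz %*% sz) / (length(surv) - 1)
  tibble(feature = rownames(v), r = r, strong = abs(r) > strong_threshold)
}

#' Intra- and inter-diet fold changes
#'
#' Orientation-free fold changes on the raw intensity scale: per diet, the
#' ratio of the maximum to the minimum replicate-averaged level across ages
#' (intradiet amplitude); between diets, the ratio of the larger
#' lifespan-averaged mean level to the smaller, with the twofold flag used
#' to split heatmap panels.
#'
#' @param m An unscaled `trajectory_matrix` built with
#'   `transform = "identity"` (strictly positive values).
#' @return A tibble per feature: `intra_<diet>` ratios, `interdiet_ratio`,
#'   `above_twofold`.
#' @export
fold_changes <- function(m) {
  stopifnot(inherits(m, "trajectory_matrix"))
  if (m$scaling != "none" || m$transform != "identity") {
    abort("fold changes need an unscaled, identity-transform trajectory matrix.")
  }
  if (any(vapply(m$values, function(v) any(v <= 0), logical(1)))) {
    abort("nonpositive trajectory values; exclude zero-containing features first.")
  }
  intra <- lapply(m$values, function(v) {
    apply(v, 1, max) / apply(v, 1, min)
  })
  life_means <- vapply(m$values, rowMeans, numeric(length(m$features)))
  life_means <- matrix(life_means, ncol = length(m$values))
  inter <- pmax(life_means[, 1] / life_means[, 2],
                life_means[, 2] / life_means[, 1])
  out <- tibble(feature = m$features)
  for (d in names(m$values)) out[[paste0("intra_", d)]] <- unname(intra[[d]])
  out$interdiet_ratio <- inter
  out$above_twofold <- inter > 2
  out
}
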