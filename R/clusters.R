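#' Complete-linkage hierarchical trajectory clusters
#'
#' Agglomerative clustering of feature trajectories with complete linkage on
#' Euclidean distances, cut into exactly `k` groups (the semantics of
#' cutting a hierarchical tree into k rectangles; an optional k-means mode
#' is provided for comparison). The input is typically the across-diet
#' scaled concatenated trajectory matrix, so clusters group features by
#' shape and inter-diet level pattern simultaneously.
#'
#' @param m A `trajectory_matrix` (scaled recommended) or a plain numeric
#'   matrix of feature rows.
#' @param k Number of clusters (default 12).
#' @param method `"hclust"` (complete linkage, default) or `"kmeans"`.
#' @return An object of class `cluster_set`: list with `assignments`
#'   (tibble `feature`, `cluster`), `k`, `method`, `tree` (the `hclust`
#'   object, `NULL` for k-means), and `matrix` (the clustered input rows).
#' @export
hierarchical_clusters <- function(m, k = 12, method = c("hclust", "kmeans")) {
  method <- arg_match(method)
  mat <- if (inherits(m, "trajectory_matrix")) do.call(cbind, m$values) else m
  if (!is.matrix(mat)) abort("`m` must be a trajectory_matrix or a matrix.")
  if (k > nrow(mat)) abort("k exceeds the number of features.")
  if (k < 1) abort("k must be >= 1.")
  if (method == "hclust") {
    tree <- hclust(dist(mat, method = "euclidean"), method = "complete")
    cl <- cutree(tree, k = k)
  } else {
    tree <- NULL
    cl <- kmeans(mat, centers = k, nstart = 10)$cluster
  }
  structure(
    list(assignments = tibble(feature = rownames(mat), cluster = unname(cl)),
         k = k, method = method, tree = tree, matrix = mat),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  cat(sprintf("<cluster_set> %d features in %d clusters (%s); sizes: %s\n",
              nrow(x$assignments), x$k, x$method,
              paste(as.integer(sizes), collapse = ", ")))
  invisible(x)
}

#' Tidy cluster assignments
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @return The assignment tibble (`feature`, `cluster`).
#' @method tidy cluster_set
#' @export
tidy.cluster_set <- function(x, ...) x$assignments

#' Per-cluster summary
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @return A tibble with one row per cluster: size and (when
#'   [classify_diet_dependence()] has been run) the dependence class.
#' @method glance cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  out <- count(x$assignments, .data$cluster, name = "n_features")
  if (!is.null(x$dependence)) {
    out <- left_join(out, x$dependence[, c("cluster", "class")], by = "cluster")
  }
  out
}

cluster_members <- function(cs, cluster) {
  f <- cs$assignments$feature[cs$assignments$cluster == cluster]
  if (!length(f)) abort(paste0("cluster ", cluster, " is empty."))
  f
}

#' Mean trajectory of each cluster
#'
#' Unweighted mean of member-feature trajectories per age and diet.
#'
#' @param cs A `cluster_set`.
#' @param m A `trajectory_matrix` covering the clustered features.
#' @return A tibble `cluster`, `diet`, `age_days`, `mean_value`, `n_features`.
#' @export
cluster_mean_trajectory <- function(cs, m) {
  stopifnot(inherits(cs, "cluster_set"), inherits(m, "trajectory_matrix"))
  missing_f <- setdiff(cs$assignments$feature, m$features)
  if (length(missing_f)) abort("trajectory matrix does not cover all clustered features.")
  list_rbind(lapply(sort(unique(cs$assignments$cluster)), function(cl) {
    members <- cluster_members(cs, cl)
    list_rbind(imap(m$values, function(v, d) {
      tibble(cluster = cl, diet = d, age_days = m$ages,
             mean_value = colMeans(v[members, , drop = FALSE]),
             n_features = length(members))
    }))
  }))
}

# Yuen-style one-sample trimmed t-test: robust to a minority of member
# features that do not share the cluster's inter-diet behaviour.
trimmed_t_pvalue <- function(x, trim = 0.2) {
  n <- length(x)
  g <- floor(trim * n)
  if (n - 2 * g < 3) {            # too small to trim: plain t
    if (sd(x) <= 1e-12) return(if (abs(mean(x)) > 1e-12) 0 else 1)
    return(t.test(x)$p.value)
  }
  xs <- sort(x)
  mt <- mean(xs[(g + 1):(n - g)])
  win <- c(rep(xs[g + 1], g), xs[(g + 1):(n - g)], rep(xs[n - g], g))
  s2w <- var(win)
  h <- n - 2 * g
  if (s2w <= 1e-24) return(if (abs(mt) > 1e-12) 0 else 1)
  tt <- mt / (sqrt(s2w) / ((1 - 2 * trim) * sqrt(n)))
  2 * pt(-abs(tt), df = h - 1)
}

# per-feature inter-diet differences of replicate means (features x ages),
# optionally centered per age by the median over all given features so that
# common-mode shifts (e.g. residual normalization noise shared by every
# feature) do not register as cluster-level diet effects.
interdiet_differences <- function(t, features, diets, center = TRUE) {
  m <- log10(t$intensities[features, , drop = FALSE])
  ages <- sort(unique(t$samples$age_days))
  d <- vapply(ages, function(a) {
    per_diet <- lapply(diets, function(dd) {
      sel <- t$samples$diet == dd & t$samples$age_days == a
      rowMeans(m[, sel, drop = FALSE])
    })
    per_diet[[2]] - per_diet[[1]]
  }, numeric(length(features)))
  d <- matrix(d, nrow = length(features),
              dimnames = list(features, paste0("age_", ages)))
  if (center && length(features) > 1) {
    d <- sweep(d, 2, apply(d, 2, median), "-")
  }
  d
}

# per-age inter-diet tests for one cluster's member features.
# units = "replicate": two-sample t-test across replicates on a per-sample
# summary over member features (df = 2(s - 1)). The default summary is the
# per-sample median, which tracks the cluster's consensus trajectory and is
# insensitive to a minority of members that do not share it; replicates are
# the test units, so sample-level technical variation is correctly part of
# the error term. Also the fallback for singleton clusters.
cluster_age_pvalues <- function(t, members, diets, units, summary = "median") {
  m <- log10(t$intensities[members, , drop = FALSE])
  ages <- sort(unique(t$samples$age_days))
  sumfun <- if (summary == "median") {
    function(x) apply(x, 2, median)
  } else colMeans
  vapply(ages, function(a) {
    per_diet <- lapply(diets, function(d) {
      sel <- t$samples$diet == d & t$samples$age_days == a
      m[, sel, drop = FALSE]
    })
    x <- sumfun(per_diet[[1]]); y <- sumfun(per_diet[[2]])
    if (length(x) < 2 || length(y) < 2) abort("need >= 2 replicates per age.")
    if (sd(c(x - mean(x), y - mean(y))) <= 1e-12) {
      return(if (abs(mean(x) - mean(y)) > 1e-12) 0 else 1)
    }
    t.test(x, y)$p.value
  }, numeric(1))
}

#' Classify clusters as diet-independent, progressive, or intermittent
#'
#' For each cluster, inter-diet differences are tested age by age on the
#' member features' log10 intensities; a cluster whose difference is
#' significant at every age is `progressive` (a persistent diet effect), at
#' some but not all ages `intermittent` (e.g. a remodeling delay that opens
#' and closes a gap), and at no age `independent`.
#'
#' By default the per-age test is a two-sample t-test on the member
#' features' mean log10 intensity per replicate (3 values per diet at each
#' age), which stays valid when replicates share sample-level technical
#' variation, and the per-age p-values are Holm-adjusted within each
#' cluster before calling significance, keeping the per-cluster false-flag
#' rate at `alpha` (unadjusted per-age tests would spuriously flag about a
#' third of truly diet-independent clusters). `units = "feature"` instead
#' runs a trimmed one-sample t-test across member features on their
#' per-feature inter-diet differences (median-centered per age to discount
#' common-mode shifts); it is more powerful for subtle effects but assumes
#' feature-level independence.
#'
#' @param cs A `cluster_set`.
#' @param t The [feature_table()] with replicate-level data.
#' @param alpha Per-cluster significance level (default 0.05).
#' @param granularity `"cluster"` (classify clusters, default) or
#'   `"feature"` (classify each feature by its own replicate-level tests).
#' @param units For cluster granularity: `"replicate"` (member-feature
#'   means per replicate, default) or `"feature"` (trimmed test across
#'   member features).
#' @param p_adjust Multiplicity adjustment across ages within a cluster
#'   (any [stats::p.adjust()] method; default `"holm"`).
#' @return The `cluster_set` with a `dependence` tibble attached
#'   (`cluster`, `class`, `n_significant_ages`, `n_ages`) and, for feature
#'   granularity, a `feature_dependence` tibble.
#' @export
classify_diet_dependence <- function(cs, t, alpha = 0.05,
                                     granularity = c("cluster", "feature"),
                                     units = c("replicate", "feature"),
                                     p_adjust = "holm") {
  stopifnot(inherits(cs, "cluster_set"), inherits(t, "feature_table"))
  granularity <- arg_match(granularity)
  units <- arg_match(units)
  diets <- unique(t$samples$diet)
  if (length(diets) != 2) abort("diet-dependence classification needs exactly 2 diets.")
  classify_p <- function(p) {
    p <- stats::p.adjust(p, method = p_adjust)
    sig <- p < alpha
    cls <- if (all(sig)) "progressive" else if (any(sig)) "intermittent" else "independent"
    list(class = cls, n_sig = sum(sig), n = length(sig))
  }
  clusters <- sort(unique(cs$assignments$cluster))
  if (granularity == "cluster") {
    diffs <- if (units == "feature") {
      interdiet_differences(t, cs$assignments$feature, diets)
    } else NULL
    rows <- lapply(clusters, function(cl) {
      members <- cluster_members(cs, cl)
      p <- if (units == "feature" && length(members) >= 2) {
        apply(diffs[members, , drop = FALSE], 2, trimmed_t_pvalue)
      } else {
        cluster_age_pvalues(t, members, diets, units)
      }
      r <- classify_p(p)
      tibble(cluster = cl, class = r$class,
             n_significant_ages = r$n_sig, n_ages = r$n)
    })
    cs$dependence <- list_rbind(rows)
  } else {
    rows <- lapply(cs$assignments$feature, function(f) {
      r <- classify_p(cluster_age_pvalues(t, f, diets, units = "replicate"))
      tibble(feature = f, class = r$class,
             n_significant_ages = r$n_sig, n_ages = r$n)
    })
    cs$feature_dependence <- list_rbind(rows)
    maj <- cs$feature_dependence |>
      left_join(cs$assignments, by = "feature") |>
      group_by(.data$cluster) |>
      summarise(class = names(sort(table(.data$class), decreasing = TRUE))[1],
                n_significant_ages = NA_integer_,
                n_ages = NA_integer_, .groups = "drop")
    cs$dependence <- maj
  }
  cs
}

#' Feature-weighted frequencies of diet-dependence classes
#'
#' @param cs A classified `cluster_set` (see [classify_diet_dependence()]).
#' @return A tibble `class`, `n_features`, `fraction`; fractions sum to 1.
#' @export
dependence_frequencies <- function(cs) {
  if (is.null(cs$dependence)) abort("run classify_diet_dependence() first.")
  joined <- left_join(cs$assignments, cs$dependence[, c("cluster", "class")],
                      by = "cluster")
  out <- count(joined, .data$class, name = "n_features")
  all_classes <- tibble(class = c("independent", "progressive", "intermittent"))
  out <- left_join(all_classes, out, by = "class")
  out$n_features[is.na(out$n_features)] <- 0L
  out$fraction <- out$n_features / sum(out$n_features)
  out
}

#' Z-score replicate-level feature rows within or across diets
#'
#' Replicate-level analogue of [scale_trajectories()]: each feature's log10
#' intensities are z-scored over the samples of each diet separately
#' (`within_diet`) or over all samples jointly (`across_diets`). The result
#' feeds the sample-space principal component analysis, where every
#' replicate is an observation.
#'
#' @param t A [feature_table()] with strictly positive intensities for the
#'   requested features.
#' @param features Feature ids to include (default all).
#' @param mode `"within_diet"` or `"across_diets"`.
#' @return A features x samples matrix of scaled log10 intensities;
#'   constant rows are dropped.
#' @export
scale_feature_matrix <- function(t, features = NULL,
                                 mode = c("within_diet", "across_diets")) {
  stopifnot(inherits(t, "feature_table"))
  mode <- arg_match(mode)
  features <- features %||% feature_ids(t)
  m <- t$intensities[features, , drop = FALSE]
  if (any(m == 0)) abort("scaling requires strictly positive intensities.")
  m <- log10(m)
  if (mode == "across_diets") {
    keep <- apply(m, 1, sd) > 1e-12
    return(row_zscore(m[keep, , drop = FALSE]))
  }
  diets <- unique(t$samples$diet)
  sds <- vapply(diets, function(d) {
    apply(m[, t$samples$diet == d, drop = FALSE], 1, sd)
  }, numeric(nrow(m)))
  keep <- apply(matrix(sds, nrow = nrow(m)), 1, min) > 1e-12
  m <- m[keep, , drop = FALSE]
  for (d in diets) {
    sel <- t$samples$diet == d
    m[, sel] <- row_zscore(m[, sel, drop = FALSE])
  }
  m
}

#' Principal component projection of samples
#'
#' PCA of a feature-scaled matrix with samples as observations. The sign of
#' each component is fixed so that its first nonzero loading is positive,
#' making scores reproducible across feature orderings.
#'
#' @param m A `trajectory_matrix` (columns become observations), or a plain
#'   features x samples matrix.
#' @param n_components Number of components to return.
#' @return A list of class `pca_projection`: `scores` (tibble with one row
#'   per sample and `PC*` columns), `explained_variance` (ratios), and
#'   `loadings`.
#' @export
pca_project <- function(m, n_components = 2) {
  mat <- if (inherits(m, "trajectory_matrix")) do.call(cbind, m$values) else m
  if (!is.matrix(mat)) abort("`m` must be a trajectory_matrix or a matrix.")
  if (nrow(mat) < 2 || ncol(mat) < 2) abort("need at least 2 features and 2 samples.")
  x <- t(mat)                      # samples as observations
  if (all(abs(x - mean(x)) < 1e-14)) abort("degenerate (rank 0) input.")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    nz <- which(abs(rot[, j]) > 1e-12)[1]
    if (!is.na(nz) && rot[nz, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = as_tibble(scores, rownames = "sample"),
         explained_variance = ev[seq_len(n_components)],
         loadings = rot),
    class = "pca_projection"
  )
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("<pca_projection> %d samples, variance explained: %s\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")))
  invisible(x)
}
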