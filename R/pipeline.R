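#' Assemble a full-analysis run configuration
#'
#' A single configuration drives the whole pipeline: either a synthetic
#' study (via a [generator_config()]) or paths to a feature table, sample
#' metadata, and survivorship TSVs, plus the stage parameters. With a fixed
#' seed the run is fully deterministic.
#'
#' @param generator A [generator_config()], or `NULL` to read input files.
#' @param feature_path,metadata_path,survivorship_path Input TSV paths
#'   (used when `generator` is `NULL`).
#' @param internal_standards Feature ids used for normalization (for
#'   generated studies the generator's spike-ins are used automatically).
#' @param total_signal Normalize each sample to its total signal.
#' @param alpha Screen significance threshold (0.0014 for metabolite
#'   matrices; 0.0013 is the transcript-matrix convention).
#' @param auto_calibrate Calibrate the threshold at the error-rate knee
#'   instead of using `alpha`.
#' @param n_perm Permutations for the concordance test.
#' @param k Number of trajectory clusters.
#' @param classify_alpha Per-cluster significance level for diet-dependence
#'   classification.
#' @param strong_r Absolute-correlation threshold flagging
#'   lifespan-correlated trajectories.
#' @param seed Run seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       feature_path = NULL, metadata_path = NULL,
                       survivorship_path = NULL,
                       internal_standards = character(),
                       total_signal = TRUE,
                       alpha = 0.0014, auto_calibrate = FALSE,
                       n_perm = 1999, k = 12, classify_alpha = 0.05,
                       strong_r = 0.75, seed = 1) {
  cfg <- as.list(environment())
  if (is.null(generator) &&
      (is.null(feature_path) || is.null(metadata_path))) {
    abort("either a generator config or feature/metadata paths are required.")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `generator` mapping
#' mirrors [generator_config()] fields.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$generator)) {
    gen <- raw$generator
    for (f in c("plateau_age", "mean_lifespan")) {
      if (!is.null(gen[[f]])) gen[[f]] <- unlist(gen[[f]])
    }
    raw$generator <- do.call(generator_config, gen)
  }
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  s <- yaml::as.yaml(lapply(unclass(cfg), function(x) {
    if (inherits(x, "generator_config")) unclass(x) else x
  }))
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

stage_msg <- function(...) message("[metaboaging] ", sprintf(...))

#' Run the full remodeling analysis
#'
#' Executes the stages in dependency order: data (generate or read),
#' normalization, detection-diversity analysis with plateau estimation and
#' survival statistics, the per-feature age-association screen with
#' cross-diet overlap, trajectory concordance and fold-change analytics on
#' the overlapping features, trajectory clustering with diet-dependence
#' classification, and remodeling-delay curves. Per-stage feature counts are
#' logged via [message()].
#'
#' @param cfg A [run_config()].
#' @return A list of class `report_bundle`; see [write_report_bundle()] for
#'   the table families it contains.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))

  ## ---- stage: data ---------------------------------------------------
  if (!is.null(cfg$generator)) {
    study <- generate_study(cfg$generator, seed = cfg$seed)
    t_raw <- study$table
    lifespan <- study$lifespan
    death_times <- study$death_times
    standards <- study$internal_standards
    truth <- study$truth
  } else {
    study <- NULL; truth <- NULL; death_times <- NULL
    t_raw <- read_feature_table(cfg$feature_path, cfg$metadata_path)
    lifespan <- if (!is.null(cfg$survivorship_path)) {
      read_survivorship(cfg$survivorship_path)
    } else NULL
    standards <- cfg$internal_standards
  }
  diets <- unique(t_raw$samples$diet)
  stage_msg("data: %d features x %d samples, diets: %s",
            nrow(t_raw$intensities), ncol(t_raw$intensities),
            paste(diets, collapse = ", "))

  ## ---- stage: normalization -----------------------------------------
  t_norm <- normalize_intensities(t_raw, internal_standard_ids = standards,
                                  total_signal = cfg$total_signal)
  assay <- setdiff(feature_ids(t_norm), standards)
  t_assay <- feature_table(t_norm$intensities[assay, , drop = FALSE],
                           t_norm$samples, normalized = TRUE)
  stage_msg("normalize: %d standards, %d assayed features",
            length(standards), length(assay))

  ## ---- stage: diversity + survival ----------------------------------
  diversity <- diversity_analysis(t_raw)
  survival_stats <- NULL
  if (!is.null(death_times)) {
    means <- map_dbl(death_times, mean_lifespan)
    lr <- log_rank_test(death_times[[1]], death_times[[2]])
    survival_stats <- tibble(
      diet = names(means), mean_lifespan = unname(means),
      log_rank_chisq = lr$statistic, log_rank_p = lr$p_value
    )
  }
  stage_msg("diversity: plateau estimates %s",
            paste(sprintf("%s=%.1f", diversity$summary$diet,
                          diversity$summary$plateau_age), collapse = ", "))

  ## ---- stage: age-association screen --------------------------------
  screen <- age_assoc_screen(t_assay, alpha = cfg$alpha,
                             auto_calibrate = cfg$auto_calibrate,
                             diets = diets)
  gl <- glance(screen)
  stage_msg("screen: %s",
            paste(sprintf("%s %d/%d significant", gl$diet, gl$n_significant,
                          gl$n_features), collapse = "; "))

  overlap_features <- if (!is.null(screen$overlap)) screen$overlap$both_features else character()
  bundle <- list(
    config = cfg, seed = cfg$seed, config_hash = config_hash(cfg),
    table_raw = t_raw, table_normalized = t_assay, truth = truth,
    diversity = diversity, lifespan = lifespan,
    survival_stats = survival_stats, screen = screen
  )

  ## ---- stages needing overlapping features --------------------------
  if (length(overlap_features) < 10) {
    stage_msg("trajectories: only %d overlapping features; concordance and clustering skipped",
              length(overlap_features))
    bundle$skipped <- "fewer than 10 overlapping age-associated features"
    class(bundle) <- "report_bundle"
    return(bundle)
  }

  m_log <- average_replicates(t_assay, features = overlap_features)
  m_raw <- average_replicates(t_assay, features = overlap_features,
                              transform = "identity")
  m_within <- scale_trajectories(m_log, "within_diet")
  m_across <- scale_trajectories(m_log, "across_diets")

  concordance <- permutation_concordance(m_log, n_perm = cfg$n_perm,
                                         seed = cfg$seed + 1L)
  life_corr <- if (!is.null(lifespan)) {
    list_rbind(lapply(diets, function(d) {
      mutate(lifespan_correlation(m_log, lifespan, d,
                                  strong_threshold = cfg$strong_r),
             diet = d, .before = 1)
    }))
  } else NULL
  folds <- fold_changes(m_raw)
  stage_msg("trajectories: %d overlapping features, median r = %.3f (p = %.4g), %.0f%% below twofold",
            length(overlap_features), concordance$observed_median_r,
            concordance$p_value, 100 * mean(!folds$above_twofold))

  k_use <- min(cfg$k, length(m_across$features))
  clusters <- hierarchical_clusters(m_across, k = k_use)
  clusters <- classify_diet_dependence(clusters, t_assay,
                                       alpha = cfg$classify_alpha)
  freqs <- dependence_frequencies(clusters)
  stage_msg("clusters: k = %d; dependence fractions %s", k_use,
            paste(sprintf("%s=%.2f", freqs$class, freqs$fraction), collapse = ", "))

  delay <- tryCatch(
    remodeling_delay_curves(clusters, t_assay),
    error = function(e) {
      stage_msg("delay curves unavailable: %s", conditionMessage(e))
      NULL
    }
  )

  bundle <- c(bundle, list(
    trajectories = m_log, trajectories_within = m_within,
    trajectories_across = m_across,
    concordance = concordance, lifespan_correlations = life_corr,
    fold_changes = folds, clusters = clusters,
    cluster_means = cluster_mean_trajectory(clusters, m_within),
    dependence_frequencies = freqs, delay = delay,
    pca_across = pca_project(
      scale_feature_matrix(t_assay, overlap_features, "across_diets")),
    pca_within = pca_project(
      scale_feature_matrix(t_assay, overlap_features, "within_diet"))
  ))
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> seed %s, config %s\n", format(x$seed), x$config_hash))
  gl <- glance(x$screen)
  cat(sprintf("  screen: %s\n",
              paste(sprintf("%s %d sig (%.1f%%)", gl$diet, gl$n_significant,
                            100 * gl$frac_significant), collapse = "; ")))
  if (!is.null(x$concordance)) {
    cat(sprintf("  concordance: median r = %.3f, p = %.4g\n",
                x$concordance$observed_median_r, x$concordance$p_value))
  }
  if (!is.null(x$dependence_frequencies)) {
    f <- x$dependence_frequencies
    cat("  dependence: ",
        paste(sprintf("%s %.0f%%", f$class, 100 * f$fraction), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Remodeling-delay curves and half-change delay metric
#'
#' Clusters are labelled increasing or decreasing by the sign of their net
#' change in the short-lived (first) diet. For each direction, member
#' features' replicate-level log10 intensities are z-scored per feature
#' within each diet and averaged into a global trajectory per diet; a
#' quadratic polynomial is fitted through the replicate points for the
#' displayed trend, and the delay metric compares the ages at which each
#' diet's mean trajectory (linearly interpolated between sampled ages, which
#' unlike a low-order polynomial does not distort the ramp-then-plateau
#' shape) attains half of the short-lived diet's total change. The metric is
#' reported over all clusters of a direction (`scope = "all"`), restricted
#' to diet-dependent clusters (`"diet_dependent"`), and to progressive
#' clusters only (`"progressive"`, the cleanest view of a pure time delay
#' since persistent level offsets vanish under per-feature scaling).
#'
#' @param cs A classified `cluster_set` (see [classify_diet_dependence()]).
#' @param t The normalized [feature_table()] with replicate-level data.
#' @return A list of class `delay_curves` with `points` (per-sample mean
#'   scaled values per direction and diet), `fits` (quadratic coefficients),
#'   and `metrics` (tibble: `direction`, `scope`, per-diet half-change ages,
#'   `delay_days`, `delay_ratio`).
#' @export
remodeling_delay_curves <- function(cs, t) {
  stopifnot(inherits(cs, "cluster_set"), inherits(t, "feature_table"))
  if (is.null(cs$dependence)) abort("run classify_diet_dependence() first.")
  diets <- unique(t$samples$diet)
  if (length(diets) != 2) abort("delay curves need exactly 2 diets.")

  ## direction of each cluster from the short-lived diet's mean trajectory
  m_log <- average_replicates(t, features = cs$assignments$feature)
  cm <- m_log$values[[diets[1]]]
  net <- vapply(sort(unique(cs$assignments$cluster)), function(cl) {
    members <- cluster_members(cs, cl)
    v <- colMeans(cm[members, , drop = FALSE])
    v[length(v)] - v[1]
  }, numeric(1))
  dir_of <- setNames(ifelse(net >= 0, "increasing", "decreasing"),
                     sort(unique(cs$assignments$cluster)))
  dep <- setNames(cs$dependence$class, cs$dependence$cluster)
  if (!any(dir_of == "increasing") || !any(dir_of == "decreasing")) {
    msg <- sprintf("only %s clusters present; the other direction's curve is unavailable",
                   unique(dir_of))
    stage_msg("%s", msg)
  }
  if (!length(dir_of)) abort("no clusters to label.")

  ages <- sort(unique(t$samples$age_days))
  grid <- seq(min(ages), max(ages), length.out = 400)
  points_rows <- list(); fit_rows <- list(); metric_rows <- list()

  for (direction in intersect(c("increasing", "decreasing"), unique(dir_of))) {
    for (scope in c("all", "diet_dependent", "progressive")) {
      cl_ids <- names(dir_of)[dir_of == direction]
      if (scope == "diet_dependent") {
        cl_ids <- cl_ids[dep[cl_ids] %in% c("progressive", "intermittent")]
      } else if (scope == "progressive") {
        cl_ids <- cl_ids[dep[cl_ids] %in% "progressive"]
      }
      if (!length(cl_ids)) next
      members <- cs$assignments$feature[cs$assignments$cluster %in% as.integer(cl_ids)]
      fits <- list(); halves <- numeric(0); totals <- numeric(0)
      age_means <- list()
      for (d in diets) {
        sel <- t$samples$diet == d
        x <- log10(t$intensities[members, sel, drop = FALSE])
        x <- row_zscore(x)
        mean_traj <- colMeans(x)
        age_s <- t$samples$age_days[sel]
        fits[[d]] <- fit_polynomial_trend(age_s, mean_traj, degree = 2)
        age_means[[d]] <- vapply(ages, function(a) mean(mean_traj[age_s == a]),
                                 numeric(1))
        if (scope == "all") {
          points_rows[[length(points_rows) + 1]] <- tibble(
            direction = direction, diet = d, age_days = age_s,
            mean_scaled = mean_traj
          )
        }
        totals[[d]] <- diff(range(age_means[[d]]))
      }
      ## age at which each diet's interpolated mean trajectory attains half
      ## the SHORT-LIVED diet's total change
      target_change <- totals[[diets[1]]] / 2
      for (d in diets) {
        y <- approx(ages, age_means[[d]], xout = grid)$y
        prog <- if (direction == "increasing") y - min(y) else max(y) - y
        reached <- which(prog >= target_change)
        halves[[d]] <- if (length(reached)) grid[min(reached)] else NA_real_
      }
      fit_rows[[length(fit_rows) + 1]] <- tibble(
        direction = direction, scope = scope, diet = diets,
        c0 = vapply(fits, function(f) f$coefficients[1], 1),
        c1 = vapply(fits, function(f) f$coefficients[2], 1),
        c2 = vapply(fits, function(f) f$coefficients[3], 1)
      )
      metric_rows[[length(metric_rows) + 1]] <- tibble(
        direction = direction, scope = scope,
        half_age_short = halves[[diets[1]]],
        half_age_long = halves[[diets[2]]],
        delay_days = halves[[diets[2]]] - halves[[diets[1]]],
        delay_ratio = halves[[diets[1]]] / halves[[diets[2]]]
      )
    }
  }
  if (!length(metric_rows)) abort("no increasing or decreasing clusters available.")
  structure(
    list(points = list_rbind(points_rows), fits = list_rbind(fit_rows),
         metrics = list_rbind(metric_rows)),
    class = "delay_curves"
  )
}

#' Write a report bundle as plain TSV tables
#'
#' Every table is written with a leading comment line carrying the run seed
#' and config hash; the resolved configuration is written alongside as YAML.
#'
#' @param bundle A `report_bundle` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# seed=%s config_hash=%s", format(bundle$seed),
                   bundle$config_hash)
  emit <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    path <- file.path(dir, paste0(name, ".tsv"))
    writeLines(stamp, path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  }
  emit(bundle$diversity$series, "diversity_series")
  emit(bundle$diversity$summary, "diversity_summary")
  emit(tidy(bundle$screen), "age_association")
  if (!is.null(bundle$screen$overlap)) {
    emit(bundle$screen$overlap$counts, "overlap_counts")
  }
  emit(bundle$survival_stats, "survival_stats")
  emit(bundle$lifespan, "lifespan")
  if (!is.null(bundle$concordance)) emit(glance(bundle$concordance), "concordance")
  if (!is.null(bundle$concordance)) emit(tidy(bundle$concordance), "trajectory_correlations")
  emit(bundle$lifespan_correlations, "lifespan_correlations")
  emit(bundle$fold_changes, "fold_changes")
  if (!is.null(bundle$clusters)) {
    emit(tidy(bundle$clusters), "cluster_assignments")
    emit(bundle$clusters$dependence, "cluster_dependence")
  }
  emit(bundle$cluster_means, "cluster_means")
  emit(bundle$dependence_frequencies, "dependence_frequencies")
  if (!is.null(bundle$delay)) emit(bundle$delay$metrics, "delay_metrics")
  cfg <- lapply(unclass(bundle$config), function(x) {
    if (inherits(x, "generator_config")) unclass(x) else x
  })
  cfg$seed_used <- bundle$seed
  cfg$config_hash <- bundle$config_hash
  yaml::write_yaml(cfg, file.path(dir, "run_config.yaml"))
  invisible(dir)
}
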