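#' Configuration for the synthetic study generator
#'
#' Bundles the design of the emulated two-diet lifespan metabolomics study:
#' a short-lived reference diet and a long-lived (dietary-restriction-like)
#' diet, 7 age groups with 3 replicate collections each, and a feature panel
#' in which a planted fraction of features change with age, a separate pool
#' of low-abundance "damage" features crosses the detection limit at
#' feature-specific onset ages, and everything else is flat. Defaults follow
#' the emulated study: 14% age-associated features, 62% of them
#' diet-independent, 76% below twofold between diets, 4-8 fold intradiet
#' amplitudes, mean lifespans 50.8 and 64.4 days.
#'
#' @param n_features Number of assayed (non-standard) features.
#' @param n_damage How many of `n_features` are detection-onset ("damage")
#'   features that start below the detection limit and surface with age.
#' @param frac_age_associated Fraction of `n_features` with planted
#'   age-associated intensity trajectories (always detected).
#' @param frac_diet_independent Fraction of age-associated features whose
#'   trajectories are identical in the two diets.
#' @param frac_interdiet_below_twofold Fraction of age-associated features
#'   whose lifespan-averaged levels differ by less than twofold between diets.
#' @param ages_days Sampling ages (days post-eclosion), strictly increasing.
#' @param n_replicates Replicate collections per age group (>= 2).
#' @param noise_sd_log10 Replicate noise standard deviation on the log10
#'   intensity scale.
#' @param lod Detection limit on the raw intensity scale; values below it are
#'   recorded as 0.
#' @param plateau_age Named vector: age (days) after which trajectories level
#'   off and no new detection onsets occur, per diet.
#' @param amplitude_log10 Range (log10 units) of intradiet trajectory
#'   amplitudes; the default `c(0.6, 0.9)` corresponds to 4-8 fold changes.
#' @param mean_lifespan Named vector of target mean lifespans (days) per
#'   diet; the ratio short/long is the remodeling delay factor applied to the
#'   long-lived diet's diet-dependent trajectories.
#' @param biomass_slope Per-day linear decline of total material per sample;
#'   intensities are multiplied by `1 - biomass_slope * age`.
#' @param gompertz_b Fixed Gompertz hazard growth rate used when calibrating
#'   survivorship to the target mean lifespans.
#' @param n_flies Cohort size per diet for the simulated lifespan assay.
#' @param frac_up,frac_down Fractions of age-associated features rising /
#'   falling monotonically (the remainder are mid-life reversals).
#' @param offset_above_twofold Range (log10) of the persistent inter-diet
#'   level offsets planted on progressive features (above the twofold line).
#' @param intermittent_bump Range (log10) of the transient mid-life offset
#'   planted on intermittent features in the long-lived diet.
#' @param intermittent_window Fractions of the pre-plateau window during
#'   which the transient offset is active.
#' @param baseline_assoc,baseline_flat Baseline log10-intensity ranges
#'   (relative to the detection limit) for age-associated/damage features
#'   (low-abundance) and for flat features.
#' @param n_internal_standards Spike-in standard features added to the table
#'   (constant level, small technical noise, no biomass decline).
#' @param seed Integer seed making the generated study reproducible.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_features = 2000,
                             n_damage = 300,
                             frac_age_associated = 0.14,
                             frac_diet_independent = 0.62,
                             frac_interdiet_below_twofold = 0.76,
                             ages_days = c(3, 10, 25, 40, 50, 60, 63),
                             n_replicates = 3,
                             noise_sd_log10 = 0.1,
                             lod = 1,
                             plateau_age = c(standard = 50, defined = 60),
                             amplitude_log10 = c(0.6, 0.9),
                             mean_lifespan = c(standard = 50.8, defined = 64.4),
                             biomass_slope = 0.003,
                             gompertz_b = 0.1,
                             n_flies = 250,
                             frac_up = 0.5,
                             frac_down = 0.4,
                             offset_above_twofold = c(0.50, 0.80),
                             intermittent_bump = c(0.55, 0.75),
                             intermittent_window = c(0.3, 0.8),
                             baseline_assoc = c(1.5, 2.5),
                             baseline_flat = c(-0.25, 4.5),
                             n_internal_standards = 3,
                             seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(frac_age_associated, frac_diet_independent,
             frac_interdiet_below_twofold, frac_up, frac_down)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1].")
  if (frac_up + frac_down > 1) abort("frac_up + frac_down must not exceed 1.")
  if (any(diff(ages_days) <= 0)) abort("`ages_days` must be strictly increasing.")
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  if (n_damage > n_features) abort("`n_damage` cannot exceed `n_features`.")
  if (lod <= 0) abort("`lod` must be positive.")
  if (length(mean_lifespan) != 2 || is.null(names(mean_lifespan))) {
    abort("`mean_lifespan` must be a named length-2 vector (short-lived diet first).")
  }
  cfg$diets <- names(mean_lifespan)
  class(cfg) <- "generator_config"
  cfg
}

#' Global-null generator configuration
#'
#' Convenience wrapper for calibration studies: no age-associated features,
#' no detection-onset features, and no biomass decline, so nothing in the
#' table carries any age effect. Near-limit flat features are retained so
#' detection counts still vary stochastically.
#'
#' @param n_features Number of features.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
null_config <- function(n_features = 2000, seed = 1, ...) {
  generator_config(n_features = n_features, n_damage = 0,
                   frac_age_associated = 0, biomass_slope = 0,
                   seed = seed, ...)
}

#' Remodeling delay factor of a configuration
#'
#' Ratio of the short-lived diet's mean lifespan to the long-lived diet's;
#' the long-lived diet's diet-dependent trajectories are the short-lived
#' templates played back at this fraction of chronological speed.
#'
#' @param cfg A `generator_config`.
#' @return A number in (0, 1].
#' @export
delay_factor <- function(cfg) {
  unname(cfg$mean_lifespan[1] / cfg$mean_lifespan[2])
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Mean log10-intensity trajectory template
#'
#' Evaluates the planted mean trajectory of one feature class at the sampled
#' ages. Time runs on the short-lived diet's clock: passing
#' `delay_factor < 1` evaluates the same template at `delay_factor * t`,
#' so the long-lived diet reaches any given fraction of its amplitude at
#' proportionally later ages (the remodeling delay).
#'
#' Classes: `flat` (constant), `monotone_up` / `monotone_down_early`
#' (linear rise/fall from the first age until `plateau_age`, constant
#' after), `midlife_reversal` (tent: out and back within the pre-plateau
#' window), `damage_onset` (starts below the detection limit and rises
#' through it near the onset age `onset`, levelling at `plateau_age`).
#'
#' @param class One of `"flat"`, `"monotone_up"`, `"monotone_down_early"`,
#'   `"midlife_reversal"`, `"damage_onset"`.
#' @param ages Increasing vector of ages (days).
#' @param first_age Age at which the ramp starts (default: the first
#'   sampled age); exposed so single ages can be evaluated consistently.
#' @param plateau_age Age at which change levels off (short-lived clock).
#' @param amplitude Total log10 change from baseline over the ramp.
#' @param baseline Log10 intensity at the first age.
#' @param delay_factor Time-compression factor (1 = reference diet).
#' @param onset Onset age for `damage_onset` features.
#' @param lod_log10 Log10 of the detection limit (for `damage_onset`).
#' @param onset_margin Log10 units below the limit at the onset age.
#' @param onset_slope Log10 units gained per day after onset.
#' @return Numeric vector of mean log10 intensities at `ages`.
#' @export
trajectory_template <- function(class, ages, plateau_age, amplitude = 0,
                                baseline = 0, delay_factor = 1, onset = NULL,
                                first_age = min(ages), lod_log10 = 0,
                                onset_margin = 0.15, onset_slope = 0.05) {
  if (any(diff(ages) <= 0)) abort("`ages` must be strictly increasing.")
  a1 <- first_age
  t_eff <- ages * delay_factor
  ramp <- clamp01((t_eff - a1) / (plateau_age - a1))
  switch(class,
    flat = rep(baseline, length(ages)),
    monotone_up = baseline + amplitude * ramp,
    monotone_down_early = baseline - amplitude * ramp,
    midlife_reversal = baseline + amplitude * (1 - abs(2 * ramp - 1)),
    damage_onset = {
      if (is.null(onset)) abort("`onset` is required for damage_onset features.")
      lod_log10 - onset_margin + onset_slope * (pmin(t_eff, plateau_age) - onset)
    },
    abort(paste0("unknown trajectory class '", class, "'."))
  )
}

# triangular (linearly tapering) onset density on [a1, plateau]: damage
# accrues fastest in early-mid life and saturates towards the plateau,
# giving the rise-then-level-off detection curve.
draw_onsets <- function(n, a1, plateau) {
  a1 + (plateau - a1) * (1 - sqrt(1 - runif(n)))
}

#' Generate a synthetic two-diet lifespan metabolomics study
#'
#' Builds a feature table (both diets in one table, diets distinguished in
#' the sample metadata), the ground-truth feature labels, and simulated
#' survivorship per diet. Intensities are
#' \eqn{10^{(\mathrm{template} + \mathrm{noise})} \times (1 - s\,t)} with
#' i.i.d. log10-normal replicate noise and a linear biomass decline, then
#' left-censored at the detection limit (values below `lod` become 0).
#'
#' @param cfg A [generator_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return A list of class `synthetic_study` with elements `table`
#'   ([feature_table()]), `truth` (tibble of planted labels), `lifespan`
#'   (tibble `diet`, `day`, `fraction_alive`), `death_times` (named list),
#'   `gompertz` (named list of calibrated parameters) and `config`.
#' @export
generate_study <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  seed <- if (is.null(seed)) cfg$seed else seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  ages <- cfg$ages_days
  a1 <- min(ages)
  l0 <- log10(cfg$lod)
  w <- delay_factor(cfg)
  diets <- cfg$diets
  plateau <- cfg$plateau_age

  ## ---- planted label bookkeeping -------------------------------------
  n_aa <- round(cfg$frac_age_associated * cfg$n_features)
  n_damage <- cfg$n_damage
  if (n_aa + n_damage > cfg$n_features) {
    abort("frac_age_associated and n_damage together exceed n_features.")
  }
  n_flat <- cfg$n_features - n_aa - n_damage

  n_indep <- round(cfg$frac_diet_independent * n_aa)
  n_prog <- round((1 - cfg$frac_interdiet_below_twofold) * n_aa)
  n_int <- n_aa - n_indep - n_prog
  if (n_int < 0) {
    abort("frac_diet_independent and frac_interdiet_below_twofold are inconsistent.")
  }

  dependence <- sample(rep(
    c("progressive", "intermittent", "independent"),
    c(n_prog, n_int, n_indep)
  ))
  n_up <- round(cfg$frac_up * n_aa)
  n_down <- round(cfg$frac_down * n_aa)
  shape <- sample(rep(
    c("monotone_up", "monotone_down_early", "midlife_reversal"),
    c(n_up, n_down, n_aa - n_up - n_down)
  ))

  feat_id <- sprintf("F%05d", seq_len(cfg$n_features))
  classes <- c(shape, rep("damage_onset", n_damage), rep("flat", n_flat))

  baseline <- c(
    runif(n_aa, l0 + cfg$baseline_assoc[1], l0 + cfg$baseline_assoc[2]),
    runif(n_damage, l0 + cfg$baseline_assoc[1], l0 + cfg$baseline_assoc[2]),
    runif(n_flat, l0 + cfg$baseline_flat[1], l0 + cfg$baseline_flat[2])
  )
  amplitude <- c(runif(n_aa, cfg$amplitude_log10[1], cfg$amplitude_log10[2]),
                 rep(0, n_damage + n_flat))

  offset <- rep(0, cfg$n_features)
  bump <- rep(0, cfg$n_features)
  if (n_aa) {
    is_prog <- dependence == "progressive"
    is_int <- dependence == "intermittent"
    offset[seq_len(n_aa)][is_prog] <-
      runif(sum(is_prog), cfg$offset_above_twofold[1], cfg$offset_above_twofold[2]) *
      sample(c(-1, 1), sum(is_prog), replace = TRUE)
    bump[seq_len(n_aa)][is_int] <-
      runif(sum(is_int), cfg$intermittent_bump[1], cfg$intermittent_bump[2]) *
      sample(c(-1, 1), sum(is_int), replace = TRUE)
  }

  onset_short <- rep(NA_real_, cfg$n_features)
  onset_long <- rep(NA_real_, cfg$n_features)
  if (n_damage) {
    idx <- n_aa + seq_len(n_damage)
    onset_short[idx] <- draw_onsets(n_damage, a1, plateau[[diets[1]]])
    onset_long[idx] <- a1 + (onset_short[idx] - a1) *
      (plateau[[diets[2]]] - a1) / (plateau[[diets[1]]] - a1)
  }

  dep_out <- rep(NA_character_, cfg$n_features)
  if (n_aa) dep_out[seq_len(n_aa)] <- dependence

  ## ---- template matrices per diet ------------------------------------
  template_for <- function(i, diet_idx) {
    cls <- classes[i]
    if (cls == "flat") {
      return(rep(baseline[i], length(ages)))
    }
    if (cls == "damage_onset") {
      onset <- if (diet_idx == 1) onset_short[i] else onset_long[i]
      return(trajectory_template("damage_onset", ages,
                                 plateau_age = plateau[[diets[diet_idx]]],
                                 onset = onset, lod_log10 = l0))
    }
    warp <- if (diet_idx == 1 || dep_out[i] == "independent") 1 else w
    tmpl <- trajectory_template(cls, ages, plateau_age = plateau[[diets[1]]],
                                amplitude = amplitude[i], baseline = baseline[i],
                                delay_factor = warp)
    if (diet_idx == 2) {
      tmpl <- tmpl + offset[i]
      if (bump[i] != 0) {
        win <- a1 + cfg$intermittent_window * (plateau[[diets[1]]] - a1)
        tmpl <- tmpl + bump[i] * (ages >= win[1] & ages <= win[2])
      }
    }
    tmpl
  }
  templates <- lapply(1:2, function(d) {
    t(vapply(seq_len(cfg$n_features), template_for, numeric(length(ages)),
             diet_idx = d))
  })

  ## ---- intensities ----------------------------------------------------
  n_is <- cfg$n_internal_standards
  is_id <- if (n_is) sprintf("IS_%d", seq_len(n_is)) else character()
  sample_age <- rep(ages, each = cfg$n_replicates)
  sample_rep <- rep(seq_len(cfg$n_replicates), times = length(ages))

  make_diet_block <- function(d) {
    tm <- templates[[d]][, rep(seq_along(ages), each = cfg$n_replicates), drop = FALSE]
    noise <- matrix(rnorm(length(tm), 0, cfg$noise_sd_log10), nrow = nrow(tm))
    biomass <- log10(1 - cfg$biomass_slope * sample_age)
    block <- 10^sweep(tm + noise, 2, biomass, "+")
    if (n_is) {
      is_block <- 10^(matrix(rnorm(n_is * ncol(tm), l0 + 3, 0.02), nrow = n_is))
      block <- rbind(block, is_block)
    }
    block[block < cfg$lod] <- 0
    colnames(block) <- sprintf("%s_d%02d_r%d", diets[d], sample_age, sample_rep)
    block
  }
  blocks <- lapply(1:2, make_diet_block)
  m <- do.call(cbind, blocks)
  rownames(m) <- c(feat_id, is_id)
  if (all(m == 0)) abort("detection limit censored the entire table; rescale the config.")

  samples <- tibble(
    sample = colnames(m),
    diet = rep(diets, each = length(sample_age)),
    age_days = rep(sample_age, 2),
    replicate = rep(sample_rep, 2)
  )
  tab <- feature_table(m, samples)

  truth <- tibble(
    feature = feat_id,
    class = classes,
    age_associated = c(rep(TRUE, n_aa), rep(FALSE, n_damage + n_flat)),
    dependence = dep_out,
    onset_short = onset_short,
    onset_long = onset_long,
    offset_log10 = offset,
    bump_log10 = bump,
    amplitude_log10 = amplitude,
    baseline_log10 = baseline,
    above_twofold = abs(offset) > log10(2)
  )
  if (n_is) {
    truth <- bind_rows(truth, tibble(
      feature = is_id, class = "internal_standard", age_associated = FALSE,
      dependence = NA_character_, onset_short = NA_real_, onset_long = NA_real_,
      offset_log10 = 0, bump_log10 = 0, amplitude_log10 = 0, baseline_log10 = l0 + 3,
      above_twofold = FALSE
    ))
  }

  ## ---- survivorship ---------------------------------------------------
  gomp <- lapply(seq_along(diets), function(d) {
    calibrate_gompertz(cfg$mean_lifespan[[diets[d]]], cfg$gompertz_b)
  })
  names(gomp) <- diets
  sims <- lapply(gomp, simulate_lifespan, n_flies = cfg$n_flies)
  lifespan <- list_rbind(imap(sims, function(s, d) {
    mutate(s$curve, diet = d, .before = 1)
  }))

  structure(
    list(table = tab, truth = truth, lifespan = lifespan,
         death_times = lapply(sims, `[[`, "death_times"),
         gompertz = gomp, internal_standards = is_id, config = cfg,
         seed = seed),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> seed %s\n", format(x$seed)))
  print(x$table)
  cat("  planted classes: ",
      paste(sprintf("%s=%d", names(table(x$truth$class)), table(x$truth$class)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
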