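# small deterministic fixtures used across tests

# feature table from a plain matrix; samples named d<diet>_a<age>_r<rep>
make_table <- function(m, ages, n_reps = NULL, diets = "standard",
                       normalized = FALSE) {
  n <- ncol(m)
  per_diet <- n / length(diets)
  if (is.null(n_reps)) n_reps <- per_diet / length(ages)
  meta <- do.call(rbind, lapply(diets, function(d) {
    data.frame(diet = d,
               age_days = rep(ages, each = n_reps),
               replicate = rep(seq_len(n_reps), times = length(ages)))
  }))
  meta$sample <- sprintf("%s_a%g_r%d", meta$diet, meta$age_days, meta$replicate)
  colnames(m) <- meta$sample
  if (is.null(rownames(m))) rownames(m) <- sprintf("F%03d", seq_len(nrow(m)))
  feature_table(m, meta, normalized = normalized)
}

# two-diet table whose diets carry identical values (plus optional offset on
# the second diet for selected rows)
make_two_diet_table <- function(base, ages, n_reps = 3, offset_rows = integer(),
                                offset = 0) {
  second <- base
  if (length(offset_rows)) second[offset_rows, ] <- second[offset_rows, ] * 10^offset
  make_table(cbind(base, second), ages, n_reps, diets = c("standard", "defined"))
}

# small default-structured generator config for fast tests
small_config <- function(seed = 1, ...) {
  defaults <- list(n_features = 400, n_damage = 60, n_flies = 100, seed = seed)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

run_small_study <- function(seed = 1, ...) {
  st <- generate_study(small_config(seed = seed, ...))
  t_norm <- normalize_intensities(st$table,
                                  internal_standard_ids = st$internal_standards)
  assay <- setdiff(feature_ids(t_norm), st$internal_standards)
  t_assay <- feature_table(t_norm$intensities[assay, , drop = FALSE],
                           t_norm$samples, normalized = TRUE)
  list(study = st, assay = t_assay)
}
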