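#' Construct a feature table
#'
#' A feature table couples an intensity matrix from untargeted LC-MS profiling
#' (features in rows, samples in columns) with the sample metadata describing
#' the study design: diet, age at collection, and replicate index. An
#' intensity of exactly 0 is the non-detection code: the feature fell below
#' the detection limit in that sample. Missing values are not allowed; the
#' detection semantics require explicit zeros.
#'
#' @param intensities Non-negative numeric matrix, features x samples, with
#'   unique rownames (feature ids) and colnames (sample ids).
#' @param samples Data frame with one row per sample column and columns
#'   `sample`, `diet`, `age_days`, `replicate`. Order need not match the
#'   matrix; it is aligned by `sample`.
#' @param normalized Logical flag recording whether [normalize_intensities()]
#'   has been applied.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `intensities` (matrix), `samples` (tibble, in matrix column order) and
#'   `normalized`.
#'
#' @examples
#' m <- matrix(c(0, 1, 2, 3, 4, 0), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("F", 1:3), c("s1", "s2")))
#' meta <- data.frame(sample = c("s1", "s2"), diet = "standard",
#'                    age_days = c(3, 10), replicate = 1)
#' feature_table(m, meta)
#' @export
feature_table <- function(intensities, samples, normalized = FALSE) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    abort("`intensities` must be a numeric matrix (features x samples).")
  }
  if (anyNA(intensities)) {
    abort("`intensities` contains missing values; non-detection must be coded as explicit 0.")
  }
  if (any(intensities < 0)) {
    abort("`intensities` contains negative values.")
  }
  if (is.null(rownames(intensities)) || anyDuplicated(rownames(intensities))) {
    abort("feature ids (rownames) must be present and unique.")
  }
  if (is.null(colnames(intensities)) || anyDuplicated(colnames(intensities))) {
    abort("sample ids (colnames) must be present and unique.")
  }
  samples <- as_tibble(samples)
  required <- c("sample", "diet", "age_days", "replicate")
  if (!all(required %in% names(samples))) {
    abort(paste0("`samples` must have columns: ", paste(required, collapse = ", "), "."))
  }
  missing_meta <- setdiff(colnames(intensities), samples$sample)
  if (length(missing_meta)) {
    abort(paste0("sample columns without metadata rows: ",
                 paste(head(missing_meta, 5), collapse = ", ")))
  }
  samples <- samples[match(colnames(intensities), samples$sample), , drop = FALSE]
  if (any(samples$age_days <= 0)) abort("`age_days` must be positive.")
  if (any(samples$replicate < 1)) abort("`replicate` must be >= 1.")
  key <- paste(samples$diet, samples$age_days, samples$replicate)
  if (anyDuplicated(key)) {
    abort("(diet, age_days, replicate) keys must be unique across samples.")
  }
  age_sets <- tapply(samples$age_days, samples$diet,
                     function(a) paste(sort(unique(a)), collapse = ","))
  if (length(unique(age_sets)) > 1) {
    abort("every diet must be sampled at the same set of ages.")
  }
  structure(
    list(intensities = intensities,
         samples = samples,
         normalized = isTRUE(normalized)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  n_zero <- sum(x$intensities == 0)
  cat(sprintf(
    "<feature_table> %d features x %d samples (%s)\n",
    nrow(x$intensities), ncol(x$intensities),
    if (x$normalized) "normalized" else "raw"
  ))
  cat(sprintf("  diets: %s | ages (d): %s | non-detects: %d (%.1f%%)\n",
              paste(unique(x$samples$diet), collapse = ", "),
              paste(sort(unique(x$samples$age_days)), collapse = ", "),
              n_zero, 100 * n_zero / length(x$intensities)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Feature ids of a table
#' @param t A [feature_table()].
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(t) rownames(t$intensities)

#' Tidy a feature table into long format
#'
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A tibble with columns `feature`, `sample`, `diet`, `age_days`,
#'   `replicate`, `intensity`, `detected`.
#' @method tidy feature_table
#' @export
tidy.feature_table <- function(x, ...) {
  long <- as_tibble(x$intensities, rownames = "feature")
  long <- pivot_longer(long, -"feature", names_to = "sample", values_to = "intensity")
  long <- left_join(long, x$samples, by = "sample")
  long$detected <- long$intensity > 0
  select(long, "feature", "sample", "diet", "age_days", "replicate",
         "intensity", "detected")
}

#' Subset a feature table to the samples of one diet
#' @param t A [feature_table()].
#' @param diet Diet label present in the sample metadata.
#' @return A [feature_table()] with only that diet's samples.
#' @export
filter_diet <- function(t, diet) {
  keep <- t$samples$diet == diet
  if (!any(keep)) abort(paste0("no samples for diet '", diet, "'."))
  feature_table(t$intensities[, keep, drop = FALSE],
                t$samples[keep, , drop = FALSE],
                normalized = t$normalized)
}

delim_of <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a feature table and its sample metadata from delimited text
#'
#' The feature matrix is tab-separated (comma accepted), with a header row of
#' sample names and the feature id in the first column. The metadata file has
#' columns `sample`, `diet`, `age_days`, `replicate`. Cells must be dense:
#' an absent value is an error, distinct from an explicit 0 (non-detected).
#'
#' @param path Path to the feature matrix file.
#' @param metadata_path Path to the sample metadata file.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, metadata_path) {
  mat_df <- readr::read_delim(path, delim = delim_of(path),
                              show_col_types = FALSE, progress = FALSE)
  if (ncol(mat_df) < 2) abort("feature matrix needs an id column and at least one sample column.")
  ids <- as.character(mat_df[[1]])
  if (anyDuplicated(ids)) abort("duplicate feature ids in feature matrix.")
  m <- as.matrix(mat_df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric cells in feature matrix.")
  if (anyNA(m)) abort("missing cells in feature matrix; non-detection must be written as 0.")
  rownames(m) <- ids
  meta <- readr::read_delim(metadata_path, delim = delim_of(metadata_path),
                            show_col_types = FALSE, progress = FALSE)
  feature_table(m, meta)
}

#' Write a feature table (and optionally its metadata) as TSV
#'
#' @param t A [feature_table()].
#' @param path Output path for the feature matrix.
#' @param metadata_path Optional output path for the sample metadata.
#' @return `t`, invisibly.
#' @export
write_feature_table <- function(t, path, metadata_path = NULL) {
  df <- as_tibble(t$intensities, rownames = "feature_id")
  readr::write_tsv(df, path)
  if (!is.null(metadata_path)) readr::write_tsv(t$samples, metadata_path)
  invisible(t)
}

#' Read a survivorship table
#'
#' @param path TSV/CSV with columns `diet`, `day`, `fraction_alive`.
#' @return A tibble validated for monotone non-increasing survivorship per diet.
#' @export
read_survivorship <- function(path) {
  s <- readr::read_delim(path, delim = delim_of(path),
                         show_col_types = FALSE, progress = FALSE)
  required <- c("diet", "day", "fraction_alive")
  if (!all(required %in% names(s))) {
    abort("survivorship file needs columns diet, day, fraction_alive.")
  }
  s <- arrange(as_tibble(s), .data$diet, .data$day)
  bad <- s |>
    group_by(.data$diet) |>
    summarise(ok = all(diff(.data$fraction_alive) <= 1e-12), .groups = "drop")
  if (!all(bad$ok)) abort("fraction_alive must be non-increasing within each diet.")
  if (any(s$fraction_alive < 0 | s$fraction_alive > 1)) {
    abort("fraction_alive must lie in [0, 1].")
  }
  s
}
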