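#' Normalize intensities to internal standards and/or total signal
#'
#' Mirrors the two-step normalization used for spike-in-controlled LC-MS
#' runs: each sample column is first divided by the mean intensity of that
#' sample's internal standards (if any are given), and then, if
#' `total_signal = TRUE`, by the column total remaining after the standard
#' division. Zeros (non-detections) are preserved exactly: normalization can
#' never create or destroy a detection.
#'
#' @param t A [feature_table()].
#' @param internal_standard_ids Character vector of feature ids used as
#'   spike-in standards; may be empty. Each standard must be detected
#'   (intensity > 0) in every sample.
#' @param total_signal Divide each sample by its (post-standard) total signal
#'   so columns sum to 1.
#' @return A [feature_table()] with `normalized = TRUE`.
#'
#' @examples
#' m <- matrix(c(2, 4, 4), ncol = 1, dimnames = list(paste0("F", 1:3), "s1"))
#' meta <- data.frame(sample = "s1", diet = "standard", age_days = 3, replicate = 1)
#' t <- feature_table(m, meta)
#' normalize_intensities(t, internal_standard_ids = "F1")$intensities
#' @export
normalize_intensities <- function(t, internal_standard_ids = character(),
                                  total_signal = TRUE) {
  stopifnot(inherits(t, "feature_table"))
  m <- t$intensities
  if (length(internal_standard_ids)) {
    missing_ids <- setdiff(internal_standard_ids, rownames(m))
    if (length(missing_ids)) {
      abort(paste0("internal standards absent from table: ",
                   paste(missing_ids, collapse = ", ")))
    }
    std <- m[internal_standard_ids, , drop = FALSE]
    if (any(std == 0)) {
      abort("internal standard non-detected (intensity 0) in at least one sample.")
    }
    m <- sweep(m, 2, colMeans(std), "/")
  }
  if (total_signal) {
    tot <- colSums(m)
    if (any(tot == 0)) abort("a sample has zero total signal; cannot normalize.")
    m <- sweep(m, 2, tot, "/")
  }
  feature_table(m, t$samples, normalized = TRUE)
}

#' Display transform for censored intensities
#'
#' Replaces non-detected values (exact zeros) by a small pseudo-intensity and
#' log10-transforms, for visualization of detection-censored tables (heatmaps
#' of near-limit features). Not intended for statistics: the screen excludes
#' zero-containing features instead of imputing them.
#'
#' @param t A [feature_table()].
#' @param pseudo Positive replacement for zeros (default `1e-5`).
#' @return A numeric matrix of log10 intensities.
#' @export
log_display_transform <- function(t, pseudo = 1e-5) {
  stopifnot(inherits(t, "feature_table"))
  if (!is.numeric(pseudo) || length(pseudo) != 1 || pseudo <= 0) {
    abort("`pseudo` must be a single positive number.")
  }
  m <- t$intensities
  m[m == 0] <- pseudo
  log10(m)
}
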