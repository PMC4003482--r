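# independent oracles shared across test files

# definitional repeated-measures sums of squares, written with explicit loops
rm_anova_oracle <- function(m) {
  a <- nrow(m); s <- ncol(m); gm <- mean(m)
  ss_age <- ss_subj <- ss_tot <- 0
  for (i in seq_len(a)) ss_age <- ss_age + s * (mean(m[i, ]) - gm)^2
  for (j in seq_len(s)) ss_subj <- ss_subj + a * (mean(m[, j]) - gm)^2
  for (i in seq_len(a)) for (j in seq_len(s)) ss_tot <- ss_tot + (m[i, j] - gm)^2
  ss_res <- ss_tot - ss_age - ss_subj
  f <- (ss_age / (a - 1)) / (ss_res / ((a - 1) * (s - 1)))
  list(f = f, p = pf(f, a - 1, (a - 1) * (s - 1), lower.tail = FALSE))
}

# naive O(n^3) complete-linkage agglomeration returning merge heights
complete_linkage_oracle <- function(mat) {
  groups <- as.list(seq_len(nrow(mat)))
  d <- as.matrix(dist(mat))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(groups)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[groups[[i]], groups[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    groups[[bj]] <- c(groups[[bj]], groups[[bi]])
    groups[[bi]] <- NULL
  }
  heights
}
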