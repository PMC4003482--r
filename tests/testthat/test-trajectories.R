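two_diet_fixture <- function(n = 20, seed = 1, offset_rows = integer(),
                             offset = 0) {
  set.seed(seed)
  ages <- c(3, 10, 25, 40, 50)
  base <- 10^matrix(rnorm(n * length(ages) * 3, mean = 2, sd = 0.4),
                    nrow = n)
  make_two_diet_table(base, ages, n_reps = 3, offset_rows = offset_rows,
                      offset = offset)
}

test_that("replicate averaging is the arithmetic mean per age", {
  m <- matrix(10^c(1, 2, 3, 1, 1, 1), nrow = 1)
  t0 <- make_table(m, ages = c(3, 10), n_reps = 3)
  avg <- average_replicates(t0)
  expect_equal(unname(avg$values$standard[1, ]), c(2, 1))
  avg_raw <- average_replicates(t0, transform = "identity")
  expect_equal(unname(avg_raw$values$standard[1, ]), c(mean(c(10, 100, 1000)), 10))
})

test_that("scaling produces exact z-scores and is idempotent", {
  t0 <- two_diet_fixture(n = 12, seed = 3)
  avg <- average_replicates(t0)
  w <- scale_trajectories(avg, "within_diet")
  for (d in names(w$values)) {
    expect_equal(unname(rowMeans(w$values[[d]])), rep(0, 12), tolerance = 1e-12)
    expect_equal(unname(apply(w$values[[d]], 1, sd)), rep(1, 12), tolerance = 1e-12)
  }
  w_again <- w
  w_again$scaling <- "none"
  w2 <- scale_trajectories(w_again, "within_diet")
  for (d in names(w$values)) {
    expect_equal(w2$values[[d]], w$values[[d]], tolerance = 1e-12)
  }
  # correlations are invariant to within-diet scaling
  r0 <- diet_pair_correlations(avg)
  r1 <- diet_pair_correlations(w)
  expect_equal(r1$r, r0$r, tolerance = 1e-12)
})

test_that("within-diet scaling removes level offsets, across-diet scaling keeps them", {
  t0 <- two_diet_fixture(n = 6, seed = 4, offset_rows = 1:6, offset = 0.5)
  avg <- average_replicates(t0)
  w <- scale_trajectories(avg, "within_diet")
  expect_equal(w$values[[1]], w$values[[2]], tolerance = 1e-12)
  a <- scale_trajectories(avg, "across_diets")
  m1 <- rowMeans(a$values[[1]]); m2 <- rowMeans(a$values[[2]])
  expect_true(all(m2 > m1))
  expect_equal(unname(m1 + m2), rep(0, 6), tolerance = 1e-12)
  # simple row example
  expect_equal(unname(metaboaging:::row_zscore(matrix(1:3, 1))[1, ]),
               c(-1, 0, 1))
})

test_that("constant rows are excluded from scaling with a flag", {
  m <- rbind(10^c(1, 2, 3, 1, 2, 3), rep(7, 6))
  t0 <- make_table(m, ages = c(3, 10, 25), n_reps = 2)
  avg <- average_replicates(t0)
  sc <- scale_trajectories(avg, "within_diet")
  expect_equal(sc$excluded, "F002")
  expect_equal(length(sc$features), 1)
})

test_that("diet-pair correlations reproduce hand-computed Pearson values", {
  ages <- c(3, 10, 25, 40)
  base <- 10^rbind(c(1, 2, 3, 4), c(5, 4, 3, 2), c(1, 2, 4, 3))
  second <- 10^rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(1, 2, 3, 4))
  t0 <- make_table(cbind(base, second), ages, n_reps = 1,
                   diets = c("standard", "defined"))
  avg <- average_replicates(t0)
  r <- diet_pair_correlations(avg)
  expect_equal(r$r[1], 1)                      # identical
  expect_equal(r$r[2], -1)                     # negated slope
  expect_equal(r$r[3], 0.8, tolerance = 1e-12) # hand value
  expect_equal(attr(r, "median_r"), 0.8, tolerance = 1e-12)
})

test_that("identical diets give the smallest attainable permutation p-value", {
  set.seed(11)
  ages <- c(3, 10, 25, 40, 50, 60, 63)
  base <- 10^matrix(rnorm(50 * 21, 2, 0.5), nrow = 50)
  t0 <- make_two_diet_table(base, ages, n_reps = 3)
  avg <- average_replicates(t0)
  res <- permutation_concordance(avg, n_perm = 999, seed = 2)
  expect_equal(res$observed_median_r, 1)
  expect_equal(res$p_value, 1 / 1000)
})

test_that("exhaustive enumeration matches hand-computed pairings", {
  set.seed(12)
  ages <- c(3, 10, 25, 40)
  base <- 10^matrix(rnorm(2 * 12, 2, 0.5), nrow = 2)
  t0 <- make_two_diet_table(base, ages, n_reps = 3)
  avg <- average_replicates(t0)
  ex <- permutation_concordance(avg, exact = TRUE)
  expect_equal(ex$n_perm, 2)          # two pairings of two features
  # hand enumeration: identity pairing and the swap
  a <- avg$values[[1]]; b <- avg$values[[2]]
  medians <- c(median(c(cor(a[1, ], b[1, ]), cor(a[2, ], b[2, ]))),
               median(c(cor(a[1, ], b[2, ]), cor(a[2, ], b[1, ]))))
  expect_equal(sort(ex$null_medians), sort(medians), tolerance = 1e-10)
  expect_equal(ex$p_value, mean(medians >= ex$observed_median_r - 1e-12))
  expect_error(permutation_concordance(avg, n_perm = 99), ">= 10 matched")
})

test_that("re-paired (null) trajectories give unremarkable concordance", {
  set.seed(13)
  ages <- c(3, 10, 25, 40, 50)
  a <- 10^matrix(rnorm(40 * 15, 2, 0.5), nrow = 40)
  b <- a[sample(40), ]
  rownames(b) <- NULL
  t0 <- make_table(cbind(a, b), ages, n_reps = 3,
                   diets = c("standard", "defined"))
  avg <- average_replicates(t0)
  res <- permutation_concordance(avg, n_perm = 499, seed = 3)
  expect_gt(res$p_value, 0.05)
})

test_that("lifespan correlations flag survivorship-tracking trajectories", {
  ages <- c(3, 10, 25, 40, 50)
  curve <- tibble::tibble(diet = "standard", day = 0:60,
                          fraction_alive = seq(1, 0, length.out = 61))
  surv_at <- approx(curve$day, curve$fraction_alive, xout = ages)$y
  base <- rbind(10^surv_at, 10^(1 - surv_at))
  t0 <- make_table(matrix(rep(base, each = 1), nrow = 2), ages, n_reps = 1)
  avg <- average_replicates(t0)
  r <- lifespan_correlation(avg, curve, "standard")
  expect_equal(r$r, c(1, -1), tolerance = 1e-10)
  expect_true(all(r$strong))
})

test_that("rising planted features correlate negatively with survivorship", {
  fix <- run_small_study(seed = 91)
  truth <- fix$study$truth
  ups <- truth$feature[truth$class == "monotone_up"]
  avg <- average_replicates(fix$assay, features = ups)
  r <- lifespan_correlation(avg, fix$study$lifespan, "standard")
  expect_gt(mean(r$r < -0.75), 0.8)
})

test_that("fold changes are orientation-free ratios with a twofold flag", {
  ages <- c(3, 10, 25)
  base <- rbind(c(2, 4, 8), c(3, 3, 3))
  second <- rbind(c(2, 4, 8), c(7, 7, 7))
  t0 <- make_table(cbind(matrix(rep(base, each = 1), nrow = 2),
                         matrix(rep(second, each = 1), nrow = 2)),
                   ages, n_reps = 1, diets = c("standard", "defined"))
  avg <- average_replicates(t0, transform = "identity")
  fc <- fold_changes(avg)
  expect_equal(fc$intra_standard[1], 4)
  expect_equal(fc$interdiet_ratio[1], 1)
  expect_false(fc$above_twofold[1])
  expect_equal(fc$interdiet_ratio[2], 7 / 3, tolerance = 1e-12)
  expect_true(fc$above_twofold[2])
})
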