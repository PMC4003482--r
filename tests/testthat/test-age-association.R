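test_that("hand-computed repeated-measures examples are reproduced", {
  exact <- matrix(c(1, 2, 2, 3, 3, 4), nrow = 3, byrow = TRUE)
  res <- rm_anova_feature(exact)
  expect_equal(unname(res$ss["age"]), 4)
  expect_equal(unname(res$ss["subject"]), 1.5)
  expect_equal(unname(res$ss["residual"]), 0)
  expect_identical(res$statistic, Inf)
  expect_identical(res$p_value, 0)

  noisy <- matrix(c(1, 2, 2, 3, 4, 3), nrow = 3, byrow = TRUE)
  res2 <- rm_anova_feature(noisy)
  expect_equal(res2$statistic, 3, tolerance = 1e-12)
  expect_equal(res2$p_value, 0.25, tolerance = 1e-12)
  expect_equal(res2$p_value, 1 / (1 + res2$statistic), tolerance = 1e-12)

  const <- matrix(5, 3, 2)
  res3 <- rm_anova_feature(const)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
})

test_that("the F statistic matches a brute-force oracle on 100 random 4x3 matrices", {
  set.seed(123)
  for (i in 1:100) {
    m <- matrix(rnorm(12), 4, 3)
    mine <- rm_anova_feature(m)
    ora <- rm_anova_oracle(m)
    expect_equal(mine$statistic, ora$f, tolerance = 1e-8)
    expect_equal(mine$p_value, ora$p, tolerance = 1e-8)
  }
})

test_that("the within-subject model agrees with aov's Error-stratum table", {
  set.seed(5)
  m <- matrix(rnorm(21, sd = 2), 7, 3)
  d <- data.frame(y = as.vector(m),
                  age = factor(rep(seq_len(7), 3)),
                  subj = factor(rep(seq_len(3), each = 7)))
  fit <- summary(aov(y ~ age + Error(subj), data = d))
  tab <- fit[["Error: Within"]][[1]]
  mine <- rm_anova_feature(m)
  expect_equal(mine$statistic, tab["age", "F value"], tolerance = 1e-8)
  expect_equal(mine$p_value, tab["age", "Pr(>F)"], tolerance = 1e-8)
})

test_that("zero-containing features are routed out of the screen, not tested", {
  set.seed(1)
  m <- matrix(10^rnorm(5 * 6, mean = 2, sd = 0.2), nrow = 5)
  m[2, 4] <- 0
  t0 <- make_table(m, ages = c(3, 10, 25), n_reps = 2)
  res <- rm_anova_table(t0, "standard")
  expect_false(res$eligible[2])
  expect_true(is.na(res$p_value[2]))
  expect_false(res$significant[2])
  expect_true(all(res$eligible[-2]))
})

test_that("an all-constant eligible table yields p = 1 everywhere", {
  m <- matrix(2, nrow = 3, ncol = 6,
              dimnames = list(paste0("F", 1:3), NULL))
  t0 <- make_table(m, ages = c(3, 10, 25), n_reps = 2)
  res <- rm_anova_table(t0, "standard")
  expect_true(all(res$p_value == 1))
})

test_that("plug-in FDR matches its closed form and degenerates gracefully", {
  p <- c(rep(0.005, 10), seq(0.02, 1, length.out = 90))
  expect_equal(plug_in_fdr(p, 0.01), 0.01 * 100 / 10)
  expect_equal(plug_in_fdr(rep(0.001, 50), 0.01), 0.01)
  expect_true(is.na(plug_in_fdr(seq(0.5, 1, length.out = 20), 0.01)))
  # monotone non-increasing in the number of discoveries at fixed alpha, m
  fdr_many <- plug_in_fdr(c(rep(1e-4, 40), runif(60, 0.2, 1)), 0.01)
  fdr_few <- plug_in_fdr(c(rep(1e-4, 5), runif(95, 0.2, 1)), 0.01)
  expect_lt(fdr_many, fdr_few)
})

test_that("threshold calibration caps on null input and separates a signal mixture", {
  set.seed(2)
  null_p <- runif(5000)
  cal <- calibrate_threshold(null_p)
  expect_true(cal$no_signal)
  expect_equal(cal$alpha, 0.05)

  mix <- c(10^runif(500, -12, -8), runif(4500))
  cal2 <- calibrate_threshold(mix)
  expect_false(cal2$no_signal)
  expect_gt(cal2$alpha, max(mix[mix < 1e-7]))
  expect_lt(cal2$alpha, 0.02)
  # the chosen threshold recovers essentially the planted signal set
  expect_equal(sum(mix <= cal2$alpha), 500, tolerance = 25)

  # adding even stronger signals barely moves the knee
  mix3 <- c(mix, rep(1e-10, 100))
  cal3 <- calibrate_threshold(mix3)
  grid_step <- diff(log10(cal2$grid$alpha[1:2]))
  expect_lt(abs(log10(cal3$alpha) - log10(cal2$alpha)), 3 * grid_step + 1e-9)
  expect_error(calibrate_threshold(runif(50)), "100")
})

test_that("diet overlap counts and labels are consistent", {
  mk <- function(sig) tibble::tibble(
    feature = paste0("F", seq_along(sig)), diet = "x",
    eligible = TRUE, statistic = 1, p_value = 0.5, significant = sig
  )
  same <- diet_overlap(mk(c(TRUE, TRUE, FALSE)), mk(c(TRUE, TRUE, FALSE)))
  expect_equal(unlist(same$counts), c(a_only = 0L, both = 2L, b_only = 0L))
  disj <- diet_overlap(mk(c(rep(TRUE, 3), rep(FALSE, 4))),
                       mk(c(rep(FALSE, 3), rep(TRUE, 4))))
  expect_equal(unlist(disj$counts), c(a_only = 3L, both = 0L, b_only = 4L))
  expect_error(diet_overlap(mk(TRUE), mk(c(TRUE, FALSE))), "universe")
})

test_that("planted shared features land in the cross-diet overlap", {
  hits <- vapply(1:5, function(seed) {
    fix <- run_small_study(seed = 60 + seed)
    scr <- age_assoc_screen(fix$assay)
    truth <- fix$study$truth
    shared <- truth$feature[truth$age_associated]
    mean(shared %in% scr$overlap$both_features)
  }, numeric(1))
  expect_true(all(hits >= 0.9))
})

test_that("screen summaries report per-diet counts and the overlap", {
  fix <- run_small_study(seed = 77)
  scr <- age_assoc_screen(fix$assay)
  gl <- glance(scr)
  expect_equal(nrow(gl), 2)
  expect_true(all(gl$n_significant <= gl$n_eligible))
  expect_equal(gl$n_overlap[1], length(scr$overlap$both_features))
  td <- tidy(scr)
  expect_equal(nrow(td), 2 * nrow(fix$assay$intensities))
})
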