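test_that("complete-linkage merges match exhaustive enumeration on small matrices", {
  set.seed(21)
  for (i in 1:5) {
    mat <- matrix(rnorm(6 * 4), nrow = 6,
                  dimnames = list(paste0("F", 1:6), NULL))
    cs <- hierarchical_clusters(mat, k = 2)
    expect_equal(sort(cs$tree$height), sort(complete_linkage_oracle(mat)),
                 tolerance = 1e-10)
  }
})

test_that("degenerate cuts behave: singletons at k = n, perfect split for two groups", {
  mat <- matrix(rnorm(5 * 3), nrow = 5, dimnames = list(paste0("F", 1:5), NULL))
  cs <- hierarchical_clusters(mat, k = 5)
  expect_equal(sort(unique(cs$assignments$cluster)), 1:5)
  two <- rbind(matrix(1, 3, 4), matrix(-1, 3, 4)) +
    matrix(rnorm(24, sd = 1e-3), 6, 4)
  rownames(two) <- paste0("F", 1:6)
  cs2 <- hierarchical_clusters(two, k = 2)
  expect_equal(length(unique(cs2$assignments$cluster[1:3])), 1)
  expect_equal(length(unique(cs2$assignments$cluster[4:6])), 1)
  expect_error(hierarchical_clusters(two, k = 10), "exceeds")
})

test_that("cluster assignments are invariant to row permutation up to relabeling", {
  set.seed(22)
  mat <- matrix(rnorm(30 * 5), nrow = 30, dimnames = list(sprintf("F%02d", 1:30), NULL))
  cs <- hierarchical_clusters(mat, k = 4)
  perm <- sample(30)
  cs_p <- hierarchical_clusters(mat[perm, ], k = 4)
  a <- cs$assignments$cluster[match(cs_p$assignments$feature, cs$assignments$feature)]
  b <- cs_p$assignments$cluster
  expect_equal(length(unique(paste(a, b))), 4)   # a bijection of labels
})

test_that("cluster mean trajectories equal hand means, mirrors cancel, singletons pass through", {
  ages <- c(3, 10, 25)
  vals <- 10^rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1), c(2, 2, 2))
  t0 <- make_two_diet_table(vals, ages, n_reps = 1)
  avg <- average_replicates(t0)
  cs <- list(assignments = tibble::tibble(feature = paste0("F00", 1:4),
                                          cluster = c(1L, 1L, 1L, 2L)),
             k = 2)
  class(cs) <- "cluster_set"
  cm <- cluster_mean_trajectory(cs, avg)
  c1 <- cm$mean_value[cm$cluster == 1 & cm$diet == "standard"]
  expect_equal(c1, colMeans(avg$values$standard[1:3, ]), ignore_attr = TRUE)
  c2 <- cm$mean_value[cm$cluster == 2 & cm$diet == "standard"]
  expect_equal(c2, avg$values$standard[4, ], ignore_attr = TRUE)
  # mirror-image members cancel after scaling
  sc <- scale_trajectories(avg, "within_diet")
  mirror <- list(assignments = tibble::tibble(feature = c("F001", "F003"),
                                              cluster = c(1L, 1L)), k = 1)
  class(mirror) <- "cluster_set"
  cm2 <- cluster_mean_trajectory(mirror, sc)
  expect_equal(unname(cm2$mean_value), rep(0, 6), tolerance = 1e-12)
})

test_that("diet-dependence classes follow the planted contrast structure", {
  set.seed(23)
  ages <- c(3, 10, 25, 40, 50)
  base <- 10^(matrix(rep(seq(1, 2, length.out = 5), each = 3), nrow = 8,
                     ncol = 15, byrow = TRUE) +
                matrix(rnorm(8 * 15, 0, 0.02), 8))
  # rows 1-3 identical across diets; 4-6 constant offset; 7-8 offset at one age
  second <- base
  second[4:6, ] <- second[4:6, ] * 10^0.6
  one_age <- rep(c(3, 10, 25, 40, 50), each = 3) == 25
  second[7:8, one_age] <- second[7:8, one_age] * 10^0.7
  t0 <- make_table(cbind(base, second), ages, n_reps = 3,
                   diets = c("standard", "defined"))
  cs <- list(assignments = tibble::tibble(feature = sprintf("F%03d", 1:8),
                                          cluster = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L)),
             k = 3)
  class(cs) <- "cluster_set"
  cs <- classify_diet_dependence(cs, t0)
  expect_equal(cs$dependence$class, c("independent", "progressive", "intermittent"))
  fr <- dependence_frequencies(cs)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$n_features[fr$class == "independent"], 3L)
})

test_that("raising a persistent offset never demotes a progressive cluster", {
  set.seed(24)
  ages <- c(3, 10, 25, 40)
  base <- 10^matrix(rnorm(6 * 12, 2, 0.05), nrow = 6)
  classify_offset <- function(delta) {
    t0 <- make_two_diet_table(base, ages, n_reps = 3,
                              offset_rows = 1:6, offset = delta)
    cs <- list(assignments = tibble::tibble(feature = sprintf("F%03d", 1:6),
                                            cluster = rep(1L, 6)), k = 1)
    class(cs) <- "cluster_set"
    classify_diet_dependence(cs, t0)$dependence$class
  }
  expect_equal(classify_offset(0.5), "progressive")
  expect_equal(classify_offset(1.0), "progressive")
})

test_that("feature granularity classifies each feature by its own tests", {
  set.seed(25)
  ages <- c(3, 10, 25, 40)
  base <- 10^matrix(rnorm(4 * 12, 2, 0.03), nrow = 4)
  t0 <- make_two_diet_table(base, ages, n_reps = 3,
                            offset_rows = 1:2, offset = 0.8)
  cs <- list(assignments = tibble::tibble(feature = sprintf("F%03d", 1:4),
                                          cluster = rep(1L, 4)), k = 1)
  class(cs) <- "cluster_set"
  cs <- classify_diet_dependence(cs, t0, granularity = "feature")
  expect_equal(cs$feature_dependence$class[1:2], rep("progressive", 2))
  expect_equal(cs$feature_dependence$class[3:4], rep("independent", 2))
})

test_that("dependence frequencies recover the planted diet-independent fraction", {
  fracs <- vapply(1:6, function(seed) {
    fix <- run_small_study(seed = 100 + seed, n_features = 1000,
                           n_damage = 150)
    scr <- age_assoc_screen(fix$assay)
    m <- average_replicates(fix$assay, features = scr$overlap$both_features)
    cs <- hierarchical_clusters(scale_trajectories(m, "across_diets"), k = 12)
    cs <- classify_diet_dependence(cs, fix$assay)
    fr <- dependence_frequencies(cs)
    fr$fraction[fr$class == "independent"]
  }, numeric(1))
  expect_equal(mean(fracs), 0.62, tolerance = 0.06)
})

test_that("PCA behaves on degenerate and structured inputs", {
  # two perfectly correlated features: one component carries all variance
  m <- rbind(seq(1, 5), 2 * seq(1, 5) + 3)
  rownames(m) <- c("F1", "F2")
  colnames(m) <- paste0("s", 1:5)
  p <- pca_project(m)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(pca_project(matrix(1, 3, 4)), "degenerate")
  # scores invariant (up to machine error) to feature order
  set.seed(26)
  m2 <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("F", 1:8), paste0("s", 1:5)))
  p1 <- pca_project(m2)
  p2 <- pca_project(m2[sample(8), ])
  expect_equal(p1$scores$PC1, p2$scores$PC1, tolerance = 1e-9)
})

test_that("dual scaling separates diets versus ages in sample space", {
  skip_if_not_installed("cluster")
  fix <- run_small_study(seed = 31, n_features = 1000, n_damage = 150)
  scr <- age_assoc_screen(fix$assay)
  m <- average_replicates(fix$assay, features = scr$overlap$both_features)
  samples <- fix$assay$samples
  diet_f <- as.integer(factor(samples$diet))
  age_f <- as.integer(factor(samples$age_days))

  sil <- function(scores, grouping) {
    mean(cluster::silhouette(grouping, dist(scores))[, "sil_width"])
  }
  ov <- scr$overlap$both_features
  # across-diet scaling: some leading component linearly separates the diets
  pa <- pca_project(scale_feature_matrix(fix$assay, ov, "across_diets"),
                    n_components = 2)
  best_diet <- max(sil(pa$scores$PC1, diet_f), sil(pa$scores$PC2, diet_f))
  best_age <- max(sil(pa$scores$PC1, age_f), sil(pa$scores$PC2, age_f))
  expect_gt(best_diet, best_age)

  # within-diet scaling: the first component orders samples by age per diet
  pw <- pca_project(scale_feature_matrix(fix$assay, ov, "within_diet"),
                    n_components = 2)
  for (d in unique(samples$diet)) {
    sel <- samples$diet == d
    rho <- cor(pw$scores$PC1[sel], samples$age_days[sel], method = "spearman")
    expect_gt(abs(rho), 0.8)
  }
})
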