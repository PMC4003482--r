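test_that("trajectory templates have the planted shapes", {
  ages <- c(3, 10, 25, 40, 50, 60, 63)
  flat <- trajectory_template("flat", ages, plateau_age = 50, baseline = 2)
  expect_equal(flat, rep(2, 7))
  up <- trajectory_template("monotone_up", ages, plateau_age = 50,
                            amplitude = 1, baseline = 0)
  expect_true(all(diff(up[1:5]) > 0))
  expect_equal(up[5:7], rep(up[5], 3))
  down <- trajectory_template("monotone_down_early", ages, plateau_age = 50,
                              amplitude = 1, baseline = 0)
  expect_equal(down, -up)
  rev <- trajectory_template("midlife_reversal", ages, plateau_age = 50,
                             amplitude = 1, baseline = 0)
  expect_equal(rev[1], rev[5])
  expect_gt(max(rev), rev[1])
  expect_error(trajectory_template("wiggle", ages, 50), "unknown")
})

test_that("the delay factor is an exact time warp of the reference template", {
  w <- 50.8 / 64.4
  for (x in c(0.2, 0.5, 0.9)) {
    ref <- trajectory_template("monotone_up", 50.8 * x, plateau_age = 50,
                               amplitude = 1, first_age = 3)
    delayed <- trajectory_template("monotone_up", 64.4 * x, plateau_age = 50,
                                   amplitude = 1, delay_factor = w,
                                   first_age = 3)
    expect_equal(delayed, ref, tolerance = 1e-12)
  }
})

test_that("delayed trajectories attain any amplitude fraction strictly later", {
  w <- 50.8 / 64.4
  grid <- seq(3, 120, by = 0.01)
  ref <- trajectory_template("monotone_up", grid, plateau_age = 50, amplitude = 1)
  del <- trajectory_template("monotone_up", grid, plateau_age = 50,
                             amplitude = 1, delay_factor = w)
  for (q in c(0.25, 0.5, 0.75)) {
    expect_gt(grid[min(which(del >= q))], grid[min(which(ref >= q))])
  }
})

test_that("planted label counts follow the config fractions exactly", {
  cfg <- generator_config(n_features = 1000, n_damage = 100, seed = 3,
                          n_flies = 50)
  st <- generate_study(cfg)
  truth <- st$truth[st$truth$class != "internal_standard", ]
  expect_equal(nrow(truth), 1000)
  expect_equal(sum(truth$age_associated), 140)
  expect_equal(sum(truth$class == "damage_onset"), 100)
  dep <- table(truth$dependence)
  expect_equal(unname(dep["independent"]), round(0.62 * 140))
  expect_equal(unname(dep["progressive"]), round(0.24 * 140))
  expect_equal(sum(dep), 140)
  # labels partition the feature set
  expect_equal(sort(unique(truth$class)),
               sort(c("flat", "damage_onset", "monotone_up",
                      "monotone_down_early", "midlife_reversal")))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_study(small_config(seed = 9))
  b <- generate_study(small_config(seed = 9))
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$death_times, b$death_times)
  c <- generate_study(small_config(seed = 10))
  expect_false(identical(a$table$intensities, c$table$intensities))
})

test_that("raising the detection limit never increases any sample's detected count", {
  lo <- generate_study(small_config(seed = 4))
  hi <- generate_study(small_config(seed = 4, lod = 3))
  expect_true(all(count_detected(hi$table) <= count_detected(lo$table)))
})

test_that("detected counts rise with age and total signal declines", {
  for (seed in 1:5) {
    st <- generate_study(small_config(seed = seed))
    s <- diversity_series(st$table)
    for (d in unique(s$diet)) {
      sd_ <- s[s$diet == d, ]
      first <- sd_$detected_count[sd_$age_days == min(sd_$age_days)]
      last <- sd_$detected_count[sd_$age_days == max(sd_$age_days)]
      expect_true(all(last > max(first)))
      expect_lt(coef(lm(total_signal ~ age_days, data = sd_))[[2]], 0)
    }
  }
})

test_that("a null config produces a detection count flat in age", {
  slopes <- vapply(1:6, function(seed) {
    st <- generate_study(null_config(n_features = 500, seed = seed,
                                     n_flies = 50))
    s <- diversity_series(st$table)
    coef(lm(detected_count ~ age_days, data = s))[[2]]
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("inconsistent fraction settings are rejected", {
  expect_error(generator_config(frac_age_associated = 1.4), "fractions")
  expect_error(generator_config(ages_days = c(3, 3, 10)), "increasing")
  expect_error(generator_config(n_replicates = 1), "replicates")
  expect_error(generate_study(generator_config(
    frac_diet_independent = 0.9, frac_interdiet_below_twofold = 0.5,
    n_flies = 50)), "inconsistent")
})
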