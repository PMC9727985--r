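test_that("simulation is reproducible and balanced under both structures", {
  vc <- variance_components(1, 1, sigma2_e = 18)
  des <- design_config(groups_per_condition = 3, members_per_group = 4)
  d1 <- simulate_rm(des, vc, seed = 11)
  d2 <- simulate_rm(des, vc, seed = 11)
  expect_identical(d1, d2)
  expect_false(identical(d1$y, simulate_rm(des, vc, seed = 12)$y))
  expect_equal(nrow(d1), 2 * 3 * 4 * 5)
  expect_equal(as.vector(table(d1$group_id, d1$period)),
               rep(4L, 6 * 5), ignore_attr = TRUE)
  # cross-sectional member ids are disjoint across periods
  expect_true(all(table(d1$member_id) == 1))
  # cohort member ids identical across periods
  vcc <- variance_components(1, 1, 12.6, 0, 5.4, "RM", "cohort")
  desc <- design_config(groups_per_condition = 3, members_per_group = 4,
                        structure = "cohort")
  dc <- simulate_rm(desc, vcc, seed = 11)
  expect_true(all(table(dc$member_id) == 5))
  ids_by_period <- split(dc$member_id, dc$period)
  for (j in 2:5)
    expect_setequal(ids_by_period[[j]], ids_by_period[[1]])
})

test_that("all-zero variances and zero fixed effects give exactly zero", {
  vc0 <- variance_components(0, 0, sigma2_e = 0)
  des <- design_config(groups_per_condition = 2, members_per_group = 3)
  expect_true(all(simulate_rm(des, vc0, seed = 1)$y == 0))
  vc0r <- variance_components(0, 0, sigma2_e = 0, mechanism = "RC")
  expect_true(all(simulate_rc(des, vc0r, seed = 1)$y == 0))
})

test_that("degenerate RC structure is a pure group-slope line", {
  # only the group slope variance is nonzero: y = slope_k * t_j exactly
  vc <- variance_components(0, 1, sigma2_e = 0, mechanism = "RC")
  des <- design_config(groups_per_condition = 3, members_per_group = 2)
  d <- simulate_rc(des, vc, seed = 9)
  expect_true(all(d$y[d$period == 1] == 0))           # t = 0
  for (g in unique(d$group_id)) {
    sub <- d[d$group_id == g & d$time > 0, ]
    slopes <- sub$y / sub$time
    expect_lt(diff(range(slopes)), 1e-12)
  }
})

test_that("RC group-mean variance grows as sigma2_g + t^2 sigma2_tlg", {
  # with (1, 1) the residual-free variance at t = 4 is 17x that at t = 0
  vc <- variance_components(1, 1, sigma2_e = 0, mechanism = "RC")
  des <- design_config(groups_per_condition = 20, members_per_group = 1)
  v0 <- v4 <- numeric(150)
  for (r in 1:150) {
    d <- simulate_rc(des, vc, seed = 3000 + r)
    v0[r] <- var(d$y[d$period == 1])
    v4[r] <- var(d$y[d$period == 5])
  }
  expect_equal(mean(v4) / mean(v0), 17, tolerance = 0.15)
})

test_that("cohort lag covariance matches the random-effects algebra", {
  # same member across periods: cov = sigma2_g + sigma2_m = 13.6
  vc <- variance_components(1, 1, 12.6, 0, 5.4, "RM", "cohort")
  des <- design_config(groups_per_condition = 4, members_per_group = 10,
                       structure = "cohort")
  cc <- numeric(200)
  for (r in 1:200) {
    d <- simulate_rm(des, vc, seed = 5000 + r)
    ym <- matrix(d$y[order(d$member_id, d$period)], nrow = 5)
    cm <- cov(t(ym))
    cc[r] <- mean(cm[upper.tri(cm)])
  }
  se <- sd(cc) / sqrt(length(cc))
  expect_lt(abs(mean(cc) - 13.6), 3 * se + 0.2)
  # RC cohort: member-level covariance between periods 0 and 1 equals
  # sigma2_g + sigma2_m (slopes contribute t_j t_j' = 0)
  vcr <- variance_components(1, 1, 12.6, 1, 4.4, "RC", "cohort")
  cc2 <- numeric(200)
  for (r in 1:200) {
    d <- simulate_rc(des, vcr, seed = 7000 + r)
    ym <- matrix(d$y[order(d$member_id, d$period)], nrow = 5)
    cc2[r] <- cov(ym[1, ], ym[2, ])
  }
  se2 <- sd(cc2) / sqrt(length(cc2))
  expect_lt(abs(mean(cc2) - (1 + 12.6 + 1 * 0 * 1)), 3 * se2 + 0.2)
})

test_that("per-effect sample variances match their nominal values", {
  # >= 1e4 draws of each random effect via a wide design, one dataset
  vc <- variance_components(2, 3, sigma2_e = 5)
  des <- design_config(groups_per_condition = 2, members_per_group = 5500)
  d <- simulate_rm(des, vc, seed = 101)
  # within-cell residual variance
  cellkey <- interaction(d$group_id, d$period)
  dev <- d$y - ave(d$y, cellkey)
  n <- length(dev)
  s2e <- sum(dev^2) / (n - nlevels(cellkey))
  expect_lt(abs(s2e - 5) / (5 * sqrt(2 / n)), 3)
})

test_that("null generation is centered: condition difference near zero", {
  vc <- variance_components(1, 1, sigma2_e = 18)
  des <- design_config(groups_per_condition = 5, members_per_group = 10)
  diffs <- vapply(1:100, function(r) {
    d <- simulate_rm(des, vc, seed = 400 + r)
    mean(d$y[d$condition == 2]) - mean(d$y[d$condition == 1])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("nonzero fixed effects shift the cell means as specified", {
  vc0 <- variance_components(0, 0, sigma2_e = 0)
  des <- design_config(groups_per_condition = 2, members_per_group = 2)
  fx <- fixed_effects(mu = 1, condition = c(0, 2),
                      time = c(0, 1, 2, 3, 4),
                      interaction = cbind(0, c(0, 10, 20, 30, 40)))
  d <- simulate_rm(des, vc0, fx = fx, seed = 1)
  expect_equal(unique(d$y[d$period == 1 & d$condition == 1]), 1)
  expect_equal(unique(d$y[d$period == 3 & d$condition == 1]), 1 + 2)
  expect_equal(unique(d$y[d$period == 3 & d$condition == 2]), 1 + 2 + 2 + 20)
  # reference-level violations are rejected
  expect_error(simulate_rm(des, vc0, fx = fixed_effects(condition = c(1, 0)),
                           seed = 1), "C_1")
  # mechanism/structure mismatches are rejected
  expect_error(simulate_rm(des, variance_components(1, 1, sigma2_e = 1,
                                                    mechanism = "RC"),
                           seed = 1), "RM-mechanism")
  expect_error(simulate_rm(design_config(groups_per_condition = 2,
                                         members_per_group = 2,
                                         structure = "cohort"),
                           vc0, seed = 1), "cohort")
})

test_that("empirical moments recover the configured targets", {
  vc <- variance_components(1, 1, sigma2_e = 18)
  des <- design_config(groups_per_condition = 8, members_per_group = 20)
  ds <- lapply(1:120, function(r) simulate_rm(des, vc, seed = 800 + r))
  mo <- empirical_moments(ds)
  expect_lt(abs(mo$wpicc$estimate - 0.10), 3 * mo$wpicc$se)
  expect_lt(abs(mo$cac$estimate - 0.50), 3 * mo$cac$se)
  expect_true(is.na(mo$iac$estimate))
  # group-level variances zero -> WPICC estimate near zero
  vc0 <- variance_components(0, 0, sigma2_e = 5)
  ds0 <- lapply(1:80, function(r) simulate_rm(des, vc0, seed = 900 + r))
  mo0 <- empirical_moments(ds0)
  expect_lt(abs(mo0$wpicc$estimate), 3 * mo0$wpicc$se)
  # single group per condition is refused
  d1 <- simulate_rm(design_config(groups_per_condition = 1,
                                  members_per_group = 4), vc, seed = 2)
  expect_error(empirical_moments(d1), "two groups")
})
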