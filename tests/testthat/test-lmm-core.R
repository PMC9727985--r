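test_that("blocked REML log-likelihood equals the dense oracle", {
  dd <- small_cohort_data()
  dx <- small_cross_data()
  for (structure in c("cohort", "cross-sectional")) {
    d <- if (structure == "cohort") dd else dx
    for (mod in all_model_names(structure)) {
      spec <- make_spec(mod)
      ss <- build_matrices(d, spec)
      th <- pd_theta(ss)
      ev <- grtsim:::reml_eval(th, ss, "loglik")
      expect_false(is.null(ev))
      expect_equal(ev$loglik, dense_reml(d, spec, th), tolerance = 1e-6)
      # and at the REML optimum
      fit <- reml_fit(d, spec)
      expect_true(fit$converged)
      expect_equal(fit$reml_loglik,
                   dense_reml(d, spec, fit$vtheta_hat), tolerance = 1e-6)
    }
  }
})

test_that("the optimum dominates the dense oracle at random points", {
  d <- small_cohort_data(seed = 13)
  for (fam in c("rm_vc", "rc")) {
    spec <- make_spec(fam, structure = "cohort")
    ss <- build_matrices(d, spec)
    fit <- reml_fit(d, spec)
    expect_true(fit$converged)
    for (s in 1:10) {
      th <- pd_theta(ss, shift = s) * (0.6 + 0.1 * s)
      ev <- grtsim:::reml_eval(th, ss, "loglik")
      if (is.null(ev)) next
      expect_gte(fit$reml_loglik, ev$loglik - 1e-8)
    }
  }
})

test_that("REML reproduces balanced closed-form ANOVA estimators", {
  # one-period design, group intercept + residual
  d1 <- simulate_rm(design_config(n_periods = 1, groups_per_condition = 8,
                                  members_per_group = 6),
                    variance_components(1, 0, sigma2_e = 4), seed = 3)
  f <- reml_fit(d1, make_spec(analytic_model("rm_vc", timexgroup = FALSE)))
  a <- anova(lm(y ~ factor(condition) + factor(group_id),
                data = as.data.frame(d1)))
  msw <- a["Residuals", "Mean Sq"]
  msb <- a["factor(group_id)", "Mean Sq"]
  expect_equal(unname(f$vtheta_hat["sigma2_g"]), (msb - msw) / 6,
               tolerance = 1e-7)
  expect_equal(unname(f$vtheta_hat["sigma2_e"]), msw, tolerance = 1e-7)
  # residual-only model: sigma2_e = RSS / (n - rank X)
  dx <- small_cross_data()
  f0 <- reml_fit(dx, residual_only_spec())
  ols <- lm(y ~ factor(condition) * factor(period), data = as.data.frame(dx))
  expect_equal(unname(f0$vtheta_hat["sigma2_e"]),
               sum(resid(ols)^2) / df.residual(ols), tolerance = 1e-9)
  expect_equal(f0$reml_loglik, as.numeric(logLik(ols, REML = TRUE)),
               tolerance = 1e-8)
})

test_that("REML matches lme4 on a model both can fit", {
  library(lme4)
  vc <- variance_components(1, 1, sigma2_e = 18)
  d <- simulate_rm(design_config(groups_per_condition = 6,
                                 members_per_group = 10), vc, seed = 11)
  f <- reml_fit(d, make_spec("rm_vc"))
  df <- as.data.frame(d)
  df$period <- factor(df$period)
  df$condition <- factor(df$condition)
  lm4 <- lmer(y ~ condition * period + (1 | group_id) +
                (1 | group_id:period), data = df, REML = TRUE)
  expect_equal(f$reml_loglik, as.numeric(logLik(lm4)), tolerance = 1e-5)
  vcv <- as.data.frame(VarCorr(lm4))
  expect_equal(unname(f$vtheta_hat["sigma2_g"]),
               vcv$vcov[vcv$grp == "group_id"], tolerance = 1e-3)
  expect_equal(unname(f$vtheta_hat["sigma2_tg"]),
               vcv$vcov[vcv$grp == "group_id:period"], tolerance = 1e-3)
  expect_equal(unname(f$vtheta_hat["sigma2_e"]),
               vcv$vcov[vcv$grp == "Residual"], tolerance = 1e-3)
  expect_equal(unname(f$beta_hat), unname(fixef(lm4)), tolerance = 1e-4)
})

test_that("REML is invariant to a constant shift of the outcome", {
  d <- small_cross_data(seed = 19)
  spec <- make_spec("rm_vc")
  f1 <- reml_fit(d, spec)
  d2 <- d
  d2$y <- d$y + 100
  f2 <- reml_fit(d2, spec)
  expect_equal(f1$vtheta_hat, f2$vtheta_hat, tolerance = 1e-8)
  expect_equal(unname(f2$beta_hat["(Intercept)"] -
                        f1$beta_hat["(Intercept)"]), 100, tolerance = 1e-6)
  expect_equal(f1$beta_hat[-1], f2$beta_hat[-1], tolerance = 1e-6)
})

test_that("the returned betas are the GLS solution at theta-hat", {
  d <- small_cohort_data(seed = 23)
  spec <- make_spec("rc", structure = "cohort")
  fit <- reml_fit(d, spec)
  ss <- fit$ss
  # independent dense GLS recomputation
  design <- ss$design
  t <- ss$t
  m <- ss$m
  A <- matrix(0, t, t)
  B <- matrix(0, t, t)
  for (i in seq_along(ss$bases)) {
    if (!is.null(ss$bases[[i]]$A))
      A <- A + fit$vtheta_hat[i] * ss$bases[[i]]$A
    if (!is.null(ss$bases[[i]]$B))
      B <- B + fit$vtheta_hat[i] * ss$bases[[i]]$B
  }
  S1 <- m * A + B
  C <- matrix(0, ss$p, ss$p)
  rhs <- numeric(ss$p)
  for (g in seq_len(ss$G)) {
    Xg <- ss$Xt[[ss$cond[g]]]
    C <- C + m * t(Xg) %*% solve(S1, Xg)
    rhs <- rhs + m * t(Xg) %*% solve(S1, ss$ybar[, g])
  }
  expect_equal(unname(fit$beta_hat), unname(drop(solve(C, rhs))),
               tolerance = 1e-8)
  expect_equal(unname(fit$beta_cov), unname(solve(C)), tolerance = 1e-8)
})

test_that("unconstrained estimation lets a null variance straddle zero", {
  vc <- variance_components(1, 0, sigma2_e = 9)
  des <- design_config(groups_per_condition = 6, members_per_group = 8)
  est <- vapply(1:30, function(r) {
    d <- simulate_rm(des, vc, seed = 1300 + r)
    f <- reml_fit(d, make_spec("rm_vc"))
    unname(f$vtheta_hat["sigma2_tg"])
  }, numeric(1))
  expect_gt(sum(est < 0), 0)
  expect_gt(sum(est > 0), 0)
})

test_that("group-mean reduction is exact and guards its preconditions", {
  d <- small_cross_data(seed = 29)
  gm <- group_mean_reduce(d)
  expect_equal(nrow(gm), 6 * 3)              # c * g * t
  agg <- aggregate(y ~ group_id + period, data = as.data.frame(d), mean)
  key <- paste(gm$group_id, gm$period)
  expect_equal(gm$y, agg$y[match(key, paste(agg$group_id, agg$period))],
               tolerance = 1e-12)
  dconst <- d
  dconst$y <- 7
  expect_true(all(group_mean_reduce(dconst)$y == 7))
  dun <- d[-1, ]
  attr(dun, "design") <- attr(d, "design")
  class(dun) <- class(d)
  expect_error(group_mean_reduce(dun), "unequal")
})

test_that("group-mean and individual-level fits give equal p-values", {
  vc <- variance_components(1, 1, sigma2_e = 18)
  d <- simulate_rm(design_config(groups_per_condition = 4,
                                 members_per_group = 6), vc, seed = 21)
  for (fam in c("saturated", "rm_un")) {
    f_mean <- reml_fit(d, make_spec(fam))
    f_ind <- reml_fit(d, make_spec(fam, fitting_level = "individual"))
    expect_true(f_mean$converged && f_ind$converged)
    p_mean <- kr_adjust(f_mean)
    p_ind <- kr_adjust(f_ind)
    expect_equal(p_mean$p_value, p_ind$p_value, tolerance = 1e-8)
    expect_equal(p_mean$ddf, p_ind$ddf, tolerance = 1e-6)
  }
})

test_that("non-convergence yields a flagged result, not an error", {
  d <- small_cross_data(seed = 31)
  f <- reml_fit(d, make_spec("rm_vc"), control = list(max_iter = 0L))
  expect_s3_class(f, "grt_fit")
  expect_false(f$converged)
  expect_s3_class(kr_adjust(f), "interaction_test")
  expect_true(is.na(kr_adjust(f)$p_value))
})
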