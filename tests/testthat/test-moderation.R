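test_that("pearson_test matches the closed form and cor.test", {
  x <- c(1, 2, 4, 4.5, 7, 9.2)
  res <- pearson_test(x, 2 * x + 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  res_neg <- pearson_test(x, -x)
  expect_equal(res_neg$r, -1, tolerance = 1e-12)

  withr::with_seed(41, {
    a <- rnorm(30)
    b <- 0.4 * a + rnorm(30)
  })
  got <- pearson_test(a, b)
  want <- stats::cor.test(a, b)
  expect_equal(got$r, unname(want$estimate), tolerance = 1e-12)
  expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)

  expect_error(pearson_test(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_test(1:2, 1:2))
})

test_that("pearson_test p-value agrees with a permutation test", {
  withr::with_seed(42, {
    x <- rnorm(12)
    y <- 0.8 * x + rnorm(12)
    obs <- pearson_test(x, y)
    perm <- replicate(1e4, abs(stats::cor(x, sample(y))))
  })
  p_perm <- mean(perm >= abs(obs$r))
  expect_lt(abs(p_perm - obs$p_value), 0.02)
})

test_that("fit_moderation interpolates exact linear data", {
  withr::with_seed(43, {
    x <- rnorm(25)
    m <- rnorm(25)
  })
  y <- 1.5 - 0.2 * x + 0.7 * m + 0.5 * x * m
  fit <- fit_moderation(x, m, y)
  expect_equal(unname(fit$coefficients), c(1.5, -0.2, 0.7, 0.5),
               tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("fit_moderation equals the normal-equations oracle", {
  withr::with_seed(44, {
    x <- rnorm(20)
    m <- rnorm(20)
    y <- 0.3 + 0.5 * x - 0.2 * m + 0.4 * x * m + rnorm(20)
  })
  fit <- fit_moderation(x, m, y)
  want <- ols_oracle(cbind(1, x, m, x * m), y)
  expect_equal(unname(fit$coefficients), unname(want$coef),
               tolerance = 1e-8)
  expect_equal(unname(fit$vcov), unname(want$vcov), tolerance = 1e-8)
  # and the overall F/R2 match lm's summary
  lmfit <- summary(stats::lm(y ~ x * m))
  expect_equal(fit$r_squared, lmfit$r.squared, tolerance = 1e-10)
  expect_equal(fit$f, unname(lmfit$fstatistic[1]), tolerance = 1e-8)

  expect_error(fit_moderation(x, x, y), "singular")
})

test_that("conditional effects are linear in the probe with the delta SE", {
  withr::with_seed(45, {
    x <- rnorm(40)
    m <- rnorm(40, 5, 2)
    y <- 0.3 + 0.5 * x - 0.2 * m + 0.4 * x * m + rnorm(40)
  })
  fit <- fit_moderation(x, m, y)
  probes <- c(2, 5, 9)
  pm <- probe_moderator(fit, probes = probes)
  b <- fit$coefficients
  V <- fit$vcov
  expect_equal(pm$effect, unname(b["b1"] + b["b3"] * probes),
               tolerance = 1e-12)
  expect_equal(pm$se,
               sqrt(V["b1", "b1"] + probes^2 * V["b3", "b3"] +
                      2 * probes * V["b1", "b3"]),
               tolerance = 1e-12)
  expect_equal(pm$p_value, 2 * stats::pt(-abs(pm$effect / pm$se), fit$df2),
               tolerance = 1e-12)

  # zero interaction: the effect is b1 at every probe
  y0 <- 1 + 2 * x + 3 * m
  fit0 <- fit_moderation(x, m, y0)
  pm0 <- probe_moderator(fit0, probes = probes)
  expect_equal(pm0$effect, rep(2, 3), tolerance = 1e-8)

  # default policies
  pm_pct <- probe_moderator(fit)
  expect_equal(pm_pct$probe,
               unname(stats::quantile(m, c(0.16, 0.5, 0.84))))
  pm_sd <- probe_moderator(fit, policy = "meansd")
  expect_equal(pm_sd$probe, mean(m) + c(-1, 0, 1) * stats::sd(m))
  expect_warning(probe_moderator(fit, probes = max(m) + 10), "range")
})

test_that("an interaction confined to low moderator values probes out", {
  withr::with_seed(46, {
    n <- 300
    x <- rnorm(n)
    m <- runif(n, 0, 10)
    # effect of x fades to zero as m grows
    y <- 1 + pmax(1 - m / 5, 0) * x + 0.3 * m + rnorm(n, 0, 0.5)
  })
  fit <- fit_moderation(x, m, y)
  pm <- probe_moderator(fit)
  expect_lt(pm$p_value[pm$label == "low"], 0.01)
  expect_gt(pm$p_value[pm$label == "high"], 0.05)
})

test_that("bootstrap intervals are seeded, degenerate on exact data", {
  withr::with_seed(47, {
    x <- rnorm(30)
    m <- rnorm(30)
  })
  y <- 1 + 2 * x + 3 * m + 0.5 * x * m
  ci <- bootstrap_ci(x, m, y, B = 200, seed = 5)
  expect_lt(max(ci$coefficients$upper - ci$coefficients$lower), 1e-8)
  ci2 <- bootstrap_ci(x, m, y, B = 200, seed = 5)
  expect_identical(ci, ci2)
  ci3 <- bootstrap_ci(x, m, y, B = 200, seed = 6)
  expect_false(identical(ci$coefficients$lower, ci3$coefficients$lower))
  expect_error(bootstrap_ci(x, m, y, B = 50), "B >= 100")
})

test_that("bootstrap coverage of a known interaction is near nominal", {
  hits <- 0L
  n_rep <- 200
  for (rep in seq_len(n_rep)) {
    dat <- withr::with_seed(1000 + rep, {
      x <- rnorm(60)
      m <- rnorm(60)
      y <- 0.2 + 0.3 * x + 0.4 * m + 0.5 * x * m + rnorm(60)
      list(x = x, m = m, y = y)
    })
    ci <- bootstrap_ci(dat$x, dat$m, dat$y, B = 400, seed = rep)
    b3 <- ci$coefficients[ci$coefficients$term == "b3", ]
    if (b3$lower <= 0.5 && 0.5 <= b3$upper) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
  expect_lte(hits / n_rep, 0.99)
})

test_that("zero coupling keeps the interaction test near its nominal size", {
  cfg <- sim_config(n_participants = 60, coupling_k = 0, seed = 1)
  n_rep <- 200
  rejections <- 0L
  for (rep in seq_len(n_rep)) {
    meth <- simulate_methylation(cfg, seed = 5000 + rep)
    truth <- draw_participants(cfg, meth, seed = 6000 + rep)
    un <- truth$condition %in% c("female_untrustworthy",
                                 "male_untrustworthy")
    y <- tapply(truth$log_k[un], truth$participant_id[un], mean)
    m <- truth$log_k[truth$condition == "baseline"][
      match(names(y), truth$participant_id[truth$condition == "baseline"])]
    x <- meth$site3[match(names(y), meth$participant_id)]
    fit <- fit_moderation(x, m, unname(y))
    t3 <- fit$coefficients["b3"] / fit$se["b3"]
    if (2 * stats::pt(-abs(t3), fit$df2) < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_rep, 0.015)
  expect_lte(rejections / n_rep, 0.105)
})

test_that("moderation_analysis wires deltas, sites and bootstrap together", {
  cfg <- sim_config(n_participants = 40, seed = 19)
  meth <- simulate_methylation(cfg, seed = 19)
  truth <- draw_participants(cfg, meth, seed = 20)
  est <- data.frame(participant_id = truth$participant_id,
                    condition = truth$condition,
                    value = truth$k, parameter_kind = "k")
  mod <- moderation_analysis(est, meth, B = 200, seed = 3)
  expect_named(mod$correlations, paste0("site", 1:4))
  expect_s3_class(mod$fit, "moderation_fit")
  expect_equal(nrow(mod$probes), 3)
  expect_equal(mod$bootstrap$B, 200)
  # site-3 coupling surfaces as a positive delta correlation
  expect_gt(mod$correlations$site3$r, 0)
})
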