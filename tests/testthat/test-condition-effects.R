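cond_means_null <- stats::setNames(rep(-3, 7), trustdisc::condition_labels())
cond_means_alt <- stats::setNames(
  c(-3.768, -3.895, -3.819, -3.674, -3.435, -3.169, -3.041),
  trustdisc::condition_labels())

test_that("identical values across conditions give zero contrasts", {
  est <- toy_estimates(8, cond_means_null, sigma_u = 0, sigma_e = 0)
  fit <- fit_condition_model(est, "treatment")
  coefs <- fit$coefficients
  expect_equal(coefs$estimate[coefs$term == "(Intercept)"], -3,
               tolerance = 1e-8)
  expect_equal(coefs$estimate[coefs$term != "(Intercept)"], rep(0, 6),
               tolerance = 1e-8)
  expect_lt(unname(lme4::VarCorr(fit$model)$participant_id[1]), 1e-8)
})

test_that("balanced random-intercept fits match the OLS oracle", {
  est <- toy_estimates(6, cond_means_alt, sigma_u = 0.8, sigma_e = 0.4,
                       seed = 11)
  fit <- fit_condition_model(est, "treatment")
  X <- stats::model.matrix(~ factor(condition,
                                    levels = condition_labels()),
                           est)
  want <- ols_oracle(X, est$log_value)
  expect_equal(fit$coefficients$estimate, unname(want$coef),
               tolerance = 1e-6)
})

test_that("treatment and sum codings imply identical cell means", {
  est <- toy_estimates(10, cond_means_alt, sigma_u = 0.6, sigma_e = 0.5,
                       seed = 12)
  fit_t <- fit_condition_model(est, "treatment")
  fit_s <- fit_condition_model(est, "sum")
  # face-condition cell means from the treatment fit
  bt <- fit_t$coefficients$estimate
  cell_t <- bt[1] + bt[2:7]
  # same cells from the sum-coded trust x gender fit
  mm <- marginal_means(fit_s, "trust")
  grid <- expand.grid(trust = c("trustworthy", "neutral", "untrustworthy"),
                      gender = c("female", "male"))
  ct <- condition_table()
  lab <- paste(grid$gender, grid$trust, sep = "_")
  ord <- match(condition_labels()[-1], lab)
  Xg <- stats::model.matrix(
    ~ trust * gender,
    transform(grid,
              trust = factor(trust, levels = c("trustworthy", "neutral",
                                               "untrustworthy")),
              gender = factor(gender, levels = c("female", "male"))),
    contrasts.arg = list(trust = "contr.sum", gender = "contr.sum"))
  cell_s <- drop(Xg %*% lme4::fixef(fit_s$model))[ord]
  expect_equal(unname(cell_t), unname(cell_s), tolerance = 1e-8)
})

test_that("singular designs fail with the deficient term named", {
  est <- toy_estimates(6, cond_means_alt, seed = 13)
  est <- est[est$condition %in% c("baseline", "female_neutral"), ]
  est$condition <- factor(est$condition, levels = condition_labels())
  expect_error(fit_condition_model(est, "treatment"), "singular|conditions")
})

test_that("omnibus Wald tests are type-3 blocks of the sum coding", {
  est <- toy_estimates(12, cond_means_alt, sigma_u = 0.5, sigma_e = 0.5,
                       seed = 14)
  fit <- fit_condition_model(est, "sum")
  om <- omnibus_wald(fit)
  expect_setequal(om$term, c("(Intercept)", "trust", "gender",
                             "trust:gender"))
  expect_equal(om$df[match(c("trust", "gender", "trust:gender"), om$term)],
               c(2, 1, 2))
  expect_true(all(om$wald_chisq >= 0))
  expect_true(all(om$p_value >= 0 & om$p_value <= 1))

  # single-df term: chi-square equals the squared z exactly
  z <- fit$coefficients$statistic[fit$coefficients$term == "gender1"]
  expect_equal(om$wald_chisq[om$term == "gender"], z^2, tolerance = 1e-10)
})

test_that("omnibus Wald matches car::Anova on a toy fit", {
  skip_if_not_installed("car")
  est <- toy_estimates(8, cond_means_alt, sigma_u = 0.4, sigma_e = 0.6,
                       seed = 15)
  fit <- fit_condition_model(est, "sum")
  om <- omnibus_wald(fit)
  ca <- car::Anova(fit$model, type = 3)
  idx <- match(c("trust", "gender", "trust:gender"), rownames(ca))
  expect_equal(om$wald_chisq[match(c("trust", "gender", "trust:gender"),
                                   om$term)],
               ca$Chisq[idx], tolerance = 1e-6)
})

test_that("marginal means average a balanced grid and back-transform", {
  est <- toy_estimates(10, cond_means_alt, sigma_u = 0, sigma_e = 0.4,
                       seed = 16)
  fit <- fit_condition_model(est, "treatment")
  mm <- marginal_means(fit, "condition")
  # balanced one-factor design: marginal means equal cell means of the data
  cells <- tapply(est$log_value, factor(est$condition,
                                        levels = condition_labels()), mean)
  expect_equal(mm$means$emmean, unname(c(cells)), tolerance = 1e-6)
  expect_equal(mm$means$response, exp(mm$means$emmean))
  expect_equal(nrow(mm$contrasts), choose(7, 2))

  fit_s <- fit_condition_model(est, "sum")
  mm_s <- marginal_means(fit_s, "trust")
  expect_equal(nrow(mm_s$contrasts), 3)
  expect_true(all(mm_s$contrasts$p_bonferroni >= mm_s$contrasts$p_raw))
  expect_true(all(mm_s$contrasts$p_bonferroni <= 1))
  expect_equal(mm_s$contrasts$p_bonferroni,
               pmin(1, mm_s$contrasts$p_raw * 3))
})

test_that("marginal means agree with emmeans", {
  skip_if_not_installed("emmeans")
  est <- toy_estimates(8, cond_means_alt, sigma_u = 0.5, sigma_e = 0.5,
                       seed = 17)
  fit <- fit_condition_model(est, "sum")
  mm <- marginal_means(fit, "trust")
  em <- as.data.frame(emmeans::emmeans(fit$model, "trust",
                                       lmer.df = "asymptotic"))
  expect_equal(mm$means$emmean, em$emmean, tolerance = 1e-6)
  expect_equal(mm$means$se, em$SE, tolerance = 1e-6)
})

test_that("delta scores subtract baseline from the untrustworthy mean", {
  est <- data.frame(
    participant_id = rep("p1", 7),
    condition = condition_labels(),
    value = 0.05, parameter_kind = "k")
  expect_equal(delta_scores(est)$delta, 0)

  est$value[est$condition == "female_untrustworthy"] <- 0.05
  est$value[est$condition == "male_untrustworthy"] <- 0.07
  est$value[est$condition == "baseline"] <- 0.03
  expect_equal(delta_scores(est)$delta, 0.03, tolerance = 1e-12)

  incomplete <- est[est$condition != "baseline", ]
  incomplete$participant_id <- "p2"
  expect_message(d <- delta_scores(rbind(est, incomplete)), "skipped")
  expect_equal(d$participant_id, "p1")
})

test_that("delta scores inherit the simulated coupling direction", {
  cfg <- sim_config(n_participants = 2000, seed = 31)
  meth <- simulate_methylation(cfg, seed = 31)
  truth <- draw_participants(cfg, meth, seed = 32)
  est <- data.frame(participant_id = truth$participant_id,
                    condition = truth$condition,
                    value = truth$k, parameter_kind = "k")
  d <- delta_scores(est)
  r <- pearson_test(meth$site3[match(d$participant_id,
                                     meth$participant_id)], d$delta)
  expect_gt(r$r, 0)
  expect_lt(r$p_value, 0.01)
})

test_that("the response-time filter removes exactly the flagged trials", {
  base <- data.frame(participant_id = "p1", task = "delay",
                     rt_ms = rep(1000, 40))
  out <- filter_rts(base)
  expect_equal(nrow(out$trials), 40)
  expect_equal(out$report$n_fast + out$report$n_slow, 0)

  fast <- rbind(base, data.frame(participant_id = "p1", task = "delay",
                                 rt_ms = 200))
  out <- filter_rts(fast)
  expect_equal(out$report$n_fast, 1)
  expect_false(200 %in% out$trials$rt_ms)

  # one value at mean + 4 SD of the pre-filter distribution
  rt <- c(rep(c(900, 1100), 20), NA)
  rt[41] <- mean(rt, na.rm = TRUE) + 4 * stats::sd(rt, na.rm = TRUE)
  slow <- data.frame(participant_id = "p1", task = "delay", rt_ms = rt)
  expect_gt(rt[41], mean(rt[1:40]) + 3 * stats::sd(rt[1:40]))
  out <- filter_rts(slow)
  expect_equal(out$report$n_slow, 1)
  expect_equal(out$report$n_fast, 0)
  expect_false(rt[41] %in% out$trials$rt_ms)

  # idempotent on its own output
  again <- filter_rts(out$trials)
  expect_identical(again$trials, out$trials)

  # per-participant statistics: a second participant's slow trial does not
  # move the first participant's bound
  two <- rbind(slow,
               data.frame(participant_id = "p2", task = "delay",
                          rt_ms = rep(5000, 41)))
  out2 <- filter_rts(two)
  expect_equal(out2$report$n_slow, 1)
})

test_that("inverse-Gaussian response-time models recover the structure", {
  cfg <- sim_config(n_participants = 40, seed = 7)
  coh <- simulate_cohort(cfg)
  tr <- coh$trials[coh$trials$task == "delay", ]
  kept <- filter_rts(tr)$trials

  fit <- fit_rt_model(kept, "treatment")
  face_terms <- fit$coefficients$term != "(Intercept)"
  expect_true(all(fit$coefficients$estimate[face_terms] < 0))
  expect_true(all(fit$coefficients$significant[face_terms]))

  fit_s <- fit_rt_model(kept, "sum")
  om <- omnibus_wald(fit_s)
  expect_lt(om$p_value[om$term == "response"], 0.001)

  const <- transform(kept, rt_ms = 1000)
  expect_error(fit_rt_model(const), "degenerate")
})
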