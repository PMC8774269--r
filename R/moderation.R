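#' Pearson correlation with t-based p-value
#'
#' Sample product-moment correlation with the classical two-tailed test:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, finite, with
#'   nonzero variance.
#' @return List of class `"correlation_result"`: `r`, `n`, `t`,
#'   `p_value`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  structure(list(r = r, n = n, t = t,
                 p_value = 2 * stats::pt(-abs(t), n - 2)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), t = %.3f, two-tailed p = %.4g\n",
              x$r, x$n, x$t, x$p_value))
  invisible(x)
}

#' Fit the simple moderation model
#'
#' Ordinary least squares of `Y` on `{1, X, M, X*M}` — the single-moderator
#' model in which `b3` carries the moderation: the conditional (simple)
#' effect of `X` at moderator value `m` is `b1 + b3 * m`. In the intended
#' application `X` is the site-3 percent methylation, `M` the baseline
#' discount rate and `Y` the rate in the untrustworthy conditions.
#'
#' @param x Predictor.
#' @param m Moderator.
#' @param y Outcome.
#' @return Object of class `"moderation_fit"`: coefficients `b0..b3`,
#'   their covariance and SEs, `r_squared`, overall `f` on (3, n - 4)
#'   degrees of freedom with `p_value`, residuals and the data.
#' @export
fit_moderation <- function(x, m, y) {
  n <- length(y)
  stopifnot(length(x) == n, length(m) == n, n > 4,
            all(is.finite(c(x, m, y))))
  X <- cbind(1, x, m, x * m)
  colnames(X) <- c("b0", "b1", "b2", "b3")
  qrX <- qr(X)
  if (qrX$rank < 4) stop("singular design: predictor, moderator and their ",
                         "product are collinear")
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  res <- fit$residuals
  df2 <- n - 4
  sigma2 <- sum(res^2) / df2
  XtX_inv <- chol2inv(qr.R(qrX))
  V <- sigma2 * XtX_inv
  dimnames(V) <- list(names(b), names(b))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / ss_tot
  f <- (r2 / 3) / ((1 - r2) / df2)
  structure(list(coefficients = b, vcov = V, se = sqrt(diag(V)),
                 r_squared = r2, f = f, df1 = 3, df2 = df2,
                 p_value = stats::pf(f, 3, df2, lower.tail = FALSE),
                 residuals = res, sigma2 = sigma2,
                 data = data.frame(x = x, m = m, y = y)),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("Moderation model Y ~ X * M (n = %d)\n", x$df2 + 4))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    t = x$coefficients / x$se)
  tab$p <- 2 * stats::pt(-abs(tab$t), x$df2)
  print(tab, digits = 4)
  cat(sprintf("R^2 = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
              x$r_squared, x$df1, x$df2, x$f, x$p_value))
  invisible(x)
}

#' Conditional effects of the predictor at moderator probes
#'
#' Pick-a-point analysis: the effect of `X` on `Y` at moderator value `m`
#' is `b1 + b3 * m`, with standard error
#' `sqrt(V11 + m^2 V33 + 2 m V13)` from the fit covariance and a t test on
#' `n - 4` degrees of freedom. Default probes are the 16th, 50th and 84th
#' percentiles of the observed moderator (low / middle / high); `"meansd"`
#' uses mean - SD, mean, mean + SD instead. Probes outside the observed
#' moderator range trigger a warning, not an error.
#'
#' @param fit A `"moderation_fit"`.
#' @param probes Optional explicit probe values (overrides `policy`).
#' @param policy `"percentile"` (default) or `"meansd"`.
#' @return Data frame `label`, `probe`, `effect`, `se`, `t`, `p_value`.
#' @export
probe_moderator <- function(fit, probes = NULL,
                            policy = c("percentile", "meansd")) {
  stopifnot(inherits(fit, "moderation_fit"))
  policy <- match.arg(policy)
  m_obs <- fit$data$m
  if (is.null(probes)) {
    probes <- if (policy == "percentile")
      unname(stats::quantile(m_obs, c(0.16, 0.50, 0.84)))
    else
      mean(m_obs) + c(-1, 0, 1) * stats::sd(m_obs)
  }
  if (any(probes < min(m_obs) | probes > max(m_obs)))
    warning("probe value(s) outside the observed moderator range")
  labels <- if (length(probes) == 3) c("low", "middle", "high")
            else paste0("probe", seq_along(probes))
  b <- fit$coefficients
  V <- fit$vcov
  effect <- b["b1"] + b["b3"] * probes
  se <- sqrt(V["b1", "b1"] + probes^2 * V["b3", "b3"] +
               2 * probes * V["b1", "b3"])
  t <- effect / se
  data.frame(label = labels, probe = probes, effect = unname(effect),
             se = unname(se), t = unname(t),
             p_value = unname(2 * stats::pt(-abs(t), fit$df2)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Case-resampling bootstrap confidence intervals
#'
#' Resamples rows (cases) with replacement `B` times, refits the
#' moderation model on each resample and returns percentile intervals at
#' the requested level for the four coefficients and for the conditional
#' effects at the probes. Singular resamples are skipped and counted; more
#' than 10% skips is an error.
#'
#' @inheritParams fit_moderation
#' @param B Number of resamples (>= 100; 1000 is customary).
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed; the same seed gives identical intervals.
#' @param probes Moderator probe values; default as in
#'   [probe_moderator()].
#' @param policy Probe policy when `probes` is `NULL`.
#' @return List with `coefficients` and `conditional_effects` data frames
#'   (point estimate, lower, upper), plus `B`, `level` and `n_skipped`.
#' @export
bootstrap_ci <- function(x, m, y, B = 1000, level = 0.95, seed = 1L,
                         probes = NULL, policy = c("percentile", "meansd")) {
  stopifnot(B >= 100, level > 0, level < 1)
  policy <- match.arg(policy)
  fit <- fit_moderation(x, m, y)
  pm <- probe_moderator(fit, probes = probes, policy = policy)
  probes <- pm$probe
  n <- length(y)
  draws <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  })
  coefs <- matrix(NA_real_, B, 4)
  effects <- matrix(NA_real_, B, length(probes))
  skipped <- 0L
  for (i in seq_len(B)) {
    idx <- draws[i, ]
    Xb <- cbind(1, x[idx], m[idx], x[idx] * m[idx])
    fb <- stats::.lm.fit(Xb, y[idx])
    if (fb$rank < 4) { skipped <- skipped + 1L; next }
    bb <- fb$coefficients
    coefs[i, ] <- bb
    effects[i, ] <- bb[2] + bb[4] * probes
  }
  if (skipped > 0.1 * B)
    stop("more than 10% of bootstrap resamples were singular (",
         skipped, " of ", B, ")")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- function(mat) apply(mat, 2, stats::quantile, probs = probs,
                            na.rm = TRUE)
  qc <- qs(coefs)
  qe <- qs(effects)
  list(
    coefficients = data.frame(
      term = c("b0", "b1", "b2", "b3"),
      estimate = unname(fit$coefficients),
      lower = qc[1, ], upper = qc[2, ], row.names = NULL,
      stringsAsFactors = FALSE),
    conditional_effects = data.frame(
      label = pm$label, probe = pm$probe, effect = pm$effect,
      lower = qe[1, ], upper = qe[2, ], row.names = NULL,
      stringsAsFactors = FALSE),
    B = B, level = level, n_skipped = skipped)
}

#' Full moderation analysis for one discounting parameter
#'
#' Convenience wrapper mirroring the analysis stage: correlates the
#' untrustworthy-minus-baseline delta scores with each CpG site, then fits
#' the moderation model with site-3 methylation as predictor (X), the
#' baseline rate as moderator (M) and the mean untrustworthy rate as
#' outcome (Y), probes the conditional effect at low/middle/high moderator
#' values and attaches bootstrap intervals.
#'
#' @param estimates Estimate table for one `parameter_kind` (see
#'   [score_all()]).
#' @param methylation Methylation records (see [read_methylation()]).
#' @param B,level,seed,policy Passed to [bootstrap_ci()].
#' @return List: `correlations` (one [pearson_test()] per site),
#'   `fit`, `probes`, `bootstrap`.
#' @export
moderation_analysis <- function(estimates, methylation, B = 1000,
                                level = 0.95, seed = 1L,
                                policy = "percentile") {
  deltas <- delta_scores(estimates)
  keep <- intersect(deltas$participant_id, methylation$participant_id)
  if (length(keep) < 5)
    stop("too few participants with both estimates and methylation")
  d <- deltas[match(keep, deltas$participant_id), ]
  meth <- methylation[match(keep, methylation$participant_id), ]
  correlations <- lapply(paste0("site", 1:4), function(s)
    pearson_test(meth[[s]], d$delta))
  names(correlations) <- paste0("site", 1:4)
  wide <- estimates[estimates$participant_id %in% keep, ]
  base <- wide$value[wide$condition == "baseline"][
    match(keep, wide$participant_id[wide$condition == "baseline"])]
  un <- vapply(keep, function(id) {
    mean(wide$value[wide$participant_id == id &
                      wide$condition %in% untrustworthy_labels()])
  }, numeric(1))
  x <- meth$site3
  fit <- fit_moderation(x, base, un)
  probes <- probe_moderator(fit, policy = policy)
  boot <- bootstrap_ci(x, base, un, B = B, level = level, seed = seed,
                       policy = policy)
  list(correlations = correlations, fit = fit, probes = probes,
       bootstrap = boot)
}
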