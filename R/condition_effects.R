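#' Mixed model of log discount rates on proposer condition
#'
#' Fits a random-intercept linear model of the log-transformed discount
#' rate. With `coding = "treatment"` the predictor is the seven-level
#' proposer condition with baseline as the reference, so each coefficient
#' is the contrast of one face condition against baseline; the
#' significance flag applies the |t| > 2 rule of thumb (treating the
#' mixed-model t as z, approximate and marked as such). With
#' `coding = "sum"` the baseline rows are dropped and trustworthiness and
#' gender of the proposer enter as sum-coded factors with their
#' interaction, the parameterization that feeds [omnibus_wald()].
#'
#' @param estimates Estimate table (one `parameter_kind`) with columns
#'   `participant_id`, `condition`, `log_value`, e.g. a filtered
#'   [score_all()] result.
#' @param coding `"treatment"` or `"sum"`.
#' @return Object of class `"condition_fit"`: the lme4 fit plus a
#'   coefficient table (`estimate`, `se`, `statistic`, `significant`),
#'   fixed-effect covariance, coding and bookkeeping counts.
#' @export
fit_condition_model <- function(estimates, coding = c("treatment", "sum")) {
  coding <- match.arg(coding)
  stopifnot(all(c("participant_id", "condition", "log_value") %in%
                  names(estimates)))
  if (length(unique(estimates$parameter_kind)) > 1)
    stop("estimates mix k and h rows; fit them separately")
  if (!all(is.finite(estimates$log_value))) stop("log values must be finite")
  kind <- if (is.null(estimates$parameter_kind)) "log_value" else
    paste0("log_", estimates$parameter_kind[1])
  d <- build_condition_frame(estimates, coding)
  formula <- if (coding == "treatment")
    log_value ~ condition + (1 | participant_id)
  else
    log_value ~ trust * gender + (1 | participant_id)
  check_design_rank(formula, d)
  model <- lme4::lmer(formula, data = d, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular =
                                                    "ignore"))
  new_condition_fit(model, coding, outcome_kind = kind,
                    n_obs = nrow(d),
                    n_participants = length(unique(d$participant_id)))
}

build_condition_frame <- function(data, coding) {
  ct <- condition_table()
  d <- data
  if (coding == "treatment") {
    d$condition <- factor(d$condition, levels = ct$label)
  } else {
    d <- d[d$condition != "baseline", , drop = FALSE]
    i <- match(d$condition, ct$label)
    d$trust <- factor(ct$trust_level[i],
                      levels = c("trustworthy", "neutral", "untrustworthy"))
    d$gender <- factor(ct$gender[i], levels = c("female", "male"))
    stats::contrasts(d$trust) <- stats::contr.sum(3)
    stats::contrasts(d$gender) <- stats::contr.sum(2)
  }
  if (length(unique(d$condition)) < 2)
    stop("need at least two conditions")
  d
}

check_design_rank <- function(formula, d) {
  X <- stats::model.matrix(lme4::nobars(formula), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effects design; deficient term(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

new_condition_fit <- function(model, coding, outcome_kind, n_obs,
                              n_participants) {
  b <- lme4::fixef(model)
  # degenerate fits (all variance components zero) break lme4's vcov;
  # fall back to the least-squares covariance, which is 0 in that case
  V <- tryCatch(suppressWarnings(as.matrix(stats::vcov(model))),
                error = function(e) {
                  X <- lme4::getME(model, "X")
                  stats::sigma(model)^2 * chol2inv(qr.R(qr(X)))
                })
  se <- sqrt(diag(V))
  stat <- b / se
  structure(list(
    model = model,
    coding = coding,
    outcome_kind = outcome_kind,
    coefficients = data.frame(term = names(b), estimate = unname(b),
                              se = unname(se), statistic = unname(stat),
                              significant = abs(unname(stat)) > 2,
                              stringsAsFactors = FALSE),
    vcov = V,
    n_obs = n_obs,
    n_participants = n_participants
  ), class = "condition_fit")
}

#' @export
print.condition_fit <- function(x, ...) {
  cat("Random-intercept model of ", x$outcome_kind, " (", x$coding,
      " coding), ", x$n_obs, " observations / ", x$n_participants,
      " participants\n", sep = "")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat("significance flag: |t| > 2 (t-as-z rule, approximate)\n")
  invisible(x)
}

#' Type-3 Wald chi-square omnibus tests
#'
#' For each model term with coefficient rows `L` tests `L b = 0` via
#' `chi^2 = (Lb)' (L V L')^-1 (Lb)` with `df = rank(L)`, each term
#' adjusted for all others. With sum-coded factors these are the
#' ANOVA-like type-3 omnibus tests of main effects and interactions; a
#' single-df term's chi-square equals its squared z statistic.
#'
#' @param fit A `"condition_fit"` (typically sum-coded).
#' @return Data frame `term`, `wald_chisq`, `df`, `p_value`.
#' @export
omnibus_wald <- function(fit) {
  stopifnot(inherits(fit, "condition_fit"))
  X <- lme4::getME(fit$model, "X")
  asgn <- attr(X, "assign")
  labels <- c("(Intercept)",
              attr(stats::terms(fit$model), "term.labels"))
  b <- lme4::fixef(fit$model)
  V <- fit$vcov
  rows <- lapply(sort(unique(asgn)), function(a) {
    idx <- which(asgn == a)
    Vsub <- V[idx, idx, drop = FALSE]
    if (qr(Vsub)$rank < length(idx))
      stop("rank-deficient contrast block for term ", labels[a + 1])
    chi <- drop(t(b[idx]) %*% solve(Vsub, b[idx]))
    data.frame(term = labels[a + 1], wald_chisq = chi, df = length(idx),
               p_value = stats::pchisq(chi, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimated marginal means with Bonferroni-corrected comparisons
#'
#' Model-based cell means averaged over a balanced grid of the other
#' factors in the fit, back-transformed by exponentiation when the outcome
#' is on the log scale (delta-method SE). All pairwise comparisons of the
#' requested factor's levels are returned with raw and Bonferroni-adjusted
#' p-values (raw p times the number of comparisons, capped at 1).
#'
#' @param fit A `"condition_fit"`.
#' @param spec Factor whose marginal means are wanted; defaults to the
#'   single predictor of a treatment-coded fit or `"trust"` for sum-coded
#'   fits.
#' @return List with `means` (level, emmean, se, response, response_se)
#'   and `contrasts` (pairwise differences on the model scale with
#'   statistics and adjusted p).
#' @export
marginal_means <- function(fit, spec = NULL) {
  stopifnot(inherits(fit, "condition_fit"))
  mf <- stats::model.frame(fit$model)
  factors <- names(mf)[vapply(mf, is.factor, logical(1))]
  factors <- setdiff(factors, "participant_id")
  if (is.null(spec))
    spec <- if (fit$coding == "treatment") "condition" else "trust"
  if (!spec %in% factors) stop("unknown factor: ", spec)
  grid <- expand.grid(lapply(mf[factors], levels),
                      KEEP.OUT.ATTRS = FALSE)
  contr <- attr(lme4::getME(fit$model, "X"), "contrasts")
  Xg <- stats::model.matrix(
    stats::delete.response(stats::terms(lme4::nobars(
      stats::formula(fit$model)))),
    grid, contrasts.arg = contr[names(contr) %in% factors])
  b <- lme4::fixef(fit$model)
  V <- fit$vcov
  lev <- levels(mf[[spec]])
  L <- t(vapply(lev, function(s)
    colMeans(Xg[grid[[spec]] == s, , drop = FALSE]), numeric(ncol(Xg))))
  mu <- drop(L %*% b)
  se <- sqrt(diag(L %*% V %*% t(L)))
  log_scale <- startsWith(fit$outcome_kind, "log_")
  means <- data.frame(level = lev, emmean = mu, se = se,
                      response = if (log_scale) exp(mu) else mu,
                      response_se = if (log_scale) exp(mu) * se else se,
                      row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(seq_along(lev), 2)
  m <- ncol(pairs)
  ctr <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    l <- L[i1, ] - L[i2, ]
    est <- drop(l %*% b)
    s <- sqrt(drop(t(l) %*% V %*% l))
    z <- est / s
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(contrast = paste(lev[i1], "-", lev[i2]), estimate = est,
               se = s, statistic = z, p_raw = p,
               p_bonferroni = min(1, p * m), stringsAsFactors = FALSE)
  })
  list(means = means, contrasts = do.call(rbind, ctr))
}

#' Untrustworthy-minus-baseline delta scores
#'
#' For each participant, the mean of the discount rate in the two
#' untrustworthy conditions minus the baseline rate, on the raw (not log)
#' scale. A positive delta means the participant discounted more steeply
#' with an untrustworthy proposer. Participants missing the baseline or
#' either untrustworthy estimate are skipped with a message.
#'
#' @param estimates Estimate table for one `parameter_kind` with columns
#'   `participant_id`, `condition`, `value`.
#' @return Data frame `participant_id`, `delta`.
#' @export
delta_scores <- function(estimates) {
  if (length(unique(estimates$parameter_kind)) > 1)
    stop("estimates mix k and h rows; compute deltas separately")
  need <- c("baseline", untrustworthy_labels())
  parts <- split(estimates, estimates$participant_id)
  rows <- lapply(parts, function(d) {
    if (!all(need %in% d$condition)) return(NULL)
    v <- d$value[match(need, d$condition)]
    data.frame(participant_id = d$participant_id[1],
               delta = mean(v[2:3]) - v[1], stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    message(skipped, " participant(s) missing baseline or untrustworthy ",
            "estimates; skipped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter implausible response times
#'
#' Removes trials faster than 250 ms and trials slower than the
#' participant's mean plus three standard deviations, with the mean and SD
#' computed per participant and task on the unfiltered data (the slow
#' bound is fixed before any removal, so re-applying the filter to its own
#' output removes nothing more).
#'
#' @param trials Trial table with `participant_id`, `task`, `rt_ms`.
#' @param fast_ms Lower bound in milliseconds (default 250).
#' @return List with `trials` (kept rows) and `report` (per-task counts of
#'   fast and slow removals).
#' @export
filter_rts <- function(trials, fast_ms = 250) {
  stopifnot(all(c("participant_id", "task", "rt_ms") %in% names(trials)))
  grp <- interaction(trials$participant_id, trials$task, drop = TRUE)
  mu <- tapply(trials$rt_ms, grp, mean)[grp]
  sd_ <- tapply(trials$rt_ms, grp, stats::sd)[grp]
  sd_[is.na(sd_)] <- 0
  fast <- trials$rt_ms < fast_ms
  slow <- !fast & trials$rt_ms > mu + 3 * sd_
  report <- do.call(rbind, lapply(unique(trials$task), function(tk) {
    i <- trials$task == tk
    data.frame(task = tk, n_total = sum(i), n_fast = sum(fast[i]),
               n_slow = sum(slow[i]), n_kept = sum(i & !fast & !slow),
               stringsAsFactors = FALSE)
  }))
  list(trials = trials[!fast & !slow, , drop = FALSE], report = report)
}

#' Inverse-Gaussian mixed model of response times
#'
#' Fits response times (in seconds) with a generalized mixed model, family
#' inverse Gaussian with identity link, and a participant random
#' intercept — the skew-respecting alternative to transforming the times.
#' With `coding = "treatment"` the predictor is the proposer condition
#' with baseline as reference, so negative coefficients mean faster
#' responses with that proposer present. With `coding = "sum"` baseline
#' trials are dropped and trustworthiness, gender and the response given
#' (smaller-sooner/certain vs larger-later/probabilistic) enter sum-coded
#' with all interactions, for [omnibus_wald()].
#'
#' @param trials Filtered trial table of a single task, with
#'   `participant_id`, `condition`, `choice`, `rt_ms`.
#' @param coding `"treatment"` or `"sum"`.
#' @return A `"condition_fit"`.
#' @export
fit_rt_model <- function(trials, coding = c("treatment", "sum")) {
  coding <- match.arg(coding)
  stopifnot(all(c("participant_id", "condition", "choice", "rt_ms") %in%
                  names(trials)))
  if (length(unique(trials$task)) > 1)
    stop("fit response-time models per task")
  if (stats::var(trials$rt_ms) == 0)
    stop("degenerate response times: zero variance")
  d <- trials
  d$rt_s <- d$rt_ms / 1000
  d <- build_condition_frame(d, coding)
  if (coding == "treatment") {
    formula <- rt_s ~ condition + (1 | participant_id)
  } else {
    d$response <- factor(ifelse(d$choice == 1, "larger", "smaller"),
                         levels = c("smaller", "larger"))
    stats::contrasts(d$response) <- stats::contr.sum(2)
    formula <- rt_s ~ trust * gender * response + (1 | participant_id)
  }
  check_design_rank(formula, d)
  model <- tryCatch(
    lme4::glmer(formula, data = d,
                family = stats::inverse.gaussian(link = "identity"),
                nAGQ = 0L),
    error = function(e) stop("response-time model did not converge: ",
                             conditionMessage(e)))
  fit <- new_condition_fit(model, coding, outcome_kind = "rt",
                           n_obs = nrow(d),
                           n_participants = length(unique(d$participant_id)))
  fit
}
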