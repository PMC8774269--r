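#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator with defaults that
#' emulate the statistical structure reported for studies of discounting
#' with proposer faces: log-normally distributed per-condition discount
#' rates with condition offsets ordered untrustworthy > neutral >
#' trustworthy, logistic choice given hyperbolic subjective values,
#' shifted inverse-Gaussian response times that are faster with a face
#' present and faster for smaller-sooner/certain responses, and beta
#' distributed percent methylation at four CpG sites with site 3 coupled
#' to the untrustworthy shift.
#'
#' Log-scale means, condition offsets and noise components default to the
#' magnitudes of the published mixed-model coefficient tables
#' (`mu_log_k = -3.768`, untrustworthy offsets near 0.6-0.7 log units,
#' etc.); response-time cell means default to the reported task averages
#' (about 3.1 s without a face, 2.8 s with one, with smaller-sooner
#' responses about 0.3 s faster). `coupling_k = 0.361` and
#' `coupling_h = 0.431` are the target correlations between site-3 percent
#' methylation and the per-participant untrustworthy-minus-baseline shift
#' of the log discount rate.
#'
#' @param n_participants Cohort size.
#' @param mu_log_k,mu_log_h Baseline means of the log discount rates.
#' @param sigma_between_k,sigma_between_h SD of the participant random
#'   intercept (log scale).
#' @param noise_sd_k,noise_sd_h SD of the per-condition residual
#'   (log scale).
#' @param condition_offsets_k,condition_offsets_h Named log-scale shifts,
#'   one per condition label, baseline 0.
#' @param choice_sensitivity Logistic slope per currency unit of
#'   subjective-value difference (>= 0; 0 gives coin-flip choices).
#' @param rt_shift_ms Non-decision time added to every response time.
#' @param rt_mean_ms 2x2 numeric matrix of total mean response times (ms),
#'   rows = face absent/present, columns = response smaller/larger.
#' @param rt_shape_ms Inverse-Gaussian shape parameter (ms); larger means
#'   less skew and variance.
#' @param methylation_alpha,methylation_beta Beta-distribution parameters,
#'   one pair per CpG site (percent scale = 100 x beta draw).
#' @param coupling_k,coupling_h Target correlations in (-1, 1) between
#'   site-3 methylation and the untrustworthy log-shift; require the
#'   matching `noise_sd_*` > 0 unless 0.
#' @param seed Integer seed governing the whole cohort draw.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 60,
                       mu_log_k = -3.768,
                       mu_log_h = 0.933,
                       sigma_between_k = 1.15,
                       sigma_between_h = 0.87,
                       noise_sd_k = 0.755,
                       noise_sd_h = 0.49,
                       condition_offsets_k = c(
                         baseline = 0,
                         female_trustworthy = -0.127,
                         male_trustworthy = -0.051,
                         female_neutral = 0.094,
                         male_neutral = 0.333,
                         female_untrustworthy = 0.599,
                         male_untrustworthy = 0.727),
                       condition_offsets_h = c(
                         baseline = 0,
                         female_trustworthy = 0.021,
                         male_trustworthy = 0.096,
                         female_neutral = 0.159,
                         male_neutral = 0.336,
                         female_untrustworthy = 0.534,
                         male_untrustworthy = 0.513),
                       choice_sensitivity = 1,
                       rt_shift_ms = 250,
                       rt_mean_ms = matrix(c(2960, 2690, 3260, 2990), 2, 2,
                                           dimnames = list(
                                             face = c("no_face", "face"),
                                             response = c("smaller",
                                                          "larger"))),
                       rt_shape_ms = 9000,
                       methylation_alpha = c(7, 8, 9, 10),
                       methylation_beta = c(13, 12, 11, 10),
                       coupling_k = 0.361,
                       coupling_h = 0.431,
                       seed = 1L) {
  cfg <- list(n_participants = n_participants, mu_log_k = mu_log_k,
              mu_log_h = mu_log_h, sigma_between_k = sigma_between_k,
              sigma_between_h = sigma_between_h, noise_sd_k = noise_sd_k,
              noise_sd_h = noise_sd_h,
              condition_offsets_k = condition_offsets_k,
              condition_offsets_h = condition_offsets_h,
              choice_sensitivity = choice_sensitivity,
              rt_shift_ms = rt_shift_ms, rt_mean_ms = rt_mean_ms,
              rt_shape_ms = rt_shape_ms,
              methylation_alpha = methylation_alpha,
              methylation_beta = methylation_beta,
              coupling_k = coupling_k, coupling_h = coupling_h,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1,
            cfg$sigma_between_k >= 0, cfg$sigma_between_h >= 0,
            cfg$noise_sd_k >= 0, cfg$noise_sd_h >= 0,
            cfg$choice_sensitivity >= 0,
            cfg$rt_shift_ms >= 0, all(cfg$rt_mean_ms > cfg$rt_shift_ms),
            cfg$rt_shape_ms > 0,
            all(cfg$methylation_alpha > 0), all(cfg$methylation_beta > 0),
            length(cfg$methylation_alpha) == 4,
            length(cfg$methylation_beta) == 4,
            abs(cfg$coupling_k) < 1, abs(cfg$coupling_h) < 1)
  lab <- condition_labels()
  if (!setequal(names(cfg$condition_offsets_k), lab) ||
      !setequal(names(cfg$condition_offsets_h), lab))
    stop("condition offsets must be named with the seven condition labels")
  invisible(cfg)
}

# gamma making cor(z, mean(U offsets noise) - baseline noise) = rho, where
# the shift's noise part has variance 1.5 * noise_sd^2 (two untrustworthy
# cells averaged, one baseline cell subtracted)
coupling_gamma <- function(rho, noise_sd) {
  if (rho == 0) return(0)
  if (noise_sd <= 0)
    stop("coupling cannot be calibrated: a nonzero target correlation ",
         "below 1 requires noise_sd > 0")
  sqrt(1.5) * noise_sd * rho / sqrt(1 - rho^2)
}

#' Simulate CpG methylation records
#'
#' Draws percent methylation at four CpG sites from per-site beta
#' distributions (multiplied by 100, matching pyrosequencing output that
#' is bounded in \[0, 100\]) and their arithmetic mean.
#'
#' @param config A [sim_config()].
#' @param participant_ids Identifiers; defaults to `p001...`.
#' @param seed Optional seed; by default draws from the current RNG
#'   stream so [simulate_cohort()] stays reproducible as a whole.
#' @return Data frame `participant_id`, `site1..site4`, `mean_pct`.
#' @export
simulate_methylation <- function(config,
                                 participant_ids = default_ids(config),
                                 seed = NULL) {
  draw <- function() {
    n <- length(participant_ids)
    sites <- matrix(NA_real_, n, 4)
    for (s in 1:4)
      sites[, s] <- 100 * stats::rbeta(n, config$methylation_alpha[s],
                                       config$methylation_beta[s])
    out <- data.frame(participant_id = participant_ids)
    out[paste0("site", 1:4)] <- as.data.frame(sites)
    out$mean_pct <- rowMeans(sites)
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

default_ids <- function(config) sprintf("p%03d", seq_len(config$n_participants))

#' Draw per-participant true discount rates
#'
#' Generates the truth table of the simulated cohort: for participant `i`
#' and condition `c`, `log k[i, c] = mu_log_k + u_i + offset_c +
#' gamma * z_i * [c untrustworthy] + eps`, with `u_i` the participant
#' random intercept, `z_i` the standardized site-3 methylation (population
#' beta moments) and `gamma` calibrated so that at large `n` the
#' correlation between site-3 methylation and the untrustworthy log-shift
#' (mean of the two untrustworthy cells minus baseline) equals
#' `coupling_k`; analogously for `h`. Baseline rates are independent of
#' methylation by construction.
#'
#' @inheritParams simulate_methylation
#' @param methylation Methylation records from [simulate_methylation()].
#' @return Data frame `participant_id`, `condition`, `log_k`, `log_h`,
#'   `k`, `h` covering the full cross.
#' @export
draw_participants <- function(config, methylation, seed = NULL) {
  draw <- function() {
    ids <- methylation$participant_id
    n <- length(ids)
    lab <- condition_labels()
    mu3 <- 100 * config$methylation_alpha[3] /
      (config$methylation_alpha[3] + config$methylation_beta[3])
    v3 <- 100^2 * config$methylation_alpha[3] * config$methylation_beta[3] /
      ((config$methylation_alpha[3] + config$methylation_beta[3])^2 *
         (config$methylation_alpha[3] + config$methylation_beta[3] + 1))
    z <- (methylation$site3 - mu3) / sqrt(v3)
    gam_k <- coupling_gamma(config$coupling_k, config$noise_sd_k)
    gam_h <- coupling_gamma(config$coupling_h, config$noise_sd_h)
    u_k <- stats::rnorm(n, 0, config$sigma_between_k)
    u_h <- stats::rnorm(n, 0, config$sigma_between_h)
    grid <- expand.grid(participant_id = ids, condition = lab,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(grid$participant_id, ids)
    untrust <- grid$condition %in% untrustworthy_labels()
    grid$log_k <- config$mu_log_k + u_k[i] +
      config$condition_offsets_k[grid$condition] +
      gam_k * z[i] * untrust +
      stats::rnorm(nrow(grid), 0, config$noise_sd_k)
    grid$log_h <- config$mu_log_h + u_h[i] +
      config$condition_offsets_h[grid$condition] +
      gam_h * z[i] * untrust +
      stats::rnorm(nrow(grid), 0, config$noise_sd_h)
    grid$k <- exp(grid$log_k)
    grid$h <- exp(grid$log_h)
    rownames(grid) <- NULL
    grid
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Probability of choosing the larger option
#'
#' Logistic (softmax) choice rule on the hyperbolic subjective-value
#' difference: `P(larger) = logistic(beta * (V_larger - V_smaller))`,
#' where `V_larger` is the hyperbolically discounted value of the delayed
#' or probabilistic reward at the decision maker's true rate and
#' `V_smaller` the face value of the immediate/certain option. At the
#' item's indifference rate the probability is exactly 0.5 for any `beta`.
#'
#' @param item Rows of an item bank.
#' @param rate True discount rate(s), recycled against `item`.
#' @param beta Choice sensitivity (>= 0) per currency unit.
#' @return Probabilities in (0, 1).
#' @export
choice_prob <- function(item, rate, beta) {
  stopifnot(all(rate > 0), beta >= 0)
  denom <- ifelse(item$task == "delay",
                  1 + rate * item$delay_days,
                  1 + rate * odds_against(item$win_probability))
  v_larger <- item$larger_amount / denom
  stats::plogis(beta * (v_larger - item$smaller_amount))
}

#' Simulate binary choices for a session design
#'
#' One Bernoulli draw per trial at [choice_prob()], using the true rate of
#' the trial's participant and condition from the truth table.
#'
#' @param design Trials from [build_session()] (or several stacked).
#' @param truth Truth table from [draw_participants()].
#' @param bank The ranked item bank of the design's task.
#' @param config A [sim_config()] (for `choice_sensitivity`).
#' @inheritParams simulate_methylation
#' @return `design` with a `choice` column appended.
#' @export
simulate_choices <- function(design, truth, bank, config, seed = NULL) {
  draw <- function() {
    key_d <- paste(design$participant_id, design$condition)
    key_t <- paste(truth$participant_id, truth$condition)
    i <- match(key_d, key_t)
    if (anyNA(i))
      stop("truth table does not cover all design participants/conditions")
    rate <- if (bank$task[1] == "delay") truth$k[i] else truth$h[i]
    item <- bank[match(design$item_id, bank$item_id), ]
    p <- choice_prob(item, rate, config$choice_sensitivity)
    design$choice <- stats::rbinom(nrow(design), 1, p)
    design
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# Inverse-Gaussian deviates, Michael/Schucany/Haas transformation.
rinvgauss <- function(n, mean, shape) {
  if (any(mean <= 0) || any(shape <= 0))
    stop("inverse-Gaussian mean and shape must be positive")
  y <- stats::rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Simulate response times
#'
#' Draws each trial's response time as a fixed non-decision shift plus an
#' inverse-Gaussian deviate whose mean depends on whether a proposer face
#' was present (faster with a face) and on the response given (faster for
#' the smaller-sooner/certain option), per the `rt_mean_ms` cell means of
#' the configuration.
#'
#' @param trials Trials with `condition` and `choice` columns.
#' @param config A [sim_config()].
#' @inheritParams simulate_methylation
#' @return `trials` with an `rt_ms` column appended; all values exceed
#'   `rt_shift_ms`.
#' @export
simulate_rts <- function(trials, config, seed = NULL) {
  draw <- function() {
    face <- ifelse(trials$condition == "baseline", 1L, 2L)
    resp <- trials$choice + 1L
    mu <- config$rt_mean_ms[cbind(face, resp)] - config$rt_shift_ms
    trials$rt_ms <- config$rt_shift_ms +
      rinvgauss(nrow(trials), mu, config$rt_shape_ms)
    trials
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Simulate a full cohort
#'
#' Orchestrates the generator: methylation records, the truth table of
#' per-condition discount rates (with site-3 coupling), one randomized
#' session design per participant and task, logistic choices and
#' inverse-Gaussian response times. Everything is drawn from a single RNG
#' stream seeded by `config$seed`, so the output is byte-identical across
#' calls with the same configuration.
#'
#' @param config A [sim_config()].
#' @param banks Named list of ranked banks, as in [score_all()].
#' @return List of class `"discounting_cohort"` with elements `trials`
#'   (choice records with response times), `truth`, `methylation` and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            banks = list(delay = mcq_bank(),
                                         probability = pdq_bank())) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    meth <- simulate_methylation(config)
    truth <- draw_participants(config, meth)
    sessions <- lapply(names(banks), function(task) {
      bank <- banks[[task]]
      per_part <- lapply(meth$participant_id, function(id) {
        des <- build_session(bank, id,
                             seed = stats::runif(1, 1, 2^31 - 2),
                             key_mapping = sample(c("standard", "reversed"),
                                                  1))
        simulate_choices(des, truth, bank, config)
      })
      do.call(rbind, per_part)
    })
    trials <- do.call(rbind, sessions)
    trials <- simulate_rts(trials, config)
    rownames(trials) <- NULL
    structure(list(trials = trials, truth = truth, methylation = meth,
                   config = config),
              class = "discounting_cohort")
  })
}

#' @export
print.discounting_cohort <- function(x, ...) {
  cat("Simulated discounting cohort\n",
      "  participants: ", x$config$n_participants, "\n",
      "  trials:       ", nrow(x$trials), " (",
      paste(unique(x$trials$task), collapse = " + "), ")\n",
      "  methylation:  4 CpG sites, site-3 coupling ",
      x$config$coupling_k, " (k) / ", x$config$coupling_h, " (h)\n",
      sep = "")
  invisible(x)
}
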