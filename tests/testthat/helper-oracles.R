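# Independent oracles and tiny fixtures used across the suite.

# Brute-force consistency scorer: plain loops over every cut point,
# recomputing rank-group values and per-item predictions from scratch.
oracle_score <- function(choices, bank) {
  ranks <- sort(unique(bank$rank))
  v <- vapply(ranks, function(r) {
    exp(mean(log(bank$indiff[bank$rank == r])))
  }, numeric(1))
  G <- length(v)
  values <- numeric(G + 1)
  cons <- numeric(G + 1)
  for (r in 0:G) {
    values[r + 1] <- if (r == 0) v[1] else if (r == G) v[G]
                     else sqrt(v[r] * v[r + 1])
    n_ok <- 0
    for (i in seq_len(nrow(choices))) {
      g <- bank$rank[match(choices$item_id[i], bank$item_id)]
      predicted <- if (g > r) 1L else 0L
      if (choices$choice[i] == predicted) n_ok <- n_ok + 1
    }
    cons[r + 1] <- n_ok / nrow(choices)
  }
  best <- which(cons == max(cons))
  list(value = exp(mean(log(values[best]))), consistency = max(cons))
}

# Normal-equations least squares, independent of lm machinery.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = drop(b), vcov = sigma2 * solve(XtX))
}

# Delay bank with one item per requested indifference value, all in one
# magnitude group, so each item forms its own rank group (group value =
# item value).
toy_delay_bank <- function(kvals, delay = 10, smaller = 10) {
  bank <- data.frame(
    item_id = sprintf("t%02d", seq_along(kvals)),
    task = "delay",
    smaller_amount = smaller,
    larger_amount = smaller * (1 + kvals * delay),
    delay_days = delay,
    win_probability = NA,
    group = "g1",
    stringsAsFactors = FALSE
  )
  bank$indiff <- trustdisc::indifference_k(bank)
  trustdisc::assign_ranks(bank)
}

# Deterministic hyperbolic responder: larger option iff rate < item k*.
deterministic_choices <- function(bank, rate) {
  data.frame(item_id = bank$item_id,
             choice = as.integer(rate < bank$indiff),
             stringsAsFactors = FALSE)
}

# Balanced per-participant-per-condition estimate table with known
# condition means (log scale) for the condition-model tests.
toy_estimates <- function(n_participants, cond_means, sigma_u = 0,
                          sigma_e = 0.3, kind = "k", seed = 1) {
  withr::with_seed(seed, {
    lab <- trustdisc::condition_labels()
    ids <- sprintf("s%02d", seq_len(n_participants))
    grid <- expand.grid(participant_id = ids, condition = lab,
                        stringsAsFactors = FALSE)
    u <- stats::rnorm(n_participants, 0, sigma_u)
    grid$log_value <- cond_means[grid$condition] +
      u[match(grid$participant_id, ids)] +
      stats::rnorm(nrow(grid), 0, sigma_e)
    grid$value <- exp(grid$log_value)
    grid$parameter_kind <- kind
    grid
  })
}
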