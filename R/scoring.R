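#' Rank-group indifference values
#'
#' Geometric mean of the item indifference values sharing each rank label,
#' in rank order. These are the "group values" that consistency scoring
#' compares candidate rates against; they must be strictly increasing.
#'
#' @param bank A ranked item bank (see [assign_ranks()]).
#' @return Named numeric vector, one value per rank group, increasing.
#' @export
rank_group_values <- function(bank) {
  if (is.null(bank$rank) || anyNA(bank$rank))
    stop("bank has no ranks; call assign_ranks() first")
  v <- vapply(split(bank$indiff, bank$rank), function(x) exp(mean(log(x))),
              numeric(1))
  v <- v[order(as.integer(names(v)))]
  if (any(diff(v) <= 0))
    stop("rank-group indifference values must be strictly increasing")
  v
}

#' Candidate discount rates for consistency scoring
#'
#' For rank-group values `v_1 < ... < v_G` the candidates are the lower
#' edge `v_1` (a responder who always prefers the larger, later/riskier
#' option), the geometric means of adjacent group values (a responder who
#' switches between rank `r` and `r + 1`), and the upper edge `v_G`
#' (always smaller, sooner/certain). Edge candidates reuse the extreme
#' group values so that assigned rates, and hence their logs, stay finite.
#'
#' @inheritParams rank_group_values
#' @return Strictly increasing numeric vector of `G + 1` candidate rates
#'   (a single value when `G = 1`).
#' @export
candidate_values <- function(bank) {
  v <- unname(rank_group_values(bank))
  G <- length(v)
  if (G == 1) return(v)
  c(v[1], sqrt(v[-G] * v[-1]), v[G])
}

# Cut-point representation used internally: candidate r in 0..G predicts
# the smaller option for rank groups <= r and the larger option above.
candidate_cuts <- function(v) {
  G <- length(v)
  list(cut = 0:G,
       value = if (G == 1) c(v, v) else c(v[1], sqrt(v[-G] * v[-1]), v[G]))
}

#' Consistency of choices with a candidate rate
#'
#' Proportion of observed binary choices that match the choices a perfectly
#' hyperbolic decision maker with discount rate `candidate` would make:
#' pick the larger option on items whose rank-group indifference value
#' exceeds the candidate. The smallest candidate (the lower edge of
#' [candidate_values()]) predicts the larger option everywhere.
#'
#' @param candidate A single positive candidate rate.
#' @param choices Data frame with columns `item_id` and `choice`
#'   (0 = smaller-sooner/certain, 1 = larger-later/probabilistic).
#' @param bank The ranked item bank the items belong to.
#' @return Fraction in \[0, 1\].
#' @export
consistency <- function(candidate, choices, bank) {
  if (is.null(choices) || nrow(choices) == 0) stop("empty choice set")
  v <- unname(rank_group_values(bank))
  idx <- match(choices$item_id, bank$item_id)
  if (anyNA(idx))
    stop("choices refer to items not in the bank: ",
         paste(unique(choices$item_id[is.na(idx)]), collapse = ", "))
  g <- bank$rank[idx]
  predict_larger <- candidate <= v[1] | candidate < v[g]
  mean(choices$choice == as.integer(predict_larger))
}

#' Score one participant-condition choice set
#'
#' Evaluates every candidate rate's consistency with the observed choices
#' and assigns the geometric mean of all candidates attaining the maximum.
#' A responder who always takes the larger option receives the smallest
#' rank-group value, one who always takes the smaller option the largest,
#' both with consistency 1.
#'
#' @param choices Data frame with columns `item_id` and `choice`; items
#'   missing from the set are simply not scored (`n_items` records how
#'   many were).
#' @param bank Ranked item bank.
#' @param subscores If `TRUE` (default for the delay task), also score
#'   each magnitude group / block separately; returned as the
#'   `"subscores"` attribute.
#' @return One-row data frame: `parameter_kind` (`"k"` or `"h"`), `value`,
#'   `log_value` (natural log), `consistency`, `n_items`.
#' @export
score <- function(choices, bank, subscores = FALSE) {
  if (is.null(choices) || nrow(choices) == 0) stop("empty choice set")
  if (!all(choices$choice %in% c(0L, 1L))) stop("choices must be 0 or 1")
  v <- unname(rank_group_values(bank))
  cand <- candidate_cuts(v)
  idx <- match(choices$item_id, bank$item_id)
  if (anyNA(idx))
    stop("choices refer to items not in the bank: ",
         paste(unique(choices$item_id[is.na(idx)]), collapse = ", "))
  g <- bank$rank[idx]
  cons <- vapply(cand$cut,
                 function(r) mean(choices$choice == as.integer(g > r)),
                 numeric(1))
  best <- which(cons == max(cons))
  out <- data.frame(
    parameter_kind = if (bank$task[1] == "delay") "k" else "h",
    value = exp(mean(log(cand$value[best]))),
    consistency = max(cons),
    n_items = nrow(choices),
    stringsAsFactors = FALSE
  )
  out$log_value <- log(out$value)
  out <- out[, c("parameter_kind", "value", "log_value", "consistency",
                 "n_items")]
  if (subscores) {
    sub <- lapply(unique(bank$group), function(gr) {
      sb <- bank[bank$group == gr, ]
      sc <- choices[choices$item_id %in% sb$item_id, , drop = FALSE]
      if (nrow(sc) == 0) return(NULL)
      cbind(group = gr, score(sc, sb, subscores = FALSE))
    })
    attr(out, "subscores") <- do.call(rbind, sub)
  }
  out
}

#' Score a full trial table
#'
#' Splits trial-level choice records by participant, task and condition
#' and scores each cell with [score()]. Each trial must be unique in
#' (participant, task, condition, item); duplicates are an error.
#' Participant-condition cells absent from the input produce no row; a
#' message lists how many cells were missing relative to the full
#' participants x conditions x tasks cross.
#'
#' @param trials Data frame of choice records with columns
#'   `participant_id`, `task`, `condition`, `item_id`, `choice` (and
#'   optionally `rt_ms`, ignored here).
#' @param banks Named list of ranked banks, e.g.
#'   `list(delay = mcq_bank(), probability = pdq_bank())`.
#' @return Data frame with one [score()] row per participant, task and
#'   condition, plus the identifying columns.
#' @export
score_all <- function(trials,
                      banks = list(delay = mcq_bank(),
                                   probability = pdq_bank())) {
  stopifnot(all(c("participant_id", "task", "condition", "item_id",
                  "choice") %in% names(trials)))
  bad <- setdiff(unique(trials$condition), condition_labels())
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))
  if (!all(trials$task %in% names(banks)))
    stop("trials contain tasks with no bank: ",
         paste(setdiff(unique(trials$task), names(banks)), collapse = ", "))
  key <- interaction(trials$participant_id, trials$task, trials$condition,
                     trials$item_id, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated trial rows for the same participant/condition/item")
  cell <- interaction(trials$participant_id, trials$task, trials$condition,
                      drop = TRUE, sep = "\r")
  parts <- split(trials, cell)
  rows <- lapply(parts, function(d) {
    cbind(participant_id = d$participant_id[1], task = d$task[1],
          condition = d$condition[1],
          score(d[, c("item_id", "choice")], banks[[d$task[1]]]))
  })
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  n_expected <- length(unique(trials$participant_id)) *
    length(condition_labels()) * length(unique(trials$task))
  if (nrow(est) < n_expected)
    message(n_expected - nrow(est),
            " participant-condition cells had no trials and were skipped")
  est
}
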