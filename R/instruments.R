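#' Proposer conditions
#'
#' The seven within-participant conditions of the discounting tasks: a
#' baseline block with no proposer, plus the cross of proposer gender
#' (female, male) and perceived trustworthiness (trustworthy, neutral,
#' untrustworthy).
#'
#' @return A data frame with columns `label`, `gender` and `trust_level`.
#'   `baseline` has gender and trust level `"none"`.
#' @export
#' @examples
#' condition_table()
condition_table <- function() {
  data.frame(
    label = c("baseline",
              "female_trustworthy", "male_trustworthy",
              "female_neutral", "male_neutral",
              "female_untrustworthy", "male_untrustworthy"),
    gender = c("none", "female", "male", "female", "male", "female", "male"),
    trust_level = c("none", "trustworthy", "trustworthy", "neutral",
                    "neutral", "untrustworthy", "untrustworthy"),
    stringsAsFactors = FALSE
  )
}

#' @rdname condition_table
#' @export
condition_labels <- function() condition_table()$label

untrustworthy_labels <- function() {
  ct <- condition_table()
  ct$label[ct$trust_level == "untrustworthy"]
}

#' Packaged item banks
#'
#' `mcq_bank()` returns the 27-item monetary choice questionnaire (delay
#' discounting): nine small, nine medium and nine large delayed rewards,
#' each pitting an immediate amount against a larger delayed amount.
#' `pdq_bank()` returns the 30-item probability discounting questionnaire:
#' three blocks of ten items, each pitting a certain amount against a
#' larger probabilistic amount (block 1: 20 vs 80, block 2: 40 vs 100,
#' block 3: 40 vs 60 currency units).
#'
#' Banks are shipped as plain comma-separated tables under
#' `inst/extdata/` and returned with the hyperbolic indifference value of
#' every item (`indiff`) and its within-group rank (`rank`) already
#' computed; see [assign_ranks()].
#'
#' @return A ranked item-bank data frame with columns `item_id`, `task`,
#'   `smaller_amount`, `larger_amount`, `delay_days`, `win_probability`,
#'   `group`, `indiff`, `rank`.
#' @seealso [indifference_k()], [indifference_h()], [assign_ranks()]
#' @export
mcq_bank <- function() load_bank("mcq_items.csv")

#' @rdname mcq_bank
#' @export
pdq_bank <- function() load_bank("pdq_items.csv")

load_bank <- function(file) {
  path <- system.file("extdata", file, package = "trustdisc")
  if (path == "") stop("packaged item table not found: ", file)
  bank <- utils::read.csv(path, stringsAsFactors = FALSE)
  bank$indiff <- item_indifference(bank)
  assign_ranks(validate_bank(bank))
}

validate_bank <- function(bank) {
  required <- c("item_id", "task", "smaller_amount", "larger_amount",
                "delay_days", "win_probability", "group")
  missing <- setdiff(required, names(bank))
  if (length(missing))
    stop("item bank is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(bank$item_id))
    stop("item_id values must be unique")
  if (!all(bank$task %in% c("delay", "probability")))
    stop("task must be 'delay' or 'probability'")
  if (any(bank$smaller_amount <= 0))
    stop("smaller_amount must be positive")
  if (any(bank$larger_amount <= bank$smaller_amount))
    stop("larger_amount must exceed smaller_amount")
  is_delay <- bank$task == "delay"
  if (any(is_delay & (is.na(bank$delay_days) | bank$delay_days <= 0)))
    stop("delay items need delay_days > 0")
  if (any(is_delay & !is.na(bank$win_probability)))
    stop("delay items must not set win_probability")
  if (any(!is_delay & (is.na(bank$win_probability) |
                       bank$win_probability <= 0 | bank$win_probability >= 1)))
    stop("probability items need win_probability in (0, 1)")
  if (any(!is_delay & !is.na(bank$delay_days)))
    stop("probability items must not set delay_days")
  bank
}

item_indifference <- function(items) {
  ifelse(items$task == "delay",
         (items$larger_amount / items$smaller_amount - 1) / items$delay_days,
         (items$larger_amount / items$smaller_amount - 1) *
           items$win_probability / (1 - items$win_probability))
}

#' Hyperbolic indifference values
#'
#' For a delay item the subjective value of the delayed reward is
#' `V = A / (1 + k D)` with amount `A` and delay `D` (days); the
#' indifference rate `k*` is the discount rate at which `V` equals the
#' immediate amount, `k* = (A / A_s - 1) / D`. For a probability item the
#' delay is replaced by the odds against winning `theta = (1 - p) / p`, so
#' `V = A / (1 + h theta)` and `h* = (A / A_s - 1) / theta`. Larger values
#' mean the item tolerates steeper discounting before the smaller option
#' wins.
#'
#' @param item One or more rows of an item-bank data frame.
#' @return Numeric vector of indifference rates (per day for `k*`,
#'   per odds unit for `h*`).
#' @export
#' @examples
#' bank <- mcq_bank()
#' indifference_k(bank[1, ])
indifference_k <- function(item) {
  if (!all(item$task == "delay"))
    stop("indifference_k() requires delay items")
  (item$larger_amount / item$smaller_amount - 1) / item$delay_days
}

#' @rdname indifference_k
#' @export
indifference_h <- function(item) {
  if (!all(item$task == "probability"))
    stop("indifference_h() requires probability items")
  (item$larger_amount / item$smaller_amount - 1) /
    odds_against(item$win_probability)
}

#' Odds against winning
#'
#' Transforms a win probability `p` into the odds against winning,
#' `theta = (1 - p) / p`, the quantity that puts probability discounting
#' in the same hyperbolic form as delay discounting.
#'
#' @param p Win probability, strictly between 0 and 1.
#' @return `(1 - p) / p`, strictly decreasing in `p`.
#' @export
#' @examples
#' odds_against(0.1) # 9
odds_against <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("win probability must lie strictly between 0 and 1")
  (1 - p) / p
}

#' Assign within-group item ranks
#'
#' Orders the items of each magnitude group (delay bank) or block
#' (probability bank) by their indifference value and assigns ranks
#' `1..n` ascending. Because the packaged banks place one item per rank
#' and group with closely matched indifference values across groups, the
#' rank labels partition the bank into rank groups (9 for the delay bank,
#' 10 for the probability bank) that drive consistency scoring.
#'
#' Ties in indifference value within a group are an error: ranks would be
#' ambiguous and the packaged instruments contain none.
#'
#' @param bank An item-bank data frame with an `indiff` column (added
#'   automatically if absent).
#' @return The bank with a `rank` column; row order is preserved.
#' @export
assign_ranks <- function(bank) {
  if (is.null(bank$indiff)) bank$indiff <- item_indifference(bank)
  bank$rank <- NA_integer_
  for (g in unique(bank$group)) {
    idx <- which(bank$group == g)
    v <- bank$indiff[idx]
    if (anyDuplicated(v))
      stop("tied indifference values within group '", g,
           "': ranks are ambiguous")
    bank$rank[idx][order(v)] <- seq_along(idx)
  }
  bank
}

#' Build a full-session trial design
#'
#' Crosses every item of a bank with the seven proposer conditions and
#' returns the trials in a seeded random order, as presented to one
#' participant (189 trials for the delay bank, 210 for the probability
#' bank). The key-side counterbalancing flag is recorded with each trial
#' but plays no role in the analysis.
#'
#' @param bank A (ranked) item bank.
#' @param participant_id Identifier copied onto every trial.
#' @param seed Integer seed for the presentation order; the same seed
#'   reproduces the same order. The caller's RNG state is left untouched.
#' @param key_mapping `"standard"` or `"reversed"`.
#' @return Data frame with columns `participant_id`, `trial`, `task`,
#'   `condition`, `item_id`, `key_mapping`.
#' @export
build_session <- function(bank, participant_id, seed,
                          key_mapping = c("standard", "reversed")) {
  key_mapping <- match.arg(key_mapping)
  validate_bank(bank)
  cross <- expand.grid(item_id = bank$item_id,
                       condition = condition_labels(),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ord <- withr::with_seed(as.integer(seed), sample.int(nrow(cross)))
  cross <- cross[ord, ]
  data.frame(participant_id = participant_id,
             trial = seq_len(nrow(cross)),
             task = bank$task[1],
             condition = cross$condition,
             item_id = cross$item_id,
             key_mapping = key_mapping,
             row.names = NULL, stringsAsFactors = FALSE)
}
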