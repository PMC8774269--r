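#' Read and write trial-level choice records
#'
#' Trial tables are plain comma-separated files with header
#' `participant_id, task, condition, item_id, choice, rt_ms`. Response
#' times are in milliseconds (reports convert to seconds). Reading
#' validates every row: `task` must be `delay` or `probability`,
#' `condition` one of the seven fixed labels, `choice` 0 or 1 and `rt_ms`
#' (if present) non-negative; offending row numbers are listed in the
#' error.
#'
#' @param path File path.
#' @param trials Trial data frame to write.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "task", "condition", "item_id", "choice")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  problems <- character(0)
  bad <- which(!d$task %in% c("delay", "probability"))
  if (length(bad))
    problems <- c(problems, paste0("unknown task at row(s) ",
                                   paste(bad, collapse = ", ")))
  bad <- which(!d$condition %in% condition_labels())
  if (length(bad))
    problems <- c(problems, paste0("unknown condition at row(s) ",
                                   paste(bad, collapse = ", ")))
  bad <- which(!d$choice %in% c(0L, 1L))
  if (length(bad))
    problems <- c(problems, paste0("choice must be 0 or 1 at row(s) ",
                                   paste(bad, collapse = ", ")))
  if (!is.null(d$rt_ms)) {
    bad <- which(!is.na(d$rt_ms) & d$rt_ms < 0)
    if (length(bad))
      problems <- c(problems, paste0("negative rt_ms at row(s) ",
                                     paste(bad, collapse = ", ")))
  }
  if (length(problems))
    stop("malformed trial table:\n  ", paste(problems, collapse = "\n  "))
  d
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write methylation tables
#'
#' Comma-separated files with header `participant_id, site1, site2, site3,
#' site4`, percent methylation in \[0, 100\] at each CpG site. The
#' per-participant mean of the four sites (`mean_pct`) is recomputed on
#' read.
#'
#' @param path File path.
#' @param methylation Methylation data frame to write (the `mean_pct`
#'   column is dropped on write and recomputed on read).
#' @return `read_methylation()` returns the validated data frame with
#'   `mean_pct`; `write_methylation()` returns `path` invisibly.
#' @export
read_methylation <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", paste0("site", 1:4))
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("methylation table is missing columns: ",
         paste(missing, collapse = ", "))
  sites <- as.matrix(d[paste0("site", 1:4)])
  if (any(!is.finite(sites)) || any(sites < 0) || any(sites > 100))
    stop("percent methylation must lie in [0, 100] at row(s) ",
         paste(which(rowSums(!is.finite(sites) | sites < 0 | sites > 100)
                     > 0), collapse = ", "))
  d$mean_pct <- rowMeans(sites)
  d
}

#' @rdname read_methylation
#' @export
write_methylation <- function(methylation, path) {
  keep <- c("participant_id", paste0("site", 1:4))
  utils::write.csv(methylation[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the complete analysis on a trial table (and optionally a
#' methylation table): consistency scoring of every participant-condition
#' cell; for each discounting parameter a treatment-coded mixed model
#' against baseline, a sum-coded trust-by-gender model with type-3 Wald
#' omnibus tests, and estimated marginal means by trust level with
#' Bonferroni-corrected comparisons; response-time filtering (250 ms /
#' mean + 3 SD) and inverse-Gaussian mixed models per task; delta scores;
#' and, when methylation data are supplied, per-site Pearson correlations
#' plus the moderation model with probed conditional effects and bootstrap
#' intervals. Without methylation data the moderation stage is skipped
#' with a message.
#'
#' @param trials Trial data frame or path to one (see [read_trials()]).
#' @param methylation Optional methylation data frame or path.
#' @param banks Named list of ranked item banks.
#' @param seed Seed for the bootstrap stage.
#' @param bootstrap_B Bootstrap resamples.
#' @param probe_policy `"percentile"` or `"meansd"`.
#' @param out_dir If non-`NULL`, `report.json` (machine readable) and
#'   `summary.txt` (human readable) are written there.
#' @param verbose Print stage progress.
#' @return The report: a nested list that serializes deterministically to
#'   JSON (see [report_json()], [validate_report()]).
#' @export
run_pipeline <- function(trials, methylation = NULL,
                         banks = list(delay = mcq_bank(),
                                      probability = pdq_bank()),
                         seed = 1L, bootstrap_B = 1000,
                         probe_policy = "percentile",
                         out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.character(methylation)) methylation <- read_methylation(methylation)

  say("scoring choices")
  estimates <- stage("scoring", score_all(trials, banks))

  report <- list(meta = list(
    package = "trustdisc",
    seed = as.integer(seed),
    n_participants = length(unique(trials$participant_id)),
    n_trials = nrow(trials),
    tasks = sort(unique(trials$task)),
    bootstrap_B = bootstrap_B,
    probe_policy = probe_policy
  ))
  report$estimates <- estimates

  report$condition_models <- list()
  for (kind in intersect(c("k", "h"), unique(estimates$parameter_kind))) {
    say("condition models for ", kind)
    est <- estimates[estimates$parameter_kind == kind, ]
    fit_t <- stage(paste0("condition model (", kind, ", treatment)"),
                   fit_condition_model(est, "treatment"))
    fit_s <- stage(paste0("condition model (", kind, ", sum)"),
                   fit_condition_model(est, "sum"))
    report$condition_models[[kind]] <- list(
      treatment = fit_t$coefficients,
      omnibus = omnibus_wald(fit_s),
      marginal_means_trust = marginal_means(fit_s, "trust")
    )
  }

  say("response times")
  filtered <- stage("rt filter", filter_rts(trials))
  report$response_times <- list(filter_report = filtered$report)
  for (tk in sort(unique(trials$task))) {
    tt <- filtered$trials[filtered$trials$task == tk, ]
    fit_t <- stage(paste0("rt model (", tk, ", treatment)"),
                   fit_rt_model(tt, "treatment"))
    fit_s <- stage(paste0("rt model (", tk, ", sum)"),
                   fit_rt_model(tt, "sum"))
    report$response_times[[tk]] <- list(
      treatment = fit_t$coefficients,
      omnibus = omnibus_wald(fit_s)
    )
  }

  say("delta scores")
  report$delta_scores <- list()
  for (kind in names(report$condition_models)) {
    est <- estimates[estimates$parameter_kind == kind, ]
    report$delta_scores[[kind]] <-
      stage(paste0("delta scores (", kind, ")"), delta_scores(est))
  }

  if (is.null(methylation)) {
    say("no methylation table supplied; skipping the moderation stage")
  } else {
    report$moderation <- list()
    for (kind in names(report$condition_models)) {
      say("moderation for ", kind)
      est <- estimates[estimates$parameter_kind == kind, ]
      mod <- stage(paste0("moderation (", kind, ")"),
                   moderation_analysis(est, methylation, B = bootstrap_B,
                                       seed = seed, policy = probe_policy))
      report$moderation[[kind]] <- list(
        correlations = lapply(mod$correlations, unclass),
        model = list(coefficients = as.list(mod$fit$coefficients),
                     se = as.list(mod$fit$se),
                     r_squared = mod$fit$r_squared, f = mod$fit$f,
                     df1 = mod$fit$df1, df2 = mod$fit$df2,
                     p_value = mod$fit$p_value),
        conditional_effects = mod$probes,
        bootstrap = mod$bootstrap[c("coefficients", "conditional_effects",
                                    "B", "level", "n_skipped")]
      )
    }
  }

  validate_report(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(report_json(report), file.path(out_dir, "report.json"))
    writeLines(report_summary(report), file.path(out_dir, "summary.txt"))
    say("report written to ", out_dir)
  }
  invisible(report)
}

#' Serialize, summarize and validate pipeline reports
#'
#' `report_json()` renders the report as canonical JSON (stable key order,
#' full precision) so identical inputs and seed give byte-identical
#' output. `report_summary()` renders a short human-readable summary.
#' `validate_report()` checks the report against the packaged schema
#' (`inst/extdata/report_schema.json`): required sections must be present
#' and of the declared JSON type.
#'
#' @param report A report from [run_pipeline()].
#' @return `report_json()` a JSON string; `report_summary()` a character
#'   vector of lines; `validate_report()` `TRUE` invisibly (errors
#'   otherwise).
#' @export
report_json <- function(report) {
  jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, na = "null",
                   dataframe = "columns")
}

#' @rdname report_json
#' @export
validate_report <- function(report) {
  schema_path <- system.file("extdata", "report_schema.json",
                             package = "trustdisc")
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  json_type <- function(x) {
    if (is.data.frame(x) || (is.list(x) && !is.null(names(x)))) "object"
    else if (is.list(x)) "array"
    else if (is.character(x)) "string"
    else if (is.numeric(x)) "number"
    else "other"
  }
  for (section in names(schema$required)) {
    if (is.null(report[[section]]))
      stop("report is missing required section '", section, "'")
    want <- schema$required[[section]]
    got <- json_type(report[[section]])
    if (got != want)
      stop("report section '", section, "' has type ", got,
           ", schema requires ", want)
  }
  for (section in names(schema$optional)) {
    if (!is.null(report[[section]])) {
      want <- schema$optional[[section]]
      got <- json_type(report[[section]])
      if (got != want)
        stop("report section '", section, "' has type ", got,
             ", schema requires ", want)
    }
  }
  invisible(TRUE)
}

#' @rdname report_json
#' @export
report_summary <- function(report) {
  lines <- c(
    "Discounting-with-proposers pipeline report",
    sprintf("participants: %d, trials: %d, tasks: %s",
            report$meta$n_participants, report$meta$n_trials,
            paste(report$meta$tasks, collapse = ", ")),
    ""
  )
  for (kind in names(report$condition_models)) {
    cm <- report$condition_models[[kind]]
    sig <- cm$treatment$term[cm$treatment$significant &
                               cm$treatment$term != "(Intercept)"]
    lines <- c(lines,
               sprintf("log %s vs baseline: significant conditions (|t| > 2): %s",
                       kind, if (length(sig)) paste(sig, collapse = ", ")
                       else "none"),
               sprintf("  trust-level omnibus: chi2 = %.2f (df %d), p = %.4g",
                       cm$omnibus$wald_chisq[cm$omnibus$term == "trust"],
                       cm$omnibus$df[cm$omnibus$term == "trust"],
                       cm$omnibus$p_value[cm$omnibus$term == "trust"]),
               sprintf("  back-transformed %s by trust level: %s", kind,
                       paste(sprintf("%s %.3f", cm$marginal_means_trust$means$level,
                                     cm$marginal_means_trust$means$response),
                             collapse = ", ")))
  }
  fr <- report$response_times$filter_report
  lines <- c(lines, "",
             sprintf("rt filter: removed %d fast / %d slow of %d trials",
                     sum(fr$n_fast), sum(fr$n_slow), sum(fr$n_total)))
  if (!is.null(report$moderation)) {
    for (kind in names(report$moderation)) {
      mo <- report$moderation[[kind]]
      lines <- c(lines,
                 sprintf("moderation (%s): site3-delta r = %.3f (p = %.4g); R2 = %.3f, F(%d, %d) = %.2f",
                         kind, mo$correlations$site3$r,
                         mo$correlations$site3$p_value, mo$model$r_squared,
                         mo$model$df1, mo$model$df2, mo$model$f))
    }
  } else {
    lines <- c(lines, "moderation: skipped (no methylation data)")
  }
  lines
}
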