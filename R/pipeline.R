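#' Score a full trial
#'
#' Runs the complete chain on a validated dataset: session delivery
#' scores, team-level receipt, individual participation and
#' responsiveness, the per-participant exposure/implementation totals,
#' and stratified summaries at every level.
#'
#' @param trial an [imp_trial()].
#' @return a list of class `imp_scores`: `session_scores`, `team_scores`,
#'   `responsiveness`, `individual`, `delivery` (one tibble per scope),
#'   `summaries` (one tibble per stratification), `consistency`.
#' @export
score_trial <- function(trial) {
  stopifnot(inherits(trial, "imp_trial"))
  session_scores <- score_sessions(trial)
  team_scores <- pe_team_scores(trial)
  resp <- responsiveness_scores(trial, session_scores)
  chain <- session_score_table(trial, session_scores, team_scores, resp)
  individual <- individual_scores(trial, chain, resp)
  delivery <- lapply(
    stats::setNames(nm = c("organization", "component", "workplace", "step")),
    function(b) summarize_delivery(session_scores, by = b))
  summaries <- lapply(
    stats::setNames(nm = c("total", "component", "step", "workplace")),
    function(b) stratified_summary(individual, by = b))
  consistency <- org_vs_individual_consistency(trial, individual)
  structure(
    list(session_scores = session_scores, team_scores = team_scores,
         responsiveness = resp, individual = individual,
         delivery = delivery, summaries = summaries,
         consistency = consistency),
    class = "imp_scores"
  )
}

#' @export
print.imp_scores <- function(x, ...) {
  org <- x$delivery$organization
  tot <- x$summaries$total
  fmt <- function(m) {
    row <- tot[tot$measure == m, ]
    sprintf("%s %d (n=%d)", m, percent(row$mean / 100), row$n)
  }
  cat(sprintf(
    "<imp_scores> dose %d%% (%d/%d sessions held), held-session fidelity %d\n  individual means: %s\n",
    percent(org$dose), org$n_held, org$n_intended,
    percent(org$fidelity_mean / 100),
    paste(vapply(imp_measures, fmt, ""), collapse = ", ")
  ))
  invisible(x)
}

#' Validate, score and write out a trial dataset
#'
#' The end-to-end run behind the command-line interface: reads a dataset
#' directory (see [read_trial()]) or takes an [imp_trial()], validates it,
#' aborts if violations at or above the configured severity are present,
#' scores everything, and writes the outputs as CSV plus a run log.
#' Repeated runs on identical inputs are byte-identical: the pipeline
#' draws no random numbers.
#'
#' Files written: `validation.csv`, `delivery_summary.csv` (all scopes,
#' keyed by `scope`/`stratum`), `receipt_team.csv`,
#' `receipt_individual.csv`, `individual_scores.csv`,
#' `summary_by_component.csv`, `summary_by_step.csv`,
#' `summary_by_workplace.csv`, `summary_total.csv`, `run_log.txt`.
#'
#' @param input a dataset directory or an `imp_trial`.
#' @param out_dir output directory (created if needed).
#' @param abort_on abort when violations of this severity (or worse)
#'   exist: `"error"` (default), `"warning"` (strict), or `"never"`.
#' @return invisibly, a list with the `imp_scores`, the validation
#'   report, and the written paths.
#' @export
run_score <- function(input, out_dir, abort_on = c("error", "warning", "never")) {
  abort_on <- match.arg(abort_on)
  trial <- if (inherits(input, "imp_trial")) input else read_trial(input)
  report <- validate_dataset(trial)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
    path
  }
  paths <- c(validation = wr(report, "validation"))
  bad <- switch(abort_on,
    never = FALSE,
    error = any(report$severity == "error"),
    warning = nrow(report) > 0
  )
  if (bad) {
    stop(sprintf(
      "validation failed (%d violation(s) at severity '%s' or above); see %s — first: [%s] %s",
      nrow(report), abort_on, paths[["validation"]],
      report$rule[1], report$message[1]
    ), call. = FALSE)
  }
  scores <- score_trial(trial)
  paths <- c(
    paths,
    delivery_summary = wr(dplyr::bind_rows(scores$delivery), "delivery_summary"),
    receipt_team = wr(scores$team_scores, "receipt_team"),
    receipt_individual = wr(scores$responsiveness, "receipt_individual"),
    individual_scores = wr(scores$individual, "individual_scores"),
    summary_total = wr(scores$summaries$total, "summary_total"),
    summary_by_component = wr(scores$summaries$component, "summary_by_component"),
    summary_by_step = wr(scores$summaries$step, "summary_by_step"),
    summary_by_workplace = wr(scores$summaries$workplace, "summary_by_workplace")
  )
  org <- scores$delivery$organization
  log_lines <- c(
    sprintf("impquant %s | R %s", as.character(utils::packageVersion("impquant")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("protocol: %s (%g h, %d planned sessions per participant)",
            trial$protocol$name, trial$protocol$total_hours,
            nrow(trial$protocol$sessions)),
    sprintf("participants: %d | teams: %d | workplaces: %d | steps: %d",
            nrow(trial$roster$participants), nrow(trial$roster$teams),
            length(unique(trial$roster$teams$workplace_id)),
            length(trial$roster$steps)),
    sprintf("sessions: %d intended / %d held (dose %d%%)",
            org$n_intended, org$n_held, percent(org$dose)),
    sprintf("logbooks: %d | attendance rows: %d | questionnaires: %d",
            nrow(trial$logbooks), nrow(trial$attendance),
            nrow(trial$questionnaires)),
    sprintf("validation: %d violation(s)", nrow(report))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths <- c(paths, run_log = file.path(out_dir, "run_log.txt"))
  invisible(list(scores = scores, validation = report, paths = paths))
}
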