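#' Construct a trial roster
#'
#' The roster ties participants to teams, workplaces and trial steps. In a
#' stepped-wedge design the step is the randomization group that fixes when
#' a participant's cluster crosses into the intervention; sessions inherit
#' the step of the group they are delivered to.
#'
#' @param participants data frame with columns `participant_id`, `team_id`,
#'   `workplace_id`, `step`.
#' @param teams data frame with columns `team_id`, `workplace_id`, `size`;
#'   `size` must equal the number of rostered members.
#' @param steps ordered character vector of step labels.
#' @return an object of class `imp_roster`.
#' @export
imp_roster <- function(participants, teams, steps) {
  participants <- tibble::as_tibble(participants)
  teams <- tibble::as_tibble(teams)
  steps <- as.character(steps)

  stopifnot(
    all(c("participant_id", "team_id", "workplace_id", "step") %in% names(participants)),
    all(c("team_id", "workplace_id", "size") %in% names(teams))
  )
  if (nrow(participants) == 0) stop("empty roster: no participants", call. = FALSE)
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant ids in roster", call. = FALSE)
  }
  if (anyDuplicated(teams$team_id)) stop("duplicate team ids in roster", call. = FALSE)

  unknown_team <- setdiff(participants$team_id, teams$team_id)
  if (length(unknown_team)) {
    stop("participant references unknown team: first offender ",
         unknown_team[1], call. = FALSE)
  }
  wp <- teams$workplace_id[match(participants$team_id, teams$team_id)]
  bad_wp <- which(wp != participants$workplace_id)
  if (length(bad_wp)) {
    stop("participant/team workplace mismatch: first offender ",
         participants$participant_id[bad_wp[1]], call. = FALSE)
  }
  counted <- table(participants$team_id)
  n_members <- as.integer(counted[match(teams$team_id, names(counted))])
  n_members[is.na(n_members)] <- 0L
  if (!all(teams$size == n_members)) {
    off <- teams$team_id[which(teams$size != n_members)[1]]
    stop("team size does not match member count: first offender ", off,
         call. = FALSE)
  }
  if (!all(participants$step %in% steps)) {
    stop("participant step label not in declared steps", call. = FALSE)
  }

  structure(list(participants = participants, teams = teams, steps = steps),
            class = "imp_roster")
}

#' @export
print.imp_roster <- function(x, ...) {
  cat(sprintf("<imp_roster> %d participants, %d teams, %d workplaces, %d steps\n",
              nrow(x$participants), nrow(x$teams),
              length(unique(x$teams$workplace_id)), length(x$steps)))
  invisible(x)
}

#' Bundle a full process-evaluation dataset
#'
#' Collects the protocol, roster, delivery-unit membership, session
#' records, deliverer logbooks, attendance and end-of-intervention
#' questionnaires into one object consumed by the scoring pipeline.
#' Structural requirements (column presence, known classes) are enforced
#' here; record-level consistency is reported by [validate_dataset()].
#'
#' @param protocol a [protocol_spec()].
#' @param roster an [imp_roster()].
#' @param units long-format delivery-unit membership: `unit_id`,
#'   `participant_id`. Each session is delivered to one unit (a team
#'   working group, a merged training group, or a kick-off assembly); a
#'   participant must belong to at most one unit holding any given session
#'   plan.
#' @param sessions one row per scheduled session: `session_id`, `plan_id`,
#'   `component_id`, `workplace_id`, `unit_id`, `step`, `held` (logical),
#'   `deliverer_id`.
#' @param logbooks one row per completed deliverer logbook: `session_id`,
#'   criterion rating columns `crit_1` ... `crit_5` (canonical
#'   four-category tokens, positionally matching the plan's criteria),
#'   understanding items `und_1` ... `und_4` and contribution items
#'   `con_1` ... `con_4` (five-category extent tokens), `performance`
#'   (integer 0-10), `intensity` (integer 0-10, physical-training sessions
#'   only), `motivation` (five-category extent token for the group).
#' @param attendance long format: `session_id`, `participant_id`.
#' @param questionnaires one row per responding participant:
#'   `participant_id`, component-specific satisfaction items named
#'   `sat_<component id, lowercase>`, overall items `sat_overall`,
#'   `sat_relevant`, `sat_interesting` (extent tokens), and social-support
#'   items `sup_1` ... `sup_4` (frequency tokens).
#' @return an object of class `imp_trial`.
#' @export
imp_trial <- function(protocol, roster, units, sessions, logbooks,
                      attendance, questionnaires) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(roster, "imp_roster"))
  units <- tibble::as_tibble(units)
  sessions <- tibble::as_tibble(sessions)
  logbooks <- tibble::as_tibble(logbooks)
  attendance <- tibble::as_tibble(attendance)
  questionnaires <- tibble::as_tibble(questionnaires)

  stopifnot(
    all(c("unit_id", "participant_id") %in% names(units)),
    all(c("session_id", "plan_id", "component_id", "workplace_id",
          "unit_id", "step", "held", "deliverer_id") %in% names(sessions)),
    "session_id" %in% names(logbooks),
    all(c("session_id", "participant_id") %in% names(attendance)),
    "participant_id" %in% names(questionnaires)
  )
  if (nrow(sessions) == 0) stop("unusable input: no sessions", call. = FALSE)
  if (!is.logical(sessions$held)) stop("sessions$held must be logical", call. = FALSE)

  structure(
    list(protocol = protocol, roster = roster, units = units,
         sessions = sessions, logbooks = logbooks, attendance = attendance,
         questionnaires = questionnaires),
    class = "imp_trial"
  )
}

#' @export
print.imp_trial <- function(x, ...) {
  cat(sprintf(
    "<imp_trial> %s\n  %d participants / %d teams / %d workplaces / %d steps\n  %d scheduled sessions (%d held), %d logbooks, %d attendance rows, %d questionnaires\n",
    x$protocol$name, nrow(x$roster$participants), nrow(x$roster$teams),
    length(unique(x$roster$teams$workplace_id)), length(x$roster$steps),
    nrow(x$sessions), sum(x$sessions$held), nrow(x$logbooks),
    nrow(x$attendance), nrow(x$questionnaires)
  ))
  invisible(x)
}

logbook_item_columns <- function() {
  c(paste0("crit_", 1:5), paste0("und_", 1:4), paste0("con_", 1:4),
    "performance", "intensity", "motivation")
}

#' Write or read a trial dataset as plain-text tables
#'
#' A directory holding `protocol.yaml` plus CSV tables (`participants`,
#' `teams`, `steps`, `units`, `sessions`, `logbooks`, `attendance`,
#' `questionnaires`). CSVs are UTF-8, comma-separated, with a header row
#' and `NA` for missing values. Writing then re-reading a validated
#' dataset round-trips exactly.
#'
#' @param trial an [imp_trial()].
#' @param dir directory to write to (created if needed) or read from.
#' @return `write_trial()` returns `dir` invisibly; `read_trial()` returns
#'   an `imp_trial`.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "imp_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  }
  write_protocol(trial$protocol, file.path(dir, "protocol.yaml"))
  wr(trial$roster$participants, "participants")
  wr(trial$roster$teams, "teams")
  wr(tibble::tibble(step = trial$roster$steps,
                    position = seq_along(trial$roster$steps)), "steps")
  wr(trial$units, "units")
  wr(trial$sessions, "sessions")
  wr(trial$logbooks, "logbooks")
  wr(trial$attendance, "attendance")
  wr(trial$questionnaires, "questionnaires")
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  rd <- function(name, cols = NULL) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing table: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = cols %||% NA)
    tibble::as_tibble(df)
  }
  protocol <- read_protocol(file.path(dir, "protocol.yaml"))
  steps_df <- rd("steps")
  roster <- imp_roster(
    rd("participants", cols = c(participant_id = "character", team_id = "character",
                                workplace_id = "character", step = "character")),
    rd("teams", cols = c(team_id = "character", workplace_id = "character",
                         size = "integer")),
    steps_df$step[order(steps_df$position)]
  )
  logbooks <- rd("logbooks")
  # enforce stable types on rating columns (all-NA columns parse as logical)
  for (col in logbook_item_columns()) {
    if (!col %in% names(logbooks)) next
    if (col %in% c("performance", "intensity")) {
      logbooks[[col]] <- as.integer(logbooks[[col]])
    } else {
      logbooks[[col]] <- as.character(logbooks[[col]])
    }
  }
  sessions <- rd("sessions")
  sessions$held <- as.logical(sessions$held)
  imp_trial(
    protocol = protocol, roster = roster, units = rd("units"),
    sessions = sessions, logbooks = logbooks,
    attendance = rd("attendance"), questionnaires = rd("questionnaires")
  )
}
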