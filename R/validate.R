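#' Validate a trial dataset
#'
#' Cross-checks the records of an [imp_trial()] and returns a structured
#' report of violations rather than raising: unknown identifiers, held
#' sessions with no logbook, logbooks for sessions never held, duplicate
#' logbooks or questionnaires, attendance at sessions that were not held,
#' attendees outside the session's delivery unit, missing criterion
#' ratings, and intensity ratings present or absent against the plan.
#' Structurally unusable input (no sessions, empty roster) raises at
#' construction time in [imp_trial()] / [imp_roster()].
#'
#' The function is pure: it never mutates its input and is idempotent.
#'
#' @param trial an [imp_trial()].
#' @return a tibble of class `validation_report` with columns `rule`,
#'   `severity` (`"error"` or `"warning"`), `record` (the first offending
#'   identifier) and `message`; zero rows for a consistent dataset.
#' @export
validate_dataset <- function(trial) {
  stopifnot(inherits(trial, "imp_trial"))
  v <- list()
  add <- function(rule, severity, record, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      rule = rule, severity = severity,
      record = as.character(record), message = message
    )
  }

  proto <- trial$protocol
  parts <- trial$roster$participants
  sess <- trial$sessions

  unknown_plan <- setdiff(sess$plan_id, proto$sessions$plan_id)
  for (p in unknown_plan) {
    add("unknown_plan", "error", p, "session references a plan not in the protocol")
  }
  unknown_step <- setdiff(sess$step, trial$roster$steps)
  for (s in unknown_step) {
    add("unknown_step", "error", s, "session step is not a declared trial step")
  }

  # unit membership references
  unknown_member <- setdiff(trial$units$participant_id, parts$participant_id)
  for (p in unknown_member) {
    add("unknown_participant", "error", p, "unit membership names a participant not in the roster")
  }
  unknown_unit <- setdiff(sess$unit_id, trial$units$unit_id)
  for (u in unknown_unit) {
    add("unknown_unit", "error", u, "session delivered to a unit with no members")
  }

  # a participant must have at most one session instance per plan
  inst <- dplyr::inner_join(
    sess[c("session_id", "plan_id", "unit_id")], trial$units,
    by = "unit_id", relationship = "many-to-many"
  )
  dup <- dplyr::count(inst, participant_id, plan_id)
  dup <- dup[dup$n > 1, ]
  for (i in seq_len(nrow(dup))) {
    add("ambiguous_schedule", "error", dup$participant_id[i],
        sprintf("participant is scheduled for %d instances of plan %s",
                dup$n[i], dup$plan_id[i]))
  }

  # logbooks
  lb <- trial$logbooks
  held_ids <- sess$session_id[sess$held]
  missing_lb <- setdiff(held_ids, lb$session_id)
  for (s in missing_lb) {
    add("missing_logbook", "warning", s, "session was held but has no logbook")
  }
  orphan_lb <- setdiff(lb$session_id, sess$session_id)
  for (s in orphan_lb) {
    add("unknown_session", "error", s, "logbook for a session not on the schedule")
  }
  not_held_lb <- intersect(lb$session_id, sess$session_id[!sess$held])
  for (s in not_held_lb) {
    add("logbook_for_unheld", "error", s, "logbook exists but the session is recorded as not held")
  }
  if (anyDuplicated(lb$session_id)) {
    for (s in unique(lb$session_id[duplicated(lb$session_id)])) {
      add("duplicate_logbook", "error", s, "more than one logbook for the session")
    }
  }

  # per-logbook item consistency against the plan
  lb_known <- lb[lb$session_id %in% sess$session_id, , drop = FALSE]
  if (nrow(lb_known)) {
    plan_of <- proto$sessions[match(
      sess$plan_id[match(lb_known$session_id, sess$session_id)],
      proto$sessions$plan_id), ]
    n_crit <- lengths(plan_of$criteria)
    for (i in seq_len(nrow(lb_known))) {
      k <- n_crit[i]
      if (k > 0) {
        vals <- unlist(lb_known[i, paste0("crit_", seq_len(k))])
        if (anyNA(vals)) {
          add("missing_criterion_rating", "warning", lb_known$session_id[i],
              sprintf("%d of %d criterion ratings missing", sum(is.na(vals)), k))
        }
      }
      has_int <- !is.na(lb_known$intensity[i])
      if (isTRUE(plan_of$has_intensity[i]) && !has_int) {
        add("missing_intensity", "warning", lb_known$session_id[i],
            "plan requires an intensity rating but none recorded")
      }
      if (!isTRUE(plan_of$has_intensity[i]) && has_int) {
        add("unexpected_intensity", "warning", lb_known$session_id[i],
            "intensity recorded for a plan without an intensity rating")
      }
    }
  }

  # attendance
  att <- trial$attendance
  for (s in setdiff(att$session_id, sess$session_id)) {
    add("unknown_session", "error", s, "attendance recorded for an unscheduled session")
  }
  for (p in setdiff(att$participant_id, parts$participant_id)) {
    add("unknown_participant", "error", p, "attendance names a participant not in the roster")
  }
  att_unheld <- att$session_id %in% sess$session_id[!sess$held]
  for (s in unique(att$session_id[att_unheld])) {
    add("attendance_for_unheld", "error", s, "attendance recorded for a session not held")
  }
  # attendee must belong to the session's delivery unit
  att_known <- att[att$session_id %in% sess$session_id &
                     att$participant_id %in% parts$participant_id, , drop = FALSE]
  if (nrow(att_known)) {
    att_known$unit_id <- sess$unit_id[match(att_known$session_id, sess$session_id)]
    member_key <- paste(trial$units$unit_id, trial$units$participant_id)
    outside <- !(paste(att_known$unit_id, att_known$participant_id) %in% member_key)
    for (i in which(outside)) {
      add("attendee_outside_unit", "warning", att_known$participant_id[i],
          sprintf("attended session %s without belonging to its delivery unit",
                  att_known$session_id[i]))
    }
  }

  # questionnaires
  q <- trial$questionnaires
  for (p in setdiff(q$participant_id, parts$participant_id)) {
    add("unknown_participant", "error", p, "questionnaire from a participant not in the roster")
  }
  if (anyDuplicated(q$participant_id)) {
    for (p in unique(q$participant_id[duplicated(q$participant_id)])) {
      add("duplicate_questionnaire", "error", p, "more than one questionnaire for the participant")
    }
  }

  out <- if (length(v)) dplyr::bind_rows(v) else tibble::tibble(
    rule = character(), severity = character(),
    record = character(), message = character()
  )
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> no violations\n")
  } else {
    cat(sprintf("<validation_report> %d violation(s): %d error(s), %d warning(s)\n",
                nrow(x), sum(x$severity == "error"), sum(x$severity == "warning")))
    print(tibble::as_tibble(x), ...)
  }
  invisible(x)
}

# Resolve each participant's planned protocol to concrete session instances.
# Returns one row per participant x plan with the matching session (if any
# was scheduled for one of the participant's units), its held flag, and the
# participant's strata. A plan with no scheduled instance for the
# participant keeps session_id = NA and counts as not held.
participant_session_grid <- function(trial) {
  parts <- trial$roster$participants
  plans <- trial$protocol$sessions[
    c("plan_id", "component_id", "duration_hours", "receipt_mode")]
  grid <- tidyr::crossing(
    participant_id = parts$participant_id,
    plan_id = plans$plan_id
  )
  grid <- dplyr::left_join(grid, plans, by = "plan_id")
  inst <- dplyr::inner_join(
    trial$sessions[c("session_id", "plan_id", "unit_id", "held")],
    trial$units, by = "unit_id", relationship = "many-to-many"
  )[c("participant_id", "plan_id", "session_id", "held")]
  if (anyDuplicated(inst[c("participant_id", "plan_id")])) {
    stop("ambiguous schedule: a participant has multiple session instances for one plan; run validate_dataset()",
         call. = FALSE)
  }
  grid <- dplyr::left_join(grid, inst, by = c("participant_id", "plan_id"))
  grid$held[is.na(grid$held)] <- FALSE
  grid <- dplyr::left_join(
    grid, parts[c("participant_id", "team_id", "workplace_id", "step")],
    by = "participant_id"
  )
  grid$weight <- grid$duration_hours / trial$protocol$total_hours
  grid
}
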