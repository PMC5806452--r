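#' The default team-representation schedule
#'
#' Teams send representatives to team-mode (participatory-ergonomics)
#' sessions according to team size: fewer than 5 workers require 2
#' representatives, 5-9 require 3, 10-14 require 4, 15-19 require 5, and
#' 20 or more require 6.
#'
#' @return a tibble with columns `min_size`, `max_size`, `required`.
#' @export
default_representation_schedule <- function() {
  tibble::tibble(
    min_size = c(1, 5, 10, 15, 20),
    max_size = c(4, 9, 14, 19, Inf),
    required = c(2L, 3L, 4L, 5L, 6L)
  )
}

#' Required representatives for a team
#'
#' @param team_size integer vector of team sizes (>= 1).
#' @param schedule a representation schedule (`min_size`, `max_size`,
#'   `required`); defaults to [default_representation_schedule()].
#' @return integer vector of required representative counts.
#' @export
#' @examples
#' required_representatives(c(4, 12, 20)) # 2 4 6
required_representatives <- function(team_size,
                                     schedule = default_representation_schedule()) {
  if (any(team_size < 1)) {
    stop("team_size must be >= 1", call. = FALSE)
  }
  idx <- vapply(team_size, function(s) {
    which(s >= schedule$min_size & s <= schedule$max_size)[1]
  }, 0L)
  if (anyNA(idx)) stop("team size not covered by the representation schedule",
                       call. = FALSE)
  as.integer(schedule$required[idx])
}

#' Team participation at one team-mode session
#'
#' The fraction of the required representatives who attended, capped at 1
#' (extra attendees beyond the quota do not raise the score above 100%).
#'
#' @param attending number of team members who attended.
#' @param required required representative count for the team.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' team_session_participation(2, 3) # 0.667
#' team_session_participation(5, 3) # capped at 1
team_session_participation <- function(attending, required) {
  stopifnot(all(attending >= 0), all(required >= 1))
  pmin(attending / required, 1)
}

#' Team continuity over the team-mode sessions
#'
#' Continuity rewards the same representatives attending throughout: the
#' number of team members present at every held team-mode session (or all
#' but `max_missed` of them), divided by the required representative
#' count, capped at 1. Missing when no team-mode session was held.
#'
#' @param attendee_sets list of character vectors, one per held team-mode
#'   session, each the team members present.
#' @param required required representative count for the team.
#' @param max_missed leniency: sessions a "persistent" representative may
#'   miss (default 0, the strict reading).
#' @return fraction in `[0, 1]`, or `NA` if `attendee_sets` is empty.
#' @export
#' @examples
#' team_continuity(list(c("a", "b", "c"), c("a", "b"), c("a", "b", "d")), 3)
team_continuity <- function(attendee_sets, required, max_missed = 0) {
  stopifnot(required >= 1, max_missed >= 0)
  n_sessions <- length(attendee_sets)
  if (n_sessions == 0) return(NA_real_)
  counts <- table(unlist(lapply(attendee_sets, unique)))
  persistent <- sum(counts >= n_sessions - max_missed)
  min(persistent / required, 1)
}

#' Score team-level receipt of the team-mode component
#'
#' For each team: the duration-weighted mean of per-session team
#' participation over held team-mode sessions, the continuity score, and
#' their average (the combined score broadcast to every team member as
#' presence at those sessions — the intended spill-over of the
#' participatory component within a team).
#'
#' @param trial an [imp_trial()].
#' @param max_missed leniency passed to [team_continuity()].
#' @return a tibble with one row per team: `team_id`, `required`,
#'   `n_team_sessions`, `n_held`, `participation_score`,
#'   `continuity_score`, `combined` (all fractions).
#' @export
pe_team_scores <- function(trial, max_missed = 0) {
  stopifnot(inherits(trial, "imp_trial"))
  proto <- trial$protocol
  team_plans <- proto$sessions$plan_id[proto$sessions$receipt_mode == "team"]
  teams <- trial$roster$teams
  parts <- trial$roster$participants
  sess <- trial$sessions[trial$sessions$plan_id %in% team_plans, , drop = FALSE]
  sess$duration_hours <- proto$sessions$duration_hours[
    match(sess$plan_id, proto$sessions$plan_id)]
  att_by_session <- split(trial$attendance$participant_id,
                          trial$attendance$session_id)
  unit_of <- split(trial$units$unit_id, trial$units$participant_id)

  out <- lapply(seq_len(nrow(teams)), function(i) {
    team_id <- teams$team_id[i]
    members <- parts$participant_id[parts$team_id == team_id]
    req <- required_representatives(teams$size[i], proto$representation_schedule)
    member_units <- unique(unlist(unit_of[members]))
    ts <- sess[sess$unit_id %in% member_units, , drop = FALSE]
    held <- ts[ts$held, , drop = FALSE]
    if (nrow(held) == 0) {
      return(tibble::tibble(
        team_id = team_id, required = req, n_team_sessions = nrow(ts),
        n_held = 0L, participation_score = NA_real_,
        continuity_score = NA_real_, combined = NA_real_
      ))
    }
    attendee_sets <- lapply(held$session_id, function(s) {
      intersect(att_by_session[[s]] %||% character(0), members)
    })
    per_session <- team_session_participation(lengths(attendee_sets), req)
    participation <- sum(per_session * held$duration_hours) / sum(held$duration_hours)
    continuity <- team_continuity(attendee_sets, req, max_missed = max_missed)
    tibble::tibble(
      team_id = team_id, required = req, n_team_sessions = nrow(ts),
      n_held = nrow(held), participation_score = participation,
      continuity_score = continuity,
      combined = (participation + continuity) / 2
    )
  })
  dplyr::bind_rows(out)
}

#' Per-participant presence at every planned session
#'
#' Expands the roster against the protocol: one row per participant and
#' planned session, with the realized session instance (if scheduled for
#' one of the participant's delivery units), its held flag, and the
#' presence used for participation weighting. Presence is 0/1 attendance
#' for individual-mode sessions and the team's combined
#' participation-continuity score for team-mode sessions (identical for
#' all members of a team); cancelled or unscheduled sessions have
#' presence 0 — a participant cannot gain a session the organization
#' never held.
#'
#' @param trial an [imp_trial()].
#' @param team_scores optional precomputed [pe_team_scores()].
#' @return a tibble with one row per participant x plan, including
#'   `presence` in `[0, 1]` and the duration weight
#'   `weight = duration_hours / total_hours`.
#' @export
session_presence <- function(trial, team_scores = NULL) {
  stopifnot(inherits(trial, "imp_trial"))
  if (is.null(team_scores)) team_scores <- pe_team_scores(trial)
  grid <- participant_session_grid(trial)
  att_key <- paste(trial$attendance$session_id, trial$attendance$participant_id)
  attended <- !is.na(grid$session_id) &
    paste(grid$session_id, grid$participant_id) %in% att_key
  grid$attended <- attended & grid$held

  combined <- team_scores$combined[match(grid$team_id, team_scores$team_id)]
  presence <- numeric(nrow(grid))
  indiv <- grid$receipt_mode == "individual"
  presence[indiv] <- as.numeric(grid$attended[indiv])
  team <- !indiv & grid$held
  presence[team] <- ifelse(is.na(combined[team]), 0, combined[team])
  grid$presence <- presence
  grid
}

#' Individual participation
#'
#' Duration-weighted participation per participant: the sum over planned
#' sessions of presence x duration / total planned hours, overall and per
#' component (with the component's own hours as denominator).
#'
#' @param trial an [imp_trial()].
#' @param presence optional precomputed [session_presence()] table.
#' @return a tibble with one row per participant: `participation` and one
#'   `participation_<component>` column per component, all in `[0, 1]`.
#' @export
#' @examples
#' # a participant present at one 3-h session of a 27-h protocol adds
#' # 3/27 = 0.11 to their participation
individual_participation <- function(trial, presence = NULL) {
  if (is.null(presence)) presence <- session_presence(trial)
  total <- dplyr::summarise(
    dplyr::group_by(presence, participant_id),
    participation = sum(presence * weight),
    .groups = "drop"
  )
  comp_hours <- stats::aggregate(
    duration_hours ~ component_id, data = trial$protocol$sessions, FUN = sum)
  by_comp <- dplyr::summarise(
    dplyr::group_by(presence, participant_id, component_id),
    hours = sum(presence * duration_hours),
    .groups = "drop"
  )
  by_comp$participation <- by_comp$hours /
    comp_hours$duration_hours[match(by_comp$component_id, comp_hours$component_id)]
  wide <- tidyr::pivot_wider(
    by_comp[c("participant_id", "component_id", "participation")],
    names_from = component_id, values_from = participation,
    names_prefix = "participation_"
  )
  dplyr::left_join(total, wide, by = "participant_id")
}

#' Responsiveness from questionnaires and logged motivation
#'
#' Satisfaction is the mean of the six scored satisfaction items; social
#' support the mean of the four scored support items; motivation the
#' duration-weighted mean of the group-motivation ratings over the
#' sessions the participant personally attended. Responsiveness `R` is
#' the mean of the available sub-indexes, and is missing for participants
#' without a questionnaire (they are excluded from implementation scores
#' but keep their exposure).
#'
#' Component-level responsiveness replaces the satisfaction index by the
#' component-specific item plus the three overall items, restricts
#' motivation to the component's attended sessions, and reuses the
#' support index unchanged.
#'
#' @param trial an [imp_trial()].
#' @param session_scores optional precomputed [score_sessions()] table
#'   (for the per-session motivation scores).
#' @return a tibble with one row per participant: `satisfaction`,
#'   `support`, `motivation`, `responsiveness`, plus per-component
#'   `satisfaction_<c>`, `motivation_<c>`, `responsiveness_<c>` columns,
#'   all on 0-100.
#' @export
responsiveness_scores <- function(trial, session_scores = NULL) {
  stopifnot(inherits(trial, "imp_trial"))
  if (is.null(session_scores)) session_scores <- score_sessions(trial)
  parts <- trial$roster$participants
  comps <- trial$protocol$components$component_id
  q <- trial$questionnaires
  qi <- match(parts$participant_id, q$participant_id)

  comp_item_cols <- paste0("sat_", tolower(comps))
  overall_cols <- c("sat_overall", "sat_relevant", "sat_interesting")
  sup_cols <- paste0("sup_", 1:4)
  score_item <- function(col, variant = "extent") {
    if (!col %in% names(q)) return(rep(NA_real_, nrow(parts)))
    score_likert5(as.character(q[[col]][qi]), variant = variant)
  }
  sat_items <- vapply(c(comp_item_cols, overall_cols), score_item,
                      numeric(nrow(parts)))
  sup_items <- vapply(sup_cols, function(cl) score_item(cl, "frequency"),
                      numeric(nrow(parts)))
  if (nrow(parts) == 1) {
    sat_items <- matrix(sat_items, nrow = 1)
    sup_items <- matrix(sup_items, nrow = 1)
  }
  satisfaction <- apply(sat_items, 1, score_index)
  support <- apply(sup_items, 1, score_index)

  # motivation: duration-weighted over personally attended, scored sessions
  att <- trial$attendance
  att <- dplyr::inner_join(
    att, session_scores[c("session_id", "component_id", "held",
                          "motivation", "duration_hours")],
    by = "session_id"
  )
  att <- att[att$held & !is.na(att$motivation), , drop = FALSE]
  mot_total <- dplyr::summarise(
    dplyr::group_by(att, participant_id),
    motivation = sum(motivation * duration_hours) / sum(duration_hours),
    .groups = "drop"
  )
  mot_comp <- dplyr::summarise(
    dplyr::group_by(att, participant_id, component_id),
    motivation = sum(motivation * duration_hours) / sum(duration_hours),
    .groups = "drop"
  )

  out <- tibble::tibble(
    participant_id = parts$participant_id,
    satisfaction = satisfaction,
    support = support,
    motivation = mot_total$motivation[
      match(parts$participant_id, mot_total$participant_id)]
  )
  has_q <- !is.na(qi)
  out$responsiveness <- ifelse(
    has_q,
    apply(cbind(out$satisfaction, out$support, out$motivation), 1, score_index),
    NA_real_
  )

  for (k in seq_along(comps)) {
    comp <- comps[k]
    sat_c <- apply(cbind(sat_items[, comp_item_cols[k]],
                         sat_items[, overall_cols, drop = FALSE]), 1, score_index)
    mc <- mot_comp[mot_comp$component_id == comp, , drop = FALSE]
    mot_c <- mc$motivation[match(parts$participant_id, mc$participant_id)]
    resp_c <- ifelse(has_q, apply(cbind(sat_c, out$support, mot_c), 1, score_index),
                     NA_real_)
    out[[paste0("satisfaction_", comp)]] <- sat_c
    out[[paste0("motivation_", comp)]] <- mot_c
    out[[paste0("responsiveness_", comp)]] <- resp_c
  }
  out
}
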