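# Hand-built miniature trial used across the unit tests: a 10-hour,
# 6-session protocol (kick-off + two team-mode working groups, two
# intensity-rated training sessions, one 3-h workshop) delivered to two
# teams in different workplaces/steps. The default dataset is "perfect"
# (everything held, everyone attends, every rating top category) so tests
# perturb exactly the piece they exercise.

mini_protocol <- function() {
  protocol_spec(
    components = tibble::tibble(
      component_id = c("PE", "PT", "CBT"),
      label = c("ergonomics", "training", "workshops")
    ),
    sessions = tibble::tibble(
      plan_id = c("KICK", "WG1", "WG2", "PT1", "PT2", "C1"),
      component_id = c("PE", "PE", "PE", "PT", "PT", "CBT"),
      duration_hours = c(1, 2, 2, 1, 1, 3),
      receipt_mode = c("individual", "team", "team", "individual",
                       "individual", "individual"),
      has_intensity = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
      criteria = list(c("KICK_c1", "KICK_c2"), c("WG1_c1", "WG1_c2"),
                      c("WG2_c1", "WG2_c2"), "PT1_c1", "PT2_c1",
                      c("C1_c1", "C1_c2"))
    ),
    representation_schedule = default_representation_schedule(),
    name = "mini-10h"
  )
}

# participants P01..P04 (team A, W1, S1) and P05..P10 (team B, W2, S2)
mini_roster <- function() {
  ids <- sprintf("P%02d", 1:10)
  imp_roster(
    participants = tibble::tibble(
      participant_id = ids,
      team_id = rep(c("A", "B"), c(4, 6)),
      workplace_id = rep(c("W1", "W2"), c(4, 6)),
      step = rep(c("S1", "S2"), c(4, 6))
    ),
    teams = tibble::tibble(
      team_id = c("A", "B"), workplace_id = c("W1", "W2"), size = c(4L, 6L)
    ),
    steps = c("S1", "S2")
  )
}

mini_units <- function() {
  ids <- sprintf("P%02d", 1:10)
  a <- ids[1:4]; b <- ids[5:10]
  dplyr::bind_rows(
    tibble::tibble(unit_id = "UA", participant_id = a),
    tibble::tibble(unit_id = "UB", participant_id = b)
  )
}

# 12 sessions: each team-unit holds every plan once
mini_sessions <- function(held = rep(TRUE, 12)) {
  plans <- c("KICK", "WG1", "WG2", "PT1", "PT2", "C1")
  comps <- c("PE", "PE", "PE", "PT", "PT", "CBT")
  tibble::tibble(
    session_id = sprintf("s%02d", 1:12),
    plan_id = rep(plans, 2),
    component_id = rep(comps, 2),
    workplace_id = rep(c("W1", "W2"), each = 6),
    unit_id = rep(c("UA", "UB"), each = 6),
    step = rep(c("S1", "S2"), each = 6),
    held = held,
    deliverer_id = "D1"
  )
}

# a perfect logbook row; override fields to construct scenarios
mini_logbook_row <- function(session_id, has_intensity = FALSE, ...) {
  row <- c(
    list(session_id = session_id),
    stats::setNames(as.list(rep("completely", 5)), paste0("crit_", 1:5)),
    stats::setNames(as.list(rep("very_large_extent", 4)), paste0("und_", 1:4)),
    stats::setNames(as.list(rep("very_large_extent", 4)), paste0("con_", 1:4)),
    list(performance = 10L,
         intensity = if (has_intensity) 9L else NA_integer_,
         motivation = "very_large_extent")
  )
  over <- list(...)
  row[names(over)] <- over
  tibble::as_tibble(row)
}

mini_logbooks <- function(sessions = mini_sessions()) {
  held <- sessions[sessions$held, ]
  has_int <- held$plan_id %in% c("PT1", "PT2")
  dplyr::bind_rows(lapply(seq_len(nrow(held)), function(i) {
    mini_logbook_row(held$session_id[i], has_intensity = has_int[i])
  }))
}

mini_attendance_full <- function(sessions = mini_sessions()) {
  held <- sessions[sessions$held, ]
  members <- list(UA = sprintf("P%02d", 1:4), UB = sprintf("P%02d", 5:10))
  dplyr::bind_rows(lapply(seq_len(nrow(held)), function(i) {
    tibble::tibble(session_id = held$session_id[i],
                   participant_id = members[[held$unit_id[i]]])
  }))
}

mini_questionnaires <- function(ids = sprintf("P%02d", 1:10),
                                sat = "very_large_extent", sup = "always") {
  q <- tibble::tibble(participant_id = ids)
  for (col in c("sat_pe", "sat_pt", "sat_cbt", "sat_overall",
                "sat_relevant", "sat_interesting")) {
    q[[col]] <- sat
  }
  for (j in 1:4) q[[paste0("sup_", j)]] <- sup
  q
}

mini_trial <- function(sessions = mini_sessions(),
                       logbooks = mini_logbooks(sessions),
                       attendance = mini_attendance_full(sessions),
                       questionnaires = mini_questionnaires()) {
  imp_trial(mini_protocol(), mini_roster(), mini_units(),
            sessions, logbooks, attendance, questionnaires)
}

# uniform-fidelity variant: every scored element 50 -> C = Q = F = 50
mini_logbooks_half <- function(sessions = mini_sessions()) {
  held <- sessions[sessions$held, ]
  has_int <- held$plan_id %in% c("PT1", "PT2")
  dplyr::bind_rows(lapply(seq_len(nrow(held)), function(i) {
    mini_logbook_row(
      held$session_id[i], has_intensity = FALSE,
      crit_1 = "partly", crit_2 = "partly", crit_3 = "partly",
      crit_4 = "partly", crit_5 = "partly",
      und_1 = "somewhat", und_2 = "somewhat", und_3 = "somewhat",
      und_4 = "somewhat",
      con_1 = "somewhat", con_2 = "somewhat", con_3 = "somewhat",
      con_4 = "somewhat",
      performance = 6L,
      intensity = if (has_int[i]) 5L else NA_integer_,
      motivation = "somewhat"
    )
  }))
}
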