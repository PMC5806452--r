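test_that("required representatives follow the team-size schedule", {
  expect_equal(required_representatives(c(1, 4, 5, 9, 10, 14, 15, 19, 20, 57)),
               c(2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L))
  expect_error(required_representatives(0), ">= 1")
})

test_that("team session participation is the attended/required ratio capped at one", {
  expect_equal(team_session_participation(3, 3), 1)
  expect_equal(team_session_participation(2, 3), 2 / 3)
  expect_equal(team_session_participation(5, 3), 1)
  expect_equal(team_session_participation(0, 2), 0)
})

test_that("continuity counts persistent attendees against the quota", {
  same3 <- replicate(4, c("a", "b", "c"), simplify = FALSE)
  expect_equal(team_continuity(same3, 3), 1)
  rotating <- list(c("a", "b"), c("c", "d"), c("e", "f"))
  expect_equal(team_continuity(rotating, 3), 0)
  two_persist <- list(c("a", "b", "x"), c("a", "b", "y"), c("a", "b"))
  expect_equal(team_continuity(two_persist, 4), 0.5)
  expect_true(is.na(team_continuity(list(), 3)))
  # leniency: one missed session tolerated
  mostly <- list(c("a", "b"), c("a", "b"), c("b"))
  expect_equal(team_continuity(mostly, 2), 0.5)
  expect_equal(team_continuity(mostly, 2, max_missed = 1), 1)
  # continuity never exceeds the best single-session participation
  set.seed(99)
  for (i in 1:20) {
    sets <- lapply(1:4, function(j) sample(letters[1:8], sample(0:6, 1)))
    req <- sample(2:5, 1)
    expect_lte(team_continuity(sets, req),
               max(team_session_participation(lengths(sets), req)))
  }
})

test_that("team scores combine participation and continuity and broadcast to members", {
  # team A (size 4, required 2): P01, P02 at both working groups -> perfect
  # team B (size 6, required 3): rotating attendance
  sess <- mini_sessions()
  att <- dplyr::bind_rows(
    tibble::tibble(session_id = "s02", participant_id = c("P01", "P02")),
    tibble::tibble(session_id = "s03", participant_id = c("P01", "P02")),
    tibble::tibble(session_id = "s08", participant_id = c("P05", "P06")),
    tibble::tibble(session_id = "s09", participant_id = c("P07", "P08"))
  )
  trial <- mini_trial(attendance = att)
  ts <- pe_team_scores(trial)
  a <- ts[ts$team_id == "A", ]
  expect_equal(a$required, 2L)
  expect_equal(a$participation_score, 1)
  expect_equal(a$continuity_score, 1)
  expect_equal(a$combined, 1)
  b <- ts[ts$team_id == "B", ]
  expect_equal(b$participation_score, 2 / 3)  # 2 of required 3 each time
  expect_equal(b$continuity_score, 0)         # nobody attended both
  expect_equal(b$combined, 1 / 3)
  # broadcast: every member of a team carries the combined value as
  # presence at team-mode sessions
  pres <- session_presence(trial, ts)
  team_rows <- pres[pres$receipt_mode == "team", ]
  for (tid in c("A", "B")) {
    vals <- unique(team_rows$presence[team_rows$team_id == tid])
    expect_length(vals, 1)
    expect_equal(vals, ts$combined[ts$team_id == tid])
  }
})

test_that("cancelled team sessions are excluded from weights and contribute zero", {
  held <- rep(TRUE, 12); held[2] <- FALSE   # cancel WG1 for team A
  sess <- mini_sessions(held)
  att <- dplyr::bind_rows(
    tibble::tibble(session_id = "s03", participant_id = c("P01", "P02")),
    tibble::tibble(session_id = "s08", participant_id = sprintf("P%02d", 5:7)),
    tibble::tibble(session_id = "s09", participant_id = sprintf("P%02d", 5:7))
  )
  trial <- mini_trial(sessions = sess, logbooks = mini_logbooks(sess),
                      attendance = att)
  ts <- pe_team_scores(trial)
  a <- ts[ts$team_id == "A", ]
  expect_equal(a$n_held, 1L)
  expect_equal(a$participation_score, 1)  # weighted over held sessions only
  pres <- session_presence(trial, ts)
  cancelled <- pres[pres$participant_id == "P01" & pres$plan_id == "WG1", ]
  expect_equal(cancelled$presence, 0)
})

test_that("individual participation is the duration-weighted presence sum", {
  # P05 attends only the 3-h workshop of the 10-h mini protocol
  att <- tibble::tibble(session_id = "s12", participant_id = "P05")
  trial <- mini_trial(attendance = att)
  part <- individual_participation(trial)
  expect_equal(part$participation[part$participant_id == "P05"], 3 / 10)
  expect_equal(part$participation_CBT[part$participant_id == "P05"], 1)
  expect_equal(part$participation_PT[part$participant_id == "P05"], 0)
  # full attendance everywhere -> participation exactly 1
  full <- individual_participation(mini_trial())
  expect_true(all(abs(full$participation - 1) < 1e-12))
  # monotonicity: adding an attended session never decreases participation
  att2 <- rbind(att, tibble::tibble(session_id = "s10", participant_id = "P05"))
  part2 <- individual_participation(mini_trial(attendance = att2))
  expect_gt(part2$participation[part2$participant_id == "P05"],
            part$participation[part$participant_id == "P05"])
})

test_that("responsiveness averages available sub-indexes, missing without questionnaire", {
  # P01 has no questionnaire: motivation exists but R is missing
  q <- mini_questionnaires(sprintf("P%02d", 2:10))
  trial <- mini_trial(questionnaires = q)
  resp <- responsiveness_scores(trial)
  p1 <- resp[resp$participant_id == "P01", ]
  expect_true(is.na(p1$responsiveness))
  expect_false(is.na(p1$motivation))
  # full top-category answers give 100 everywhere
  p2 <- resp[resp$participant_id == "P02", ]
  expect_equal(p2$satisfaction, 100)
  expect_equal(p2$support, 100)
  expect_equal(p2$motivation, 100)
  expect_equal(p2$responsiveness, 100)
})

test_that("motivation is the duration-weighted mean over personally attended sessions", {
  # motivation somewhat (50) at the 3-h workshop, top (100) at 1-h PT1;
  # P05 attends only those two -> (50*3 + 100*1) / 4 = 62.5
  lbs <- mini_logbooks()
  lbs$motivation[lbs$session_id == "s12"] <- "somewhat"
  att <- tibble::tibble(session_id = c("s12", "s10"),
                        participant_id = "P05")
  trial <- mini_trial(logbooks = lbs, attendance = att)
  resp <- responsiveness_scores(trial)
  expect_equal(resp$motivation[resp$participant_id == "P05"], 62.5)
  # component restriction: CBT motivation is the workshop's alone
  expect_equal(resp$motivation_CBT[resp$participant_id == "P05"], 50)
  expect_equal(resp$motivation_PT[resp$participant_id == "P05"], 100)
})

test_that("component responsiveness uses the component item plus overall items and shared support", {
  q <- mini_questionnaires()
  q$sat_pt <- "very_small_extent"   # component item 0, overall items 100
  trial <- mini_trial(questionnaires = q)
  resp <- responsiveness_scores(trial)
  expect_equal(resp$satisfaction_PT[1], 75)   # mean(0, 100, 100, 100)
  expect_equal(resp$satisfaction_PE[1], 100)
  # support is identical across components (it has no component items)
  expect_equal(resp$support, rep(100, 10))
  r_pt <- resp$responsiveness_PT[1]
  expect_equal(r_pt, mean(c(75, 100, 100)))
})
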