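test_that("the packaged protocol matches the planned intervention structure", {
  proto <- default_protocol()
  expect_equal(proto$total_hours, 27)
  expect_equal(nrow(proto$sessions), 19)
  expect_equal(sum(lengths(proto$sessions$criteria)), 55)
  hours <- tapply(proto$sessions$duration_hours, proto$sessions$component_id, sum)
  expect_equal(hours[["PT"]], 12)
  expect_equal(hours[["CBT"]], 6)
  expect_equal(hours[["PE"]], 9)
  counts <- table(proto$sessions$component_id)
  expect_equal(counts[["PT"]], 12)
  expect_equal(counts[["CBT"]], 2)
  expect_equal(counts[["PE"]], 5)
  # team mode only for the four working-group/evaluation sessions
  expect_equal(sum(proto$sessions$receipt_mode == "team"), 4)
  expect_false(proto$sessions$receipt_mode[proto$sessions$plan_id == "PE_KICKOFF"] == "team")
  expect_true(all(proto$sessions$has_intensity == (proto$sessions$component_id == "PT")))
})

test_that("protocol invariants are enforced at construction", {
  proto <- mini_protocol()
  bad_hours <- proto$sessions
  expect_error(
    protocol_spec(proto$components, bad_hours, proto$representation_schedule,
                  total_hours = 99),
    "total_hours"
  )
  bad_comp <- proto$sessions
  bad_comp$component_id[1] <- "ZZ"
  expect_error(
    protocol_spec(proto$components, bad_comp, proto$representation_schedule),
    "undeclared component"
  )
  gap_sched <- tibble::tibble(min_size = c(1, 6), max_size = c(4, Inf),
                              required = c(2L, 3L))
  expect_error(
    protocol_spec(proto$components, proto$sessions, gap_sched),
    "gaps or overlaps"
  )
  open_sched <- tibble::tibble(min_size = 1, max_size = 50, required = 2L)
  expect_error(
    protocol_spec(proto$components, proto$sessions, open_sched),
    "open-ended"
  )
})

test_that("roster construction rejects inconsistent membership", {
  r <- mini_roster()
  expect_equal(nrow(r$participants), 10)
  bad <- r$participants
  bad$team_id[1] <- "ZZ"
  expect_error(imp_roster(bad, r$teams, r$steps), "unknown team.*ZZ")
  bad2 <- r$teams
  bad2$size[1] <- 3L
  expect_error(imp_roster(r$participants, bad2, r$steps),
               "size does not match.*A")
  bad3 <- r$participants
  bad3$workplace_id[5] <- "W1"
  expect_error(imp_roster(bad3, r$teams, r$steps), "workplace mismatch.*P05")
  expect_error(imp_roster(r$participants[0, ], r$teams, r$steps), "empty roster")
})

test_that("a consistent dataset validates with zero violations", {
  report <- validate_dataset(mini_trial())
  expect_s3_class(report, "validation_report")
  expect_equal(nrow(report), 0)
})

test_that("constructed defects are each reported once with the right rule", {
  sessions <- mini_sessions()
  lbs <- mini_logbooks(sessions)

  # a held session with no logbook
  report <- validate_dataset(mini_trial(logbooks = lbs[lbs$session_id != "s04", ]))
  expect_equal(report$rule, "missing_logbook")
  expect_equal(report$record, "s04")
  expect_equal(report$severity, "warning")

  # attendance naming a participant not in the roster
  att <- rbind(mini_attendance_full(),
               tibble::tibble(session_id = "s01", participant_id = "P99"))
  report <- validate_dataset(mini_trial(attendance = att))
  expect_true("unknown_participant" %in% report$rule)
  expect_true("P99" %in% report$record[report$rule == "unknown_participant"])

  # duplicate questionnaire
  q <- mini_questionnaires(c(sprintf("P%02d", 1:10), "P03"))
  report <- validate_dataset(mini_trial(questionnaires = q))
  expect_equal(report$rule, "duplicate_questionnaire")
  expect_equal(report$record, "P03")

  # logbook for a cancelled session
  held <- rep(TRUE, 12); held[2] <- FALSE
  trial <- mini_trial(sessions = mini_sessions(held),
                      logbooks = mini_logbooks(mini_sessions()),
                      attendance = mini_attendance_full(mini_sessions(held)))
  report <- validate_dataset(trial)
  expect_true("logbook_for_unheld" %in% report$rule)

  # intensity mismatch both ways
  lbs2 <- mini_logbooks(sessions)
  lbs2$intensity[lbs2$session_id == "s01"] <- 5L   # KICK has no intensity
  lbs2$intensity[lbs2$session_id == "s04"] <- NA_integer_  # PT1 needs one
  report <- validate_dataset(mini_trial(logbooks = lbs2))
  expect_setequal(report$rule, c("unexpected_intensity", "missing_intensity"))
})

test_that("validation is idempotent and does not mutate its input", {
  trial <- mini_trial()
  before <- unserialize(serialize(trial, NULL))
  r1 <- validate_dataset(trial)
  r2 <- validate_dataset(trial)
  expect_identical(r1, r2)
  expect_identical(trial, before)
})

test_that("datasets round-trip through the plain-text format", {
  dir <- withr::local_tempdir()
  trial <- simulate_trial(sim_config(seed = 11))
  write_trial(trial, dir)
  back <- read_trial(dir)
  expect_equal(back$roster$participants, trial$roster$participants)
  expect_equal(back$roster$teams, trial$roster$teams)
  expect_equal(back$units, trial$units)
  expect_equal(back$sessions, trial$sessions)
  expect_equal(back$logbooks, trial$logbooks)
  expect_equal(back$attendance, trial$attendance)
  expect_equal(back$questionnaires, trial$questionnaires)
  expect_equal(back$protocol$sessions, trial$protocol$sessions)
  expect_equal(back$protocol$total_hours, trial$protocol$total_hours)
  # and scoring the round-tripped dataset gives identical numbers
  expect_equal(individual_scores(back), individual_scores(trial))
})
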