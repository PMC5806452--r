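test_that("exposure and implementation are the documented products", {
  p_s <- 1 * 3 / 27
  expect_equal(round(p_s, 2), 0.11)
  e_s <- session_exposure(0.65, p_s)
  expect_equal(round(e_s, 3), 0.072)
  expect_equal(session_implementation(0.072, 0.8), 0.0576)
  # identities and zero propagation
  expect_equal(session_exposure(1, 0.3), 0.3)
  expect_equal(session_exposure(0.9, 0), 0)
  expect_equal(session_implementation(0.25, 1), 0.25)
  expect_equal(session_implementation(0.25, 0), 0)
})

test_that("the session chain carries worked-example arithmetic at full precision", {
  # C = Q = F = 50 -> f_s = 0.5; P05 attends only the 3-h workshop of 10 h
  att <- tibble::tibble(session_id = "s12", participant_id = "P05")
  trial <- mini_trial(logbooks = mini_logbooks_half(),
                      attendance = att,
                      questionnaires = mini_questionnaires(sat = "somewhat",
                                                           sup = "sometimes"))
  chain <- session_score_table(trial)
  row <- chain[chain$participant_id == "P05" & chain$plan_id == "C1", ]
  expect_equal(row$p_s, 3 / 10)
  expect_equal(row$f_s, 0.5)
  expect_equal(row$e_s, 0.5 * 3 / 10)
  # R: satisfaction 50, support 50, motivation 50 -> 0.5
  expect_equal(row$i_s, 0.5 * 3 / 10 * 0.5)
  ind <- individual_scores(trial, chain)
  p5 <- ind[ind$participant_id == "P05", ]
  expect_equal(p5$exposure, 100 * 0.15)
  expect_equal(p5$implementation, 100 * 0.075)
})

test_that("perfect delivery, attendance and responsiveness give total scores of 100", {
  ind <- individual_scores(mini_trial())
  expect_true(all(abs(ind$participation - 100) < 1e-9))
  expect_true(all(abs(ind$exposure - 100) < 1e-9))
  expect_true(all(abs(ind$implementation - 100) < 1e-9))
  expect_true(all(ind$fidelity == 100))
})

test_that("chain inequality and zero propagation hold across random scenarios", {
  set.seed(2024)
  for (rep in 1:5) {
    held <- runif(12) > 0.15
    sess <- mini_sessions(held)
    att_full <- mini_attendance_full(sess)
    att <- att_full[runif(nrow(att_full)) < 0.6, ]
    q <- mini_questionnaires(sprintf("P%02d", sample(10, 7)),
                             sat = sample(names(likert5_tokens()), 1),
                             sup = sample(names(likert5_tokens("frequency")), 1))
    trial <- mini_trial(sessions = sess, logbooks = mini_logbooks(sess),
                        attendance = att, questionnaires = q)
    ind <- individual_scores(trial)
    ok <- !is.na(ind$implementation)
    expect_true(all(ind$implementation[ok] <= ind$exposure[ok] + 1e-9))
    expect_true(all(ind$exposure <= ind$participation + 1e-9))
    expect_true(all(ind$participation <= 100 + 1e-9))
  }
  # R = 0 forces implementation to zero while exposure survives
  trial0 <- mini_trial(
    logbooks = {
      lb <- mini_logbooks(); lb$motivation <- "very_small_extent"; lb
    },
    questionnaires = mini_questionnaires(sat = "very_small_extent",
                                         sup = "never"))
  ind0 <- individual_scores(trial0)
  expect_true(all(ind0$implementation == 0))
  expect_true(all(ind0$exposure > 0))
  # attending nothing forces exposure and implementation to zero
  trial_none <- mini_trial(attendance = mini_attendance_full()[0, ])
  ind_none <- individual_scores(trial_none)
  expect_true(all(ind_none$exposure == 0))
  expect_true(all(ind_none$implementation == 0))
})

test_that("constant fidelity factorizes exposure as fidelity times participation", {
  set.seed(5)
  att_full <- mini_attendance_full()
  att <- att_full[runif(nrow(att_full)) < 0.5, ]
  trial <- mini_trial(logbooks = mini_logbooks_half(), attendance = att)
  ind <- individual_scores(trial)
  expect_equal(ind$exposure, 0.5 * ind$participation, tolerance = 1e-12)
})

test_that("pointwise increases in presence or responsiveness never lower implementation", {
  att <- mini_attendance_full()[c(1, 5, 12, 20), ]
  q_mid <- mini_questionnaires(sat = "somewhat", sup = "sometimes")
  base <- individual_scores(mini_trial(attendance = att, questionnaires = q_mid))
  more_att <- individual_scores(mini_trial(attendance = mini_attendance_full(),
                                           questionnaires = q_mid))
  expect_true(all(more_att$implementation >= base$implementation - 1e-9))
  better_r <- individual_scores(mini_trial(attendance = att))
  expect_true(all(better_r$implementation >= base$implementation - 1e-9))
})

test_that("stratified summaries report n of non-missing units and exact means", {
  # two steps with known uniform scores via attendance patterns
  att <- mini_attendance_full()
  q <- mini_questionnaires(sprintf("P%02d", 1:7))
  trial <- mini_trial(attendance = att, questionnaires = q)
  by_step <- stratified_summary(trial, by = "step")
  impl <- by_step[by_step$measure == "implementation", ]
  expect_equal(impl$n, c(4L, 3L))  # responders per step
  part <- by_step[by_step$measure == "participation", ]
  expect_equal(part$n, c(4L, 6L))
  expect_equal(part$mean, c(100, 100))
  by_comp <- stratified_summary(trial, by = "component")
  expect_setequal(unique(by_comp$stratum), c("PE", "PT", "CBT"))
  expect_true(all(by_comp$mean[by_comp$measure == "participation"] == 100))
  # direct mean check on constructed strata {0.4, 0.6} vs {0.8}
  fake <- tibble::tibble(
    participant_id = c("a", "b", "c"),
    team_id = "t", workplace_id = c("w1", "w1", "w2"), step = "s",
    participation = c(40, 60, 80), fidelity = 100,
    exposure = c(40, 60, 80), responsiveness = 100,
    implementation = c(40, 60, 80)
  )
  by_wp <- stratified_summary(fake, by = "workplace")
  expect_equal(by_wp$mean[by_wp$measure == "participation"], c(50, 80))
})

test_that("organizational and mean-individual implementation coincide in the exact case", {
  # everything held, full attendance, R = 1, and no team-mode shortfall:
  # dose = 1, F = 1, org = 1; every individual implementation = 100
  trial <- mini_trial()
  cons <- org_vs_individual_consistency(trial)
  expect_equal(cons$organizational, 1)
  expect_equal(cons$mean_individual_implementation, 1)
  expect_equal(cons$abs_difference, 0)
  # dose < 1 with full attendance at held sessions: difference reported
  held <- rep(TRUE, 12); held[c(4, 10)] <- FALSE
  sess <- mini_sessions(held)
  trial2 <- mini_trial(sessions = sess, logbooks = mini_logbooks(sess),
                       attendance = mini_attendance_full(sess))
  cons2 <- org_vs_individual_consistency(trial2)
  expect_true(is.finite(cons2$abs_difference))
  expect_lt(cons2$mean_individual_implementation, 1)
})
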