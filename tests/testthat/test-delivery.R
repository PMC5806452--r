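test_that("dose is the exact delivered/intended ratio with guarded domain", {
  expect_equal(dose(700, 800), 0.875)
  expect_equal(percent(dose(700, 800)), 88)
  expect_equal(percent(dose(713, 753)), 95)
  expect_equal(dose(0, 10), 0)
  expect_error(dose(1, 0), "undefined")
  expect_error(dose(11, 10), "\\[0, intended\\]")
})

test_that("content score averages criteria, folding in intensity for training sessions", {
  plan2 <- list(criteria = list(c("a", "b")), has_intensity = FALSE)
  expect_equal(content_score(list(crit_1 = "completely", crit_2 = "partly"), plan2), 75)
  expect_equal(content_score(list(crit_1 = "completely", crit_2 = "completely"), plan2), 100)
  # two perfect criteria plus intensity 5 (-> 50): mean of {100, 100, 50}
  plan_pt <- list(criteria = list(c("a", "b")), has_intensity = TRUE)
  expect_equal(
    content_score(list(crit_1 = "completely", crit_2 = "completely",
                       intensity = 5L), plan_pt),
    250 / 3
  )
  # no rated elements -> missing, not zero
  empty_plan <- list(criteria = list(character(0)), has_intensity = FALSE)
  expect_true(is.na(content_score(list(), empty_plan)))
})

test_that("quality is the equal-weight mean of understanding, contribution, performance", {
  lb <- c(
    stats::setNames(as.list(rep("large_extent", 4)), paste0("und_", 1:4)),
    stats::setNames(as.list(rep("large_extent", 4)), paste0("con_", 1:4)),
    list(performance = 9L)
  )
  q <- quality_score(lb)
  expect_equal(q$understanding, 100)
  expect_equal(q$contribution, 100)
  expect_equal(q$performance, 100)
  expect_equal(q$quality, 100)

  lb$performance <- 6L
  expect_equal(quality_score(lb)$quality, 250 / 3)
  # (92 + 92 + 80) / 3 = 88: mixed item patterns
  lb2 <- lb
  lb2[paste0("und_", 1:4)] <- list("large_extent", "large_extent",
                                   "large_extent", "somewhat")  # 87.5
  expect_equal(quality_score(lb2)$understanding, 87.5)

  # all sub-scores missing -> missing quality
  expect_true(is.na(quality_score(list())$quality))
})

test_that("fidelity is the mean of content and quality and lies between them", {
  expect_equal(session_fidelity(0.5, 0.8), 0.65)
  expect_equal(session_fidelity(1, 1), 1)
  expect_equal(session_fidelity(0, 0), 0)
  set.seed(7)
  c_s <- runif(50, 0, 100); q_s <- runif(50, 0, 100)
  f <- session_fidelity(c_s, q_s)
  expect_true(all(f >= pmin(c_s, q_s) & f <= pmax(c_s, q_s)))
})

test_that("organizational implementation averages dose and fidelity", {
  expect_equal(organizational_implementation(0.875, 0.65), 0.7625)
  expect_equal(percent(organizational_implementation(0.875, 0.65)), 76)
  expect_equal(organizational_implementation(1, 1), 1)
  expect_equal(organizational_implementation(0, 0), 0)
})

test_that("fidelity of intended sessions discounts held-session fidelity by dose", {
  expect_equal(fidelity_of_intended(0.91, 713 / 753), 0.91 * 713 / 753)
  expect_equal(fidelity_of_intended(1, 1), 1)
  expect_equal(fidelity_of_intended(0.9, 0.5), 0.45)
  # equals fidelity when everything was held
  expect_equal(fidelity_of_intended(0.77, 1), 0.77)
})

test_that("score_sessions scores held sessions and leaves unmeasured ones missing", {
  trial <- mini_trial()
  scored <- score_sessions(trial)
  expect_equal(nrow(scored), 12)
  expect_true(all(scored$content[scored$held] == 100))
  expect_true(all(scored$fidelity[scored$held] == 100))

  held <- rep(TRUE, 12); held[4] <- FALSE  # cancel PT1 at team A
  sess <- mini_sessions(held)
  trial2 <- mini_trial(sessions = sess, logbooks = mini_logbooks(sess),
                       attendance = mini_attendance_full(sess))
  scored2 <- score_sessions(trial2)
  expect_true(is.na(scored2$fidelity[scored2$session_id == "s04"]))

  # held but missing logbook: counted in dose, missing for fidelity
  trial3 <- mini_trial(logbooks = mini_logbooks()[-3, ])
  scored3 <- score_sessions(trial3)
  expect_true(is.na(scored3$fidelity[3]))
  expect_true(scored3$held[3])
})

test_that("delivery summaries aggregate dose and held-session scores per stratum", {
  trial <- mini_trial()
  by_comp <- summarize_delivery(trial, by = "component")
  expect_setequal(by_comp$stratum, c("PE", "PT", "CBT"))
  expect_true(all(by_comp$dose == 1))
  expect_true(all(by_comp$fidelity_mean == 100))
  expect_true(all(by_comp$fidelity_of_intended == by_comp$fidelity_mean))

  # sample SD from a two-session stratum: fidelity 100 and 50
  sess <- mini_sessions()
  lbs <- mini_logbooks(sess)
  half <- mini_logbooks_half(sess)
  lbs[lbs$session_id == "s12", ] <- half[half$session_id == "s12", ]
  trial2 <- mini_trial(logbooks = lbs)
  cbt <- summarize_delivery(trial2, by = "component")
  cbt <- cbt[cbt$stratum == "CBT", ]
  expect_equal(cbt$fidelity_mean, 75)
  expect_equal(cbt$fidelity_sd, sd(c(100, 50)))

  # adding a session at the stratum mean leaves the mean unchanged
  scored <- score_sessions(trial2)
  extra <- scored[scored$component_id == "CBT", ][1, ]
  extra$session_id <- "s99"
  extra[c("content", "understanding", "contribution", "performance",
          "quality", "fidelity", "motivation")] <-
    as.list(colMeans(scored[scored$component_id == "CBT" & scored$held,
                            c("content", "understanding", "contribution",
                              "performance", "quality", "fidelity", "motivation")]))
  aug <- summarize_delivery(rbind(scored, extra), by = "component")
  expect_equal(aug$fidelity_mean[aug$stratum == "CBT"], cbt$fidelity_mean)
})

test_that("empty strata report zero counts and missing means", {
  scored <- score_sessions(mini_trial())
  none_held <- scored
  none_held$held <- FALSE
  out <- summarize_delivery(none_held, by = "organization")
  expect_equal(out$n_held, 0)
  expect_equal(out$dose, 0)
  expect_true(is.na(out$fidelity_mean))
})
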