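#' Configure a synthetic trial
#'
#' Builds the configuration for [simulate_trial()]. The defaults emulate a
#' four-workplace stepped-wedge trial: 594 participants in 58 teams across
#' 4 workplaces, randomized to 4 steps of 126/146/158/164 participants,
#' receiving the packaged 19-session / 27-hour protocol through 753
#' scheduled sessions — 172 participatory-ergonomics sessions (16
#' kick-offs, one per workplace-step cell, plus 39 working groups x 4
#' team-mode sessions), 501 physical-training sessions (42 training groups
#' x 12 weekly sessions, with 3 groups merging one week), and 80
#' cognitive-behavioural sessions (40 groups x 2 workshops).
#'
#' Category ratings are drawn by thresholding a latent uniform against the
#' configured propensity so that the *expected* scored value equals the
#' propensity exactly, avoiding distributional assumptions the scoring
#' scales cannot support. Attendance is Bernoulli per participant and
#' session with a logit-normal individual propensity, which both spreads
#' participation realistically and makes questionnaire response (tied to
#' presence at the final workshop) positively selected on participation,
#' emulating responders participating far more than non-responders.
#'
#' @param seed master seed; every table draws from its own stream derived
#'   from it, so regenerating one table never perturbs the others.
#' @param protocol a [protocol_spec()]; defaults to [default_protocol()].
#' @param participants_per_step participants randomized to each step.
#' @param teams_per_step teams per step (sums to the team count).
#' @param n_workplaces number of workplaces.
#' @param n_pe_groups,n_pt_groups,n_cbt_groups delivery-unit counts for the
#'   team-mode, training and workshop components.
#' @param pt_short_groups training groups that merge one week (one fewer
#'   scheduled session).
#' @param n_deliverers deliverer pool size.
#' @param cancellation_prob per-component probability a scheduled session
#'   is not held.
#' @param content_propensity,quality_propensity per-component expected
#'   content/quality score (fractions).
#' @param intensity_propensity expected scored physical intensity.
#' @param motivation_propensity expected scored group motivation.
#' @param more_in_depth_prob probability a fully-implemented criterion is
#'   recorded as implemented-more-in-depth (scores identically).
#' @param deliverer_sd SD of the per-deliverer shift on content/quality
#'   propensities.
#' @param attendance_prob per-component attendance probability at
#'   individual-mode sessions (for the team-mode component this applies to
#'   its individual-mode kick-off).
#' @param rep_attendance_prob,nonrep_attendance_prob attendance probability
#'   at team-mode sessions for designated representatives and other team
#'   members.
#' @param individual_sd SD of the per-participant attendance propensity on
#'   the logit scale.
#' @param response_prob_attended,response_prob_otherwise questionnaire
#'   response probability given presence/absence at the final session.
#' @param satisfaction_propensity,support_propensity expected scored
#'   questionnaire sub-indexes (fractions).
#' @param step_content_effect additive per-step shift on the content
#'   propensity (step drift in delivery).
#' @param workplace_attendance_effect additive per-workplace shift on
#'   attendance probabilities.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       protocol = default_protocol(),
                       participants_per_step = c(126L, 146L, 158L, 164L),
                       teams_per_step = c(12L, 14L, 16L, 16L),
                       n_workplaces = 4L,
                       n_pe_groups = 39L,
                       n_pt_groups = 42L,
                       n_cbt_groups = 40L,
                       pt_short_groups = 3L,
                       n_deliverers = 6L,
                       cancellation_prob = c(PE = 0.006, PT = 0.074, CBT = 0.025),
                       content_propensity = c(PE = 0.95, PT = 0.86, CBT = 0.96),
                       quality_propensity = c(PE = 0.92, PT = 0.93, CBT = 0.92),
                       intensity_propensity = 0.80,
                       motivation_propensity = 0.92,
                       more_in_depth_prob = 0.10,
                       deliverer_sd = 0.02,
                       attendance_prob = c(PE = 0.60, PT = 0.38, CBT = 0.48),
                       rep_attendance_prob = 0.87,
                       nonrep_attendance_prob = 0.05,
                       individual_sd = 1.3,
                       response_prob_attended = 0.92,
                       response_prob_otherwise = 0.08,
                       satisfaction_propensity = 0.83,
                       support_propensity = 0.93,
                       step_content_effect = c(0, 0, 0, 0),
                       workplace_attendance_effect = c(0, 0, 0, 0)) {
  stopifnot(
    inherits(protocol, "protocol_spec"),
    length(participants_per_step) == length(teams_per_step),
    all(participants_per_step >= 4 * teams_per_step),
    n_workplaces >= 1, n_deliverers >= 1,
    length(step_content_effect) == length(participants_per_step),
    length(workplace_attendance_effect) == n_workplaces
  )
  n_teams <- sum(teams_per_step)
  for (ng in c(n_pe_groups, n_pt_groups, n_cbt_groups)) {
    if (ng < 1 || ng > n_teams) {
      stop("infeasible config: delivery-group counts must lie in [1, n_teams]",
           call. = FALSE)
    }
  }
  comps <- protocol$components$component_id
  for (nm in c("cancellation_prob", "content_propensity", "quality_propensity",
               "attendance_prob")) {
    val <- get(nm)
    if (!all(comps %in% names(val))) {
      stop("config ", nm, " must name every protocol component", call. = FALSE)
    }
  }
  probs <- c(cancellation_prob, content_propensity, quality_propensity,
             attendance_prob, intensity_propensity, motivation_propensity,
             more_in_depth_prob, rep_attendance_prob, nonrep_attendance_prob,
             response_prob_attended, response_prob_otherwise,
             satisfaction_propensity, support_propensity)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities and propensities must lie in [0, 1]", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$n_teams <- n_teams
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d: %d participants, %d teams, %d workplaces, %d steps\n",
    x$seed, sum(x$participants_per_step), x$n_teams, x$n_workplaces,
    length(x$participants_per_step)
  ))
  invisible(x)
}

clamp <- function(x, lo = 0.01, hi = 0.99) pmin(pmax(x, lo), hi)

# Latent-threshold draw on {0, 50, 100} with exact expected score 100*p:
# for p >= 1/2 mix 100 (weight 2p-1) with 50; for p < 1/2 mix 50 (2p) with 0.
draw_threshold_score <- function(n, p) {
  u <- stats::runif(n)
  if (p >= 0.5) ifelse(u < 2 * p - 1, 100, 50) else ifelse(u < 2 * p, 50, 0)
}

likert_token_for_score <- function(score, variant = c("extent", "frequency")) {
  variant <- match.arg(variant)
  pos <- if (variant == "extent") c("very_large_extent", "large_extent")
         else c("always", "often")
  mid <- if (variant == "extent") "somewhat" else "sometimes"
  neg <- if (variant == "extent") c("small_extent", "very_small_extent")
         else c("seldom", "never")
  vapply(score, function(s) {
    if (is.na(s)) NA_character_
    else if (s == 100) sample(pos, 1)
    else if (s == 50) mid
    else sample(neg, 1)
  }, "")
}

criterion_token_for_score <- function(score, more_in_depth_prob) {
  vapply(score, function(s) {
    if (is.na(s)) NA_character_
    else if (s == 100) {
      if (stats::runif(1) < more_in_depth_prob) "more_in_depth" else "completely"
    } else if (s == 50) "partly" else "not"
  }, "")
}

# 0-10 intensity with exact expected score p (fractions); mixes the 75 band
# (weight w) with a 50/100 two-point mixture where feasible
draw_intensity <- function(n, p, w75 = 0.3) {
  m <- (p - 0.75 * w75) / (1 - w75)
  if (m < 0.5 || m > 1) { w75 <- 0; m <- p }
  vapply(seq_len(n), function(i) {
    u <- stats::runif(1)
    if (u < w75) return(sample(6:7, 1))
    s <- draw_threshold_score(1, m)
    if (s == 100) sample(8:10, 1) else if (s == 50) sample(4:5, 1) else sample(0:3, 1)
  }, 0L)
}

performance_for_score <- function(score) {
  vapply(score, function(s) {
    if (s == 100) sample(8:10, 1) else if (s == 50) sample(5:7, 1) else sample(0:4, 1)
  }, 0L)
}

# pair teams (rows of a data frame ordered by cell) into n_groups units,
# pairing only within the same workplace-step cell
pair_teams_into_groups <- function(teams, n_groups, prefix) {
  n_pairs <- nrow(teams) - n_groups
  stopifnot(n_pairs >= 0)
  cells <- split(teams$team_id,
                 paste(teams$workplace_id, teams$step, sep = "|"))
  groups <- list()
  for (cell in cells) {
    i <- 1
    while (i <= length(cell)) {
      if (n_pairs > 0 && i + 1 <= length(cell)) {
        groups[[length(groups) + 1]] <- cell[i:(i + 1)]
        n_pairs <- n_pairs - 1
        i <- i + 2
      } else {
        groups[[length(groups) + 1]] <- cell[i]
        i <- i + 1
      }
    }
  }
  if (n_pairs > 0) {
    stop("infeasible config: not enough same-cell team pairs to reach the requested group count",
         call. = FALSE)
  }
  names(groups) <- sprintf("%s%02d", prefix, seq_along(groups))
  groups
}

#' Generate a synthetic trial
#'
#' Deterministic given the config seed: emits a complete [imp_trial()]
#' (roster, units, schedule, logbooks, attendance, questionnaires) that
#' passes [validate_dataset()] with zero violations, and attaches the
#' generating parameters as ground truth (see [ground_truth()]).
#'
#' @param config a [sim_config()].
#' @return an `imp_trial` with attributes `ground_truth` and `sim_config`.
#' @export
simulate_trial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  proto <- config$protocol
  comps <- proto$components$component_id
  n_steps <- length(config$participants_per_step)
  steps <- sprintf("S%d", seq_len(n_steps))
  workplaces <- sprintf("W%d", seq_len(config$n_workplaces))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, 6L)

  ## --- roster stream ---------------------------------------------------
  set.seed(stream_seeds[1])
  team_rows <- list()
  part_rows <- list()
  team_no <- 0L
  pid_no <- 0L
  for (s in seq_len(n_steps)) {
    t_s <- config$teams_per_step[s]
    n_s <- config$participants_per_step[s]
    sizes <- as.vector(stats::rmultinom(1, n_s - 4L * t_s, rep(1, t_s))) + 4L
    wps <- workplaces[((seq_len(t_s) - 1L + (s - 1L)) %% config$n_workplaces) + 1L]
    for (j in seq_len(t_s)) {
      team_no <- team_no + 1L
      tid <- sprintf("T%02d", team_no)
      team_rows[[team_no]] <- tibble::tibble(
        team_id = tid, workplace_id = wps[j], size = sizes[j], step = steps[s])
      ids <- sprintf("P%04d", pid_no + seq_len(sizes[j]))
      pid_no <- pid_no + sizes[j]
      part_rows[[team_no]] <- tibble::tibble(
        participant_id = ids, team_id = tid, workplace_id = wps[j],
        step = steps[s])
    }
  }
  teams <- dplyr::bind_rows(team_rows)
  participants <- dplyr::bind_rows(part_rows)
  roster <- imp_roster(participants, teams[c("team_id", "workplace_id", "size")],
                       steps)
  # designated representatives per team (used for team-mode attendance)
  reps <- unlist(lapply(seq_len(nrow(teams)), function(i) {
    members <- participants$participant_id[participants$team_id == teams$team_id[i]]
    req <- required_representatives(teams$size[i], proto$representation_schedule)
    sample(members, min(req, length(members)))
  }))
  is_rep <- participants$participant_id %in% reps

  ## --- units & schedule stream -----------------------------------------
  set.seed(stream_seeds[2])
  team_plans <- proto$sessions$plan_id[proto$sessions$receipt_mode == "team"]
  indiv_plans_by_comp <- split(
    proto$sessions$plan_id[proto$sessions$receipt_mode == "individual"],
    proto$sessions$component_id[proto$sessions$receipt_mode == "individual"])
  team_comp <- unique(proto$sessions$component_id[proto$sessions$receipt_mode == "team"])
  # individual-mode plans of the team component (the kick-off) are
  # delivered to workplace-step assemblies; other components to groups
  ko_plans <- intersect(indiv_plans_by_comp[[team_comp]] %||% character(0),
                        proto$sessions$plan_id)

  teams$cell <- paste(teams$workplace_id, teams$step, sep = "|")
  pe_groups <- pair_teams_into_groups(teams, config$n_pe_groups, "PEG")
  pt_groups <- pair_teams_into_groups(teams, config$n_pt_groups, "PTG")
  cbt_groups <- pair_teams_into_groups(teams, config$n_cbt_groups, "CBG")

  members_of_teams <- function(tids) {
    participants$participant_id[participants$team_id %in% tids]
  }
  unit_rows <- list()
  add_unit <- function(unit_id, member_ids) {
    unit_rows[[length(unit_rows) + 1]] <<- tibble::tibble(
      unit_id = unit_id, participant_id = member_ids)
  }
  unit_meta <- list()
  add_meta <- function(unit_id, workplace, step, plans) {
    unit_meta[[length(unit_meta) + 1]] <<- tibble::tibble(
      unit_id = unit_id, workplace_id = workplace, step = step,
      plan_id = plans)
  }
  cells <- unique(teams$cell)
  for (cell in cells) {
    tin <- teams[teams$cell == cell, ]
    uid <- paste0("KO_", gsub("\\|", "_", cell))
    add_unit(uid, members_of_teams(tin$team_id))
    add_meta(uid, tin$workplace_id[1], tin$step[1], ko_plans)
  }
  add_group_units <- function(groups, plans_fn) {
    for (g in names(groups)) {
      tids <- groups[[g]]
      trow <- teams[teams$team_id == tids[1], ]
      add_unit(g, members_of_teams(tids))
      add_meta(g, trow$workplace_id, trow$step, plans_fn(g))
    }
  }
  add_group_units(pe_groups, function(g) team_plans)
  # remaining components in protocol order take the training-group and
  # workshop-group partitions respectively
  other_comps <- setdiff(comps, team_comp)
  pt_plans <- sort(indiv_plans_by_comp[[other_comps[1]]])
  short <- sample(names(pt_groups), min(config$pt_short_groups, length(pt_groups)))
  add_group_units(pt_groups, function(g) {
    if (g %in% short) utils::head(pt_plans, -1) else pt_plans
  })
  if (length(other_comps) > 1) {
    cbt_plans <- sort(unlist(indiv_plans_by_comp[other_comps[-1]], use.names = FALSE))
    add_group_units(cbt_groups, function(g) cbt_plans)
  }

  units <- dplyr::bind_rows(unit_rows)
  schedule <- dplyr::bind_rows(unit_meta)
  schedule$component_id <- proto$sessions$component_id[
    match(schedule$plan_id, proto$sessions$plan_id)]
  schedule$session_id <- sprintf("SES%04d", seq_len(nrow(schedule)))
  deliverer_of_unit <- stats::setNames(
    sample(sprintf("D%d", seq_len(config$n_deliverers)),
           length(unique(schedule$unit_id)), replace = TRUE),
    unique(schedule$unit_id))
  schedule$deliverer_id <- unname(deliverer_of_unit[schedule$unit_id])
  schedule$held <- unname(stats::runif(nrow(schedule)) >=
    config$cancellation_prob[schedule$component_id])
  sessions <- schedule[c("session_id", "plan_id", "component_id",
                         "workplace_id", "unit_id", "step", "held",
                         "deliverer_id")]

  ## --- attendance stream ------------------------------------------------
  set.seed(stream_seeds[3])
  z <- stats::rnorm(nrow(participants), 0, config$individual_sd)
  names(z) <- participants$participant_id
  wp_eff <- stats::setNames(config$workplace_attendance_effect, workplaces)
  unit_members <- split(units$participant_id, units$unit_id)
  plan_mode <- stats::setNames(proto$sessions$receipt_mode, proto$sessions$plan_id)
  att_rows <- list()
  held_sessions <- sessions[sessions$held, ]
  for (i in seq_len(nrow(held_sessions))) {
    srow <- held_sessions[i, ]
    members <- unit_members[[srow$unit_id]]
    zi <- z[members]
    if (plan_mode[[srow$plan_id]] == "individual") {
      base <- clamp(config$attendance_prob[[srow$component_id]] +
                      wp_eff[[srow$workplace_id]])
      p <- stats::plogis(stats::qlogis(base) + zi)
    } else {
      rep_here <- is_rep[match(members, participants$participant_id)]
      base <- ifelse(rep_here, config$rep_attendance_prob,
                     config$nonrep_attendance_prob)
      p <- stats::plogis(stats::qlogis(clamp(base)) + zi)
    }
    came <- members[stats::runif(length(members)) < p]
    if (length(came)) {
      att_rows[[length(att_rows) + 1]] <- tibble::tibble(
        session_id = srow$session_id, participant_id = came)
    }
  }
  attendance <- dplyr::bind_rows(att_rows)

  ## --- logbook stream ---------------------------------------------------
  set.seed(stream_seeds[4])
  deliverers <- sprintf("D%d", seq_len(config$n_deliverers))
  del_eff <- stats::setNames(stats::rnorm(length(deliverers), 0,
                                          config$deliverer_sd), deliverers)
  step_eff <- stats::setNames(config$step_content_effect, steps)
  lb_rows <- vector("list", nrow(held_sessions))
  for (i in seq_len(nrow(held_sessions))) {
    srow <- held_sessions[i, ]
    plan <- proto$sessions[match(srow$plan_id, proto$sessions$plan_id), ]
    k <- length(plan$criteria[[1]])
    p_c <- clamp(config$content_propensity[[srow$component_id]] +
                   step_eff[[srow$step]] + del_eff[[srow$deliverer_id]],
                 0.01, 0.999)
    p_q <- clamp(config$quality_propensity[[srow$component_id]] +
                   del_eff[[srow$deliverer_id]], 0.01, 0.999)
    crit <- rep(NA_character_, 5)
    if (k > 0) {
      crit[seq_len(k)] <- criterion_token_for_score(
        draw_threshold_score(k, p_c), config$more_in_depth_prob)
    }
    und <- likert_token_for_score(draw_threshold_score(4, p_q))
    con <- likert_token_for_score(draw_threshold_score(4, p_q))
    perf <- performance_for_score(draw_threshold_score(1, p_q))
    intensity <- if (isTRUE(plan$has_intensity)) {
      draw_intensity(1, config$intensity_propensity)
    } else NA_integer_
    motiv <- likert_token_for_score(
      draw_threshold_score(1, config$motivation_propensity))
    row <- c(list(session_id = srow$session_id),
             stats::setNames(as.list(crit), paste0("crit_", 1:5)),
             stats::setNames(as.list(und), paste0("und_", 1:4)),
             stats::setNames(as.list(con), paste0("con_", 1:4)),
             list(performance = perf, intensity = intensity,
                  motivation = motiv))
    lb_rows[[i]] <- tibble::as_tibble(row)
  }
  logbooks <- dplyr::bind_rows(lb_rows)

  ## --- questionnaire stream ---------------------------------------------
  set.seed(stream_seeds[5])
  final_plan <- proto$sessions$plan_id[nrow(proto$sessions)]
  final_sessions <- sessions$session_id[sessions$plan_id == final_plan &
                                          sessions$held]
  att_key <- attendance$participant_id[attendance$session_id %in% final_sessions]
  attended_final <- participants$participant_id %in% att_key
  p_resp <- ifelse(attended_final, config$response_prob_attended,
                   config$response_prob_otherwise)
  responded <- stats::runif(nrow(participants)) < p_resp
  resp_ids <- participants$participant_id[responded]
  n_r <- length(resp_ids)
  q <- tibble::tibble(participant_id = resp_ids)
  for (comp in comps) {
    q[[paste0("sat_", tolower(comp))]] <- likert_token_for_score(
      draw_threshold_score(n_r, config$satisfaction_propensity))
  }
  for (col in c("sat_overall", "sat_relevant", "sat_interesting")) {
    q[[col]] <- likert_token_for_score(
      draw_threshold_score(n_r, config$satisfaction_propensity))
  }
  for (j in 1:4) {
    q[[paste0("sup_", j)]] <- likert_token_for_score(
      draw_threshold_score(n_r, config$support_propensity), "frequency")
  }

  trial <- imp_trial(proto, roster, units, sessions, logbooks, attendance, q)
  attr(trial, "sim_config") <- config
  attr(trial, "ground_truth") <- compute_ground_truth(config)
  trial
}

# expected attendance probability after the logit-normal individual shift
logit_normal_mean <- function(p, sd) {
  if (sd == 0) return(p)
  f <- function(zz) stats::plogis(stats::qlogis(p) + zz) * stats::dnorm(zz, 0, sd)
  stats::integrate(f, -Inf, Inf)$value
}

compute_ground_truth <- function(config) {
  comps <- config$protocol$components$component_id
  fid <- (config$content_propensity[comps] + config$quality_propensity[comps]) / 2
  att <- vapply(comps, function(cc) {
    logit_normal_mean(config$attendance_prob[[cc]], config$individual_sd)
  }, 0)
  list(
    content_propensity = config$content_propensity[comps],
    quality_propensity = config$quality_propensity[comps],
    fidelity_propensity = fid,
    motivation_propensity = config$motivation_propensity,
    satisfaction_propensity = config$satisfaction_propensity,
    support_propensity = config$support_propensity,
    responsiveness_expected = mean(c(config$satisfaction_propensity,
                                     config$support_propensity,
                                     config$motivation_propensity)),
    attendance_expected = att,
    # individual-mode participation: attendance x probability the session
    # was held; the team-mode component's team scores have no simple
    # closed form and are checked by invariants, not recovery
    participation_expected = att * (1 - config$cancellation_prob[comps]),
    dose_expected = 1 - config$cancellation_prob[comps],
    step_content_effect = config$step_content_effect,
    workplace_attendance_effect = config$workplace_attendance_effect
  )
}

#' Ground truth of a simulated trial
#'
#' @param trial an `imp_trial` produced by [simulate_trial()].
#' @return the list of generating parameters and derived expectations
#'   stored with the dataset.
#' @export
ground_truth <- function(trial) {
  gt <- attr(trial, "ground_truth")
  if (is.null(gt)) stop("trial carries no ground truth (not simulated?)",
                        call. = FALSE)
  gt
}

#' Parameter recovery over replicated simulations
#'
#' Simulates `replicates` trials (seeds `seed`, `seed + 1`, ...), runs the
#' full scoring pipeline on each, and compares the recovered stratum means
#' with the generating ground truth: mean estimate, bias, RMSE and the
#' Monte-Carlo standard error of the mean estimate. Covered metrics are
#' the per-component held-session content, quality and fidelity means,
#' the per-component dose, and the individual-mode participation means;
#' team-mode receipt has no closed-form truth and is exercised by
#' invariant tests instead.
#'
#' @param config a [sim_config()].
#' @param replicates number of simulated trials.
#' @return a tibble: `metric`, `truth`, `estimate`, `bias`, `rmse`,
#'   `mc_se` (truth and estimates as fractions).
#' @export
recovery_check <- function(config = sim_config(), replicates = 5) {
  comps <- config$protocol$components$component_id
  team_comp <- unique(config$protocol$sessions$component_id[
    config$protocol$sessions$receipt_mode == "team"])
  indiv_comps <- setdiff(comps, team_comp)
  gt <- compute_ground_truth(config)

  one_rep <- function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    trial <- simulate_trial(cfg)
    deliv <- summarize_delivery(trial, by = "component")
    ind <- individual_scores(trial)
    est <- c()
    for (comp in comps) {
      d <- deliv[deliv$stratum == comp, ]
      est[paste0("content_", comp)] <- d$content_mean / 100
      est[paste0("quality_", comp)] <- d$quality_mean / 100
      est[paste0("fidelity_", comp)] <- d$fidelity_mean / 100
      est[paste0("dose_", comp)] <- d$dose
    }
    for (comp in indiv_comps) {
      est[paste0("participation_", comp)] <-
        mean(ind[[paste0("participation_", comp)]], na.rm = TRUE) / 100
    }
    est
  }
  ests <- t(vapply(seq_len(replicates), one_rep,
                   one_rep_template(comps, indiv_comps)))
  truth <- c(
    stats::setNames(as.numeric(gt$content_propensity), paste0("content_", comps)),
    stats::setNames(as.numeric(gt$quality_propensity), paste0("quality_", comps)),
    stats::setNames(as.numeric(gt$fidelity_propensity), paste0("fidelity_", comps)),
    stats::setNames(as.numeric(gt$dose_expected), paste0("dose_", comps)),
    stats::setNames(as.numeric(gt$participation_expected[indiv_comps]),
                    paste0("participation_", indiv_comps))
  )
  truth <- truth[colnames(ests)]
  tibble::tibble(
    metric = colnames(ests),
    truth = as.numeric(truth),
    estimate = colMeans(ests),
    bias = colMeans(ests) - as.numeric(truth),
    rmse = sqrt(colMeans((t(t(ests) - truth))^2)),
    mc_se = apply(ests, 2, stats::sd) / sqrt(replicates)
  )
}

one_rep_template <- function(comps, indiv_comps) {
  nm <- c(as.vector(outer(c("content_", "quality_", "fidelity_", "dose_"),
                          comps, paste0)),
          paste0("participation_", indiv_comps))
  stats::setNames(numeric(length(nm)), nm)
}
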