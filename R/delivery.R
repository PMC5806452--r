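#' Dose delivered
#'
#' The fraction of protocol-planned sessions actually held,
#' `D = delivered / intended`.
#'
#' @param delivered number of sessions held.
#' @param intended number of sessions planned; must be positive.
#' @return the dose as an exact fraction in `[0, 1]`.
#' @export
#' @examples
#' dose(700, 800)   # 0.875
#' percent(dose(713, 753)) # 95
dose <- function(delivered, intended) {
  if (any(intended <= 0)) {
    stop("dose is undefined for intended <= 0", call. = FALSE)
  }
  if (any(delivered < 0) || any(delivered > intended)) {
    stop("delivered count must lie in [0, intended]", call. = FALSE)
  }
  delivered / intended
}

#' Session content score
#'
#' The mean of the scored success-criterion ratings for the session. For
#' plans rated for physical intensity, the scored intensity enters the
#' mean as one additional element with the same weight as each criterion.
#'
#' @param logbook a single logbook record: a list or one-row data frame
#'   with criterion columns `crit_1` ... and, where applicable, `intensity`.
#' @param plan the matching protocol session plan (one row of
#'   `protocol$sessions`, or a list with `criteria` and `has_intensity`).
#' @return content score on 0-100, or `NA` if no element was rated.
#' @export
#' @examples
#' plan <- list(criteria = list(c("a", "b")), has_intensity = FALSE)
#' content_score(list(crit_1 = "completely", crit_2 = "partly"), plan) # 75
content_score <- function(logbook, plan) {
  criteria <- plan$criteria
  if (is.list(criteria) && !is.character(criteria)) criteria <- criteria[[1]]
  k <- length(criteria)
  ratings <- if (k > 0) {
    unlist(lapply(seq_len(k), function(i) {
      val <- logbook[[paste0("crit_", i)]]
      if (is.null(val)) NA_character_ else as.character(val)
    }))
  } else {
    character(0)
  }
  elements <- score_criterion4(ratings)
  if (isTRUE(plan$has_intensity[[1]])) {
    intensity <- logbook[["intensity"]]
    elements <- c(elements, score_intensity10(
      if (is.null(intensity)) NA_integer_ else intensity))
  }
  score_index(elements)
}

#' Session quality score
#'
#' Deliverer performance for one session: the understanding index (mean of
#' four items), the contribution index (mean of four items), and the
#' scored self-rated performance, averaged with equal weight. Sub-scores
#' that are entirely missing are dropped; quality is missing only when all
#' three are.
#'
#' @param logbook a single logbook record with columns `und_1` ... `und_4`,
#'   `con_1` ... `con_4` (five-category extent tokens) and `performance`
#'   (integer 0-10).
#' @return a one-row tibble with `understanding`, `contribution`,
#'   `performance` and `quality`, each on 0-100 or `NA`.
#' @export
quality_score <- function(logbook) {
  get_items <- function(prefix, n) {
    vapply(seq_len(n), function(i) {
      val <- logbook[[paste0(prefix, i)]]
      if (is.null(val)) NA_character_ else as.character(val)
    }, "")
  }
  understanding <- score_index(score_likert5(get_items("und_", 4)))
  contribution <- score_index(score_likert5(get_items("con_", 4)))
  perf_raw <- logbook[["performance"]]
  performance <- score_performance10(
    if (is.null(perf_raw)) NA_integer_ else perf_raw)
  tibble::tibble(
    understanding = understanding,
    contribution = contribution,
    performance = as.numeric(performance),
    quality = score_index(c(understanding, contribution, performance))
  )
}

#' Session fidelity
#'
#' Fidelity is the mean of the content and quality scores,
#' `F = (C + Q) / 2`. Scale-agnostic: feed fractions to get a fraction,
#' 0-100 scores to get a 0-100 score. Missing if either input is missing.
#'
#' @param content,quality numeric vectors on a common scale.
#' @return elementwise fidelity on the same scale.
#' @export
#' @examples
#' session_fidelity(0.5, 0.8) # 0.65
session_fidelity <- function(content, quality) {
  (content + quality) / 2
}

#' Fidelity of intended sessions
#'
#' Discounts the fidelity observed at held sessions by the dose:
#' `fidelity x fraction of sessions held`. Cancelled sessions thus count
#' as zero-fidelity against the protocol.
#'
#' @param fidelity_held mean fidelity over held sessions (any scale).
#' @param dose fraction of intended sessions held, in `[0, 1]`.
#' @return score on the scale of `fidelity_held`.
#' @export
fidelity_of_intended <- function(fidelity_held, dose) {
  stopifnot(all(is.na(dose) | (dose >= 0 & dose <= 1)))
  fidelity_held * dose
}

#' Organizational-level implementation
#'
#' The average of dose and fidelity, `(D + F) / 2`, both as fractions.
#'
#' @param dose fraction of intended sessions held.
#' @param fidelity organization-level fidelity as a fraction.
#' @return implementation fraction in `[0, 1]`.
#' @export
#' @examples
#' organizational_implementation(0.875, 0.65) # 0.7625
organizational_implementation <- function(dose, fidelity) {
  stopifnot(
    all(is.na(dose) | (dose >= 0 & dose <= 1)),
    all(is.na(fidelity) | (fidelity >= 0 & fidelity <= 1))
  )
  (dose + fidelity) / 2
}

#' Score every scheduled session
#'
#' Joins the session schedule to the deliverer logbooks and computes the
#' session-level content, quality (with sub-scores) and fidelity, all on
#' 0-100. Sessions not held, or held without a logbook, keep missing
#' scores (absence of measurement is not zero fidelity; they still count
#' in the dose denominator and numerator respectively).
#'
#' @param trial an [imp_trial()].
#' @return a tibble with one row per scheduled session: identifiers,
#'   strata, `held`, `content`, `understanding`, `contribution`,
#'   `performance`, `quality`, `fidelity`.
#' @export
score_sessions <- function(trial) {
  stopifnot(inherits(trial, "imp_trial"))
  sess <- trial$sessions
  plans <- trial$protocol$sessions
  lb <- trial$logbooks
  lb_row <- match(sess$session_id, lb$session_id)

  out <- sess[c("session_id", "plan_id", "component_id", "workplace_id",
                "unit_id", "step", "held", "deliverer_id")]
  n <- nrow(sess)
  content <- understanding <- contribution <- performance <-
    quality <- motivation <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    j <- lb_row[i]
    if (is.na(j) || !sess$held[i]) next
    entry <- lb[j, ]
    plan <- plans[match(sess$plan_id[i], plans$plan_id), ]
    content[i] <- content_score(entry, plan)
    q <- quality_score(entry)
    understanding[i] <- q$understanding
    contribution[i] <- q$contribution
    performance[i] <- q$performance
    quality[i] <- q$quality
    mot <- entry[["motivation"]]
    if (!is.null(mot) && !is.na(mot)) motivation[i] <- score_likert5(mot)
  }
  out$content <- content
  out$understanding <- understanding
  out$contribution <- contribution
  out$performance <- performance
  out$quality <- quality
  out$fidelity <- session_fidelity(content, quality)
  out$motivation <- motivation
  out$duration_hours <- plans$duration_hours[match(out$plan_id, plans$plan_id)]
  out
}

#' Summarize delivery by stratum
#'
#' Per-stratum session counts, dose, and the mean and sample SD of
#' content, quality (with sub-scores) and fidelity over held, scored
#' sessions, plus the fidelity of intended sessions
#' (held-session fidelity x dose).
#'
#' @param trial an [imp_trial()], or a session score table from
#'   [score_sessions()].
#' @param by grouping: `"organization"`, `"component"`, `"workplace"` or
#'   `"step"`.
#' @return a tibble with one row per stratum; scores on 0-100, `dose` as a
#'   fraction.
#' @export
summarize_delivery <- function(trial, by = c("organization", "component",
                                             "workplace", "step")) {
  by <- match.arg(by)
  scored <- if (inherits(trial, "imp_trial")) score_sessions(trial) else trial
  key <- switch(by,
    organization = NULL,
    component = "component_id",
    workplace = "workplace_id",
    step = "step"
  )
  grouped <- if (is.null(key)) {
    dplyr::group_by(dplyr::mutate(scored, stratum = "organization"), stratum)
  } else {
    dplyr::group_by(dplyr::rename(scored, stratum = dplyr::all_of(key)), stratum)
  }
  out <- dplyr::summarise(
    grouped,
    n_intended = dplyr::n(),
    n_held = sum(held),
    dose = n_held / n_intended,
    content_mean = mean_or_na(content[held]),
    content_sd = sd_or_na(content[held]),
    understanding_mean = mean_or_na(understanding[held]),
    understanding_sd = sd_or_na(understanding[held]),
    contribution_mean = mean_or_na(contribution[held]),
    contribution_sd = sd_or_na(contribution[held]),
    performance_mean = mean_or_na(performance[held]),
    performance_sd = sd_or_na(performance[held]),
    quality_mean = mean_or_na(quality[held]),
    quality_sd = sd_or_na(quality[held]),
    fidelity_mean = mean_or_na(fidelity[held]),
    fidelity_sd = sd_or_na(fidelity[held]),
    .groups = "drop"
  )
  out$fidelity_of_intended <- fidelity_of_intended(out$fidelity_mean, out$dose)
  out <- dplyr::mutate(out, scope = by, .before = 1)
  out
}
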