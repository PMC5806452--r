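#' Session-level exposure and implementation
#'
#' Exposure is the fidelity a participant was actually exposed to at a
#' session, `E = F x P`, with `F` the session fidelity and `P` the
#' duration-weighted presence (both as fractions). Implementation further
#' discounts exposure by the participant's responsiveness, `I = E x R`.
#' If any factor is zero, implementation is zero.
#'
#' @param fidelity,participation,exposure,responsiveness numeric vectors of
#'   fractions in `[0, 1]`.
#' @return elementwise products (fractions).
#' @export
#' @examples
#' e <- session_exposure(0.65, 3 / 27) # 0.072 to 3 d.p.
#' session_implementation(round(e, 3), 0.8) # 0.0576
session_exposure <- function(fidelity, participation) {
  stopifnot(
    all(is.na(fidelity) | (fidelity >= 0 & fidelity <= 1)),
    all(is.na(participation) | (participation >= 0 & participation <= 1))
  )
  fidelity * participation
}

#' @rdname session_exposure
#' @export
session_implementation <- function(exposure, responsiveness) {
  stopifnot(
    all(is.na(exposure) | (exposure >= 0 & exposure <= 1)),
    all(is.na(responsiveness) | (responsiveness >= 0 & responsiveness <= 1))
  )
  exposure * responsiveness
}

#' Per-participant, per-session score chain
#'
#' One row per participant and planned session carrying the full chain as
#' fractions: the duration-weighted presence `p_s = presence x duration /
#' total_hours`, the session fidelity `f_s`, the exposure `e_s = f_s x
#' p_s`, and the implementation `i_s = e_s x r` with the participant's
#' responsiveness `r` applied as a constant across sessions (it is
#' measured once, at the end of the intervention). Cancelled or
#' unscheduled sessions contribute zeros; held sessions whose fidelity
#' was not measured keep `e_s` missing.
#'
#' @param trial an [imp_trial()].
#' @param session_scores,team_scores,responsiveness optional precomputed
#'   pieces ([score_sessions()], [pe_team_scores()],
#'   [responsiveness_scores()]).
#' @return a tibble; `p_s`, `e_s`, `i_s` are fractions.
#' @export
session_score_table <- function(trial, session_scores = NULL,
                                team_scores = NULL, responsiveness = NULL) {
  stopifnot(inherits(trial, "imp_trial"))
  if (is.null(session_scores)) session_scores <- score_sessions(trial)
  if (is.null(team_scores)) team_scores <- pe_team_scores(trial)
  if (is.null(responsiveness)) {
    responsiveness <- responsiveness_scores(trial, session_scores)
  }
  grid <- session_presence(trial, team_scores)
  grid$fidelity <- session_scores$fidelity[
    match(grid$session_id, session_scores$session_id)]
  grid$f_s <- grid$fidelity / 100
  grid$p_s <- grid$presence * grid$weight
  grid$e_s <- ifelse(grid$p_s == 0, 0, session_exposure(grid$f_s, grid$p_s))
  r <- responsiveness$responsiveness[
    match(grid$participant_id, responsiveness$participant_id)] / 100
  grid$i_s <- session_implementation(grid$e_s, r)
  grid
}

#' Individual-level totals
#'
#' Sums the session chain per participant: participation `sum(p_s)`,
#' exposure `E_all = sum(e_s)`, implementation `I_all = sum(i_s)`
#' (missing for participants without a questionnaire, whose
#' responsiveness is unmeasured), and the duration-and-presence-weighted
#' mean fidelity over attended sessions. Component columns recompute the
#' sums restricted to each component's sessions with the component's own
#' planned hours as denominator. All scores are reported on 0-100.
#'
#' @param trial an [imp_trial()].
#' @param chain optional precomputed [session_score_table()].
#' @param responsiveness optional precomputed [responsiveness_scores()].
#' @return a tibble with one row per participant: strata
#'   (`team_id`, `workplace_id`, `step`), `participation`, `fidelity`,
#'   `exposure`, `responsiveness`, `implementation`, and
#'   `<measure>_<component>` columns, all on 0-100.
#' @export
individual_scores <- function(trial, chain = NULL, responsiveness = NULL) {
  stopifnot(inherits(trial, "imp_trial"))
  if (is.null(responsiveness)) responsiveness <- responsiveness_scores(trial)
  if (is.null(chain)) {
    chain <- session_score_table(trial, responsiveness = responsiveness)
  }
  comp_hours <- stats::aggregate(
    duration_hours ~ component_id, data = trial$protocol$sessions, FUN = sum)
  total_hours <- trial$protocol$total_hours

  totals <- dplyr::summarise(
    dplyr::group_by(chain, participant_id, team_id, workplace_id, step),
    participation = 100 * sum(p_s),
    fidelity = wmean_or_na(fidelity, p_s),
    exposure = 100 * sum(e_s, na.rm = TRUE),
    implementation = 100 * sum(i_s, na.rm = TRUE),
    .groups = "drop"
  )
  totals$responsiveness <- responsiveness$responsiveness[
    match(totals$participant_id, responsiveness$participant_id)]
  totals$implementation[is.na(totals$responsiveness)] <- NA_real_

  by_comp <- dplyr::summarise(
    dplyr::group_by(chain, participant_id, component_id),
    hours = sum(presence * duration_hours),
    fid = wmean_or_na(fidelity, p_s),
    exp_hours = sum(f_s * presence * duration_hours, na.rm = TRUE),
    .groups = "drop"
  )
  by_comp$ch <- comp_hours$duration_hours[
    match(by_comp$component_id, comp_hours$component_id)]
  by_comp$participation <- 100 * by_comp$hours / by_comp$ch
  by_comp$exposure <- 100 * by_comp$exp_hours / by_comp$ch

  out <- totals
  for (comp in trial$protocol$components$component_id) {
    bc <- by_comp[by_comp$component_id == comp, , drop = FALSE]
    idx <- match(out$participant_id, bc$participant_id)
    resp_c <- responsiveness[[paste0("responsiveness_", comp)]][
      match(out$participant_id, responsiveness$participant_id)]
    out[[paste0("participation_", comp)]] <- bc$participation[idx]
    out[[paste0("fidelity_", comp)]] <- bc$fid[idx]
    out[[paste0("exposure_", comp)]] <- bc$exposure[idx]
    out[[paste0("responsiveness_", comp)]] <- resp_c
    out[[paste0("implementation_", comp)]] <- bc$exposure[idx] * resp_c / 100
  }
  out
}

imp_measures <- c("fidelity", "exposure", "participation",
                  "responsiveness", "implementation")

#' Stratified summary of individual-level scores
#'
#' Long-format per-stratum summaries (n, mean, sample SD) of fidelity,
#' exposure, participation, responsiveness and implementation at the
#' individual level, stratified by trial step, workplace, intervention
#' component, or reported in total. `n` counts the participants with a
#' non-missing value for the measure (responsiveness and implementation
#' are only defined for questionnaire responders; fidelity only for
#' participants who attended at least one scored session).
#'
#' @param scores an [individual_scores()] table (or an [imp_trial()],
#'   scored on the fly).
#' @param by `"total"`, `"step"`, `"workplace"` or `"component"`.
#' @return a tibble with columns `level`, `stratum_kind`, `stratum`,
#'   `measure`, `n`, `mean`, `sd`; scores on 0-100.
#' @export
stratified_summary <- function(scores, by = c("total", "step", "workplace",
                                              "component")) {
  by <- match.arg(by)
  if (inherits(scores, "imp_trial")) scores <- individual_scores(scores)

  summarize_block <- function(df, stratum, cols = imp_measures) {
    rows <- lapply(seq_along(cols), function(k) {
      x <- df[[cols[k]]]
      tibble::tibble(
        measure = imp_measures[k],
        n = sum(!is.na(x)),
        mean = mean_or_na(x),
        sd = sd_or_na(x)
      )
    })
    out <- dplyr::bind_rows(rows)
    out$stratum <- stratum
    out
  }

  blocks <- switch(by,
    total = list(summarize_block(scores, "total")),
    step = lapply(sort(unique(scores$step)), function(s) {
      summarize_block(scores[scores$step == s, ], s)
    }),
    workplace = lapply(sort(unique(scores$workplace_id)), function(w) {
      summarize_block(scores[scores$workplace_id == w, ], w)
    }),
    component = {
      comps <- unique(sub("^participation_", "",
                          grep("^participation_", names(scores), value = TRUE)))
      lapply(comps, function(comp) {
        summarize_block(scores, comp, cols = paste(imp_measures, comp, sep = "_"))
      })
    }
  )
  out <- dplyr::bind_rows(blocks)
  out <- dplyr::mutate(out, level = "individual", stratum_kind = by, .before = 1)
  out[c("level", "stratum_kind", "stratum", "measure", "n", "mean", "sd")]
}

#' Organizational vs mean-individual implementation
#'
#' The organizational implementation (mean of dose and held-session
#' fidelity) and the mean of the individual implementation scores measure
#' the same construct from two directions and should be close but not
#' identical: receipt terms (participation, responsiveness) only enter
#' the individual chain. This diagnostic reports both and their absolute
#' difference, with the intermediate quantities, without asserting
#' agreement.
#'
#' @param trial an [imp_trial()].
#' @param scores optional precomputed [individual_scores()].
#' @return a one-row tibble: `dose`, `fidelity_held`, `organizational`,
#'   `mean_individual_implementation`, `mean_individual_exposure`,
#'   `abs_difference` (fractions except the 0-100 fidelity).
#' @export
org_vs_individual_consistency <- function(trial, scores = NULL) {
  stopifnot(inherits(trial, "imp_trial"))
  deliv <- summarize_delivery(trial, by = "organization")
  if (is.null(scores)) scores <- individual_scores(trial)
  org <- organizational_implementation(deliv$dose, deliv$fidelity_mean / 100)
  mean_impl <- mean_or_na(scores$implementation) / 100
  tibble::tibble(
    dose = deliv$dose,
    fidelity_held = deliv$fidelity_mean,
    organizational = org,
    mean_individual_implementation = mean_impl,
    mean_individual_exposure = mean_or_na(scores$exposure) / 100,
    abs_difference = abs(org - mean_impl)
  )
}
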