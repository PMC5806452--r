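#' Cronbach's alpha for a score index
#'
#' Internal-consistency reliability of an index built from scored items,
#' `alpha = k/(k-1) x (1 - sum of item variances / variance of row sums)`.
#' Rows with any missing item are dropped (listwise deletion). Item
#' matrices should hold the 0-100 scored values, not raw categories,
#' since scoring precedes all analysis.
#'
#' @param items a numeric matrix or data frame, one column per item, one
#'   row per respondent; at least 2 items and 2 complete rows.
#' @param name optional index label carried into the result.
#' @return a one-row tibble of class `reliability_result`: `index`,
#'   `n_items`, `n_respondents`, `alpha`.
#' @export
#' @examples
#' m <- cbind(a = c(100, 50, 0, 100), b = c(100, 50, 50, 100))
#' cronbach_alpha(m)$alpha
cronbach_alpha <- function(items, name = "index") {
  items <- as.matrix(items)
  storage.mode(items) <- "double"
  if (ncol(items) < 2) {
    stop("cronbach_alpha needs at least 2 items", call. = FALSE)
  }
  complete <- stats::complete.cases(items)
  items <- items[complete, , drop = FALSE]
  if (nrow(items) < 2) {
    stop("cronbach_alpha needs at least 2 complete respondents", call. = FALSE)
  }
  k <- ncol(items)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) {
    stop("undefined alpha: total score has zero variance", call. = FALSE)
  }
  item_vars <- apply(items, 2, stats::var)
  alpha <- k / (k - 1) * (1 - sum(item_vars) / total_var)
  out <- tibble::tibble(
    index = name, n_items = k, n_respondents = nrow(items), alpha = alpha
  )
  class(out) <- c("reliability_result", class(out))
  out
}

#' One-way ANOVA across strata
#'
#' Standard one-way analysis of variance of a score across groups (trial
#' steps, workplaces), via [stats::aov()], with per-group summaries
#' alongside the F statistic so external tools can run post hoc
#' procedures. Missing values are dropped pairwise with their labels.
#'
#' @param values numeric vector of scores.
#' @param groups group labels (coerced to factor), same length.
#' @param measure,grouping optional labels carried into the result.
#' @return a list of class `group_comparison`: `measure`, `grouping`,
#'   `groups` (tibble of n/mean/sd per group), `df`, `F`, `p`.
#' @export
#' @examples
#' oneway_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$F # 13.5
oneway_anova <- function(values, groups, measure = "score",
                         grouping = "group") {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- as.numeric(values[keep])
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) {
    stop("oneway_anova needs at least 2 groups with data", call. = FALSE)
  }
  if (length(values) < nlevels(groups) + 1) {
    stop("oneway_anova needs more observations than groups", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  per_group <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(value = values, group = groups), group),
    n = dplyr::n(), mean = mean(value), sd = sd_or_na(value),
    .groups = "drop"
  )
  structure(
    list(
      measure = measure, grouping = grouping, groups = per_group,
      df = unname(tab[["Df"]]),
      F = tab[["F value"]][1],
      p = tab[["Pr(>F)"]][1]
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$measure, x$grouping, x$df[1], x$df[2], x$F, x$p))
  print(x$groups, ...)
  invisible(x)
}

#' Compare an implementation measure across strata
#'
#' Convenience wrapper running [oneway_anova()] on a column of an
#' [individual_scores()] table across steps or workplaces.
#'
#' @param scores an [individual_scores()] table.
#' @param measure one of `"implementation"`, `"exposure"`, `"fidelity"`,
#'   `"participation"`, `"responsiveness"`.
#' @param by `"step"` or `"workplace"`.
#' @return a `group_comparison`.
#' @export
compare_groups <- function(scores, measure = "implementation",
                           by = c("step", "workplace")) {
  by <- match.arg(by)
  stopifnot(measure %in% imp_measures)
  col <- switch(by, step = scores$step, workplace = scores$workplace_id)
  oneway_anova(scores[[measure]], col, measure = measure, grouping = by)
}
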