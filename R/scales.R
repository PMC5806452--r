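#' Response-category scales and their 0-100 score maps
#'
#' All raw responses — logbook success-criterion ratings, five-category
#' Likert items, the 0-10 self-rated performance scale, and the 0-10
#' physical-intensity scale — are rescored onto a common 0-100 scale before
#' any aggregation. The maps are:
#'
#' * five-category extent/frequency items: the two most positive categories
#'   score 100, the middle category 50, the two most negative 0;
#' * four-category success-criterion ratings: `not` scores 0, `partly` 50,
#'   `completely` and `more_in_depth` both 100 (the in-depth category is
#'   recorded but carries no extra weight);
#' * self-rated performance 0-10: 0-4 score 0, 5-7 score 50, 8-10 score 100;
#' * physical intensity 0-10: 0-3 score 0, 4-5 score 50, 6-7 score 75,
#'   8-10 score 100.
#'
#' Ratings are stored as canonical lowercase tokens, not display text, so
#' scoring is bit-stable; [likert5_tokens()] and [criterion4_tokens()]
#' expose the canonical vocabularies.
#'
#' @name scales
NULL

.likert5_extent <- c(
  very_large_extent = 100,
  large_extent      = 100,
  somewhat          = 50,
  small_extent      = 0,
  very_small_extent = 0
)

.likert5_frequency <- c(
  always    = 100,
  often     = 100,
  sometimes = 50,
  seldom    = 0,
  never     = 0
)

.criterion4 <- c(
  not           = 0,
  partly        = 50,
  completely    = 100,
  more_in_depth = 100
)

#' @rdname scales
#' @param variant `"extent"` (to a very large extent ... to a very small
#'   extent) or `"frequency"` (always ... never); both score identically.
#' @return For the token helpers, a named numeric vector mapping canonical
#'   tokens to scores.
#' @export
likert5_tokens <- function(variant = c("extent", "frequency")) {
  variant <- match.arg(variant)
  if (variant == "extent") .likert5_extent else .likert5_frequency
}

#' @rdname scales
#' @export
criterion4_tokens <- function() .criterion4

#' Score a five-category Likert rating
#'
#' The two most positive categories map to 100, the middle to 50, and the
#' two most negative to 0. Applies to the extent scale (understanding,
#' contribution, satisfaction, motivation items) and the frequency scale
#' (social-support items) alike.
#'
#' @param rating character vector of canonical tokens (see
#'   [likert5_tokens()]); `NA` passes through as `NA`.
#' @param variant which five-category vocabulary the ratings use.
#' @return numeric vector of scores in \{0, 50, 100\}.
#' @export
#' @examples
#' score_likert5(c("large_extent", "somewhat", "very_small_extent"))
score_likert5 <- function(rating, variant = c("extent", "frequency")) {
  map <- likert5_tokens(match.arg(variant))
  score_categorical(rating, map, scale_name = "likert5")
}

#' Score a four-category success-criterion rating
#'
#' `not` scores 0, `partly` 50, `completely` and `more_in_depth` 100.
#'
#' @param rating character vector of tokens in
#'   `c("not", "partly", "completely", "more_in_depth")`; `NA` passes through.
#' @return numeric vector of scores in \{0, 50, 100\}.
#' @export
#' @examples
#' score_criterion4(c("partly", "more_in_depth", "not"))
score_criterion4 <- function(rating) {
  score_categorical(rating, .criterion4, scale_name = "criterion4")
}

score_categorical <- function(rating, map, scale_name) {
  if (is.factor(rating)) rating <- as.character(rating)
  stopifnot(is.character(rating) || all(is.na(rating)))
  known <- is.na(rating) | rating %in% names(map)
  if (!all(known)) {
    bad <- unique(rating[!known])
    stop(sprintf(
      "unknown %s rating token(s): %s (expected one of: %s)",
      scale_name, paste(sQuote(bad), collapse = ", "),
      paste(names(map), collapse = ", ")
    ), call. = FALSE)
  }
  unname(map[match(rating, names(map))])
}

#' Score the 0-10 self-rated performance scale
#'
#' Banded: 0-4 scores 0, 5-7 scores 50, 8-10 scores 100.
#'
#' @param value integer vector in 0..10; `NA` passes through.
#' @return numeric vector of scores in \{0, 50, 100\}.
#' @export
#' @examples
#' score_performance10(c(7, 0, 10))
score_performance10 <- function(value) {
  check_integer_range(value, 0, 10, "performance")
  ifelse(is.na(value), NA_real_, ifelse(value <= 4, 0, ifelse(value <= 7, 50, 100)))
}

#' Score the 0-10 physical-intensity scale
#'
#' Banded: 0-3 scores 0, 4-5 scores 50, 6-7 scores 75, 8-10 scores 100. The
#' intensity of a physical-training session is rated once per session at
#' group level and enters that session's content score as one additional
#' averaged element.
#'
#' @param value integer vector in 0..10; `NA` passes through.
#' @return numeric vector of scores in \{0, 50, 75, 100\}.
#' @export
#' @examples
#' score_intensity10(c(3, 5, 6, 9))
score_intensity10 <- function(value) {
  check_integer_range(value, 0, 10, "intensity")
  ifelse(is.na(value), NA_real_,
    ifelse(value <= 3, 0, ifelse(value <= 5, 50, ifelse(value <= 7, 75, 100)))
  )
}

check_integer_range <- function(value, lo, hi, what) {
  ok <- is.na(value) | (value >= lo & value <= hi & value == floor(value))
  if (!all(ok)) {
    stop(sprintf(
      "%s rating must be an integer in [%d, %d]; got %s",
      what, lo, hi, paste(unique(value[!ok]), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(value)
}

#' Mean of item scores within an index
#'
#' Indexes (understanding, contribution, satisfaction, social support) are
#' the arithmetic mean of their item scores. Missing items are dropped
#' (available-item mean); an index with no answered items is missing.
#' Missingness propagates, it never raises.
#'
#' @param items numeric vector of item scores on 0-100 (NAs allowed).
#' @return a single score in `[0, 100]`, or `NA` if all items are missing.
#' @export
#' @examples
#' score_index(c(100, 100, 50, 100)) # 87.5
#' score_index(c(NA, NA, 50, NA))    # 50
score_index <- function(items) {
  items <- as.numeric(items)
  if (all(is.na(items))) return(NA_real_)
  mean(items, na.rm = TRUE)
}
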