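#' Published summary tallies from the motivating 12-month trial
#'
#' Small reference tallies reported by the 12-month adolescent type 1
#' diabetes app trial that this package's machinery models. They are inputs
#' for the desk-scale reproduction arithmetic (engagement distribution,
#' satisfaction proportions, feature rankings); no participant-level trial
#' data were ever deposited, so these counts are the only reproducible
#' published numbers.
#'
#' @return `study_engagement_counts()`: named integer vector of intervention
#'   participants per engagement level (of 46).
#' @export
study_engagement_counts <- function() {
  c(very_low = 17L, low = 13L, moderate = 12L, high = 4L)
}

#' @rdname study_engagement_counts
#' @return `study_satisfaction_counts()`: data.frame of numerator/denominator
#'   for the satisfied-or-very-satisfied ratings at 6 and 12 months and the
#'   would-continue-to-use question.
#' @export
study_satisfaction_counts <- function() {
  data.frame(
    measure = c("satisfied_6mo", "satisfied_12mo", "would_continue"),
    numerator = c(30L, 34L, 43L),
    denominator = c(38L, 45L, 45L),
    stringsAsFactors = FALSE
  )
}

#' @rdname study_engagement_counts
#' @return `study_feature_rankings()`: data.frame of most-useful-feature
#'   votes (of 44 respondents).
#' @export
study_feature_rankings <- function() {
  data.frame(
    feature = c("trends", "logbook", "home_page"),
    votes = c(20L, 6L, 5L),
    respondents = 44L,
    stringsAsFactors = FALSE
  )
}

#' Integer-rounded percentage, as printed in trial summary tables
#'
#' @param numerator,denominator counts.
#' @export
printed_pct <- function(numerator, denominator) {
  round(100 * numerator / denominator)
}
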