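#' Questionnaire scoring specifications
#'
#' Builds the scoring specification for one of the three validated
#' instruments. Only ids, scales and scoring arithmetic are represented;
#' item wording is licensed and never embedded.
#'
#' * **SCI** (Self-Care Inventory): 14 items rated 1–5 with a
#'   "not applicable" option (NA allowed); overall score is the mean of the
#'   non-NA items times 10, ranging 10–50.
#' * **DQOLY** (Diabetes Quality of Life for Youth): 22 items over 6
#'   subscales scored on an inverted 0–4 scale, except the single-item
#'   Health Perception subscale on an inverted 1–4 scale. Subscale scores
#'   are sums of inverted items; higher = poorer quality of life. Item
#'   counts per subscale follow from the published subscale ranges
#'   (e.g. Worries About Diabetes: 7 items x 0–4 = 0–28). The default
#'   item-to-subscale assignment is positional; studies with the licensed
#'   instrument should supply their own mapping via `items`.
#' * **DFRQ** (Diabetes Family Responsibility Questionnaire): 17 items on a
#'   1–3 scale over 3 subscales; subscale and total scores are raw sums
#'   (total 17–51).
#'
#' @param name `"SCI"`, `"DQOLY"`, or `"DFRQ"`.
#' @param items optional replacement item table (data.frame with columns
#'   item, subscale, min, max, invert) for instruments whose published
#'   item-to-subscale mapping the user holds.
#' @return object of class `"instrument_spec"`.
#' @export
instrument_spec <- function(name = c("SCI", "DQOLY", "DFRQ"), items = NULL) {
  name <- match.arg(name)
  if (is.null(items)) {
    items <- switch(name,
      SCI = data.frame(
        item = sprintf("SCI%02d", 1:14), subscale = "overall",
        min = 1, max = 5, invert = FALSE, stringsAsFactors = FALSE
      ),
      DQOLY = {
        sub <- c(rep("impact_symptoms", 3), rep("impact_treatment", 3),
                 rep("impact_activities", 5), rep("parental_issues", 3),
                 rep("worries", 7), "health_perception")
        data.frame(
          item = sprintf("DQOLY%02d", 1:22), subscale = sub,
          min = ifelse(sub == "health_perception", 1, 0),
          max = 4, invert = TRUE, stringsAsFactors = FALSE
        )
      },
      DFRQ = data.frame(
        item = sprintf("DFRQ%02d", 1:17),
        subscale = c(rep("general_health", 7), rep("social_presentation", 4),
                     rep("regimen", 6)),
        min = 1, max = 3, invert = FALSE, stringsAsFactors = FALSE
      )
    )
  }
  needed <- c("item", "subscale", "min", "max", "invert")
  if (!is.data.frame(items) || !all(needed %in% names(items))) {
    abort_glucolog("items must carry columns item, subscale, min, max, invert",
                   "glucolog_parameter_error")
  }
  structure(list(name = name, items = items, allows_na = name == "SCI"),
            class = "instrument_spec")
}

#' Expected score ranges per instrument (from the published scale ranges)
#' @param spec an [instrument_spec()].
#' @return named list of `c(min, max)` per reported score.
#' @export
instrument_score_ranges <- function(spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  switch(spec$name,
    SCI = list(overall = c(10, 50)),
    DQOLY = list(impact_symptoms = c(0, 12), impact_treatment = c(0, 12),
                 impact_activities = c(0, 20), parental_issues = c(0, 12),
                 worries = c(0, 28), health_perception = c(1, 4)),
    DFRQ = list(general_health = c(7, 21), social_presentation = c(4, 12),
                regimen = c(6, 18), total = c(17, 51))
  )
}

#' Score a questionnaire response set
#'
#' Validates each response against its item scale (NA permitted only where
#' the instrument allows a "not applicable" option), applies reverse coding
#' where the instrument is inverted (`score = min + max - raw`), and
#' computes the instrument's reported scores.
#'
#' @param responses named numeric vector (names = item ids) or data.frame
#'   with columns `item_id`, `value`.
#' @param spec an [instrument_spec()].
#' @return named list of scores (subscales, plus `overall`/`total` where
#'   the instrument defines one).
#' @export
score_instrument <- function(responses, spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  if (is.data.frame(responses)) {
    responses <- stats::setNames(responses$value, responses$item_id)
  }
  items <- spec$items
  missing_items <- setdiff(items$item, names(responses))
  if (length(missing_items)) {
    abort_glucolog(sprintf("missing responses for item(s): %s",
                           paste(missing_items, collapse = ", ")),
                   "glucolog_validation_error")
  }
  x <- as.numeric(responses[items$item])
  if (any(is.na(x)) && !spec$allows_na) {
    abort_glucolog(sprintf("%s does not allow not-applicable responses",
                           spec$name),
                   "glucolog_validation_error")
  }
  ok <- is.na(x) | (x >= items$min & x <= items$max & x == round(x))
  if (!all(ok)) {
    abort_glucolog(sprintf("out-of-scale response for item(s): %s",
                           paste(items$item[!ok], collapse = ", ")),
                   "glucolog_validation_error")
  }
  scored <- ifelse(items$invert, items$min + items$max - x, x)
  if (spec$name == "SCI") {
    if (all(is.na(scored))) {
      abort_glucolog("SCI score undefined: all items not applicable",
                     "glucolog_validation_error")
    }
    return(list(overall = mean(scored, na.rm = TRUE) * 10))
  }
  out <- lapply(split(scored, items$subscale), sum)
  out <- out[unique(items$subscale)]
  if (spec$name == "DFRQ") out$total <- sum(scored)
  out
}
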