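#' Published per-patient predictions and clinical tables
#'
#' The package ships the published per-patient results of the two cohorts
#' (19 men, 30 women) as plain-CSV fixtures: actual outcome label (+1
#' favorable, -1 non-favorable), out-of-fold SVM decision value, and the
#' individual clinical characteristics. They let the whole evaluation layer
#' be exercised against known numbers without any image data.
#'
#' In the female cohort, patient F19's label is printed inconsistently in
#' the source tables: the prediction table says favorable while her
#' clinical record (ILAE class 3, the scale's non-favorable range) says
#' non-favorable. `actual` carries the clinically consistent label
#' (non-favorable); the printed prediction-table value is preserved in
#' `actual_printed`.
#'
#' @param cohort `"male"` or `"female"`.
#' @return `published_predictions`: data frame with `id`, `actual` (and for
#'   the female cohort `actual_printed`), `decision`.
#'   `published_clinical`: data frame with `id`, `label`, ages, febrile
#'   history, seizure frequency, follow-up months and ILAE class.
#' @examples
#' p <- published_predictions("male")
#' confusion_from_decisions(p$actual, p$decision)
#' @export
published_predictions <- function(cohort = c("male", "female")) {
  cohort <- match.arg(cohort)
  f <- system.file("extdata", paste0(cohort, "_predictions.csv"),
                   package = "wmpredict", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' @rdname published_predictions
#' @export
published_clinical <- function(cohort = c("male", "female")) {
  cohort <- match.arg(cohort)
  f <- system.file("extdata", paste0(cohort, "_clinical.csv"),
                   package = "wmpredict", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Febrile-seizure 2x2 contingency table of a cohort
#'
#' Cross-tabulates childhood febrile-seizure history against outcome group
#' from the shipped clinical table: rows febrile yes/no, columns
#' favorable/non-favorable. (Male cohort: 4/11 FO vs 4/8 Non-FO had febrile
#' seizures.)
#'
#' @inheritParams published_predictions
#' @return 2x2 integer matrix with dimnames.
#' @export
febrile_table <- function(cohort = c("male", "female")) {
  cl <- published_clinical(cohort)
  m <- matrix(c(sum(cl$febrile == 1 & cl$label == 1),
                sum(cl$febrile == 1 & cl$label == -1),
                sum(cl$febrile == 0 & cl$label == 1),
                sum(cl$febrile == 0 & cl$label == -1)),
              2, 2, byrow = TRUE,
              dimnames = list(febrile = c("yes", "no"),
                              outcome = c("FO", "NonFO")))
  m
}
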