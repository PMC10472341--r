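#' Recode raw questionnaire answers to smoking status
#'
#' Maps the verbatim answers of the three supported survey dialects onto the
#' common three-category smoking status: \code{"S"} (current smoker),
#' \code{"ExS"} (ex-smoker), \code{"NS"} (never smoker). Answers that do not
#' match the dialect's schema map to \code{"unclassifiable"}; callers drop
#' those rows before estimation and report the count.
#'
#' Dialects:
#' \describe{
#'   \item{ENSE}{Single question. Daily or non-daily current smoking is
#'     \code{S}; "smoked before" is \code{ExS}; never smoked regularly is
#'     \code{NS}.}
#'   \item{ESCA}{Two questions. Current daily or occasional smoking (Q1) is
#'     \code{S}; current non-smokers are routed to Q2, where "Never smoked
#'     at all" is \code{NS} and every past-smoking history (daily or less
#'     than daily, any duration) collapses to \code{ExS}.}
#'   \item{SICRI}{Two questions. "No, never" at Q1 is \code{NS}; ever-smokers
#'     are routed to Q2, where any current smoking (daily, at least weekly,
#'     or sporadic less than weekly) is \code{S} and "Never" (i.e. quit) is
#'     \code{ExS}.}
#'   \item{generic}{\code{q1} already holds \code{S}/\code{ExS}/\code{NS}.}
#' }
#'
#' @param q1 Character vector of first-question answers (or precomputed
#'   status for the generic dialect).
#' @param q2 Character vector of second-question answers; \code{NA} where
#'   not routed. Ignored by ENSE and generic.
#' @param dialect One of \code{"ENSE"}, \code{"ESCA"}, \code{"SICRI"},
#'   \code{"generic"}.
#' @return Character vector over \code{"S"}, \code{"ExS"}, \code{"NS"},
#'   \code{"unclassifiable"}, with attribute \code{n_unclassifiable}.
#' @export
recode_status <- function(q1, q2 = NULL, dialect = c("generic", "ENSE", "ESCA", "SICRI")) {
  dialect <- match.arg(dialect)
  if (is.null(q2)) q2 <- rep(NA_character_, length(q1))
  stopifnot(length(q1) == length(q2))
  out <- rep("unclassifiable", length(q1))

  if (dialect == "generic") {
    ok <- q1 %in% c("S", "ExS", "NS")
    out[ok] <- q1[ok]
  } else if (dialect == "ENSE") {
    out[q1 %in% c("Yes, I smoke daily",
                  "Yes, I do smoke, but not daily")] <- "S"
    out[q1 == "I do not currently smoke, but I have smoked before"] <- "ExS"
    out[q1 == "I do not smoke, and I have never smoked on a regular basis"] <- "NS"
  } else if (dialect == "ESCA") {
    out[q1 %in% c("You currently smoke every day",
                  "You currently smoke occasionally (less than once a day)")] <- "S"
    routed <- q1 == "You currently do not smoke at all"
    out[routed & q2 == "Never smoked at all"] <- "NS"
    out[routed & q2 %in% c(
      "Had smoked less than once a day for 6 months or more",
      "Had smoked less than once a day for less than 6 months",
      "Has smoked daily 6 months or more",
      "Had smoke daily for less than 6 months")] <- "ExS"
  } else if (dialect == "SICRI") {
    out[q1 == "No, never"] <- "NS"
    routed <- q1 %in% c("Yes, daily", "Yes, occasionally")
    out[routed & q2 %in% c("Daily",
                           "Occasionally, at least once a week",
                           "Sporadically, less than once a week")] <- "S"
    out[routed & q2 == "Never"] <- "ExS"
  }
  attr(out, "n_unclassifiable") <- sum(out == "unclassifiable")
  out
}

#' Read survey microdata from delimited text
#'
#' Expects a header row with \code{respondent_id}, \code{area_id},
#' \code{weight}, and either a \code{status} column (generic dialect) or
#' raw-answer columns \code{q1}/\code{q2} to be recoded via
#' [recode_status()]. Unclassifiable rows are dropped with a message; the
#' drop count is kept as an attribute so cleaning is auditable.
#'
#' @param path CSV file path.
#' @param dialect Passed to [recode_status()].
#' @param survey_id Label stored on the result.
#' @return A \code{survey_microdata} data frame; attributes
#'   \code{n_dropped}, \code{survey_id}.
#' @export
read_survey_microdata <- function(path, dialect = "generic", survey_id = "national") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "generic" && "status" %in% names(raw)) {
    status <- recode_status(raw$status, dialect = "generic")
  } else {
    if (!"q1" %in% names(raw)) stop("expected a 'status' or 'q1' column")
    status <- recode_status(raw$q1, raw$q2, dialect = dialect)
  }
  keep <- status != "unclassifiable"
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " unclassifiable record(s) dropped during cleaning")
  }
  micro <- data.frame(respondent_id = raw$respondent_id[keep],
                      area_id = raw$area_id[keep],
                      weight = raw$weight[keep],
                      status = as.character(status)[keep],
                      stringsAsFactors = FALSE)
  if (any(micro$weight <= 0)) stop("sampling weights must be positive")
  class(micro) <- c("survey_microdata", "data.frame")
  attr(micro, "survey_id") <- survey_id
  attr(micro, "n_dropped") <- n_dropped
  micro
}
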