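#' Design-based direct estimation of area prevalences
#'
#' The direct estimator is the survey-weighted ratio (Hajek) estimator
#' \deqn{\hat p = \sum_i W_i X_i / \sum_i W_i} over the respondents of one
#' area, where \eqn{X_i} indicates membership of the status category and
#' \eqn{W_i} is the sampling weight.
#'
#' @param micro A \code{survey_microdata} data frame.
#' @param area_id Single area id.
#' @param category One of \code{"S"}, \code{"ExS"}, \code{"NS"}.
#' @return The prevalence in \[0, 1\], or \code{NA} (no sample) when the
#'   area has no respondents.
#' @export
weighted_prevalence <- function(micro, area_id, category) {
  i <- micro$area_id == area_id
  if (!any(i)) return(NA_real_)
  w <- micro$weight[i]
  x <- as.numeric(micro$status[i] == category)
  sum(w * x) / sum(w)
}

#' Taylor-linearized variance of the direct estimator
#'
#' Single-stage with-replacement linearization of the ratio estimator:
#' \deqn{v(\hat p) = \frac{n}{n-1} \frac{\sum_i W_i^2 (X_i - \hat p)^2}
#'   {(\sum_i W_i)^2}.}
#' With equal weights this reduces exactly to \eqn{p(1-p)/(n-1)}. Stratum
#' and cluster structure is deliberately ignored: the companion synthetic
#' sampler is single-stage.
#'
#' @inheritParams weighted_prevalence
#' @return The variance, or \code{NA} when the area has fewer than two
#'   respondents.
#' @export
taylor_variance <- function(micro, area_id, category) {
  i <- micro$area_id == area_id
  n <- sum(i)
  if (n < 2) return(NA_real_)
  w <- micro$weight[i]
  x <- as.numeric(micro$status[i] == category)
  p <- sum(w * x) / sum(w)
  n / (n - 1) * sum(w^2 * (x - p)^2) / sum(w)^2
}

#' Direct estimates for every area and category
#'
#' Computes the weighted prevalence, Taylor-linearized standard error and
#' coefficient of variation (CV, percent) for each area x category cell.
#' Areas present in \code{frame} but absent from the microdata are reported
#' with \code{no_sample = TRUE} rather than silently dropped: these are the
#' cells where a direct estimate does not exist. A CV is flagged undefined
#' (\code{cv_defined = FALSE}) when the prevalence is 0.
#'
#' @param micro A \code{survey_microdata} data frame.
#' @param frame Optional \code{area_frame}; when supplied, every frame area
#'   appears in the output and region/sex/age labels are attached.
#' @return Data frame of class \code{"direct_estimates"} with columns
#'   \code{area_id}, (\code{region}, \code{sex}, \code{age_group},)
#'   \code{category}, \code{prevalence}, \code{se}, \code{cv}, \code{n},
#'   \code{no_sample}, \code{cv_defined}. Within each sampled area the three
#'   prevalences sum to 1.
#' @export
direct_estimates <- function(micro, frame = NULL) {
  ids <- if (is.null(frame)) sort(unique(micro$area_id)) else frame$area_id
  categories <- c("S", "ExS", "NS")
  # split once; avoids rescanning the microdata per area
  idx <- split(seq_len(nrow(micro)), factor(micro$area_id, levels = ids))
  out <- vector("list", length(ids))
  for (a in seq_along(ids)) {
    i <- idx[[a]]
    n <- length(i)
    if (n == 0) {
      out[[a]] <- data.frame(area_id = ids[a], category = categories,
                             prevalence = NA_real_, se = NA_real_, cv = NA_real_,
                             n = 0L, no_sample = TRUE, cv_defined = FALSE,
                             stringsAsFactors = FALSE)
      next
    }
    w <- micro$weight[i]
    sw <- sum(w)
    p <- se <- cv <- numeric(3)
    for (k in 1:3) {
      x <- as.numeric(micro$status[i] == categories[k])
      p[k] <- sum(w * x) / sw
      v <- if (n >= 2) n / (n - 1) * sum(w^2 * (x - p[k])^2) / sw^2 else NA_real_
      se[k] <- sqrt(v)
      cv[k] <- if (!is.na(v) && p[k] > 0) 100 * se[k] / p[k] else NA_real_
    }
    out[[a]] <- data.frame(area_id = ids[a], category = categories,
                           prevalence = p, se = se, cv = cv, n = n,
                           no_sample = FALSE,
                           cv_defined = !is.na(cv),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  if (!is.null(frame)) {
    res <- merge(frame[, c("area_id", "region", "sex", "age_group")], res,
                 by = "area_id", sort = TRUE)
    res <- res[order(res$area_id, match(res$category, categories)), ]
    row.names(res) <- NULL
  }
  class(res) <- c("direct_estimates", "data.frame")
  attr(res, "survey_id") <- attr(micro, "survey_id")
  res
}
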