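#' Absolute-agreement intraclass correlation between two estimation methods
#'
#' One-way random-effects, single-measure, absolute-agreement ICC between
#' two methods (here: direct estimator and small-area model) observed on the
#' same D areas. With \eqn{m = 2} methods the mean squares are
#' \deqn{WMS = \sum_d \sum_m (p_{dm} - \bar p_{d.})^2 / D, \qquad
#'       BMS = 2 \sum_d (\bar p_{d.} - \bar p_{..})^2 / (D - 1),}
#' and \eqn{ICC = (BMS - WMS)/(BMS + WMS)}. An ICC of 1 means perfect
#' concordance; values at or above 0.60 are deemed acceptable agreement
#' (Cicchetti's rule of thumb).
#'
#' @param direct,model Numeric vectors in \[0, 1\]: the two methods'
#'   prevalences for the same areas, in the same order.
#' @return Object of class \code{"icc_result"}: \code{D}, \code{WMS},
#'   \code{BMS}, \code{icc}, \code{acceptable} (\code{icc >= 0.60}), and
#'   after [icc_ci()] the interval \code{ci_lower}, \code{ci_upper}.
#' @export
icc <- function(direct, model) {
  stopifnot(length(direct) == length(model))
  keep <- !is.na(direct) & !is.na(model)
  direct <- direct[keep]; model <- model[keep]
  D <- length(direct)
  if (D < 3) stop("need at least 3 areas with both estimates")
  if (any(direct < 0 | direct > 1 | model < 0 | model > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  p <- cbind(direct, model)
  pd <- rowMeans(p)
  pg <- mean(pd)
  WMS <- sum((p - pd)^2) / D
  BMS <- 2 * sum((pd - pg)^2) / (D - 1)
  val <- (BMS - WMS) / (BMS + WMS)
  structure(list(D = D, WMS = WMS, BMS = BMS, icc = val,
                 acceptable = val >= 0.60,
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 degenerate = FALSE),
            class = "icc_result")
}

#' F-based confidence interval for the ICC
#'
#' Exact one-way random-effects interval for the two-method ICC. With
#' \eqn{F_l} and \eqn{F_u} the upper \eqn{(1+level)/2} percentiles of the
#' \eqn{F_{D-1,D}} and \eqn{F_{D,D-1}} distributions,
#' \eqn{F_L = BMS/(WMS\,F_l)} and \eqn{F_U = BMS\,F_u/WMS}, the interval is
#' \deqn{\left(\frac{F_L - 1}{F_L + 1}, \frac{F_U - 1}{F_U + 1}\right).}
#' When \eqn{WMS = 0} (the methods agree exactly) the interval is
#' degenerate and reported as (-1, 1) with a flag; -1 is the attainable
#' lower bound of the two-method ICC.
#'
#' @param result An [icc()] result.
#' @param level Confidence level (default 0.95).
#' @return The \code{icc_result} with \code{ci_lower}, \code{ci_upper} (and
#'   \code{degenerate}) filled in.
#' @export
icc_ci <- function(result, level = 0.95) {
  stopifnot(inherits(result, "icc_result"))
  D <- result$D
  if (result$WMS == 0) {
    result$ci_lower <- -1
    result$ci_upper <- 1
    result$degenerate <- TRUE
    return(result)
  }
  alpha <- (1 - level) / 2
  Fl <- stats::qf(1 - alpha, D - 1, D)
  Fu <- stats::qf(1 - alpha, D, D - 1)
  FL <- result$BMS / (result$WMS * Fl)
  FU <- result$BMS * Fu / result$WMS
  result$ci_lower <- (FL - 1) / (FL + 1)
  result$ci_upper <- (FU - 1) / (FU + 1)
  result
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f", x$icc))
  if (!is.na(x$ci_lower)) cat(sprintf(" (95%% CI: %.3f-%.3f)", x$ci_lower, x$ci_upper))
  cat(sprintf(" over %d areas; %s\n", x$D,
              if (x$acceptable) "acceptable (>= 0.60)" else "below 0.60"))
  invisible(x)
}

#' Wald confidence interval for the difference between methods
#'
#' For one area and category, the difference is oriented model minus direct.
#' Under independence of the two surveys the variance of the difference is
#' the sum of the variances, so \eqn{SE_{diff} = \sqrt{SE_1^2 + SE_2^2}} and
#' the 95\% interval is difference ± 1.96 SE. The 1.96 multiplier is fixed:
#' the protocol is defined at the 95\% level.
#'
#' @param p_direct,p_model Prevalences of the two methods.
#' @param se_direct,se_model Their standard errors.
#' @return Data frame with \code{difference}, \code{se_diff},
#'   \code{ci_lower}, \code{ci_upper}, \code{includes_zero}. Vectorized.
#' @export
difference_ci <- function(p_direct, p_model, se_direct, se_model) {
  d <- p_model - p_direct
  se <- sqrt(se_direct^2 + se_model^2)
  lo <- d - 1.96 * se
  hi <- d + 1.96 * se
  data.frame(difference = d, se_diff = se, ci_lower = lo, ci_upper = hi,
             includes_zero = lo <= 0 & 0 <= hi)
}

#' Zero-inclusion summary of difference intervals
#'
#' Counts, per category (and optionally per group such as region), how many
#' 95\% CIs of the between-method differences include zero, and reports the
#' overall percentage. Intervals that include zero indicate no significant
#' difference between the model and the direct estimate for that area.
#' The overall percentage is truncated (not rounded) to one decimal, the
#' printing convention used in the surveillance reports this protocol
#' mirrors.
#'
#' @param diffs Data frame with columns \code{category},
#'   \code{includes_zero}, and optionally \code{group}.
#' @return List with \code{by_category} (counts), \code{n_total},
#'   \code{n_zero}, \code{overall_pct}.
#' @export
zero_inclusion_summary <- function(diffs) {
  stopifnot(nrow(diffs) >= 1)
  by <- if ("group" %in% names(diffs)) {
    stats::aggregate(includes_zero ~ category + group, diffs,
                     FUN = function(z) c(n_zero = sum(z), n = length(z)))
  } else {
    stats::aggregate(includes_zero ~ category, diffs,
                     FUN = function(z) c(n_zero = sum(z), n = length(z)))
  }
  by_category <- data.frame(by[setdiff(names(by), "includes_zero")],
                            n_zero = by$includes_zero[, "n_zero"],
                            n = by$includes_zero[, "n"])
  n_zero <- sum(diffs$includes_zero)
  n_total <- nrow(diffs)
  list(by_category = by_category,
       n_zero = n_zero, n_total = n_total,
       overall_pct = trunc(1000 * n_zero / n_total) / 10)
}

#' Coefficient-of-variation acceptability screen
#'
#' Flags every estimate whose CV is strictly below the threshold (default
#' 30\%, the National Center for Health Statistics reliability criterion) as
#' acceptable, and summarizes prevalences and CVs (median, IQR, range) per
#' method and category. Individual cells can be excluded from the summaries
#' (e.g. a near-empty cell whose huge CV would distort them); exclusions are
#' recorded, never silent.
#'
#' @param direct_tab A [direct_estimates()] table.
#' @param sae_tab A [sae_estimates()] table.
#' @param threshold CV acceptability threshold in percent (strict \code{<}).
#' @param exclude Optional data frame with columns \code{area_id},
#'   \code{category}, \code{method} naming cells to drop from the summaries.
#' @return List with \code{flags} (method, area_id, category, cv,
#'   acceptable), \code{summary} (per method x category medians, IQRs,
#'   ranges of prevalence and CV), \code{excluded}.
#' @export
cv_screen <- function(direct_tab, sae_tab, threshold = 30, exclude = NULL) {
  take <- function(tab, method) {
    data.frame(method = method, area_id = tab$area_id, category = tab$category,
               prevalence = tab$prevalence, cv = tab$cv,
               stringsAsFactors = FALSE)
  }
  flags <- rbind(take(direct_tab, "direct"), take(sae_tab, "sae"))
  flags$acceptable <- !is.na(flags$cv) & flags$cv < threshold
  keep <- rep(TRUE, nrow(flags))
  excluded <- flags[0, ]
  if (!is.null(exclude) && nrow(exclude)) {
    key <- paste(flags$method, flags$area_id, flags$category)
    drop_key <- paste(exclude$method, exclude$area_id, exclude$category)
    keep <- !(key %in% drop_key)
    excluded <- flags[!keep, ]
  }
  used <- flags[keep & !is.na(flags$cv), ]
  summ <- do.call(rbind, lapply(split(used, list(used$method, used$category)),
    function(g) {
      if (!nrow(g)) return(NULL)
      data.frame(method = g$method[1], category = g$category[1],
                 n = nrow(g),
                 prev_median = stats::median(g$prevalence),
                 prev_iqr = stats::IQR(g$prevalence),
                 prev_min = min(g$prevalence), prev_max = max(g$prevalence),
                 cv_median = stats::median(g$cv),
                 cv_iqr = stats::IQR(g$cv),
                 cv_min = min(g$cv), cv_max = max(g$cv),
                 n_acceptable = sum(g$acceptable),
                 stringsAsFactors = FALSE)
    }))
  row.names(summ) <- NULL
  list(flags = flags, summary = summ, excluded = excluded,
       threshold = threshold)
}

#' Full concordance and precision report
#'
#' Runs the external-validation protocol comparing a model-based estimates
#' table against a direct-estimates table from an independent survey:
#' per-category absolute-agreement ICC with 95\% CI and the >= 0.60
#' acceptability rule; per-area Wald 95\% CIs of the model-minus-direct
#' differences with zero-inclusion counting; and CV screening against the
#' 30\% threshold. Area x category cells where the direct estimate does not
#' exist (no sample) or lacks an SE are excluded pairwise and logged.
#'
#' @param direct_tab A [direct_estimates()] table (the reference survey).
#' @param sae_tab A [sae_estimates()] table (the model estimates).
#' @param cv_threshold CV acceptability threshold, percent.
#' @param cv_exclude Passed to [cv_screen()].
#' @return Object of class \code{"validation_report"}: \code{icc} (list of
#'   \code{icc_result} per category), \code{differences},
#'   \code{zero_inclusion}, \code{cv}, \code{excluded},
#'   \code{all_icc_acceptable}.
#' @export
concordance_report <- function(direct_tab, sae_tab, cv_threshold = 30,
                               cv_exclude = NULL) {
  keys <- c("area_id", "category")
  m <- merge(direct_tab[, c(keys, "prevalence", "se", "no_sample")],
             sae_tab[, c(keys, intersect("region", names(sae_tab)),
                         "prevalence", "se")],
             by = keys, suffixes = c("_direct", "_sae"))
  usable <- !m$no_sample & !is.na(m$se_direct) & !is.na(m$se_sae)
  excluded <- m[!usable, keys]
  m <- m[usable, ]
  if (length(unique(m$area_id)) < 3) stop("fewer than 3 areas shared by both methods")

  categories <- c("S", "ExS", "NS")
  icc_list <- lapply(categories, function(k) {
    g <- m[m$category == k, ]
    icc_ci(icc(g$prevalence_direct, g$prevalence_sae))
  })
  names(icc_list) <- categories

  diffs <- cbind(m[keys],
                 if ("region" %in% names(m)) data.frame(group = m$region),
                 difference_ci(m$prevalence_direct, m$prevalence_sae,
                               m$se_direct, m$se_sae))
  zi <- zero_inclusion_summary(diffs)
  cv <- cv_screen(direct_tab, sae_tab, threshold = cv_threshold,
                  exclude = cv_exclude)

  structure(list(icc = icc_list, differences = diffs, zero_inclusion = zi,
                 cv = cv, excluded = excluded,
                 all_icc_acceptable = all(vapply(icc_list, `[[`, TRUE, "acceptable"))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("External validation: model-based vs direct estimates\n\n")
  for (k in names(x$icc)) {
    r <- x$icc[[k]]
    cat(sprintf("  ICC %-4s %.3f (95%% CI: %.3f-%.3f)%s\n", k, r$icc,
                r$ci_lower, r$ci_upper,
                if (r$acceptable) "" else "  [below 0.60]"))
  }
  zi <- x$zero_inclusion
  cat(sprintf("\n  %d of %d difference CIs include zero (%.1f%%)\n",
              zi$n_zero, zi$n_total, zi$overall_pct))
  flg <- x$cv$flags
  ok <- flg[flg$method == "sae" & !is.na(flg$cv), "acceptable"]
  cat(sprintf("  model CVs < %g%%: %d of %d\n", x$cv$threshold, sum(ok), length(ok)))
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded cells (no direct estimate): %d\n", nrow(x$excluded)))
  }
  cat(sprintf("\n  verdict: %s\n",
              if (x$all_icc_acceptable) "all ICCs acceptable (>= 0.60)"
              else "concordance NOT acceptable for at least one category"))
  invisible(x)
}
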