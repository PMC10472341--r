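#' Generate the synthetic area frame
#'
#' Draws, for every area (region x sex x age group), a population size,
#' standardized continuous covariates, category random effects
#' \eqn{u_{dk} \sim N(0, \phi_k)}, and the implied true prevalences of the
#' three smoking-status categories through the multinomial logit inverse
#' link with "never smoker" as reference.
#'
#' Randomness is seeded from \code{cfg$seed}; the same configuration always
#' reproduces the same frame.
#'
#' @param cfg A [sim_config()].
#' @return A data frame of class \code{"area_frame"} with one row per area:
#'   \code{area_id}, \code{region}, \code{sex}, \code{age_group},
#'   \code{population_size}, covariate columns \code{x1_*} (smoker logit) and
#'   \code{x2_*} (ex-smoker logit), true random effects \code{true_u1},
#'   \code{true_u2}, and true prevalences \code{true_p1}, \code{true_p2},
#'   \code{true_p3} (summing to 1).
#' @export
generate_area_frame <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  D <- n_areas(cfg)
  regions <- sprintf("R%02d", seq_len(cfg$n_regions))
  age_groups <- c("15-34", "35-54", "55-64", "65-74", ">=75")
  grid <- expand.grid(age_group = age_groups, sex = c("male", "female"),
                      region = regions, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("region", "sex", "age_group")]

  pop <- pmax(100L, as.integer(round(stats::rlnorm(D, cfg$pop_meanlog, cfg$pop_sdlog))))

  standardize <- function(z) if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z
  m <- cfg$n_covariates
  X1 <- cbind(1, if (m > 0) sapply(seq_len(m), function(j) standardize(stats::rnorm(D))) else NULL)
  X2 <- cbind(1, if (m > 0) sapply(seq_len(m), function(j) standardize(stats::rnorm(D))) else NULL)

  u1 <- stats::rnorm(D, 0, sqrt(cfg$phi[1]))
  u2 <- stats::rnorm(D, 0, sqrt(cfg$phi[2]))
  eta1 <- drop(X1 %*% cfg$beta1) + u1
  eta2 <- drop(X2 %*% cfg$beta2) + u2
  if (any(!is.finite(eta1)) || any(!is.finite(eta2))) {
    bad <- which(!is.finite(eta1) | !is.finite(eta2))[1]
    stop("non-finite linear predictor for area ", bad)
  }
  p <- inv_mlogit(eta1, eta2)

  frame <- data.frame(
    area_id = seq_len(D), grid, population_size = pop,
    stringsAsFactors = FALSE
  )
  if (m > 0) {
    colnames(X1) <- c("(Intercept)", paste0("x1_", seq_len(m)))
    colnames(X2) <- c("(Intercept)", paste0("x2_", seq_len(m)))
    frame <- cbind(frame, X1[, -1, drop = FALSE], X2[, -1, drop = FALSE])
  }
  frame$true_u1 <- u1
  frame$true_u2 <- u2
  frame$true_p1 <- p[, 1]
  frame$true_p2 <- p[, 2]
  frame$true_p3 <- p[, 3]
  class(frame) <- c("area_frame", "data.frame")
  attr(frame, "config") <- cfg
  frame
}

#' Inverse multinomial-logit link
#'
#' Maps the two non-reference linear predictors to the three category
#' probabilities \eqn{p_k = e^{\eta_k}/(1 + e^{\eta_1} + e^{\eta_2})},
#' \eqn{p_3 = 1 - p_1 - p_2}.
#'
#' @param eta1,eta2 Numeric vectors of linear predictors.
#' @return A matrix with columns \code{p1}, \code{p2}, \code{p3}; rows sum
#'   to 1.
#' @export
inv_mlogit <- function(eta1, eta2) {
  # shift by the rowwise max (including the reference's implicit 0) so the
  # exponentials cannot overflow
  mx <- pmax(0, eta1, eta2)
  e1 <- exp(eta1 - mx)
  e2 <- exp(eta2 - mx)
  e3 <- exp(-mx)
  den <- e1 + e2 + e3
  cbind(p1 = e1 / den, p2 = e2 / den, p3 = 1 - e1 / den - e2 / den)
}

#' Design matrices of an area frame
#'
#' @param frame An \code{area_frame}.
#' @return List with matrices \code{X1}, \code{X2} (intercept first).
#' @export
area_design <- function(frame) {
  x1_cols <- grep("^x1_", names(frame), value = TRUE)
  x2_cols <- grep("^x2_", names(frame), value = TRUE)
  D <- nrow(frame)
  list(
    X1 = cbind("(Intercept)" = rep(1, D), as.matrix(frame[, x1_cols, drop = FALSE])),
    X2 = cbind("(Intercept)" = rep(1, D), as.matrix(frame[, x2_cols, drop = FALSE]))
  )
}

#' Generate synthetic survey microdata
#'
#' Draws, for each area, a multinomial sample of smoking statuses from the
#' frame's true prevalences, and attaches sampling weights. The base weight
#' is \code{population_size / n_d} (equal allocation); when
#' \code{weight_dispersion > 0} it is multiplied by lognormal noise with unit
#' mean, which keeps weights positive and their area totals correct in
#' expectation. Areas with a planned sample of zero contribute no rows,
#' emulating survey cells in which no one was interviewed.
#'
#' The random stream is seeded from \code{cfg$seed} offset by the survey
#' (national: +1, regional: +2) so the two surveys and the frame are
#' mutually independent yet jointly reproducible.
#'
#' @param frame An [generate_area_frame()] result.
#' @param cfg The same [sim_config()].
#' @param survey_id \code{"national"} or \code{"regional"}.
#' @return A data frame of class \code{"survey_microdata"} with columns
#'   \code{respondent_id}, \code{area_id}, \code{weight}, \code{status}
#'   (values \code{"S"}, \code{"ExS"}, \code{"NS"}); attribute
#'   \code{survey_id}.
#' @export
generate_survey <- function(frame, cfg, survey_id = c("national", "regional")) {
  survey_id <- match.arg(survey_id)
  validate_sim_config(cfg)
  D <- nrow(frame)
  n_d <- rep(cfg[[paste0(survey_id, "_sample_per_area")]], length.out = D)
  if (any(n_d > frame$population_size)) {
    stop("sample size exceeds population size in area ",
         which(n_d > frame$population_size)[1])
  }
  set.seed(cfg$seed + switch(survey_id, national = 1L, regional = 2L))

  status_levels <- c("S", "ExS", "NS")
  rows <- vector("list", D)
  for (d in seq_len(D)) {
    if (n_d[d] == 0) next
    counts <- drop(stats::rmultinom(1, n_d[d],
                                    c(frame$true_p1[d], frame$true_p2[d], frame$true_p3[d])))
    status <- rep(status_levels, counts)
    w <- rep(frame$population_size[d] / n_d[d], n_d[d])
    if (cfg$weight_dispersion > 0) {
      s <- cfg$weight_dispersion
      w <- w * stats::rlnorm(n_d[d], meanlog = -s^2 / 2, sdlog = s)
    }
    rows[[d]] <- data.frame(area_id = frame$area_id[d], weight = w,
                            status = status, stringsAsFactors = FALSE)
  }
  micro <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(micro)) micro <- data.frame(area_id = integer(), weight = numeric(),
                                          status = character())
  micro <- data.frame(respondent_id = seq_len(nrow(micro)), micro,
                      row.names = NULL, stringsAsFactors = FALSE)
  class(micro) <- c("survey_microdata", "data.frame")
  attr(micro, "survey_id") <- survey_id
  micro
}
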