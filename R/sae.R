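#' Aggregate survey microdata to area-level counts
#'
#' The small-area model consumes unweighted counts of the three smoking
#' statuses per area together with the frame's auxiliary covariates. Areas
#' absent from the microdata get zero counts and are flagged; they are kept
#' because the model can still predict them through its fixed effects.
#'
#' @param micro A \code{survey_microdata} data frame.
#' @param frame The \code{area_frame} the survey was drawn from.
#' @return An object of class \code{"area_counts"}: list with matrix
#'   \code{y} (D x 3, columns S/ExS/NS), vector \code{n}, design matrices
#'   \code{X1}, \code{X2}, \code{area_id} and the frame labels.
#' @export
aggregate_to_areas <- function(micro, frame) {
  if (!all(micro$area_id %in% frame$area_id)) {
    bad <- setdiff(unique(micro$area_id), frame$area_id)
    stop("microdata contain unknown area_id: ", paste(bad, collapse = ", "))
  }
  lev <- c("S", "ExS", "NS")
  tab <- table(factor(micro$area_id, levels = frame$area_id),
               factor(micro$status, levels = lev))
  y <- matrix(as.integer(tab), nrow = nrow(frame), dimnames = list(NULL, lev))
  des <- area_design(frame)
  out <- list(y = y, n = as.integer(rowSums(y)),
              X1 = des$X1, X2 = des$X2,
              area_id = frame$area_id,
              labels = frame[, c("area_id", "region", "sex", "age_group")])
  class(out) <- "area_counts"
  out
}

#' Fit the mixed multinomial small-area model
#'
#' Fits, by Laplace-approximated maximum likelihood, the multinomial logit
#' model with a Gaussian random effect per area and non-reference category:
#' \deqn{\eta_{dk} = x_{dk}'\beta_k + u_{dk}, \quad u_{dk} \sim N(0,\phi_k),
#'   \quad k = 1, 2,}
#' with category 3 (never smoker) as reference. The marginal likelihood
#' factorizes over areas into two-dimensional integrals, each approximated
#' by Laplace's method around the penalized-likelihood mode; the outer
#' optimization over \eqn{(\beta_1, \beta_2, \log\phi_1, \log\phi_2)} uses
#' \code{nlminb}. Starting values are a fixed-effects multinomial logit fit
#' and \eqn{\phi_k = 0.05}. Variances are kept nonnegative by the log
#' parameterization; an estimate below \code{1e-8} is treated as on the
#' boundary (\eqn{\hat\phi_k = 0}, \eqn{\hat u_{dk} = 0}), where the model
#' coincides with the fixed-effects multinomial logit.
#'
#' @param counts An [aggregate_to_areas()] result.
#' @param max_iter Maximum outer iterations (default 200).
#' @param rel_tol Relative convergence tolerance on the objective
#'   (default 1e-6).
#' @param phi_start Starting value for both variances.
#' @param start Optional full start vector \code{c(beta1, beta2, log phi)},
#'   used by the bootstrap to warm-start refits.
#' @param random_effects If \code{FALSE}, fit the degenerate submodel with
#'   \eqn{\phi_1 = \phi_2 = 0} (no area random effects), i.e. the
#'   fixed-effects multinomial logit; useful as the collapse limit of the
#'   mixed model.
#' @return Object of class \code{"sae_fit"}: coefficient vectors
#'   \code{beta1}, \code{beta2}; variances \code{phi}; predicted random
#'   effects \code{u} (D x 2, rows of zero-sample areas are 0); fitted area
#'   prevalences \code{prevalence} (D x 3, full mode where the area has
#'   sample, synthetic mode otherwise, flagged in \code{mode}); convergence
#'   diagnostics and the monitored objective path.
#' @export
fit_sae <- function(counts, max_iter = 200, rel_tol = 1e-6,
                    phi_start = 0.05, start = NULL, random_effects = TRUE) {
  stopifnot(inherits(counts, "area_counts"))
  obs <- counts$n > 0
  if (sum(obs) < 10) stop("need at least 10 areas with positive sample")
  X1 <- counts$X1[obs, , drop = FALSE]
  X2 <- counts$X2[obs, , drop = FALSE]
  for (nm in c("X1", "X2")) {
    X <- get(nm)
    if (qr(X)$rank < ncol(X)) {
      stop("design matrix ", nm, " is rank deficient; columns: ",
           paste(colnames(X), collapse = ", "))
    }
  }
  y1 <- counts$y[obs, 1]; y2 <- counts$y[obs, 2]; n <- counts$n[obs]
  r1 <- ncol(X1); r2 <- ncol(X2)
  D <- length(counts$n)

  if (!random_effects) {
    fe <- fit_multinom_fixed(X1, X2, y1, y2, n)
    fit <- structure(list(
      beta1 = stats::setNames(fe$beta1, colnames(counts$X1)),
      beta2 = stats::setNames(fe$beta2, colnames(counts$X2)),
      phi = c(0, 0), boundary = c(TRUE, TRUE), u = matrix(0, D, 2),
      counts = counts,
      convergence = list(code = 0L, message = "fixed-effects Newton",
                         iterations = fe$iterations,
                         objective = -fe$loglik),
      objective_trace = -fe$loglik
    ), class = "sae_fit")
    fit$prevalence <- inv_mlogit(drop(counts$X1 %*% fe$beta1),
                                 drop(counts$X2 %*% fe$beta2))
    fit$mode <- ifelse(counts$n > 0, "full", "synthetic")
    return(fit)
  }

  if (is.null(start)) {
    fe <- fit_multinom_fixed(X1, X2, y1, y2, n)
    start <- c(fe$beta1, fe$beta2, log(c(phi_start, phi_start)))
  }

  env <- new.env(parent = emptyenv())
  env$trace <- numeric(0)
  fn <- function(theta) {
    v <- laplace_nll(theta, X1, X2, y1, y2, n, env = env)
    env$trace <- c(env$trace, v)
    v
  }
  opt <- stats::nlminb(start, fn,
                       control = list(iter.max = max_iter,
                                      eval.max = 10 * max_iter,
                                      rel.tol = rel_tol))
  if (grepl("iteration limit|evaluation limit", opt$message %||% "")) {
    stop("small-area model did not converge: ", opt$message,
         " (", opt$iterations, " iterations, objective ", opt$objective, ")")
  }
  theta <- opt$par
  beta1 <- theta[1:r1]; beta2 <- theta[r1 + (1:r2)]
  phi <- exp(theta[r1 + r2 + (1:2)])
  boundary <- phi < 1e-8
  phi[boundary] <- 0

  # random-effect predictions: posterior modes at the optimum; exactly zero
  # on the variance boundary and for zero-sample areas
  u <- matrix(0, D, 2)
  if (!all(boundary)) {
    phi_in <- pmax(phi, 1e-12)
    m <- inner_modes(drop(X1 %*% beta1), drop(X2 %*% beta2), y1, y2, n, phi_in)
    u[obs, 1] <- m$u1
    u[obs, 2] <- m$u2
    u[, boundary] <- 0
  }

  fit <- structure(list(
    beta1 = stats::setNames(beta1, colnames(counts$X1)),
    beta2 = stats::setNames(beta2, colnames(counts$X2)),
    phi = phi, boundary = boundary, u = u,
    counts = counts,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations,
                       objective = opt$objective),
    objective_trace = env$trace
  ), class = "sae_fit")
  eta1 <- drop(counts$X1 %*% beta1) + u[, 1]
  eta2 <- drop(counts$X2 %*% beta2) + u[, 2]
  fit$prevalence <- inv_mlogit(eta1, eta2)
  fit$mode <- ifelse(counts$n > 0, "full", "synthetic")
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sae_fit <- function(x, ...) {
  cat("Mixed multinomial small-area model (Laplace ML)\n")
  cat(sprintf("  areas: %d (%d with sample)\n", length(x$counts$n), sum(x$counts$n > 0)))
  cat("  beta (smoker logit):    ", paste(sprintf("%.4f", x$beta1), collapse = " "), "\n")
  cat("  beta (ex-smoker logit): ", paste(sprintf("%.4f", x$beta2), collapse = " "), "\n")
  cat(sprintf("  phi: %.5f %.5f%s\n", x$phi[1], x$phi[2],
              if (any(x$boundary)) "  (boundary)" else ""))
  cat(sprintf("  converged in %d iterations\n", x$convergence$iterations))
  invisible(x)
}

#' Predict area prevalences from a fitted small-area model
#'
#' In \code{"full"} mode the linear predictor includes the predicted random
#' effect, \eqn{\eta_{dk} = x_{dk}'\hat\beta_k + \hat u_{dk}}; in
#' \code{"synthetic"} mode only the fixed (synthetic) part
#' \eqn{x_{dk}'\hat\beta_k} is used — this is the prediction that remains
#' available for areas with zero sample, where no random effect can be
#' learned. \code{"auto"} uses full mode where the area has sample and
#' synthetic mode otherwise.
#'
#' @param fit An \code{sae_fit}.
#' @param area_id Areas to predict; default all.
#' @param mode \code{"auto"}, \code{"full"} or \code{"synthetic"}.
#' @return Matrix (length(area_id) x 3) of prevalences; rows sum to 1.
#' @export
predict_prevalence <- function(fit, area_id = NULL,
                               mode = c("auto", "full", "synthetic")) {
  mode <- match.arg(mode)
  ids <- fit$counts$area_id
  if (is.null(area_id)) area_id <- ids
  j <- match(area_id, ids)
  if (anyNA(j)) stop("unknown area_id: ", paste(area_id[is.na(j)], collapse = ", "))
  use_u <- switch(mode,
                  full = rep(TRUE, length(j)),
                  synthetic = rep(FALSE, length(j)),
                  auto = fit$counts$n[j] > 0)
  eta1 <- drop(fit$counts$X1[j, , drop = FALSE] %*% fit$beta1) +
    ifelse(use_u, fit$u[j, 1], 0)
  eta2 <- drop(fit$counts$X2[j, , drop = FALSE] %*% fit$beta2) +
    ifelse(use_u, fit$u[j, 2], 0)
  p <- inv_mlogit(eta1, eta2)
  rownames(p) <- area_id
  p
}

#' Parametric-bootstrap mean squared error of the model estimates
#'
#' Generates \code{B} replicate data sets from the fitted model (new random
#' effects \eqn{u^* \sim N(0,\hat\phi)}, then multinomial counts with the
#' original area sample sizes), refits the model to each starting from the
#' original estimates, and accumulates the squared prediction error of the
#' area prevalences against each replicate's truth. The CV of a model
#' estimate is \eqn{100 \sqrt{MSE}/\hat p_{dk}}, mirroring the precision
#' measure used for the direct estimator. Replicates whose refit fails are
#' dropped and counted; more than 20\% failures is an error.
#'
#' @param fit An [fit_sae()] result.
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @return Data frame of class \code{"sae_precision"}: \code{area_id},
#'   \code{category}, \code{prevalence}, \code{mse}, \code{cv},
#'   \code{mode}; attributes \code{B} (effective replicates) and
#'   \code{n_failed}.
#' @export
mse_bootstrap <- function(fit, B = 200, seed = 1L) {
  stopifnot(inherits(fit, "sae_fit"), B >= 50)
  set.seed(seed)
  counts <- fit$counts
  D <- length(counts$n)
  obs <- counts$n > 0
  a1 <- drop(counts$X1 %*% fit$beta1)
  a2 <- drop(counts$X2 %*% fit$beta2)
  start <- c(fit$beta1, fit$beta2, log(pmax(fit$phi, 1e-4)))
  sse <- matrix(0, D, 3)
  n_ok <- 0L; n_failed <- 0L
  for (b in seq_len(B)) {
    u1 <- stats::rnorm(D, 0, sqrt(fit$phi[1]))
    u2 <- stats::rnorm(D, 0, sqrt(fit$phi[2]))
    p_true <- inv_mlogit(a1 + u1, a2 + u2)
    y <- matrix(0L, D, 3)
    for (d in which(obs)) {
      y[d, ] <- drop(stats::rmultinom(1, counts$n[d], p_true[d, ]))
    }
    cnt_b <- counts
    cnt_b$y <- y
    refit <- tryCatch(fit_sae(cnt_b, start = start), error = function(e) NULL)
    if (is.null(refit)) { n_failed <- n_failed + 1L; next }
    p_hat <- predict_prevalence(refit, mode = "auto")
    sse <- sse + (p_hat - p_true)^2
    n_ok <- n_ok + 1L
  }
  if (n_failed > 0.2 * B) {
    stop(n_failed, " of ", B, " bootstrap refits failed")
  }
  mse <- sse / n_ok
  p0 <- fit$prevalence
  res <- data.frame(
    area_id = rep(counts$area_id, 3),
    category = rep(c("S", "ExS", "NS"), each = D),
    prevalence = c(p0[, 1], p0[, 2], p0[, 3]),
    mse = c(mse[, 1], mse[, 2], mse[, 3]),
    stringsAsFactors = FALSE
  )
  res$cv <- ifelse(res$prevalence > 0, 100 * sqrt(res$mse) / res$prevalence, NA_real_)
  res$mode <- rep(fit$mode, 3)
  res <- res[order(res$area_id, match(res$category, c("S", "ExS", "NS"))), ]
  row.names(res) <- NULL
  class(res) <- c("sae_precision", "data.frame")
  attr(res, "B") <- n_ok
  attr(res, "n_failed") <- n_failed
  res
}

#' Model-based estimates table
#'
#' Convenience assembly of the estimates table consumed by the validation
#' protocol: one row per area x category with the model prevalence, its
#' root-MSE standard error and CV, and the prediction mode.
#'
#' @param fit An \code{sae_fit}.
#' @param precision The matching [mse_bootstrap()] result.
#' @return Data frame of class \code{"sae_estimates"} with frame labels,
#'   \code{prevalence}, \code{se}, \code{mse}, \code{cv}, \code{mode}.
#' @export
sae_estimates <- function(fit, precision) {
  res <- merge(fit$counts$labels, precision, by = "area_id", sort = TRUE)
  res$se <- sqrt(res$mse)
  res <- res[order(res$area_id, match(res$category, c("S", "ExS", "NS"))),
             c("area_id", "region", "sex", "age_group", "category",
               "prevalence", "se", "mse", "cv", "mode")]
  row.names(res) <- NULL
  class(res) <- c("sae_estimates", "data.frame")
  res
}
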