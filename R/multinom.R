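# Internal multinomial-logit machinery shared by the small-area model.
#
# Parameterization: categories k = 1 (S), 2 (ExS) with reference k = 3 (NS);
# per-area log-likelihood  l_d = y1*eta1 + y2*eta2 - n*log(1 + e^eta1 + e^eta2)
# up to the multinomial coefficient, which is constant in the parameters.

mlogit_probs <- function(eta1, eta2) {
  mx <- pmax(0, eta1, eta2)
  e1 <- exp(eta1 - mx); e2 <- exp(eta2 - mx); e3 <- exp(-mx)
  den <- e1 + e2 + e3
  list(p1 = e1 / den, p2 = e2 / den, p3 = e3 / den)
}

mlogit_loglik <- function(eta1, eta2, y1, y2, n) {
  mx <- pmax(0, eta1, eta2)
  logden <- mx + log(exp(-mx) + exp(eta1 - mx) + exp(eta2 - mx))
  sum(y1 * eta1 + y2 * eta2 - n * logden)
}

# Fixed-effects multinomial logit on area counts, Newton-Raphson with step
# halving. Used for starting values of the mixed fit; deliberately
# self-contained so external multinomial fitters stay available as
# independent cross-checks.
fit_multinom_fixed <- function(X1, X2, y1, y2, n, max_iter = 100, tol = 1e-10) {
  r1 <- ncol(X1); r2 <- ncol(X2)
  beta <- rep(0, r1 + r2)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta1 <- drop(X1 %*% beta[1:r1])
    eta2 <- drop(X2 %*% beta[r1 + (1:r2)])
    pr <- mlogit_probs(eta1, eta2)
    g <- c(drop(crossprod(X1, y1 - n * pr$p1)),
           drop(crossprod(X2, y2 - n * pr$p2)))
    w11 <- n * pr$p1 * (1 - pr$p1)
    w22 <- n * pr$p2 * (1 - pr$p2)
    w12 <- -n * pr$p1 * pr$p2
    H <- rbind(cbind(crossprod(X1, X1 * w11), crossprod(X1, X2 * w12)),
               cbind(crossprod(X2, X1 * w12), crossprod(X2, X2 * w22)))
    step <- tryCatch(solve(H, g), error = function(e)
      stop("singular design in multinomial fit; check covariates for collinearity"))
    # step-halve onto the concave log-likelihood
    ll_cur <- mlogit_loglik(eta1, eta2, y1, y2, n)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- mlogit_loglik(drop(X1 %*% cand[1:r1]),
                              drop(X2 %*% cand[r1 + (1:r2)]), y1, y2, n)
      if (is.finite(ll_new) && ll_new >= ll_cur - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { cand <- beta; ll_new <- ll_cur; break }
    }
    beta <- cand
    if (abs(ll_new - ll_old) < tol * (abs(ll_new) + 1)) break
    ll_old <- ll_new
  }
  list(beta1 = beta[1:r1], beta2 = beta[r1 + (1:r2)], loglik = ll_new,
       iterations = it)
}

# Profile the per-area random effects u = (u1, u2) at fixed (beta, phi):
# vectorized damped Newton on the strictly concave penalized likelihood
#   q_d(u) = y1*eta1 + y2*eta2 - n*log den - u1^2/(2 phi1) - u2^2/(2 phi2).
# Returns the modes and the 2x2 negated-Hessian entries at the modes.
inner_modes <- function(a1, a2, y1, y2, n, phi, u_start = NULL,
                        max_iter = 100, tol = 1e-9) {
  D <- length(n)
  u1 <- if (is.null(u_start)) numeric(D) else u_start[, 1]
  u2 <- if (is.null(u_start)) numeric(D) else u_start[, 2]
  ip1 <- 1 / phi[1]; ip2 <- 1 / phi[2]
  qfun <- function(u1, u2) {
    eta1 <- a1 + u1; eta2 <- a2 + u2
    mx <- pmax(0, eta1, eta2)
    logden <- mx + log(exp(-mx) + exp(eta1 - mx) + exp(eta2 - mx))
    y1 * eta1 + y2 * eta2 - n * logden - u1^2 * ip1 / 2 - u2^2 * ip2 / 2
  }
  q <- qfun(u1, u2)
  for (it in seq_len(max_iter)) {
    pr <- mlogit_probs(a1 + u1, a2 + u2)
    g1 <- y1 - n * pr$p1 - u1 * ip1
    g2 <- y2 - n * pr$p2 - u2 * ip2
    if (max(abs(g1), abs(g2)) < tol) break
    A11 <- n * pr$p1 * (1 - pr$p1) + ip1
    A22 <- n * pr$p2 * (1 - pr$p2) + ip2
    A12 <- -n * pr$p1 * pr$p2
    det <- A11 * A22 - A12^2
    d1 <- (A22 * g1 - A12 * g2) / det
    d2 <- (A11 * g2 - A12 * g1) / det
    # trust-region style cap keeps early steps sane when phi is large
    sc <- pmax(1, pmax(abs(d1), abs(d2)) / 4)
    d1 <- d1 / sc; d2 <- d2 / sc
    lambda <- rep(1, D)
    for (h in 1:30) {
      q_new <- qfun(u1 + lambda * d1, u2 + lambda * d2)
      bad <- !is.finite(q_new) | q_new < q - 1e-12
      if (!any(bad)) break
      lambda[bad] <- lambda[bad] / 2
    }
    u1 <- u1 + lambda * d1
    u2 <- u2 + lambda * d2
    q <- qfun(u1, u2)
  }
  pr <- mlogit_probs(a1 + u1, a2 + u2)
  A11 <- n * pr$p1 * (1 - pr$p1) + ip1
  A22 <- n * pr$p2 * (1 - pr$p2) + ip2
  A12 <- -n * pr$p1 * pr$p2
  list(u1 = u1, u2 = u2, q = q, logdetA = log(A11 * A22 - A12^2))
}

# Negative Laplace-approximated marginal log-likelihood of the mixed model.
# theta = (beta1, beta2, log phi1, log phi2); areas with n = 0 contribute 0.
laplace_nll <- function(theta, X1, X2, y1, y2, n, env = NULL) {
  r1 <- ncol(X1); r2 <- ncol(X2)
  beta1 <- theta[1:r1]; beta2 <- theta[r1 + (1:r2)]
  phi <- exp(theta[r1 + r2 + (1:2)])
  a1 <- drop(X1 %*% beta1); a2 <- drop(X2 %*% beta2)
  u_start <- if (!is.null(env) && !is.null(env$u)) env$u else NULL
  m <- inner_modes(a1, a2, y1, y2, n, phi, u_start = u_start)
  if (!is.null(env)) env$u <- cbind(m$u1, m$u2)
  # Laplace: log integral ~ q(u*) + log(2*pi) - (1/2) log det A; the normal
  # normalizing constant contributes -(1/2) log(phi1 phi2) - log(2*pi).
  ll <- sum(m$q) - length(n) * sum(log(phi)) / 2 - sum(m$logdetA) / 2
  if (!is.finite(ll)) return(1e10)
  -ll
}
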