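# Twin-pair similarity: casewise concordance, correlation, Plackett odds
# ratio. Closed-form ML estimators with delta-method standard errors on the
# trinomial pair counts, plus a general (optionally covariate-adjusted)
# pair-likelihood fitter and MZ-vs-DZ likelihood-ratio tests.

similarity_methods <- c("casewise", "correlation", "odds_ratio")

new_similarity_estimate <- function(method, estimate, se, ci95, n_pairs,
                                    zygosity = NA, condition = NA,
                                    boundary = FALSE) {
  structure(list(method = method, estimate = estimate, se = se,
                 ci95 = ci95, n_pairs = n_pairs, zygosity = zygosity,
                 condition = condition, boundary = boundary),
            class = "similarity_estimate")
}

#' @export
print.similarity_estimate <- function(x, ...) {
  lab <- c(casewise = "Casewise concordance",
           correlation = "Pairwise correlation",
           odds_ratio = "Pairwise odds ratio")[x$method]
  cat(sprintf("%s%s%s: %.4g", lab,
              if (!is.na(x$condition)) paste0(" for '", x$condition, "'") else "",
              if (!is.na(x$zygosity)) paste0(" (", x$zygosity, ")") else "",
              x$estimate))
  if (is.finite(x$se))
    cat(sprintf("  SE %.4g  95%% CI (%.4g, %.4g)", x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  [n = %d pairs]\n", x$n_pairs))
  if (x$boundary) cat("  note: estimate on the boundary of its range\n")
  invisible(x)
}

# multinomial covariance of (p11_hat, pd_hat) from N pairs
.trinomial_cov <- function(p11, pd, N) {
  matrix(c(p11 * (1 - p11), -p11 * pd,
           -p11 * pd, pd * (1 - pd)), 2, 2) / N
}

#' Casewise concordance from pair counts
#'
#' The casewise concordance \eqn{C} is the conditional probability that a
#' twin is affected given that the co-twin is affected. Its multinomial
#' maximum-likelihood estimate from the pair cells is
#' \eqn{\hat C = 2N_c/(2N_c + N_d)}. The standard error is obtained by the
#' delta method on the trinomial cell proportions, and the 95\% interval is
#' the untransformed Wald interval truncated to \eqn{[0, 1]}.
#'
#' @param pc a [pair_counts] object.
#' @param conf_level confidence level for the Wald interval.
#' @return a \code{"similarity_estimate"} object.
#' @export
casewise_concordance <- function(pc, conf_level = 0.95) {
  stopifnot(inherits(pc, "pair_counts"))
  Nc <- pc$n_concordant; Nd <- pc$n_discordant; N <- pc$n_pairs
  if (Nc + Nd == 0)
    stop("casewise concordance undefined: no pair contains an affected twin")
  C <- 2 * Nc / (2 * Nc + Nd)
  p11 <- Nc / N; pd <- Nd / N
  # gradient of C = 2 p11 / (2 p11 + pd)
  g <- c(2 * pd, -2 * p11) / (2 * p11 + pd)^2
  se <- sqrt(drop(t(g) %*% .trinomial_cov(p11, pd, N) %*% g))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, C - z * se), min(1, C + z * se))
  new_similarity_estimate("casewise", C, se, ci, N, pc$zygosity,
                          pc$condition, boundary = C %in% c(0, 1))
}

#' Pairwise correlation from pair counts
#'
#' ML estimate of the correlation \eqn{\rho} in the exchangeable pair model
#' \eqn{p_{11} = q^2 + \rho q(1-q)} with marginal prevalence
#' \eqn{\hat q = (2N_c + N_d)/(2N)}; algebraically identical to the phi
#' coefficient of the double-entered 2x2 table. Delta-method SE and
#' untransformed Wald interval truncated to \eqn{[-1, 1]}.
#'
#' @inheritParams casewise_concordance
#' @return a \code{"similarity_estimate"} object.
#' @export
pair_correlation <- function(pc, conf_level = 0.95) {
  stopifnot(inherits(pc, "pair_counts"))
  Nc <- pc$n_concordant; Nd <- pc$n_discordant; N <- pc$n_pairs
  q <- (2 * Nc + Nd) / (2 * N)
  if (q <= 0 || q >= 1)
    stop("degenerate margins (prevalence ", q, "): correlation undefined")
  p11 <- Nc / N; pd <- Nd / N
  rho_fun <- function(p11, pd) {
    qq <- p11 + pd / 2
    (p11 - qq^2) / (qq * (1 - qq))
  }
  rho <- rho_fun(p11, pd)
  # analytic gradient: q = p11 + pd/2
  dq <- c(1, 0.5)
  num <- p11 - q^2; den <- q * (1 - q)
  dnum <- c(1, 0) - 2 * q * dq
  dden <- (1 - 2 * q) * dq
  g <- (dnum * den - num * dden) / den^2
  se <- sqrt(drop(t(g) %*% .trinomial_cov(p11, pd, N) %*% g))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(-1, rho - z * se), min(1, rho + z * se))
  new_similarity_estimate("correlation", rho, se, ci, N, pc$zygosity,
                          pc$condition, boundary = abs(rho) >= 1)
}

#' Pairwise (Plackett) odds ratio from pair counts
#'
#' Saturated-model ML estimate
#' \eqn{\hat\psi = N_c N_{00} / (N_d/2)^2}: the ratio of the odds of being
#' affected given the co-twin is affected to the odds given the co-twin is
#' unaffected. The SE of \eqn{\log\hat\psi} is by the delta method and the
#' interval is Wald on the log scale. \eqn{N_d = 0} gives an infinite
#' estimate, flagged with no interval.
#'
#' @inheritParams casewise_concordance
#' @return a \code{"similarity_estimate"} object.
#' @export
pair_odds_ratio <- function(pc, conf_level = 0.95) {
  stopifnot(inherits(pc, "pair_counts"))
  Nc <- pc$n_concordant; Nd <- pc$n_discordant; N00 <- pc$n_neither
  N <- pc$n_pairs
  if (Nd == 0)
    return(new_similarity_estimate("odds_ratio", Inf, NA_real_,
                                   c(NA_real_, NA_real_), N,
                                   pc$zygosity, pc$condition, boundary = TRUE))
  if (Nc == 0 || N00 == 0)
    return(new_similarity_estimate("odds_ratio", 0, NA_real_,
                                   c(NA_real_, NA_real_), N,
                                   pc$zygosity, pc$condition, boundary = TRUE))
  psi <- Nc * N00 / (Nd / 2)^2
  p11 <- Nc / N; pd <- Nd / N; p00 <- N00 / N
  # log psi = log p11 + log p00 - 2 log(pd/2); p00 = 1 - p11 - pd
  g <- c(1 / p11 - 1 / p00, -1 / p00 - 2 / pd)
  se_log <- sqrt(drop(t(g) %*% .trinomial_cov(p11, pd, N) %*% g))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(psi) + c(-1, 1) * z * se_log)
  new_similarity_estimate("odds_ratio", psi, se_log, ci, N,
                          pc$zygosity, pc$condition)
}

#' Joint cell probability of the Plackett distribution
#'
#' Solves for \eqn{p_{11}} given two marginal probabilities and the odds
#' ratio \eqn{\psi}: the root in
#' \eqn{[\max(0, p_1 + p_2 - 1), \min(p_1, p_2)]} of the quadratic implied
#' by \eqn{p_{11} p_{00} / (p_{10} p_{01}) = \psi}. For \eqn{\psi = 1} the
#' margins are independent and \eqn{p_{11} = p_1 p_2}.
#'
#' @param p1,p2 marginal probabilities in (0, 1).
#' @param psi odds ratio, positive.
#' @return \eqn{p_{11}}, vectorised over its arguments.
#' @export
plackett_cell <- function(p1, p2, psi) {
  if (any(p1 <= 0 | p1 >= 1) || any(p2 <= 0 | p2 >= 1))
    stop("marginal probabilities must lie strictly in (0, 1)")
  if (any(psi <= 0)) stop("odds ratio must be positive")
  n <- max(length(p1), length(p2), length(psi))
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n); psi <- rep_len(psi, n)
  out <- numeric(n)
  near1 <- abs(psi - 1) < 1e-9
  out[near1] <- p1[near1] * p2[near1]
  i <- !near1
  if (any(i)) {
    s <- 1 + (p1[i] + p2[i]) * (psi[i] - 1)
    disc <- s^2 - 4 * psi[i] * (psi[i] - 1) * p1[i] * p2[i]
    out[i] <- (s - sqrt(pmax(disc, 0))) / (2 * (psi[i] - 1))
  }
  pmin(pmax(out, pmax(0, p1 + p2 - 1)), pmin(p1, p2))
}

# ---- general pair likelihood -----------------------------------------------

# cell probabilities (p11, p10, p01, p00) for one pair given margins p1, p2
# and the association parameter of the chosen kind. Returns NULL when the
# parameter combination is infeasible (some cell would be negative).
pair_cells <- function(p1, p2, assoc, method) {
  p11 <- switch(method,
    casewise = assoc * (p1 + p2) / 2,
    correlation = p1 * p2 + assoc * sqrt(p1 * (1 - p1) * p2 * (1 - p2)),
    odds_ratio = plackett_cell(p1, p2, assoc))
  p10 <- p1 - p11; p01 <- p2 - p11; p00 <- 1 - p1 - p2 + p11
  cells <- cbind(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
  if (any(cells < -1e-12)) return(NULL)
  pmax(cells, 0)
}

# ordered-pair log-likelihood for response matrix y (columns y1, y2)
pair_loglik_cells <- function(y, cells) {
  idx <- 1L + (1L - y[, 1]) * 2L + (1L - y[, 2])  # 11->1, 10->2, 01->3, 00->4
  p <- cells[cbind(seq_len(nrow(y)), idx)]
  if (any(p <= 0)) return(-Inf)
  sum(log(p))
}

# expand a pair_counts object to minimal unadjusted pair data
pair_counts_to_data <- function(pc) {
  data.frame(
    y1 = rep(c(1L, 1L, 0L), c(pc$n_concordant, pc$n_discordant, pc$n_neither)),
    y2 = rep(c(1L, 0L, 0L), c(pc$n_concordant, pc$n_discordant, pc$n_neither)))
}

# association parameter transforms: unconstrained scale <-> natural scale
assoc_link <- function(method) {
  switch(method,
    casewise = list(to = stats::qlogis, from = stats::plogis),
    correlation = list(to = atanh, from = tanh),
    odds_ratio = list(to = log, from = exp))
}

#' Fit a likelihood-based twin-pair similarity model
#'
#' Maximises the joint likelihood of twin-pair binary outcomes under one of
#' three parameterisations of within-pair association: casewise concordance
#' \eqn{C} (\eqn{p_{11} = C(p_1+p_2)/2}), correlation \eqn{\rho}
#' (\eqn{p_{11} = p_1 p_2 + \rho\sqrt{p_1(1-p_1)p_2(1-p_2)}}), or Plackett
#' odds ratio \eqn{\psi} ([plackett_cell]). Unadjusted fits use a constant
#' marginal prevalence \eqn{q}; adjusted fits model each twin's marginal on
#' the log-odds scale as \eqn{\mathrm{logit}(p) = \beta_0 + \beta_{age} age
#' + \beta_{sex} female}, with the association parameter common to all
#' pairs.
#'
#' @param data either a [pair_counts] object (unadjusted only) or a
#'   data.frame with columns \code{y1}, \code{y2} (0/1) and, for adjusted
#'   fits, \code{age1}, \code{age2}, \code{sex1}, \code{sex2} (sex coded
#'   female = 1).
#' @param method association parameterisation.
#' @param adjusted include age and sex in each twin's marginal.
#' @param control list with \code{maxit} and \code{reltol} passed to the
#'   optimiser.
#' @return An object of class \code{"pair_model"} with components
#'   \code{coefficients} (association parameter first, then marginal
#'   parameters, all on their natural scales), \code{se}, \code{vcov},
#'   \code{loglik}, \code{n_pairs}, \code{method}, \code{adjusted},
#'   \code{convergence} and \code{boundary}.
#' @seealso [lr_test_zygosity()], [casewise_concordance()],
#'   [pair_correlation()], [pair_odds_ratio()]
#' @export
fit_pair_model <- function(data, method = similarity_methods,
                           adjusted = FALSE,
                           control = list(maxit = 500, reltol = 1e-10)) {
  method <- match.arg(method)
  zyg <- NA_character_; cond <- NA_character_
  if (inherits(data, "pair_counts")) {
    zyg <- data$zygosity; cond <- data$condition
    data <- pair_counts_to_data(data)
  }
  y <- as.matrix(data[, c("y1", "y2")])
  if (nrow(y) < 2) stop("need at least two pairs")
  if (adjusted) {
    need <- c("age1", "age2", "sex1", "sex2")
    if (!all(need %in% names(data)))
      stop("adjusted fit needs columns ", paste(need, collapse = ", "))
    X1 <- cbind(1, data$age1, data$sex1)
    X2 <- cbind(1, data$age2, data$sex2)
  }
  link <- assoc_link(method)

  # closed-form plug-in starts from the pooled counts
  Nc <- sum(y[, 1] == 1 & y[, 2] == 1); Nd <- sum(y[, 1] != y[, 2])
  N00 <- nrow(y) - Nc - Nd
  pc0 <- new_pair_counts(Nc, Nd, N00)
  q0 <- min(max((2 * Nc + Nd) / (2 * nrow(y)), 1e-4), 1 - 1e-4)
  a0 <- switch(method,
    casewise = min(max(2 * Nc / max(2 * Nc + Nd, 1), 0.02), 0.98),
    correlation = min(max(pair_correlation_start(pc0), -0.95), 0.95),
    odds_ratio = min(max(Nc * N00 / max((Nd / 2)^2, 0.25), 0.05), 400))

  negll <- function(theta) {
    assoc <- link$from(theta[1])
    if (adjusted) {
      p1 <- stats::plogis(drop(X1 %*% theta[-1]))
      p2 <- stats::plogis(drop(X2 %*% theta[-1]))
    } else {
      p1 <- p2 <- rep(stats::plogis(theta[2]), nrow(y))
    }
    if (any(p1 <= 1e-12 | p1 >= 1 - 1e-12 | p2 <= 1e-12 | p2 >= 1 - 1e-12))
      return(1e10)
    cells <- pair_cells(p1, p2, assoc, method)
    if (is.null(cells)) return(1e10)
    ll <- pair_loglik_cells(y, cells)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  start <- c(link$to(a0),
             if (adjusted) c(stats::qlogis(q0), 0, 0) else stats::qlogis(q0))
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  if (opt$convergence != 0)
    stop("pair-model optimiser failed to converge (code ", opt$convergence,
         "): ", opt$message)

  theta <- opt$par
  nat <- c(link$from(theta[1]),
           if (adjusted) theta[-1] else stats::plogis(theta[2]))
  names(nat) <- c(switch(method, casewise = "C", correlation = "rho",
                         odds_ratio = "psi"),
                  if (adjusted) c("beta0", "beta_age", "beta_sex") else "q")

  # observed information on the natural scale
  negll_nat <- function(par) {
    th <- c(link$to(par[1]),
            if (adjusted) par[-1] else stats::qlogis(par[2]))
    negll(th)
  }
  H <- num_hessian(negll_nat, nat)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(nat),
                                                     length(nat)))
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(nat)
  boundary <- negll(theta) >= 1e10 ||
    abs(theta[1]) > switch(method, casewise = 12, correlation = 7,
                           odds_ratio = 14)

  structure(list(coefficients = nat, se = se, vcov = V,
                 loglik = -opt$value, n_pairs = nrow(y),
                 method = method, adjusted = adjusted,
                 zygosity = zyg, condition = cond,
                 convergence = opt$convergence, boundary = boundary),
            class = "pair_model")
}

# plug-in correlation start (phi identity), tolerant of degenerate tables
pair_correlation_start <- function(pc) {
  q <- (2 * pc$n_concordant + pc$n_discordant) / (2 * pc$n_pairs)
  if (q <= 0 || q >= 1) return(0)
  p11 <- pc$n_concordant / pc$n_pairs
  (p11 - q^2) / (q * (1 - q))
}

# central-difference Hessian; adequate for the smooth likelihoods here
num_hessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1) * eps
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' @export
print.pair_model <- function(x, ...) {
  lab <- c(casewise = "casewise concordance",
           correlation = "correlation",
           odds_ratio = "odds ratio")[x$method]
  cat(sprintf("Twin-pair %s model%s (%s)\n", lab,
              if (x$adjusted) ", adjusted for age and sex" else "",
              if (!is.na(x$zygosity)) x$zygosity else "pooled"))
  est <- cbind(estimate = x$coefficients, se = x$se)
  print(round(est, 4))
  cat(sprintf("log-likelihood %.4f on %d pairs\n", x$loglik, x$n_pairs))
  if (x$boundary) cat("note: association estimate near its boundary\n")
  invisible(x)
}

#' @export
coef.pair_model <- function(object, ...) object$coefficients

#' @export
vcov.pair_model <- function(object, ...) object$vcov

#' @export
logLik.pair_model <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_pairs, class = "logLik")
}

#' @export
summary.pair_model <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(model = object, coefficients = tab),
            class = "summary.pair_model")
}

#' @export
print.summary.pair_model <- function(x, ...) {
  print(x$model)
  cat("\nWald tests:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
confint.pair_model <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)),
                        "%")
  rownames(ci) <- names(object$coefficients)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Simulate twin-pair outcomes from a fitted pair model
#'
#' Draws pair outcomes from the fitted cell probabilities; used for
#' parametric-bootstrap and null-calibration checks.
#'
#' @param object a \code{"pair_model"} (unadjusted).
#' @param nsim number of data sets.
#' @param seed integer seed.
#' @param n_pairs pairs per data set (default the fitted size).
#' @param ... unused.
#' @return a list of \code{nsim} data.frames with columns \code{y1, y2}.
#' @export
simulate.pair_model <- function(object, nsim = 1, seed = NULL,
                                n_pairs = object$n_pairs, ...) {
  if (object$adjusted)
    stop("simulate() supports unadjusted pair models only")
  if (!is.null(seed)) set.seed(seed)
  q <- object$coefficients[["q"]]
  cells <- pair_cells(q, q, object$coefficients[[1]], object$method)
  pr <- cells[1, ]
  lapply(seq_len(nsim), function(i) {
    cell <- sample.int(4, n_pairs, replace = TRUE, prob = pr)
    data.frame(y1 = as.integer(cell %in% c(1, 2)),
               y2 = as.integer(cell %in% c(1, 3)))
  })
}

#' Likelihood-ratio test of an MZ-vs-DZ association difference
#'
#' Compares the unconstrained model (separate marginal and association
#' parameters per zygosity group) against the constrained model sharing one
#' association parameter across zygosities while keeping separate
#' marginals. The statistic is referred to chi-square with 1 df.
#'
#' @param mz,dz [pair_counts] objects or pair data.frames (see
#'   [fit_pair_model()]) for the two zygosity groups.
#' @param method association parameterisation.
#' @param adjusted adjust marginals for age and sex.
#' @return An object of class \code{"lr_test"}: \code{statistic},
#'   \code{df}, \code{p_value}, \code{loglik_unconstrained},
#'   \code{loglik_constrained}, and the two unconstrained fits.
#' @export
lr_test_zygosity <- function(mz, dz, method = similarity_methods,
                             adjusted = FALSE) {
  method <- match.arg(method)
  fit_mz <- fit_pair_model(mz, method, adjusted)
  fit_dz <- fit_pair_model(dz, method, adjusted)
  ll_u <- fit_mz$loglik + fit_dz$loglik

  to_df <- function(x) if (inherits(x, "pair_counts")) pair_counts_to_data(x) else x
  dmz <- to_df(mz); ddz <- to_df(dz)
  y_mz <- as.matrix(dmz[, c("y1", "y2")])
  y_dz <- as.matrix(ddz[, c("y1", "y2")])
  link <- assoc_link(method)
  if (adjusted) {
    Xm1 <- cbind(1, dmz$age1, dmz$sex1); Xm2 <- cbind(1, dmz$age2, dmz$sex2)
    Xd1 <- cbind(1, ddz$age1, ddz$sex1); Xd2 <- cbind(1, ddz$age2, ddz$sex2)
  }

  grp_negll <- function(y, assoc, marg, X1 = NULL, X2 = NULL) {
    if (adjusted) {
      p1 <- stats::plogis(drop(X1 %*% marg)); p2 <- stats::plogis(drop(X2 %*% marg))
    } else {
      p1 <- p2 <- rep(stats::plogis(marg), nrow(y))
    }
    if (any(p1 <= 1e-12 | p1 >= 1 - 1e-12 | p2 <= 1e-12 | p2 >= 1 - 1e-12))
      return(1e10)
    cells <- pair_cells(p1, p2, assoc, method)
    if (is.null(cells)) return(1e10)
    ll <- pair_loglik_cells(y, cells)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  nm <- if (adjusted) 3L else 1L
  negll_c <- function(theta) {
    assoc <- link$from(theta[1])
    m_mz <- theta[2:(1 + nm)]; m_dz <- theta[(2 + nm):(1 + 2 * nm)]
    v1 <- if (adjusted) grp_negll(y_mz, assoc, m_mz, Xm1, Xm2)
          else grp_negll(y_mz, assoc, m_mz)
    v2 <- if (adjusted) grp_negll(y_dz, assoc, m_dz, Xd1, Xd2)
          else grp_negll(y_dz, assoc, m_dz)
    v1 + v2
  }

  # start the shared association between the two group MLEs
  a_mz <- link$to(fit_mz$coefficients[[1]])
  a_dz <- link$to(fit_dz$coefficients[[1]])
  marg_start <- function(fit) {
    if (adjusted) fit$coefficients[c("beta0", "beta_age", "beta_sex")]
    else stats::qlogis(fit$coefficients[["q"]])
  }
  start <- c((a_mz + a_dz) / 2, marg_start(fit_mz), marg_start(fit_dz))
  opt <- stats::optim(start, negll_c, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0)
    stop("constrained optimiser failed to converge (code ",
         opt$convergence, ")")
  ll_c <- -opt$value
  stat <- 2 * (ll_u - ll_c)
  if (stat < -1e-6)
    stop("negative LR statistic (", stat, "): optimiser inconsistency")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 loglik_unconstrained = ll_u, loglik_constrained = ll_c,
                 shared_association = link$from(opt$par[1]),
                 method = method, adjusted = adjusted,
                 fit_mz = fit_mz, fit_dz = fit_dz),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test of equal MZ/DZ %s%s\n",
              c(casewise = "casewise concordance",
                correlation = "correlation",
                odds_ratio = "odds ratio")[x$method],
              if (x$adjusted) " (age/sex-adjusted marginals)" else ""))
  cat(sprintf("  MZ estimate %.4g, DZ estimate %.4g, shared %.4g\n",
              x$fit_mz$coefficients[[1]], x$fit_dz$coefficients[[1]],
              x$shared_association))
  cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
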