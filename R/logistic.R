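# Familial-aggregation logistic models. The fixed-effects fitter is an
# in-package iteratively reweighted least squares implementation; the
# family-level random intercept is integrated out by Gauss-Hermite
# quadrature. Wald inference throughout.

#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch construction: eigen-decomposition of the symmetric
#' tridiagonal Jacobi matrix for the Hermite weight \eqn{e^{-x^2}}.
#'
#' @param n number of nodes.
#' @return list with \code{nodes} and \code{weights} such that
#'   \eqn{\int f(x) e^{-x^2} dx \approx \sum w_i f(x_i)}.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = sqrt(pi) * e$vectors[1, idx]^2)
}

irls_logistic <- function(X, y, maxit = 100, tol = 1e-10) {
  beta <- numeric(ncol(X))
  # start the intercept at the empirical log-odds
  ybar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  if ("(Intercept)" %in% colnames(X)) beta[1] <- stats::qlogis(ybar)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit)) stop("weighted least squares step failed")
    beta_new <- fit$coefficients
    if (any(is.na(beta_new))) stop("design matrix not full rank")
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  grad <- drop(crossprod(X, y - mu))
  list(coefficients = beta, fitted = mu, eta = eta,
       gradient = grad, iterations = it,
       converged = max(abs(grad)) < 1e-6,
       loglik = sum(y * log(pmax(mu, 1e-300)) +
                    (1 - y) * log(pmax(1 - mu, 1e-300))))
}

glmm_loglik <- function(beta, log_sigma, X, y, cluster, gh) {
  sigma <- exp(log_sigma)
  eta0 <- drop(X %*% beta)
  b <- sqrt(2) * sigma * gh$nodes                 # integration points
  ll <- 0
  for (f in split(seq_along(y), cluster)) {
    # likelihood of one family at each node: prod over members
    et <- outer(eta0[f], b, `+`)
    p <- stats::plogis(et)
    lp <- y[f] * log(p) + (1 - y[f]) * log1p(-p)
    lik_node <- exp(colSums(lp))
    ll <- ll + log(sum(gh$weights * lik_node) / sqrt(pi))
  }
  ll
}

#' Fit a logistic regression for familial aggregation
#'
#' Fixed-effects maximum likelihood by iteratively reweighted least
#' squares. With \code{random_intercept}, a family-level normal random
#' intercept is integrated out by Gauss-Hermite quadrature and all
#' parameters (coefficients and the log random-intercept SD) are maximised
#' jointly. Inference is Wald: each coefficient divided by its observed-
#' information standard error, referred to the standard normal.
#'
#' @param formula model formula; the response must be 0/1.
#' @param data data.frame.
#' @param random_intercept optional name of the clustering column (e.g.
#'   \code{"family_id"}); \code{NULL} for plain logistic regression.
#' @param nodes Gauss-Hermite node count for the random-intercept integral.
#' @param maxit,tol IRLS iteration cap and convergence tolerance.
#' @return Object of class \code{"family_logit"}: \code{coefficients} (log-
#'   odds), \code{odds_ratio}, \code{se}, \code{wald_z}, \code{p_value},
#'   \code{vcov}, \code{loglik}, \code{n}, \code{sigma_u} (random-intercept
#'   SD, if fitted), \code{converged}, \code{separation}.
#' @export
fit_logistic <- function(formula, data, random_intercept = NULL,
                         nodes = 21, maxit = 100, tol = 1e-10) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("response must be 0/1")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("response has no variation (all ", y[1], ")")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; collinear terms: ",
         paste(drop_cols, collapse = ", "))
  }

  fe <- irls_logistic(X, y, maxit = maxit, tol = tol)
  separation <- max(abs(fe$eta)) > 25 || max(abs(fe$coefficients)) > 15
  if (separation)
    stop("apparent complete separation: coefficients diverging")

  if (is.null(random_intercept)) {
    beta <- fe$coefficients
    W <- fe$fitted * (1 - fe$fitted)
    info <- crossprod(X * sqrt(W))
    V <- solve(info)
    sigma_u <- NULL
    loglik <- fe$loglik
  } else {
    cl <- data[stats::complete.cases(data[, all.vars(formula)]),
               random_intercept]
    if (length(cl) != length(y))
      stop("clustering column has missing values not shared with the model frame")
    gh <- gauss_hermite(nodes)
    k <- ncol(X)
    nll <- function(par) {
      v <- -glmm_loglik(par[seq_len(k)], par[k + 1], X, y, cl, gh)
      if (!is.finite(v)) 1e10 else v
    }
    start <- c(fe$coefficients, log(0.5))
    opt <- stats::optim(start, nll, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-10))
    if (opt$convergence != 0)
      stop("random-intercept optimiser failed to converge (code ",
           opt$convergence, ")")
    H <- num_hessian(nll, opt$par)
    Vfull <- tryCatch(solve(H), error = function(e)
      matrix(NA_real_, k + 1, k + 1))
    beta <- opt$par[seq_len(k)]
    names(beta) <- colnames(X)
    V <- Vfull[seq_len(k), seq_len(k), drop = FALSE]
    dimnames(V) <- list(colnames(X), colnames(X))
    sigma_u <- unname(exp(opt$par[k + 1]))
    loglik <- -opt$value
  }

  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(beta)
  z <- beta / se
  structure(list(coefficients = beta, odds_ratio = exp(beta), se = se,
                 wald_z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 vcov = V, loglik = loglik, n = length(y),
                 sigma_u = sigma_u, formula = formula,
                 converged = if (is.null(random_intercept)) fe$converged else TRUE,
                 separation = separation,
                 gradient = if (is.null(random_intercept)) fe$gradient else NULL),
            class = "family_logit")
}

#' @export
print.family_logit <- function(x, ...) {
  cat("Familial-aggregation logistic model")
  if (!is.null(x$sigma_u))
    cat(sprintf(" (family random intercept, SD = %.3f)", x$sigma_u))
  cat(sprintf("\n  n = %d, log-likelihood = %.3f\n", x$n, x$loglik))
  tab <- cbind(coef = x$coefficients, OR = x$odds_ratio, se = x$se,
               z = x$wald_z, p = x$p_value)
  print(round(tab, 4))
  if (x$separation) cat("warning: possible complete separation\n")
  invisible(x)
}

#' @export
coef.family_logit <- function(object, ...) object$coefficients

#' @export
vcov.family_logit <- function(object, ...) object$vcov

#' @export
logLik.family_logit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + length(object$sigma_u),
            nobs = object$n, class = "logLik")
}

#' @export
summary.family_logit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Odds ratio` = object$odds_ratio,
               `Std. Error` = object$se, `z value` = object$wald_z,
               `Pr(>|z|)` = object$p_value)
  structure(list(model = object, coefficients = tab),
            class = "summary.family_logit")
}

#' @export
print.summary.family_logit <- function(x, ...) {
  print(x$model)
  invisible(x)
}

# decide which of age/sex to include for an outcome under the
# "adjust when significant" policy: each covariate's own Wald p in a
# covariates-only model must fall below alpha
covariate_terms <- function(rows, policy, alpha = 0.05) {
  if (policy == "never") return(character(0))
  if (policy == "always") return(c("twin_age", "sexf"))
  fit <- tryCatch(
    fit_logistic(twin_status ~ twin_age + sexf, rows),
    error = function(e) NULL)
  if (is.null(fit)) return(character(0))
  keep <- names(fit$p_value)[-1][fit$p_value[-1] < alpha]
  sub("^sexf$", "sexf", keep)
}

prep_family_rows <- function(rows) {
  rows$sexf <- as.integer(rows$twin_sex == "female")
  rows
}

#' Univariate family-member association scan
#'
#' One logistic model per family member: index-twin status regressed on the
#' member's status, with age/sex covariates per policy. Mirrors the
#' univariate rows of a family-aggregation table.
#'
#' @param rows complete family rows from [select_index_twins()].
#' @param members which family members to scan.
#' @param covariate_policy \code{"when_significant"} (include age or sex
#'   when its own Wald p < 0.05 in a covariates-only model),
#'   \code{"always"}, or \code{"never"}.
#' @return data.frame with one row per member: \code{member}, \code{n},
#'   \code{or}, \code{se}, \code{p}, \code{error}; fitted models in the
#'   \code{"fits"} attribute.
#' @export
univariate_scan <- function(rows,
                            members = c("cotwin", "sibling", "mother", "father"),
                            covariate_policy = c("when_significant",
                                                 "always", "never")) {
  covariate_policy <- match.arg(covariate_policy)
  if (nrow(rows) < 10) stop("too few complete families (", nrow(rows), ")")
  rows <- prep_family_rows(rows)
  covs <- covariate_terms(rows, covariate_policy)
  fits <- list()
  out <- data.frame(member = members, n = NA_integer_, or = NA_real_,
                    se = NA_real_, p = NA_real_, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(members)) {
    term <- paste0(members[i], "_status")
    fml <- stats::reformulate(c(term, covs), response = "twin_status")
    fit <- tryCatch(fit_logistic(fml, rows), error = function(e) e)
    if (inherits(fit, "error")) {
      out$error[i] <- conditionMessage(fit)
      next
    }
    fits[[members[i]]] <- fit
    out$n[i] <- fit$n
    out$or[i] <- fit$odds_ratio[[term]]
    out$se[i] <- fit$se[[term]]
    out$p[i] <- fit$p_value[[term]]
  }
  attr(out, "fits") <- fits
  attr(out, "covariates") <- covs
  out
}

#' Multivariate family-member association model
#'
#' All four member statuses as simultaneous predictors of the index twin's
#' status, covariates per policy.
#'
#' @inheritParams univariate_scan
#' @return a \code{"family_logit"} fit.
#' @export
multivariate_model <- function(rows,
                               covariate_policy = c("when_significant",
                                                    "always", "never")) {
  covariate_policy <- match.arg(covariate_policy)
  if (nrow(rows) < 10) stop("too few complete families (", nrow(rows), ")")
  rows <- prep_family_rows(rows)
  covs <- covariate_terms(rows, covariate_policy)
  terms <- c("cotwin_status", "sibling_status", "mother_status",
             "father_status", covs)
  fit_logistic(stats::reformulate(terms, response = "twin_status"), rows)
}

#' MZ-vs-DZ prevalence odds ratio with family clustering
#'
#' Regresses individual twin status on an MZ indicator (DZ reference) with
#' a family-level random intercept, since both twins of each pair enter,
#' and age/sex adjustment per policy.
#'
#' @param records cohort data.frame.
#' @param condition condition column name.
#' @param covariate_policy as in [univariate_scan()].
#' @param random_intercept set \code{FALSE} to drop the family random
#'   intercept (useful only for degenerate-clustering checks).
#' @param nodes Gauss-Hermite nodes.
#' @return a \code{"family_logit"} fit; the MZ term is \code{zygMZ}.
#' @export
zygosity_prevalence_or <- function(records, condition,
                                   covariate_policy = c("when_significant",
                                                        "always", "never"),
                                   random_intercept = TRUE, nodes = 21) {
  covariate_policy <- match.arg(covariate_policy)
  stopifnot(condition %in% cohort_conditions(records))
  tw <- records[records$role %in% c("twin1", "twin2"), ]
  d <- data.frame(family_id = tw$family_id,
                  status = tw[[condition]],
                  zygMZ = as.integer(tw$zygosity == "MZ"),
                  twin_age = tw$age,
                  sexf = as.integer(tw$sex == "female"))
  d <- d[!is.na(d$status), ]
  covs <- character(0)
  if (covariate_policy == "always") covs <- c("twin_age", "sexf")
  if (covariate_policy == "when_significant") {
    f0 <- tryCatch(fit_logistic(status ~ twin_age + sexf, d),
                   error = function(e) NULL)
    if (!is.null(f0)) covs <- names(f0$p_value)[-1][f0$p_value[-1] < 0.05]
  }
  fml <- stats::reformulate(c("zygMZ", covs), response = "status")
  fit_logistic(fml, d,
               random_intercept = if (random_intercept) "family_id" else NULL,
               nodes = nodes)
}
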