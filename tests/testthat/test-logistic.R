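# IRLS logistic fitter, Gauss-Hermite random intercept, and the
# family-association scans.

test_that("gauss_hermite integrates polynomials against exp(-x^2)", {
  gh <- gauss_hermite(21)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-10)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4,
               tolerance = 1e-9)
})

test_that("IRLS matches closed forms and satisfies the score equations", {
  # intercept-only: logit of the affected fraction
  d <- data.frame(y = rep(c(1, 0), c(7, 13)))
  fit <- fit_logistic(y ~ 1, d)
  expect_equal(unname(coef(fit)), qlogis(7 / 20), tolerance = 1e-10)

  # single binary predictor with 2x2 counts (10, 20, 20, 10) -> OR 0.25
  d2 <- data.frame(y = rep(c(1, 0, 1, 0), c(10, 20, 20, 10)),
                   x = rep(c(1, 1, 0, 0), c(10, 20, 20, 10)))
  fit2 <- fit_logistic(y ~ x, d2)
  expect_equal(unname(fit2$odds_ratio["x"]), 0.25, tolerance = 1e-8)
  expect_lt(max(abs(fit2$gradient)), 1e-8)

  # agrees with the independent glm fit on a richer design
  set.seed(14)
  n <- 400
  d3 <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.3))
  d3$y <- rbinom(n, 1, plogis(-0.5 + 0.8 * d3$x1 - 0.6 * d3$x2))
  mine <- fit_logistic(y ~ x1 + x2, d3)
  ref <- glm(y ~ x1 + x2, binomial, d3)
  expect_equal(coef(mine), coef(ref), tolerance = 1e-7)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-4)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  d <- data.frame(y = c(1, 1, 0, 0), x = c(1, 1, 0, 0))
  expect_error(fit_logistic(y ~ x, d), "separation")
  d2 <- data.frame(y = rbinom(50, 1, 0.5), x = rnorm(50))
  d2$z <- 2 * d2$x
  expect_error(fit_logistic(y ~ x + z, d2), "collinear.*z")
  expect_error(fit_logistic(y ~ x, transform(d2, y = 1)), "no variation")
})

test_that("random-intercept fit matches glmer and degenerates to glm", {
  skip_if_not_installed("lme4")
  set.seed(3)
  nf <- 300
  fid <- rep(seq_len(nf), each = 2)
  b <- rnorm(nf, 0, 1)[fid]
  x <- rbinom(2 * nf, 1, 0.5)
  d <- data.frame(y = rbinom(2 * nf, 1, plogis(-1 + 0.8 * x + b)),
                  x = x, fid = fid)
  mine <- fit_logistic(y ~ x, d, random_intercept = "fid")
  ref <- lme4::glmer(y ~ x + (1 | fid), d, binomial, nAGQ = 21)
  expect_equal(unname(coef(mine)), unname(lme4::fixef(ref)),
               tolerance = 1e-4)
  expect_equal(mine$sigma_u, sqrt(unname(unlist(lme4::VarCorr(ref)))),
               tolerance = 1e-3)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)

  # sigma -> 0 degeneracy of the quadrature marginal likelihood
  set.seed(4)
  d2 <- data.frame(y = rbinom(500, 1, plogis(-0.5 + x[1:500])),
                   x = x[1:500], fid = rep(1:250, each = 2))
  g1 <- glm(y ~ x, binomial, d2)
  X <- model.matrix(~x, d2)
  for (sig in c(1e-6, 1e-8))
    expect_equal(twinfam:::glmm_loglik(coef(g1), log(sig), X, d2$y, d2$fid,
                                       gauss_hermite(21)),
                 as.numeric(logLik(g1)), tolerance = 1e-6)
})

test_that("univariate scan isolates a strong co-twin association", {
  # co-twin association only: strong A, no C, family members unrelated to
  # twins' unique environment beyond kinship
  co <- simulate_cohort(ace_params(0.8, 0, 0.25), sim_config(1200, seed = 17))
  rows <- select_index_twins(co, "condition", seed = 1)
  scan <- univariate_scan(rows, covariate_policy = "never")
  expect_equal(scan$member, c("cotwin", "sibling", "mother", "father"))
  expect_lt(scan$p[scan$member == "cotwin"], 0.001)
  expect_gt(scan$or[scan$member == "cotwin"], 2)
  expect_error(univariate_scan(rows[1:5, ]), "too few")
  scan2 <- univariate_scan(rows, covariate_policy = "never")
  expect_identical(scan[, 1:5], scan2[, 1:5])
})

test_that("multivariate model: orthogonal predictors match univariate fits", {
  set.seed(23)
  n <- 512
  # balanced orthogonal binary design for mother and father statuses
  g <- expand.grid(m = 0:1, f = 0:1)[rep(1:4, each = n / 4), ]
  rows <- data.frame(family_id = as.character(1:n),
                     cotwin_status = 0L, sibling_status = 0L,
                     mother_status = g$m, father_status = g$f,
                     twin_sex = "female", twin_age = 10)
  rows$twin_status <- rbinom(n, 1, plogis(-1 + 0.9 * g$m + 0.6 * g$f))
  mu_m <- fit_logistic(twin_status ~ mother_status, rows)
  mu_f <- fit_logistic(twin_status ~ father_status, rows)
  mult <- fit_logistic(twin_status ~ mother_status + father_status, rows)
  # orthogonality makes log-ORs agree closely (exactly only in the linear
  # model; logistic collapsibility holds here to first order)
  expect_equal(coef(mult)[["mother_status"]], coef(mu_m)[["mother_status"]],
               tolerance = 0.08)
  expect_equal(coef(mult)[["father_status"]], coef(mu_f)[["father_status"]],
               tolerance = 0.12)

  # positively correlated predictors attenuate multivariate ORs
  co <- simulate_cohort(ace_params(0.5, 0.3, 0.15), sim_config(1500, seed = 19))
  fr <- select_index_twins(co, "condition", seed = 2)
  uni <- univariate_scan(fr, covariate_policy = "never")
  mv <- multivariate_model(fr, covariate_policy = "never")
  expect_lt(mv$odds_ratio[["cotwin_status"]],
            uni$or[uni$member == "cotwin"])
})

test_that("member-effect recovery on a structured synthetic cohort", {
  # outcome built directly from known member ORs: co-twin 8, mother 2
  set.seed(29)
  n <- 1000
  rows <- data.frame(family_id = as.character(1:n),
                     cotwin_status = rbinom(n, 1, 0.2),
                     sibling_status = rbinom(n, 1, 0.15),
                     mother_status = rbinom(n, 1, 0.25),
                     father_status = rbinom(n, 1, 0.15),
                     twin_sex = "female", twin_age = 10)
  eta <- -2 + log(8) * rows$cotwin_status + log(2) * rows$mother_status
  rows$twin_status <- rbinom(n, 1, plogis(eta))
  fit <- multivariate_model(rows, covariate_policy = "never")
  for (term in c("cotwin_status", "mother_status")) {
    truth <- c(cotwin_status = log(8), mother_status = log(2))[[term]]
    expect_lt(abs(coef(fit)[[term]] - truth) / fit$se[[term]], 3)
  }
  expect_gt(fit$p_value[["sibling_status"]], 0.01)
})

test_that("zygosity prevalence OR is null-calibrated and clustering-robust", {
  # equal MZ/DZ prevalence: OR within 3 SE of 1
  co <- simulate_cohort(ace_params(0.5, 0.2, 0.15), sim_config(800, seed = 31))
  fit <- zygosity_prevalence_or(co, "condition", covariate_policy = "never",
                                nodes = 15)
  expect_lt(abs(coef(fit)[["zygMZ"]]) / fit$se[["zygMZ"]], 3)

  # independent-pair data: dropping the random intercept leaves the point
  # estimate essentially unchanged
  set.seed(33)
  tw <- co[co$role %in% c("twin1", "twin2"), ]
  tw$condition <- rbinom(nrow(tw), 1, 0.15)  # break within-pair dependence
  co2 <- co; co2[co2$role %in% c("twin1", "twin2"), "condition"] <- tw$condition
  f_ri <- zygosity_prevalence_or(co2, "condition", covariate_policy = "never",
                                 nodes = 15)
  f_pl <- zygosity_prevalence_or(co2, "condition", covariate_policy = "never",
                                 random_intercept = FALSE)
  expect_lt(abs(coef(f_ri)[["zygMZ"]] - coef(f_pl)[["zygMZ"]]), 1e-3)
})

test_that("Wald p-values are approximately uniform under the null", {
  set.seed(37)
  reps <- 400
  n <- 150
  pvals <- vapply(seq_len(reps), function(i) {
    d <- data.frame(y = rbinom(n, 1, 0.3), x = rnorm(n))
    fit_logistic(y ~ x, d)$p_value[["x"]]
  }, 0)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})
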