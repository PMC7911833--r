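# Closed-form estimators, the Plackett cell solver, the general pair
# likelihood, and the zygosity LR test.

test_that("casewise concordance reproduces reference values and boundaries", {
  pcs <- pain_pair_counts()
  gp <- casewise_concordance(pcs$gp_MZ)
  expect_equal(round(gp$estimate, 2), 0.62)
  expect_equal(round(gp$ci95, 2), c(0.54, 0.70))
  mig <- casewise_concordance(pcs$migraine_MZ)
  expect_equal(round(mig$estimate, 2), 0.46)
  expect_equal(round(mig$ci95, 2), c(0.31, 0.60))

  expect_equal(casewise_concordance(new_pair_counts(5, 0, 10))$estimate, 1)
  expect_equal(casewise_concordance(new_pair_counts(0, 7, 10))$estimate, 0)
  expect_error(casewise_concordance(new_pair_counts(0, 0, 10)), "undefined")

  # exact MLE identity, and CI ordering, over random tables
  set.seed(41)
  for (i in 1:25) {
    pc <- new_pair_counts(sample(1:50, 1), sample(1:80, 1), sample(10:400, 1))
    est <- casewise_concordance(pc)
    expect_equal(est$estimate,
                 2 * pc$n_concordant / (2 * pc$n_concordant + pc$n_discordant))
    expect_true(est$ci95[1] <= est$estimate && est$estimate <= est$ci95[2])
  }
})

test_that("pair correlation equals phi of the double-entered table", {
  pcs <- pain_pair_counts()
  expect_equal(round(pair_correlation(pcs$gp_MZ)$estimate, 2), 0.53)
  expect_equal(round(pair_correlation(pcs$headache_MZ)$estimate, 2), 0.38)

  # independence table: p11 = q^2 exactly -> rho = 0
  expect_equal(pair_correlation(new_pair_counts(1, 18, 81))$estimate, 0)
  expect_error(pair_correlation(new_pair_counts(5, 0, 0)), "degenerate")

  set.seed(7)
  for (i in 1:40) {
    pc <- new_pair_counts(sample(0:40, 1), sample(1:90, 1), sample(5:300, 1))
    expect_equal(pair_correlation(pc)$estimate,
                 phi_coefficient(double_enter(pc)), tolerance = 1e-12)
  }
})

test_that("pair odds ratio follows the saturated closed form", {
  pcs <- pain_pair_counts()
  expect_equal(pair_odds_ratio(pcs$gp_MZ)$estimate, 61 * 368 / 37^2)
  expect_equal(round(pair_odds_ratio(pcs$gp_MZ)$estimate, 1), 16.4)
  expect_equal(pair_odds_ratio(new_pair_counts(1, 2, 1))$estimate, 1)
  expect_equal(pair_odds_ratio(new_pair_counts(1, 18, 81))$estimate, 1)
  inf <- pair_odds_ratio(new_pair_counts(5, 0, 10))
  expect_equal(inf$estimate, Inf)
  expect_true(inf$boundary)
  expect_true(all(is.na(inf$ci95)))
})

test_that("estimators are strictly increasing in concordant pairs", {
  # move pairs from discordant to concordant cells with N and margins in
  # the appropriate sense held fixed
  C <- vapply(1:10, function(k)
    casewise_concordance(new_pair_counts(k, 40 - 2 * k, 60 + k))$estimate, 0)
  expect_true(all(diff(C) > 0))
  # fixed q: moving 2 discordant pairs to 1 concordant + 1 neither
  r <- vapply(1:10, function(k)
    pair_correlation(new_pair_counts(k, 42 - 2 * k, 60 + k))$estimate, 0)
  o <- vapply(1:10, function(k)
    pair_odds_ratio(new_pair_counts(k, 42 - 2 * k, 60 + k))$estimate, 0)
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(o) > 0))
})

test_that("plackett_cell solves and inverts the odds-ratio quadratic", {
  expect_equal(plackett_cell(0.5, 0.5, 1), 0.25)
  expect_gt(plackett_cell(0.5, 0.5, 1e8), 0.499)
  expect_error(plackett_cell(0, 0.5, 2), "strictly in")
  expect_error(plackett_cell(0.4, 0.5, -1), "positive")

  p11 <- plackett_cell(0.3, 0.2, 4)
  psi_back <- p11 * (1 - 0.3 - 0.2 + p11) / ((0.3 - p11) * (0.2 - p11))
  expect_equal(psi_back, 4, tolerance = 1e-10)

  grid <- expand.grid(p1 = seq(0.05, 0.95, by = 0.15),
                      p2 = seq(0.05, 0.95, by = 0.15),
                      psi = c(0.1, 0.5, 2, 10, 100))
  p11 <- plackett_cell(grid$p1, grid$p2, grid$psi)
  recovered <- p11 * (1 - grid$p1 - grid$p2 + p11) /
    ((grid$p1 - p11) * (grid$p2 - p11))
  expect_lt(max(abs(recovered / grid$psi - 1)), 1e-10)
  expect_true(all(p11 >= pmax(0, grid$p1 + grid$p2 - 1) - 1e-12))
  expect_true(all(p11 <= pmin(grid$p1, grid$p2) + 1e-12))
})

test_that("fit_pair_model maximum agrees with closed-form estimators", {
  pcs <- pain_pair_counts()
  for (meth in c("casewise", "correlation", "odds_ratio")) {
    closed <- switch(meth,
      casewise = casewise_concordance(pcs$gp_MZ)$estimate,
      correlation = pair_correlation(pcs$gp_MZ)$estimate,
      odds_ratio = pair_odds_ratio(pcs$gp_MZ)$estimate)
    fit <- fit_pair_model(pcs$gp_MZ, meth)
    expect_equal(unname(coef(fit)[1]), closed, tolerance = 1e-5)
    expect_equal(unname(coef(fit)["q"]), (2 * 61 + 74) / (2 * 503),
                 tolerance = 1e-6)
  }
  # loglik at the casewise MLE equals the closed-form trinomial loglik
  q <- (2 * 61 + 74) / (2 * 503); C <- 122 / 196
  ll <- 61 * log(q * C) + 74 * log(q * (1 - C)) + 368 * log(1 - q * (2 - C))
  expect_equal(fit_pair_model(pcs$gp_MZ, "casewise")$loglik, ll,
               tolerance = 1e-8)
})

test_that("adjusted fit with null covariates recovers the unadjusted fit", {
  pcs <- pain_pair_counts()
  d <- twinfam:::pair_counts_to_data(pcs$headache_MZ)
  d$age1 <- d$age2 <- 0
  d$sex1 <- d$sex2 <- 0
  for (meth in c("casewise", "correlation", "odds_ratio")) {
    un <- fit_pair_model(pcs$headache_MZ, meth)
    ad <- fit_pair_model(d, meth, adjusted = TRUE)
    expect_equal(unname(coef(ad)[1]), unname(coef(un)[1]), tolerance = 1e-4)
    expect_equal(plogis(unname(coef(ad)["beta0"])), unname(coef(un)["q"]),
                 tolerance = 1e-4)
  }
})

test_that("adjusted fit recovers a real marginal covariate effect", {
  set.seed(21)
  n <- 1500
  age <- runif(n, -4, 4)          # centred ages, shared within pair
  sexf <- rbinom(n, 1, 0.5)
  b0 <- -1.6; b_age <- 0.25; b_sex <- 0.5
  p <- plogis(b0 + b_age * age + b_sex * sexf)
  psi_true <- 6
  p11 <- plackett_cell(p, p, psi_true)
  cell <- vapply(seq_len(n), function(i)
    sample.int(4, 1, prob = c(p11[i], p[i] - p11[i], p[i] - p11[i],
                              1 - 2 * p[i] + p11[i])), 0L)
  d <- data.frame(y1 = as.integer(cell %in% c(1, 2)),
                  y2 = as.integer(cell %in% c(1, 3)),
                  age1 = age, age2 = age, sex1 = sexf, sex2 = sexf)
  fit <- fit_pair_model(d, "odds_ratio", adjusted = TRUE)
  est <- coef(fit); se <- fit$se
  expect_lt(abs(log(est[["psi"]]) - log(psi_true)) / (se[["psi"]] / est[["psi"]]), 3.5)
  expect_lt(abs(est[["beta_age"]] - b_age) / se[["beta_age"]], 3.5)
  expect_lt(abs(est[["beta_sex"]] - b_sex) / se[["beta_sex"]], 3.5)
})

test_that("null correlation data yield estimates within 3 SE of zero", {
  set.seed(31)
  q <- 0.2
  for (i in 1:5) {
    cell <- sample.int(4, 800, replace = TRUE,
                       prob = c(q^2, q * (1 - q), q * (1 - q), (1 - q)^2))
    d <- data.frame(y1 = as.integer(cell %in% c(1, 2)),
                    y2 = as.integer(cell %in% c(1, 3)))
    fit <- fit_pair_model(d, "correlation")
    expect_lt(abs(coef(fit)[["rho"]]), 3 * fit$se[["rho"]] + 1e-8)
  }
})

test_that("zygosity LR test matches a grid-search oracle and is calibrated", {
  pcs <- pain_pair_counts()
  lr <- lr_test_zygosity(pcs$gp_MZ, pcs$gp_DZ, "casewise")

  # independent oracle: profile the constrained likelihood on a fine grid
  # of the shared concordance, with the group marginal solved in closed form
  ll_grp <- function(pc, C) {
    N <- pc$n_pairs
    q <- (pc$n_concordant + pc$n_discordant) / (N * (2 - C))
    pc$n_concordant * log(q * C) + pc$n_discordant * log(q * (1 - C)) +
      pc$n_neither * log(1 - q * (2 - C))
  }
  grid <- seq(0.30, 0.70, by = 1e-5)
  ll_c_oracle <- max(vapply(grid, function(C)
    ll_grp(pcs$gp_MZ, C) + ll_grp(pcs$gp_DZ, C), 0))
  expect_equal(lr$loglik_constrained, ll_c_oracle, tolerance = 1e-6)
  expect_equal(lr$statistic,
               2 * (lr$loglik_unconstrained - lr$loglik_constrained))
  expect_equal(round(lr$p_value, 3), 0.009, tolerance = 0.001)

  # identical groups: statistic ~ 0, p ~ 1
  same <- lr_test_zygosity(pcs$gp_MZ, pcs$gp_MZ, "correlation")
  expect_lt(same$statistic, 1e-4)
  expect_gt(same$p_value, 0.99)

  # constrained loglik never exceeds unconstrained
  for (cc in c("migraine", "lbp")) {
    for (meth in c("casewise", "correlation", "odds_ratio")) {
      t <- lr_test_zygosity(pcs[[paste0(cc, "_MZ")]],
                            pcs[[paste0(cc, "_DZ")]], meth)
      expect_gte(t$statistic, 0)
      expect_lte(t$loglik_constrained, t$loglik_unconstrained + 1e-6)
    }
  }
})

test_that("simulate.pair_model reproduces the fitted cell distribution", {
  pcs <- pain_pair_counts()
  fit <- fit_pair_model(pcs$gp_MZ, "casewise")
  sims <- simulate(fit, nsim = 3, seed = 5, n_pairs = 4000)
  expect_length(sims, 3)
  cbar <- mean(vapply(sims, function(d) {
    Nc <- sum(d$y1 & d$y2); Nd <- sum(d$y1 != d$y2)
    2 * Nc / (2 * Nc + Nd)
  }, 0))
  expect_equal(cbar, coef(fit)[["C"]], tolerance = 0.03)
})
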