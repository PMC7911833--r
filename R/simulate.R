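# Liability-threshold ACE simulator for twin-family cohorts of five
# members (twin1, twin2, oldest sibling, mother, father), with closed-form
# expectation oracles (bivariate-normal orthant probabilities).

#' ACE liability parameters for one condition
#'
#' Standard-normal liability decomposed into additive-genetic (a2),
#' shared-environment (c2) and unique-environment (e2 = 1 - a2 - c2)
#' variance fractions, a lifetime prevalence \code{K} fixing the affection
#' threshold, and optional probit-style covariate shifts of the liability
#' (applied to age centred at 10.5 years and sex coded female = 1; defaults
#' zero, i.e. no covariate effect).
#'
#' @param a2,c2 additive-genetic and shared-environment fractions.
#' @param prevalence lifetime prevalence K in (0, 1).
#' @param beta_age,beta_sex liability shifts per centred year of age / for
#'   female sex.
#' @return an \code{"ace_params"} list.
#' @export
ace_params <- function(a2, c2, prevalence, beta_age = 0, beta_sex = 0) {
  e2 <- 1 - a2 - c2
  if (a2 < 0 || c2 < 0 || e2 < -1e-12)
    stop("variance fractions must be non-negative and a2 + c2 <= 1")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  structure(list(a2 = a2, c2 = c2, e2 = max(e2, 0), prevalence = prevalence,
                 beta_age = beta_age, beta_sex = beta_sex),
            class = "ace_params")
}

#' Simulation configuration for a twin-family cohort
#'
#' @param n_families number of five-member families.
#' @param prop_mz probability a pair is monozygotic.
#' @param seed integer seed (mandatory).
#' @param age_range twin age range in years (uniform integer draws; both
#'   twins share one age).
#' @param p_female probability an individual is female (MZ co-twins share
#'   sex; DZ co-twins are drawn independently).
#' @param missing_rate per-member, per-condition probability a status is
#'   missing.
#' @param parent_child_c shared-environment correlation between parent and
#'   child liabilities (children among themselves always share it fully).
#' @return a \code{"sim_config"} list.
#' @export
sim_config <- function(n_families, seed, prop_mz = 0.5,
                       age_range = c(3, 18), p_female = 0.512,
                       missing_rate = 0, parent_child_c = 0) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_families >= 1, prop_mz >= 0, prop_mz <= 1,
            p_female >= 0, p_female <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_families = as.integer(n_families), seed = as.integer(seed),
                 prop_mz = prop_mz, age_range = age_range,
                 p_female = p_female, missing_rate = missing_rate,
                 parent_child_c = parent_child_c),
            class = "sim_config")
}

#' Kinship-structured liability covariance of one family
#'
#' Unit-variance liabilities for (twin1, twin2, oldest sibling, mother,
#' father). The additive-genetic correlation is 1 between MZ co-twins, 0.5
#' between DZ co-twins, twin-sibling and parent-offspring, 0 between
#' spouses; the shared-environment correlation is 1 among the co-resident
#' children, \code{parent_child_c} between parent and child, 0 between
#' spouses.
#'
#' @param params an [ace_params] object.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @param parent_child_c parent-child shared-environment correlation.
#' @return a positive-semidefinite 5x5 correlation matrix.
#' @export
kinship_liability_cov <- function(params, zygosity = c("MZ", "DZ"),
                                  parent_child_c = 0) {
  zygosity <- match.arg(zygosity)
  roles <- c("twin1", "twin2", "oldest_sibling", "mother", "father")
  A <- matrix(0.5, 5, 5, dimnames = list(roles, roles))
  diag(A) <- 1
  A["twin1", "twin2"] <- A["twin2", "twin1"] <-
    if (zygosity == "MZ") 1 else 0.5
  A["mother", "father"] <- A["father", "mother"] <- 0
  Cm <- matrix(0, 5, 5, dimnames = list(roles, roles))
  Cm[1:3, 1:3] <- 1
  Cm[1:3, 4:5] <- Cm[4:5, 1:3] <- parent_child_c
  diag(Cm) <- 1
  R <- params$a2 * A + params$c2 * Cm + params$e2 * diag(5)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("configuration yields a non-positive-semidefinite liability covariance")
  R
}

#' Liability threshold from prevalence
#'
#' The affection threshold is the upper-K quantile of the standard normal:
#' an individual is affected iff liability exceeds it.
#'
#' @param K prevalence in (0, 1).
#' @return the threshold \eqn{\tau}.
#' @export
threshold_from_prevalence <- function(K) {
  if (any(K <= 0 | K >= 1)) stop("prevalence must lie in (0, 1)")
  stats::qnorm(K, lower.tail = FALSE)
}

#' Bivariate-normal upper-orthant probability
#'
#' \eqn{P(X > h, Y > k)} for standard bivariate normal with correlation
#' \eqn{r}, by adaptive 1-D quadrature over
#' \eqn{\int_h^\infty \phi(x)\,\Phi\!\big((rx - k)/\sqrt{1-r^2}\big)\,dx}.
#'
#' @param h,k thresholds.
#' @param r correlation in [-1, 1].
#' @return the orthant probability.
#' @export
bvn_upper <- function(h, k, r) {
  stopifnot(abs(r) <= 1)
  if (r == 0) return(stats::pnorm(h, lower.tail = FALSE) *
                     stats::pnorm(k, lower.tail = FALSE))
  if (r == 1) return(stats::pnorm(max(h, k), lower.tail = FALSE))
  if (r == -1) {
    # X > h and -X > k  <=>  h < X < -k
    return(max(0, stats::pnorm(-k) - stats::pnorm(h)))
  }
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((r * x - k) / sqrt(1 - r^2))
  stats::integrate(f, h, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Liability correlation implied by ACE parameters for a twin pair
#' @param params an [ace_params] object.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return \eqn{r = a^2 \cdot k + c^2} with kinship k = 1 (MZ) or 0.5 (DZ).
#' @export
twin_liability_correlation <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  params$a2 * (if (zygosity == "MZ") 1 else 0.5) + params$c2
}

#' Expected casewise concordance under the liability-threshold model
#'
#' \eqn{C = P(L_1 > \tau, L_2 > \tau) / K} with the orthant probability at
#' the zygosity's liability correlation; the closed-form oracle the
#' simulator is validated against. Covariate shifts are not included.
#'
#' @param params an [ace_params] object.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return expected casewise concordance.
#' @export
expected_casewise <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  K <- params$prevalence
  tau <- threshold_from_prevalence(K)
  r <- twin_liability_correlation(params, zygosity)
  bvn_upper(tau, tau, r) / K
}

#' Tetrachoric-style liability correlation from pair counts
#'
#' Inverts the orthant-probability oracle: finds the liability correlation
#' whose implied \eqn{P(\mathrm{both\ affected})} matches the observed
#' \eqn{N_c/N}, using the observed prevalence for the threshold.
#'
#' @param pc a [pair_counts] object.
#' @return estimated liability correlation.
#' @export
liability_correlation <- function(pc) {
  N <- pc$n_pairs
  q <- (2 * pc$n_concordant + pc$n_discordant) / (2 * N)
  if (q <= 0 || q >= 1) stop("degenerate prevalence")
  tau <- threshold_from_prevalence(q)
  p11 <- pc$n_concordant / N
  f <- function(r) bvn_upper(tau, tau, r) - p11
  if (f(-0.999) > 0) return(-1)
  if (f(0.999) < 0) return(1)
  stats::uniroot(f, c(-0.999, 0.999), tol = 1e-10)$root
}

#' Simulate a twin-family cohort under the liability-threshold ACE model
#'
#' Families of five (twins, oldest sibling, mother, father) receive
#' multivariate-normal liabilities with the [kinship_liability_cov]
#' structure per condition; optional cross-condition genetic correlations
#' couple the additive-genetic components. Statuses are thresholded at the
#' prevalence quantile after probit-style covariate shifts, then missing
#' statuses are introduced at the configured rate. Twin ages are uniform
#' integers over the configured range (shared within a pair), the sibling
#' is drawn 2-8 years older, and parent ages are normal (mothers 42.6, SD
#' 6.3; fathers 44.8, SD 6.5 years). Deterministic given the seed.
#'
#' @param params an [ace_params] object, or a named list of them (one per
#'   condition).
#' @param config a [sim_config] object.
#' @param genetic_corr optional cross-condition genetic correlation matrix
#'   (unit diagonal, symmetric PSD); default identity.
#' @return a validated cohort data.frame (see [read_cohort()]).
#' @export
simulate_cohort <- function(params, config, genetic_corr = NULL) {
  if (inherits(params, "ace_params")) params <- list(condition = params)
  stopifnot(inherits(config, "sim_config"))
  m <- length(params)
  conds <- names(params)
  if (is.null(conds) || any(conds == ""))
    stop("params must be a named list, one element per condition")
  if (is.null(genetic_corr)) genetic_corr <- diag(m)
  genetic_corr <- as.matrix(genetic_corr)
  if (!isTRUE(all.equal(genetic_corr, t(genetic_corr))) ||
      any(abs(diag(genetic_corr) - 1) > 1e-12))
    stop("genetic_corr must be symmetric with unit diagonal")

  set.seed(config$seed)
  n <- config$n_families
  zyg <- ifelse(stats::runif(n) < config$prop_mz, "MZ", "DZ")

  ages_tw <- sample(seq(config$age_range[1], config$age_range[2]), n,
                    replace = TRUE)
  ages_sib <- ages_tw + sample(2:8, n, replace = TRUE)
  ages_mo <- round(stats::rnorm(n, 42.6, 6.3), 1)
  ages_fa <- round(stats::rnorm(n, 44.8, 6.5), 1)

  sex_t1 <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  sex_t2 <- ifelse(zyg == "MZ", sex_t1,
                   ifelse(stats::runif(n) < config$p_female, "female", "male"))
  sex_sib <- ifelse(stats::runif(n) < config$p_female, "female", "male")

  a2 <- vapply(params, `[[`, 0, "a2")
  c2 <- vapply(params, `[[`, 0, "c2")
  e2 <- vapply(params, `[[`, 0, "e2")
  # condition-major covariance over the 5m member-by-condition liabilities:
  # genetic block sqrt(a2_k a2_l) G_kl x kinship; C and E within-condition
  big_sigma <- function(zygosity) {
    A1 <- kinship_liability_cov(ace_params(1, 0, 0.5), zygosity,
                                config$parent_child_c)  # pure-A kinship
    Cm <- (kinship_liability_cov(ace_params(0, 1, 0.5), zygosity,
                                 config$parent_child_c) - diag(0, 5))
    # reconstruct the C-structure matrix (c2 = 1 case gives it directly)
    Gamma <- outer(sqrt(a2), sqrt(a2)) * genetic_corr
    kronecker(Gamma, A1) + kronecker(diag(c2, m), Cm) +
      kronecker(diag(e2, m), diag(5))
  }
  draw_liab <- function(zygosity, nfam) {
    S <- big_sigma(zygosity)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("non-PSD joint liability covariance")
    L <- chol(S + diag(1e-10, nrow(S)))
    matrix(stats::rnorm(nfam * nrow(S)), nfam) %*% L
  }

  liab <- matrix(NA_real_, n, 5 * m)
  for (z in c("MZ", "DZ")) {
    i <- which(zyg == z)
    if (length(i)) liab[i, ] <- draw_liab(z, length(i))
  }

  fam_id <- sprintf("F%05d", seq_len(n))
  roles <- FAMILY_ROLES
  out <- data.frame(
    family_id = rep(fam_id, each = 5),
    role = rep(roles, n),
    zygosity = ifelse(rep(roles, n) %in% c("twin1", "twin2"),
                      rep(zyg, each = 5), NA),
    sex = as.vector(rbind(sex_t1, sex_t2, sex_sib, "female", "male")),
    age = as.vector(rbind(ages_tw, ages_tw, ages_sib, ages_mo, ages_fa)),
    stringsAsFactors = FALSE)

  age_all <- out$age
  sexf_all <- as.integer(out$sex == "female")
  for (k in seq_len(m)) {
    p <- params[[k]]
    tau <- threshold_from_prevalence(p$prevalence)
    lk <- as.vector(t(liab[, (k - 1) * 5 + (1:5)]))  # member-major like out
    shift <- p$beta_age * (age_all - 10.5) + p$beta_sex * (sexf_all - 0.5)
    status <- as.integer(lk + shift > tau)
    if (config$missing_rate > 0) {
      status[stats::runif(length(status)) < config$missing_rate] <- NA_integer_
    }
    out[[conds[k]]] <- status
  }
  validate_cohort(out, conds)
}
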