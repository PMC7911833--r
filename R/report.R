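# Report rendering in the conventional twin-study table layouts, plus an
# end-to-end pipeline with a reproducibility manifest.

#' Round half away from zero
#' @param x numeric. @param digits decimal places.
#' @return rounded value (0.5 always rounds away from zero).
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Format a p-value for tabulation
#'
#' Three decimals, with values below 0.001 printed as \code{"<0.001"}.
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<0.001",
                sprintf("%.3f", round_half_away(p, 3))))
}

fmt_est <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"),
                                 round_half_away(x, digits)))
}

fmt_or <- function(x) {
  ifelse(is.na(x) | !is.finite(x), ifelse(is.infinite(x), "Inf", "NA"),
         formatC(signif(x, 3), format = "fg", flag = "#", digits = 3))
}

fmt_pct <- function(x) formatC(signif(x, 3), format = "fg", digits = 3)

#' Render an analysis-results table as CSV text
#'
#' Fixed column order and rounding conventions: prevalence percentages to 3
#' significant figures, concordance/correlation estimates to 2 decimals,
#' odds ratios to 3 significant figures, p-values to 3 decimals with
#' \code{"<0.001"} below that. Rounding is half-away-from-zero.
#'
#' @param results a data.frame produced by [run_pipeline()]'s analysis
#'   stages (see the layout-specific column requirements below).
#' @param layout \code{"t1"} prevalence + zygosity OR; \code{"t3"} pair
#'   counts + casewise concordance + CI + LR p; \code{"t4"} correlation and
#'   odds-ratio estimates; \code{"t5"} univariate/multivariate family
#'   associations.
#' @return a character scalar of CSV text (header + rows).
#' @export
render_table <- function(results, layout = c("t1", "t3", "t4", "t5")) {
  layout <- match.arg(layout)
  req <- switch(layout,
    t1 = c("condition", "mz_affected", "mz_unaffected", "mz_percent",
           "dz_affected", "dz_unaffected", "dz_percent", "or", "ci_lo",
           "ci_hi", "p"),
    t3 = c("condition", "mz_nc", "mz_nd", "mz_n00", "mz_c", "mz_lo",
           "mz_hi", "dz_nc", "dz_nd", "dz_n00", "dz_c", "dz_lo", "dz_hi",
           "p"),
    t4 = c("condition", "mz_corr", "mz_corr_lo", "mz_corr_hi", "dz_corr",
           "dz_corr_lo", "dz_corr_hi", "p_corr", "p_corr_adj", "mz_or",
           "mz_or_lo", "mz_or_hi", "dz_or", "dz_or_lo", "dz_or_hi", "p_or",
           "p_or_adj"),
    t5 = c("condition", "analysis", "n", "cotwin_or", "cotwin_p",
           "sibling_or", "sibling_p", "mother_or", "mother_p", "father_or",
           "father_p"))
  if (nrow(results) == 0) return(paste0(paste(req, collapse = ","), "\n"))
  miss <- setdiff(req, names(results))
  if (length(miss))
    stop("results do not match layout '", layout, "': missing ",
         paste(miss, collapse = ", "))
  df <- results[, req]
  pct <- grep("percent$", req, value = TRUE)
  ors <- grep("(^|_)or(_lo|_hi)?$|^or$|ci_lo|ci_hi", req, value = TRUE)
  ests <- grep("_(c|lo|hi|corr|corr_lo|corr_hi)$", req, value = TRUE)
  ests <- setdiff(ests, c(ors, "ci_lo", "ci_hi"))
  ps <- grep("^p$|^p_|_p$", req, value = TRUE)
  for (v in pct) df[[v]] <- fmt_pct(results[[v]])
  for (v in ests) df[[v]] <- fmt_est(results[[v]])
  for (v in ors) df[[v]] <- fmt_or(results[[v]])
  for (v in ps) df[[v]] <- format_p(results[[v]])
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Run the full twin-family analysis pipeline
#'
#' Orchestrates prevalence + zygosity-OR, twin-similarity (casewise /
#' correlation / odds ratio with MZ-vs-DZ LR tests), and family-association
#' analyses over a cohort, writing one CSV per table layout plus a
#' reproducibility manifest (seed, package version, input hash, exclusion
#' counts). Any stage failure aborts the run, removes partial outputs, and
#' names the stage.
#'
#' @param input path to a cohort CSV or a cohort data.frame.
#' @param out_dir output directory (created if needed).
#' @param conditions condition columns to analyse (default: all in input).
#' @param analyses subset of \code{c("prevalence", "similarity",
#'   "famassoc")}.
#' @param seed integer seed; mandatory (index-twin selection is random).
#' @param covariate_policy age/sex adjustment policy, see
#'   [univariate_scan()].
#' @param adjusted_similarity also fit age/sex-adjusted similarity models
#'   for the Table-4-style adjusted p-values (slower).
#' @return invisibly, a list of the result data.frames, file paths and the
#'   manifest.
#' @export
run_pipeline <- function(input, out_dir, conditions = NULL,
                         analyses = c("prevalence", "similarity", "famassoc"),
                         seed,
                         covariate_policy = "when_significant",
                         adjusted_similarity = FALSE) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.character(input)) {
    records <- read_cohort(input)
    input_hash <- unname(tools::md5sum(input))
  } else {
    records <- validate_cohort(input)
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    write_cohort(records, tmp)
    input_hash <- unname(tools::md5sum(tmp))
  }
  if (is.null(conditions)) conditions <- cohort_conditions(records)
  if (!length(conditions)) stop("config validation: empty condition list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(name, text) {
    path <- file.path(out_dir, name)
    writeLines(sub("\n$", "", text), path)
    written <<- c(written, path)
    path
  }
  results <- list()
  log <- character(0)

  if ("prevalence" %in% analyses) {
    res <- tryCatch({
      rows <- lapply(conditions, function(cc) {
        mz <- prevalence_table(records, cc, "MZ")
        dz <- prevalence_table(records, cc, "DZ")
        fit <- zygosity_prevalence_or(records, cc, covariate_policy)
        ci <- exp(fit$coefficients[["zygMZ"]] +
                    c(-1.96, 1.96) * fit$se[["zygMZ"]])
        data.frame(condition = cc,
                   mz_affected = mz$n_affected, mz_unaffected = mz$n_unaffected,
                   mz_percent = mz$percent,
                   dz_affected = dz$n_affected, dz_unaffected = dz$n_unaffected,
                   dz_percent = dz$percent,
                   or = fit$odds_ratio[["zygMZ"]], ci_lo = ci[1], ci_hi = ci[2],
                   p = fit$p_value[["zygMZ"]])
      })
      do.call(rbind, rows)
    }, error = function(e) fail("prevalence", e))
    results$prevalence <- res
    emit("prevalence.csv", render_table(res, "t1"))
    log <- c(log, sprintf("prevalence: %d conditions", length(conditions)))
  }

  if ("similarity" %in% analyses) {
    res <- tryCatch({
      t3 <- list(); t4 <- list()
      for (cc in conditions) {
        mz <- pair_counts(records, cc, "MZ")
        dz <- pair_counts(records, cc, "DZ")
        cm <- casewise_concordance(mz); cd <- casewise_concordance(dz)
        lr_c <- lr_test_zygosity(mz, dz, "casewise")
        t3[[cc]] <- data.frame(condition = cc,
          mz_nc = mz$n_concordant, mz_nd = mz$n_discordant,
          mz_n00 = mz$n_neither, mz_c = cm$estimate,
          mz_lo = cm$ci95[1], mz_hi = cm$ci95[2],
          dz_nc = dz$n_concordant, dz_nd = dz$n_discordant,
          dz_n00 = dz$n_neither, dz_c = cd$estimate,
          dz_lo = cd$ci95[1], dz_hi = cd$ci95[2],
          p = lr_c$p_value)
        rm_ <- pair_correlation(mz); rd <- pair_correlation(dz)
        om <- pair_odds_ratio(mz); od <- pair_odds_ratio(dz)
        lr_r <- lr_test_zygosity(mz, dz, "correlation")
        lr_o <- lr_test_zygosity(mz, dz, "odds_ratio")
        p_r_adj <- p_o_adj <- NA_real_
        if (adjusted_similarity) {
          pd_mz <- pair_covariate_data(records, cc, "MZ")
          pd_dz <- pair_covariate_data(records, cc, "DZ")
          p_r_adj <- lr_test_zygosity(pd_mz, pd_dz, "correlation",
                                      adjusted = TRUE)$p_value
          p_o_adj <- lr_test_zygosity(pd_mz, pd_dz, "odds_ratio",
                                      adjusted = TRUE)$p_value
        }
        t4[[cc]] <- data.frame(condition = cc,
          mz_corr = rm_$estimate, mz_corr_lo = rm_$ci95[1],
          mz_corr_hi = rm_$ci95[2],
          dz_corr = rd$estimate, dz_corr_lo = rd$ci95[1],
          dz_corr_hi = rd$ci95[2],
          p_corr = lr_r$p_value, p_corr_adj = p_r_adj,
          mz_or = om$estimate, mz_or_lo = om$ci95[1], mz_or_hi = om$ci95[2],
          dz_or = od$estimate, dz_or_lo = od$ci95[1], dz_or_hi = od$ci95[2],
          p_or = lr_o$p_value, p_or_adj = p_o_adj)
        log <- c(log, sprintf(
          "similarity %s: MZ pairs %d (excl %d), DZ pairs %d (excl %d)",
          cc, mz$n_pairs, mz$n_excluded, dz$n_pairs, dz$n_excluded))
      }
      list(t3 = do.call(rbind, t3), t4 = do.call(rbind, t4))
    }, error = function(e) fail("similarity", e))
    results$concordance <- res$t3
    results$corr_or <- res$t4
    emit("concordance.csv", render_table(res$t3, "t3"))
    emit("corr_or.csv", render_table(res$t4, "t4"))
  }

  if ("famassoc" %in% analyses) {
    res <- tryCatch({
      rows_list <- list()
      for (cc in conditions) {
        fr <- select_index_twins(records, cc, seed)
        if (nrow(fr) < 10) next
        uni <- univariate_scan(fr, covariate_policy = covariate_policy)
        mult <- multivariate_model(fr, covariate_policy = covariate_policy)
        pull <- function(df, memb, col) {
          v <- df[[col]][df$member == memb]
          if (length(v)) v else NA_real_
        }
        mterm <- function(m) paste0(m, "_status")
        rows_list[[cc]] <- data.frame(
          condition = rep(cc, 2), analysis = c("Univ", "Mult"),
          n = c(nrow(fr), mult$n),
          cotwin_or = c(pull(uni, "cotwin", "or"),
                        mult$odds_ratio[[mterm("cotwin")]]),
          cotwin_p = c(pull(uni, "cotwin", "p"),
                       mult$p_value[[mterm("cotwin")]]),
          sibling_or = c(pull(uni, "sibling", "or"),
                         mult$odds_ratio[[mterm("sibling")]]),
          sibling_p = c(pull(uni, "sibling", "p"),
                        mult$p_value[[mterm("sibling")]]),
          mother_or = c(pull(uni, "mother", "or"),
                        mult$odds_ratio[[mterm("mother")]]),
          mother_p = c(pull(uni, "mother", "p"),
                       mult$p_value[[mterm("mother")]]),
          father_or = c(pull(uni, "father", "or"),
                        mult$odds_ratio[[mterm("father")]]),
          father_p = c(pull(uni, "father", "p"),
                       mult$p_value[[mterm("father")]]))
        log <- c(log, sprintf("famassoc %s: %d complete families, %d dropped",
                              cc, nrow(fr), attr(fr, "n_dropped")))
      }
      if (!length(rows_list))
        stop("no condition had enough complete families")
      do.call(rbind, rows_list)
    }, error = function(e) fail("famassoc", e))
    results$famassoc <- res
    emit("famassoc.csv", render_table(res, "t5"))
  }

  manifest <- list(
    package = "twinfam",
    version = as.character(utils::packageVersion("twinfam")),
    seed = seed, conditions = conditions, analyses = analyses,
    covariate_policy = covariate_policy,
    input_md5 = input_hash, log = log)
  mj <- file.path(out_dir, "manifest.json")
  writeLines(manifest_json(manifest), mj)
  written <- c(written, mj)
  invisible(list(results = results, files = written, manifest = manifest))
}

# minimal JSON writer for the manifest (strings/numbers/flat vectors only)
manifest_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  one <- function(v) {
    if (is.numeric(v) && length(v) == 1) return(format(v, digits = 15))
    if (is.character(v) && length(v) == 1) return(paste0('"', esc(v), '"'))
    paste0("[", paste(vapply(v, one, ""), collapse = ","), "]")
  }
  paste0("{", paste(sprintf('"%s":%s', names(x),
                            vapply(x, one, "")), collapse = ","), "}")
}

#' Pair-level data with per-twin covariates
#'
#' Builds the input for covariate-adjusted [fit_pair_model()] /
#' [lr_test_zygosity()] fits from a cohort: one row per complete twin pair
#' with both statuses, ages and sexes (female = 1).
#'
#' @param records cohort data.frame.
#' @param condition condition column name.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return data.frame with columns \code{y1, y2, age1, age2, sex1, sex2}.
#' @export
pair_covariate_data <- function(records, condition, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  tw <- records[records$role %in% c("twin1", "twin2") &
                records$zygosity == zygosity, ]
  if (!nrow(tw)) stop("no twin pairs of zygosity ", zygosity)
  fams <- unique(tw$family_id)
  pick <- function(role, col) {
    i <- match(paste(fams, role), paste(tw$family_id, tw$role))
    tw[[col]][i]
  }
  d <- data.frame(
    y1 = pick("twin1", condition), y2 = pick("twin2", condition),
    age1 = pick("twin1", "age"), age2 = pick("twin2", "age"),
    sex1 = as.integer(pick("twin1", "sex") == "female"),
    sex2 = as.integer(pick("twin2", "sex") == "female"))
  d[stats::complete.cases(d), , drop = FALSE]
}
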