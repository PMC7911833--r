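# Cohort data model: long-format table, one row per family member.

#' Family roles recognised in a cohort table
#' @export
FAMILY_ROLES <- c("twin1", "twin2", "oldest_sibling", "mother", "father")

#' Default condition identifiers
#'
#' Six binary pediatric pain phenotypes: growing pains (gp), migraine,
#' non-migraine headache, recurrent abdominal pain (rap), low back pain
#' (lbp) and persistent pain not otherwise specified (pp). The schema is
#' extensible: any condition vector can be passed to [read_cohort()] and
#' the analysis functions.
#' @export
PAIN_CONDITIONS <- c("gp", "migraine", "headache", "rap", "lbp", "pp")

cohort_base_cols <- c("family_id", "role", "zygosity", "sex", "age")

#' Read and validate a twin-family cohort table
#'
#' Reads a long-format CSV (one row per person) with columns
#' \code{family_id, role, zygosity, sex, age} followed by one 0/1/NA column
#' per condition. Statuses are kept as observed; missing values are never
#' imputed.
#'
#' @param path path to a CSV file.
#' @param conditions character vector of condition column names expected in
#'   the file. Defaults to whatever condition columns the file declares;
#'   when supplied, condition columns outside this set are an error.
#' @return A validated \code{data.frame} with a \code{"conditions"}
#'   attribute listing the condition columns.
#' @seealso [write_cohort()], [pair_counts()], [select_index_twins()]
#' @export
read_cohort <- function(path, conditions = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing_base <- setdiff(cohort_base_cols, names(df))
  if (length(missing_base))
    stop("cohort file lacks required columns: ",
         paste(missing_base, collapse = ", "))
  found <- setdiff(names(df), cohort_base_cols)
  if (is.null(conditions)) {
    conditions <- found
  } else {
    unknown <- setdiff(found, conditions)
    if (length(unknown))
      stop("unknown condition columns: ", paste(unknown, collapse = ", "))
    absent <- setdiff(conditions, found)
    if (length(absent))
      stop("declared condition columns absent from file: ",
           paste(absent, collapse = ", "))
  }
  if (!length(conditions)) stop("cohort file declares no condition columns")
  validate_cohort(df, conditions)
}

#' Validate a cohort data frame
#'
#' Checks the structural invariants of the long cohort format: known roles,
#' one record per (family, role), twins of a family sharing zygosity,
#' non-negative ages, and 0/1/NA condition statuses. Row numbers and field
#' names are reported on failure.
#'
#' @param records a data.frame in the cohort layout.
#' @param conditions condition column names to validate.
#' @return the validated data.frame, invisibly classed with a
#'   \code{"conditions"} attribute.
#' @export
validate_cohort <- function(records, conditions = cohort_conditions(records)) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  df$family_id <- as.character(df$family_id)

  bad_role <- which(!df$role %in% FAMILY_ROLES)
  if (length(bad_role))
    stop("row ", bad_role[1], ": invalid role '", df$role[bad_role[1]], "'")
  bad_sex <- which(!df$sex %in% c("female", "male"))
  if (length(bad_sex))
    stop("row ", bad_sex[1], ": invalid sex '", df$sex[bad_sex[1]], "'")
  df$age <- as.numeric(df$age)
  bad_age <- which(!is.na(df$age) & df$age < 0)
  if (length(bad_age)) stop("row ", bad_age[1], ": negative age")

  dup <- duplicated(df[, c("family_id", "role")])
  if (any(dup))
    stop("duplicate (family_id, role): family ", df$family_id[which(dup)[1]],
         ", role ", df$role[which(dup)[1]])

  is_twin <- df$role %in% c("twin1", "twin2")
  bad_zyg <- which(is_twin & !df$zygosity %in% c("MZ", "DZ"))
  if (length(bad_zyg))
    stop("row ", bad_zyg[1], ": twin record needs zygosity MZ or DZ")
  # twins of one family must agree on zygosity
  tw <- df[is_twin, c("family_id", "zygosity")]
  if (nrow(tw)) {
    nz <- tapply(tw$zygosity, tw$family_id, function(z) length(unique(z)))
    if (any(nz > 1))
      stop("zygosity mismatch between twin1 and twin2 in family ",
           names(nz)[which(nz > 1)[1]])
  }

  for (cc in conditions) {
    v <- df[[cc]]
    bad <- which(!is.na(v) & !v %in% c(0, 1))
    if (length(bad))
      stop("row ", bad[1], ": condition '", cc, "' must be 0, 1 or NA")
    df[[cc]] <- as.integer(v)
  }
  attr(df, "conditions") <- conditions
  df
}

#' Condition columns of a cohort
#' @param records a cohort data.frame.
#' @return character vector of condition column names.
#' @export
cohort_conditions <- function(records) {
  conds <- attr(records, "conditions")
  if (is.null(conds)) conds <- setdiff(names(records), cohort_base_cols)
  conds
}

#' Write a cohort table to CSV
#'
#' Deterministic writer (fixed column and row order) so that identical
#' cohorts give byte-identical files.
#'
#' @param records cohort data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(records, path) {
  conds <- cohort_conditions(records)
  df <- records[order(records$family_id, match(records$role, FAMILY_ROLES)),
                c(cohort_base_cols, conds)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Tabulate twin pairs into concordant / discordant / unaffected cells
#'
#' Classifies every complete twin pair of the requested zygosity into one of
#' three cells for one condition: both affected (\eqn{N_c}), exactly one
#' affected (\eqn{N_d}), neither affected (\eqn{N_{00}}). Pairs in which
#' either twin's status is missing (or a co-twin record is absent) are
#' excluded and counted separately.
#'
#' @param records cohort data.frame.
#' @param condition condition column name.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return An object of class \code{"pair_counts"}: a list with
#'   \code{zygosity}, \code{condition}, \code{n_concordant},
#'   \code{n_discordant}, \code{n_neither}, \code{n_excluded} and
#'   \code{n_pairs} (complete pairs only).
#' @export
pair_counts <- function(records, condition, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  stopifnot(condition %in% cohort_conditions(records))
  tw <- records[records$role %in% c("twin1", "twin2") &
                records$zygosity == zygosity, ]
  if (!nrow(tw)) stop("no twin pairs of zygosity ", zygosity)
  fams <- unique(tw$family_id)
  s1 <- tw[[condition]][tw$role == "twin1"][match(fams, tw$family_id[tw$role == "twin1"])]
  s2 <- tw[[condition]][tw$role == "twin2"][match(fams, tw$family_id[tw$role == "twin2"])]
  complete <- !is.na(s1) & !is.na(s2)
  new_pair_counts(
    n_concordant = sum(s1[complete] == 1 & s2[complete] == 1),
    n_discordant = sum(s1[complete] != s2[complete]),
    n_neither    = sum(s1[complete] == 0 & s2[complete] == 0),
    zygosity = zygosity, condition = condition,
    n_excluded = sum(!complete))
}

#' Construct a pair-count object directly from the three cell counts
#'
#' @param n_concordant pairs with both twins affected.
#' @param n_discordant pairs with exactly one twin affected.
#' @param n_neither pairs with neither twin affected.
#' @param zygosity,condition optional labels.
#' @param n_excluded pairs dropped for missing status.
#' @return a \code{"pair_counts"} object.
#' @export
new_pair_counts <- function(n_concordant, n_discordant, n_neither,
                            zygosity = NA_character_,
                            condition = NA_character_, n_excluded = 0L) {
  counts <- c(n_concordant, n_discordant, n_neither, n_excluded)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("pair counts must be non-negative integers")
  structure(list(zygosity = zygosity, condition = condition,
                 n_concordant = as.integer(n_concordant),
                 n_discordant = as.integer(n_discordant),
                 n_neither = as.integer(n_neither),
                 n_excluded = as.integer(n_excluded),
                 n_pairs = as.integer(n_concordant + n_discordant + n_neither)),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("Twin pair counts%s%s\n",
              if (!is.na(x$condition)) paste0(" for '", x$condition, "'") else "",
              if (!is.na(x$zygosity)) paste0(" (", x$zygosity, ")") else ""))
  cat(sprintf("  concordant affected N_c  = %d\n", x$n_concordant))
  cat(sprintf("  discordant          N_d  = %d\n", x$n_discordant))
  cat(sprintf("  neither affected    N_00 = %d\n", x$n_neither))
  cat(sprintf("  complete pairs N = %d; excluded (missing) = %d\n",
              x$n_pairs, x$n_excluded))
  invisible(x)
}

#' Double-enter a pair-count table
#'
#' Enters each twin pair twice (once per ordering) to form the symmetric
#' twin-by-co-twin 2x2 table: \code{a = 2 N_c}, \code{b = c = N_d},
#' \code{d = 2 N_00}. The phi coefficient of this table equals the
#' exchangeable-model ML estimate of the pair correlation.
#'
#' @param pc a \code{"pair_counts"} object.
#' @return A 2x2 integer matrix of class \code{"double_entry"}; rows index
#'   the twin, columns the co-twin (affected, unaffected).
#' @export
double_enter <- function(pc) {
  stopifnot(inherits(pc, "pair_counts"))
  m <- matrix(c(2L * pc$n_concordant, pc$n_discordant,
                pc$n_discordant, 2L * pc$n_neither),
              2, 2, byrow = TRUE,
              dimnames = list(twin = c("affected", "unaffected"),
                              cotwin = c("affected", "unaffected")))
  structure(m, class = c("double_entry", class(m)))
}

#' Phi coefficient of a double-entered twin table
#' @param x a \code{"double_entry"} matrix (or any 2x2 table).
#' @return the Pearson correlation of the two binary margins.
#' @export
phi_coefficient <- function(x) {
  a <- as.numeric(x[1, 1]); b <- as.numeric(x[1, 2])
  c <- as.numeric(x[2, 1]); d <- as.numeric(x[2, 2])
  den <- sqrt((a + b) * (c + d) * (a + c) * (b + d))
  if (den == 0) stop("degenerate margins: phi undefined")
  (a * d - b * c) / den
}

#' Lifetime prevalence among twin individuals
#'
#' Counts affected and unaffected twin individuals (both members of every
#' pair, including any twin whose co-twin's status is missing) of one
#' zygosity; missing statuses are excluded from the denominator.
#'
#' @param records cohort data.frame.
#' @param condition condition column name.
#' @param zygosity \code{"MZ"}, \code{"DZ"}, or \code{"all"}.
#' @return list with \code{n_affected}, \code{n_unaffected} and
#'   \code{percent} (exact, in percent units).
#' @export
prevalence_table <- function(records, condition, zygosity = c("MZ", "DZ", "all")) {
  zygosity <- match.arg(zygosity)
  stopifnot(condition %in% cohort_conditions(records))
  tw <- records[records$role %in% c("twin1", "twin2"), ]
  if (zygosity != "all") tw <- tw[tw$zygosity == zygosity, ]
  v <- tw[[condition]]
  n1 <- sum(v == 1, na.rm = TRUE)
  n0 <- sum(v == 0, na.rm = TRUE)
  if (n1 + n0 == 0) stop("no observed statuses for '", condition, "' (", zygosity, ")")
  list(n_affected = n1, n_unaffected = n0, percent = 100 * n1 / (n1 + n0))
}

#' Select one index twin per complete family
#'
#' For the family-association models one twin per pair is chosen uniformly
#' at random, and only families with a non-missing status for all five
#' members (both twins, oldest sibling, mother, father) for the condition
#' are eligible. The number of dropped families is recorded in the
#' \code{"n_dropped"} attribute.
#'
#' @param records cohort data.frame.
#' @param condition condition column name.
#' @param seed integer seed; required, so selections are reproducible.
#' @return data.frame with one row per eligible family: \code{family_id},
#'   \code{twin_status}, \code{cotwin_status}, \code{sibling_status},
#'   \code{mother_status}, \code{father_status}, \code{twin_sex},
#'   \code{twin_age}, \code{zygosity}.
#' @export
select_index_twins <- function(records, condition, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(condition %in% cohort_conditions(records))
  fams <- unique(records$family_id)
  member_col <- function(role, col) {
    i <- match(paste(fams, role), paste(records$family_id, records$role))
    records[[col]][i]
  }
  st <- lapply(FAMILY_ROLES, member_col, col = condition)
  names(st) <- FAMILY_ROLES
  complete <- Reduce(`&`, lapply(st, function(v) !is.na(v)))
  complete[is.na(complete)] <- FALSE
  n_dropped <- sum(!complete)

  keep <- fams[complete]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  pick1 <- stats::runif(length(keep)) < 0.5   # TRUE -> twin1 is index
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  idx_role <- ifelse(pick1, "twin1", "twin2")
  co_role <- ifelse(pick1, "twin2", "twin1")
  i_idx <- match(paste(keep, idx_role), paste(records$family_id, records$role))
  i_co <- match(paste(keep, co_role), paste(records$family_id, records$role))
  i_k <- match(keep, fams)
  out <- data.frame(
    family_id = keep,
    twin_status = records[[condition]][i_idx],
    cotwin_status = records[[condition]][i_co],
    sibling_status = st$oldest_sibling[i_k],
    mother_status = st$mother[i_k],
    father_status = st$father[i_k],
    twin_sex = records$sex[i_idx],
    twin_age = records$age[i_idx],
    zygosity = records$zygosity[i_idx],
    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "condition") <- condition
  out
}
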