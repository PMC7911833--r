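# Shared fixtures: observed pair-count/prevalence tables for six pediatric
# pain conditions (shipped in extdata) and a tiny hand-built cohort.

pain_pair_counts <- function() {
  path <- system.file("extdata", "pediatric_pain_paircounts.csv",
                      package = "twinfam")
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    new_pair_counts(df$n_concordant[i], df$n_discordant[i], df$n_neither[i],
                    zygosity = df$zygosity[i], condition = df$condition[i]))
  names(out) <- paste(df$condition, df$zygosity, sep = "_")
  out
}

pain_prevalence_counts <- function() {
  read.csv(system.file("extdata", "pediatric_pain_prevalence.csv",
                       package = "twinfam"), stringsAsFactors = FALSE)
}

# reference estimates for the observed tables, frozen from the published
# analysis of this cohort (concordance and correlation to 2 dp; the rap/MZ
# concordance computes to 0.47 although 0.48 was published)
ref_similarity <- function() {
  data.frame(
    key = c("gp_MZ", "gp_DZ", "migraine_MZ", "migraine_DZ", "headache_MZ",
            "headache_DZ", "rap_MZ", "rap_DZ", "lbp_MZ", "lbp_DZ",
            "pp_MZ", "pp_DZ"),
    concordance = c(0.62, 0.46, 0.46, 0.23, 0.47, 0.33, 0.47, 0.28,
                    0.48, 0.25, 0.41, 0.20),
    correlation = c(0.53, 0.35, 0.42, 0.18, 0.38, 0.23, 0.39, 0.18,
                    0.39, 0.17, 0.37, 0.15),
    stringsAsFactors = FALSE)
}

# minimal two-family cohort covering every role
toy_family <- function(id, zyg, gp = c(1, 0, 0, 1, 0),
                       age_twins = 10) {
  data.frame(
    family_id = id,
    role = c("twin1", "twin2", "oldest_sibling", "mother", "father"),
    zygosity = c(zyg, zyg, NA, NA, NA),
    sex = c("female", "female", "male", "female", "male"),
    age = c(age_twins, age_twins, age_twins + 3, 40, 42),
    gp = gp,
    stringsAsFactors = FALSE)
}

toy_cohort <- function() {
  validate_cohort(rbind(toy_family("f1", "MZ", gp = c(1, 1, 0, 1, 0)),
                        toy_family("f2", "DZ", gp = c(1, 0, 0, 0, 0))),
                  conditions = "gp")
}
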