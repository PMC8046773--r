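# Shared fixtures: a tiny two-SNP panel, the weighted built-in panel, and
# writers for small genotype/cohort files.

tiny_panel <- function(weights = c(50, 100)) {
  snp_panel(
    rsid = c("rs1", "rs2"), gene = c("G1", "G2"),
    major_allele = c("C", "A"), minor_allele = c("T", "G"),
    effect_allele = c("C", "G"), maf = c(0.24, 0.3),
    weight_bp = weights
  )
}

weighted_builtin <- function() {
  set_panel_weights(builtin_panel(), synthetic_weights_path())
}

write_geno_file <- function(df, path = tempfile(fileext = ".csv"), sep = ",") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# A small deterministic cohort with both arms and full survival data.
toy_cohort <- function(n_case = 30, n_control = 30, seed = 42) {
  set.seed(seed)
  n <- n_case + n_control
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    status = rep(c("case", "control"), c(n_case, n_control)),
    sex = sample(c("male", "female"), n, TRUE),
    age = round(rnorm(n, 60, 8), 1),
    country = sample(c("Poland", "Spain"), n, TRUE),
    stage_ds = c(sample(1:3, n_case, TRUE), rep(NA, n_control)),
    stage_iss = c(sample(1:3, n_case, TRUE), rep(NA, n_control)),
    therapy = c(sample(c("new", "old"), n_case, TRUE), rep(NA, n_control)),
    vital = c(sample(c("alive", "deceased"), n_case, TRUE),
              rep(NA, n_control)),
    os_time = c(round(rexp(n_case, 1 / 40) + 1, 1), rep(NA, n_control)),
    stringsAsFactors = FALSE
  )
}

as_cohort <- function(df) {
  class(df) <- c("cohort_table", "data.frame")
  df
}
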