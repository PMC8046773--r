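# Accessors for the published reference tables of the multicentre myeloma
# study the package is modelled on. These printed summary tables are the
# only study-level data publicly available (individual-level data were not
# deposited); they drive the summary-statistic MR interface, the simulator's
# default margins, and bookkeeping checks.

#' Published per-SNP allelic association estimates
#'
#' Per-minor-allele odds ratios (risk) and hazard ratios (survival, adjusted
#' by Durie-Salmon stage) with 95% CIs for the 11 panel SNPs, as printed by
#' the source study. These are the summary statistics from which the
#' outcome side of the Mendelian randomization is reconstructed.
#'
#' @param outcome `"risk"` or `"survival"`.
#' @return Data frame with `rsid`, `gene`, `effect`, `ci_low`, `ci_high`
#'   and a `model = "allelic"` column ready for [summary_from_tables()].
#' @export
published_snp_estimates <- function(outcome = c("risk", "survival")) {
  outcome <- match.arg(outcome)
  path <- system.file("extdata", "published_snp_estimates.tsv",
                      package = "teloscore", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$outcome == outcome, setdiff(names(tab), "outcome")]
  tab$model <- "allelic"
  rownames(tab) <- NULL
  tab
}

#' Published teloscore quintile occupancy
#'
#' Control/case counts per score quintile for the four score variants as
#' printed by the source study. The unequal quintile sizes document that
#' tied integer scores were kept in the lower quintile, the convention
#' [assign_quintile()] follows.
#'
#' @return Data frame `variant`, `quintile`, `controls`, `cases`, `total`.
#' @export
published_quintile_counts <- function() {
  path <- system.file("extdata", "published_quintile_counts.tsv",
                      package = "teloscore", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reference cohort margins by country
#'
#' Case and control counts per recruiting country in the source study;
#' these are the simulator's default country distribution and the package's
#' default cohort scale (2407 cases, 1741 controls).
#'
#' @return Data frame `country`, `cases`, `controls`.
#' @export
cohort_margins <- function() {
  data.frame(
    country = c("Denmark", "France", "Hungary", "Israel", "Italy", "Poland",
                "Portugal", "Spain"),
    cases = c(277L, 330L, 83L, 89L, 231L, 1043L, 126L, 228L),
    controls = c(494L, 176L, 75L, 72L, 227L, 262L, 120L, 315L),
    stringsAsFactors = FALSE
  )
}
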