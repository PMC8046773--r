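#' Run the full teloscore analysis pipeline
#'
#' Orchestrates QC, scoring, the per-SNP and score-quintile risk models,
#' the survival models under both staging systems, and the summary-
#' statistic Mendelian randomization, writing tab-delimited result tables
#' and a JSON run manifest with per-stage subject counts and output
#' checksums.
#'
#' @param config either a YAML file path or a list. Recognised entries:
#'   \describe{
#'     \item{simulate}{list of [sim_config()] arguments (or `TRUE` for the
#'       defaults); when present the cohort is simulated.}
#'     \item{genotypes, cohort}{input file paths (used when `simulate` is
#'       absent).}
#'     \item{weights}{YAML weight file for the panel (defaults to the
#'       bundled synthetic example weights).}
#'     \item{analyses}{character subset of `c("qc", "risk", "survival-ds",
#'       "survival-iss", "mr-risk", "mr-survival")` (default: all).}
#'     \item{loo_exclusions}{rsids excluded in an additional
#'       leave-SNP-out score analysis (default none).}
#'     \item{alpha}{family-wise significance level (default 0.05).}
#'     \item{seed}{integer seed for any simulation (default 1).}
#'   }
#' @param out_dir output directory, created if needed.
#' @return The run manifest (list), invisibly; side effect: result tables
#'   and `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("teloscore_run_")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  analyses <- config$analyses %||% c("qc", "risk", "survival-ds",
                                     "survival-iss", "mr-risk", "mr-survival")
  alpha <- config$alpha %||% 0.05
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  counts <- list()
  warnings_log <- character(0)
  note <- function(stage, n) counts[[stage]] <<- n

  weights_path <- config$weights %||% synthetic_weights_path()
  panel <- set_panel_weights(builtin_panel(), weights_path)

  if (!is.null(config$simulate)) {
    sim_args <- if (isTRUE(config$simulate)) list() else config$simulate
    sim_args$panel <- panel
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    study <- simulate_study(cfg)
    g <- study$genotypes; cohort <- study$cohort
    geno_path <- file.path(out_dir, "genotypes.tsv")
    coh_path <- file.path(out_dir, "cohort.tsv")
    write_genotypes(g, geno_path); write_cohort(cohort, coh_path)
    outputs <- c(outputs, geno_path, coh_path)
  } else {
    if (is.null(config$genotypes) || is.null(config$cohort)) {
      stop("config must provide either a 'simulate' block or both ",
           "'genotypes' and 'cohort' paths")
    }
    g <- load_genotypes(config$genotypes, panel)
    cohort <- load_cohort(config$cohort)
  }
  note("subjects", nrow(g))
  note("cases", sum(cohort$status == "case", na.rm = TRUE))
  note("controls", sum(cohort$status == "control", na.rm = TRUE))

  emit <- function(tab, name) {
    path <- file.path(out_dir, name)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  threshold <- bonferroni_threshold(panel, alpha = alpha)

  results <- list(bonferroni_threshold = threshold)
  withCallingHandlers({
    if ("qc" %in% analyses) {
      qc <- qc_report(g, cohort = cohort)
      outputs <- c(outputs, write_qc_report(qc, file.path(out_dir, "qc")))
      note("qc_mean_call_rate", qc$call_rates$mean_call_rate)
      results$qc <- qc
    }
    if ("risk" %in% analyses) {
      snp_risk <- snp_models(g, cohort, panel)
      snp_risk$significant <- snp_risk$p < threshold
      emit(snp_risk, "snp_risk.tsv")
      scored <- score_cohort(g, panel, "risk", cohort)
      score_risk <- score_risk_models(scored, cohort)
      emit(scored$scores, "scores_risk.tsv")
      emit(score_risk, "score_risk.tsv")
      jsonlite::write_json(lapply(scored$cuts, unclass),
                           file.path(out_dir, "quintile_cuts_risk.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, file.path(out_dir, "quintile_cuts_risk.json"))
      note("risk_n_scored", nrow(scored$scores))
      results$snp_risk <- snp_risk
      results$score_risk <- score_risk
      if (length(config$loo_exclusions)) {
        scored_loo <- score_cohort(g, panel, "risk", cohort,
                                   exclude_rsids = config$loo_exclusions)
        emit(score_risk_models(scored_loo, cohort), "score_risk_loo.tsv")
      }
    }
    for (ss in c("ds", "iss")) {
      if (!paste0("survival-", ss) %in% analyses) next
      snp_surv <- survival_models(g, cohort, panel, stage_system = ss)
      emit(snp_surv, sprintf("snp_survival_%s.tsv", ss))
      scored_s <- score_cohort(g, panel, "survival", cohort, stage_system = ss)
      score_surv <- survival_models(scored_s, cohort, stage_system = ss)
      emit(score_surv, sprintf("score_survival_%s.tsv", ss))
      note(paste0("survival_", ss, "_n"), max(snp_surv$n_used))
      results[[paste0("snp_survival_", ss)]] <- snp_surv
      results[[paste0("score_survival_", ss)]] <- score_surv
    }
    if ("mr-risk" %in% analyses && !is.null(results$snp_risk)) {
      s <- summary_from_tables(results$snp_risk, panel)
      rep <- mr_report(s)
      emit(s, "mr_risk_inputs.tsv")
      emit(rep$scatter, "mr_risk_scatter.tsv")
      emit(rep$forest, "mr_risk_forest.tsv")
      results$mr_risk <- rep
    }
    if ("mr-survival" %in% analyses &&
        !is.null(results$snp_survival_ds)) {
      s <- summary_from_tables(results$snp_survival_ds, panel)
      rep <- mr_report(s)
      emit(s, "mr_survival_inputs.tsv")
      emit(rep$scatter, "mr_survival_scatter.tsv")
      emit(rep$forest, "mr_survival_forest.tsv")
      results$mr_survival <- rep
    }
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("teloscore")),
    config = config[setdiff(names(config), "panel")],
    alpha = alpha, bonferroni_threshold = threshold,
    n_used = counts, warnings = warnings_log,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  manifest$results <- results
  manifest$out_dir <- out_dir
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
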