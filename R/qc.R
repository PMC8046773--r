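#' Per-SNP and per-subject genotyping call rates
#'
#' @param g a [genotype_matrix()].
#' @return A list with `per_snp` (named fraction of non-missing calls per
#'   SNP), `per_subject` (named fraction per subject), `mean_call_rate`
#'   (mean of the per-SNP rates) and `complete_subjects` (ids of the
#'   100%-call-rate stratum used for the raw-score analyses).
#' @export
call_rates <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g) >= 1)
  called <- !is.na(unclass(g))
  per_snp <- colMeans(called)
  per_subject <- rowMeans(called)
  list(per_snp = per_snp,
       per_subject = per_subject,
       mean_call_rate = mean(per_snp),
       complete_subjects = rownames(g)[per_subject == 1])
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square comparing observed genotype
#' counts with the Hardy-Weinberg expectation at the sample allele
#' frequency. The statistic is invariant under swapping which allele is
#' counted (dosage `d -> 2 - d`).
#'
#' @param counts integer vector `(n0, n1, n2)`: subjects with 0, 1 and 2
#'   copies of the counted allele.
#' @return A list with `chi2`, `p` (upper chi-square tail, 1 df) and
#'   `monomorphic` (`TRUE` when the sample allele frequency is 0 or 1, in
#'   which case `chi2 = 0`, `p = 1`).
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE proportions: chi2 = 0, p = 1
#' hwe_test(c(30, 40, 30))  # chi2 = 4, p ~ 0.046
#' @export
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0), sum(counts) >= 1)
  n <- sum(counts)
  p_hat <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p_hat == 0 || p_hat == 1) {
    return(list(chi2 = 0, p = 1, monomorphic = TRUE))
  }
  expected <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Duplicate-sample genotype concordance
#'
#' Fraction of jointly non-missing calls that agree between duplicated
#' samples, pooled over pairs and SNPs.
#'
#' @param g a [genotype_matrix()].
#' @param pairs list of length-2 character vectors of subject ids.
#' @return A single fraction, or `NA` (with a warning) when no jointly
#'   non-missing calls exist.
#' @export
duplicate_concordance <- function(g, pairs) {
  stopifnot(inherits(g, "genotype_matrix"), length(pairs) >= 1)
  agree <- 0L; total <- 0L
  for (pr in pairs) {
    stopifnot(length(pr) == 2)
    if (!all(pr %in% rownames(g))) {
      stop("unknown subject id(s) in duplicate pair: ",
           paste(setdiff(pr, rownames(g)), collapse = ", "))
    }
    a <- unclass(g)[pr[1], ]; b <- unclass(g)[pr[2], ]
    joint <- !is.na(a) & !is.na(b)
    total <- total + sum(joint)
    agree <- agree + sum(a[joint] == b[joint])
  }
  if (total == 0) {
    warning("no jointly non-missing calls among duplicate pairs")
    return(NA_real_)
  }
  agree / total
}

#' Genotype quality-control report
#'
#' Bundles call rates, optional duplicate concordance and per-SNP
#' Hardy-Weinberg tests. HWE is computed in the control stratum by default,
#' matching standard case-control practice; QC is reporting-only and never
#' drops SNPs or subjects.
#'
#' @param g a [genotype_matrix()].
#' @param cohort optional `cohort_table`; when supplied, HWE uses controls
#'   only (subjects matched by id).
#' @param pairs optional list of duplicate-sample id pairs.
#' @return A list of class `qc_report` with elements `call_rates`,
#'   `duplicate_concordance` and `hwe` (data frame: rsid, chi2, p,
#'   monomorphic, n).
#' @export
qc_report <- function(g, cohort = NULL, pairs = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  cr <- call_rates(g)
  gh <- unclass(g)
  if (!is.null(cohort)) {
    controls <- cohort$subject_id[!is.na(cohort$status) & cohort$status == "control"]
    gh <- gh[rownames(g) %in% controls, , drop = FALSE]
    if (nrow(gh) == 0) stop("no control subjects found for HWE testing")
  }
  hwe <- do.call(rbind, lapply(seq_len(ncol(gh)), function(j) {
    d <- gh[, j]
    counts <- c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                sum(d == 2, na.rm = TRUE))
    h <- hwe_test(counts)
    data.frame(rsid = colnames(gh)[j], chi2 = h$chi2, p = h$p,
               monomorphic = h$monomorphic, n = sum(counts),
               stringsAsFactors = FALSE)
  }))
  dup <- if (!is.null(pairs)) duplicate_concordance(g, pairs) else NA_real_
  out <- list(call_rates = cr, duplicate_concordance = dup, hwe = hwe)
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Mean SNP call rate: %.1f%%\n", 100 * x$call_rates$mean_call_rate))
  cat(sprintf("Subjects with 100%% call rate: %d of %d\n",
              length(x$call_rates$complete_subjects),
              length(x$call_rates$per_subject)))
  if (!is.na(x$duplicate_concordance)) {
    cat(sprintf("Duplicate concordance: %.2f%%\n", 100 * x$duplicate_concordance))
  }
  cat("Hardy-Weinberg (1-df chi-square):\n")
  print(x$hwe, row.names = FALSE)
  invisible(x)
}

#' Write a QC report as tab-delimited text and JSON
#'
#' @param qc a [qc_report()].
#' @param prefix output path prefix; writes `<prefix>_hwe.tsv`,
#'   `<prefix>_call_rates.tsv` and `<prefix>.json`.
#' @return Character vector of written paths, invisibly.
#' @export
write_qc_report <- function(qc, prefix) {
  stopifnot(inherits(qc, "qc_report"))
  hwe_path <- paste0(prefix, "_hwe.tsv")
  cr_path <- paste0(prefix, "_call_rates.tsv")
  json_path <- paste0(prefix, ".json")
  utils::write.table(qc$hwe, hwe_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(rsid = names(qc$call_rates$per_snp),
               call_rate = qc$call_rates$per_snp),
    cr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mean_call_rate = qc$call_rates$mean_call_rate,
         n_complete_subjects = length(qc$call_rates$complete_subjects),
         duplicate_concordance = qc$duplicate_concordance,
         hwe = qc$hwe),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(hwe_path, cr_path, json_path))
}
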