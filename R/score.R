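#' Unweighted teloscore: count of long-telomere alleles
#'
#' Sum of effect-allele dosages over the whole panel. Following the source
#' design, the raw score is only defined for subjects with a call at every
#' SNP; with L panel SNPs it ranges from 0 (shortest telomeres) to 2L
#' (longest telomeres) — 0 to 22 for the built-in 11-SNP panel.
#'
#' @param row integer dosage vector of length L (entries 0/1/2 or `NA`).
#' @return Integer sum, or `NA` if any call is missing.
#' @export
unweighted_score <- function(row) {
  row <- as.integer(row)
  if (anyNA(row)) return(NA_integer_)
  sum(row)
}

#' Weighted teloscore in base pairs
#'
#' Each effect-allele count is multiplied by that SNP's per-allele effect on
#' leukocyte telomere length in base pairs and summed, giving the estimated
#' telomere-length difference attributable to the panel. Defined only for
#' complete rows.
#'
#' @param row dosage vector of length L.
#' @param panel a [snp_panel()] with configured `weight_bp`.
#' @return Base-pair score, or `NA` if any call is missing.
#' @export
weighted_score <- function(row, panel) {
  stopifnot(inherits(panel, "snp_panel"), length(row) == nrow(panel))
  if (anyNA(panel$weight_bp)) {
    stop("panel weights are not configured; see set_panel_weights()")
  }
  row <- as.numeric(row)
  if (anyNA(row)) return(NA_real_)
  sum(row * panel$weight_bp)
}

#' Scaled ("average") teloscores for incomplete genotype data
#'
#' Per-SNP averages of the unweighted and weighted scores over the
#' non-missing calls, so subjects with missing genotypes get score values
#' comparable with complete-data subjects. For complete rows the scaled
#' scores equal the raw scores divided by L.
#'
#' @inheritParams weighted_score
#' @return List with `unweighted_scaled` (mean dosage over non-missing
#'   SNPs, in `[0, 2]`) and `weighted_scaled` (bp per SNP); both `NA` for an
#'   all-missing row.
#' @export
scaled_scores <- function(row, panel) {
  stopifnot(inherits(panel, "snp_panel"), length(row) == nrow(panel))
  if (anyNA(panel$weight_bp)) {
    stop("panel weights are not configured; see set_panel_weights()")
  }
  row <- as.numeric(row)
  ok <- !is.na(row)
  if (!any(ok)) {
    return(list(unweighted_scaled = NA_real_, weighted_scaled = NA_real_))
  }
  list(unweighted_scaled = sum(row[ok]) / sum(ok),
       weighted_scaled = sum(row[ok] * panel$weight_bp[ok]) / sum(ok))
}

#' Compute all teloscore variants for a cohort
#'
#' @param g a [genotype_matrix()].
#' @param panel a [snp_panel()] with configured weights.
#' @param exclude_rsids optional rsids to leave out (leave-one-SNP-out
#'   sensitivity scores); all variants are recomputed over the reduced panel.
#' @return Data frame of class `score_set`: `subject_id`, `n_nonmissing`,
#'   `unweighted` (integer, `NA` unless all L' SNPs called), `weighted_bp`,
#'   `unweighted_scaled`, `weighted_scaled`. Subjects with zero non-missing
#'   calls keep a row but carry all-`NA` scores; their count is messaged.
#' @export
compute_scores <- function(g, panel, exclude_rsids = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(panel, "snp_panel"))
  if (!is.null(exclude_rsids)) {
    unknown <- setdiff(exclude_rsids, panel$rsid)
    if (length(unknown)) stop("excluded rsid(s) not in panel: ",
                              paste(unknown, collapse = ", "))
    keep <- !panel$rsid %in% exclude_rsids
    if (!any(keep)) stop("cannot exclude every SNP in the panel")
    panel <- panel[keep, ]
    class(panel) <- c("snp_panel", "data.frame")
    g <- unclass(g)[, keep, drop = FALSE]
  } else {
    g <- unclass(g)
  }
  if (anyNA(panel$weight_bp)) {
    stop("panel weights are not configured; see set_panel_weights()")
  }
  L <- nrow(panel)
  ok <- !is.na(g)
  n_nonmissing <- rowSums(ok)
  g0 <- g; g0[!ok] <- 0
  unw_sum <- rowSums(g0)
  w_sum <- as.numeric(g0 %*% panel$weight_bp)
  complete <- n_nonmissing == L
  out <- data.frame(
    subject_id = rownames(g),
    n_nonmissing = as.integer(n_nonmissing),
    unweighted = ifelse(complete, as.integer(unw_sum), NA_integer_),
    weighted_bp = ifelse(complete, w_sum, NA_real_),
    unweighted_scaled = ifelse(n_nonmissing > 0, unw_sum / n_nonmissing, NA_real_),
    weighted_scaled = ifelse(n_nonmissing > 0, w_sum / n_nonmissing, NA_real_),
    stringsAsFactors = FALSE
  )
  if (any(n_nonmissing == 0)) {
    message(sum(n_nonmissing == 0),
            " subject(s) with no non-missing genotype excluded from scoring")
  }
  class(out) <- c("score_set", "data.frame")
  out
}

#' Empirical quintile cutpoints from a reference stratum
#'
#' Cutpoint k (k = 1..4) is the smallest reference value whose empirical CDF
#' reaches k/5. Scores are assigned with [assign_quintile()]:
#' `quintile = 1 + #\{cutpoints < score\}`, so a value tied with a cutpoint
#' falls in the lower quintile. The lower tie-break matters because the
#' integer-valued scores are heavily tied.
#'
#' @param reference_scores numeric vector (>= 5 non-missing values).
#' @return List of class `quintile_cuts` with `cutpoints` (4 nondecreasing
#'   values) and `reference_n`.
#' @export
quintile_cuts <- function(reference_scores) {
  x <- sort(reference_scores[!is.na(reference_scores)])
  n <- length(x)
  if (n < 5) stop("need at least 5 non-missing reference values for quintiles")
  cutpoints <- x[ceiling(n * (1:4) / 5)]
  if (length(unique(cutpoints)) == 1 && cutpoints[1] == x[1] && x[1] == x[n]) {
    warning("degenerate reference distribution: all values equal; ",
            "every score will fall in quintile 1")
  }
  structure(list(cutpoints = cutpoints, reference_n = n),
            class = "quintile_cuts")
}

#' Assign quintiles against reference cutpoints
#'
#' @param scores numeric vector.
#' @param cuts a [quintile_cuts()].
#' @return Integer quintiles 1..5 (`NA` for missing scores).
#' @export
assign_quintile <- function(scores, cuts) {
  stopifnot(inherits(cuts, "quintile_cuts"))
  out <- vapply(scores, function(s) {
    if (is.na(s)) NA_integer_ else 1L + sum(cuts$cutpoints < s)
  }, integer(1))
  out
}

#' Score a cohort and assign reference-based quintiles
#'
#' Computes all four score variants and assigns quintiles against the
#' analysis-appropriate reference stratum:
#' \describe{
#'   \item{risk}{Raw (complete-call-rate) scores use cutpoints from the
#'     distribution in controls with 100% call rate; scaled scores use all
#'     controls.}
#'   \item{survival}{Controls are ignored. The reference is cases with
#'     non-missing stage (chosen system), therapy and overall-survival data;
#'     raw-score cutpoints come from the complete-call-rate subset of that
#'     reference, scaled from all of it.}
#' }
#'
#' @param g a [genotype_matrix()].
#' @param panel a [snp_panel()] with configured weights.
#' @param analysis `"risk"` or `"survival"`.
#' @param cohort a `cohort_table` covering the genotyped subjects.
#' @param stage_system `"ds"` or `"iss"`; survival reference stratum only.
#' @param exclude_rsids optional leave-out rsids, passed to
#'   [compute_scores()].
#' @return List with `scores` (a `score_set` plus quintile columns
#'   `q_unweighted`, `q_weighted`, `q_unweighted_scaled`,
#'   `q_weighted_scaled`) and `cuts` (named list of [quintile_cuts()]).
#' @export
score_cohort <- function(g, panel, analysis = c("risk", "survival"), cohort,
                         stage_system = c("ds", "iss"), exclude_rsids = NULL) {
  analysis <- match.arg(analysis)
  stage_system <- match.arg(stage_system)
  scores <- compute_scores(g, panel, exclude_rsids = exclude_rsids)
  idx <- match(scores$subject_id, cohort$subject_id)
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " genotyped subject(s) absent from the cohort table")
  }
  co <- cohort[idx, ]
  L <- sum(!panel$rsid %in% exclude_rsids)
  complete <- scores$n_nonmissing == L
  if (analysis == "risk") {
    ref_all <- !is.na(co$status) & co$status == "control"
  } else {
    stage <- if (stage_system == "ds") co$stage_ds else co$stage_iss
    ref_all <- !is.na(co$status) & co$status == "case" &
      !is.na(stage) & !is.na(co$therapy) & !is.na(co$vital) & !is.na(co$os_time)
  }
  if (!any(ref_all)) stop("empty reference stratum for quintile cutpoints")
  ref_raw <- ref_all & complete
  if (!any(ref_raw)) stop("no complete-call-rate subjects in the reference stratum")
  cuts <- list(
    unweighted = quintile_cuts(scores$unweighted[ref_raw]),
    weighted = quintile_cuts(scores$weighted_bp[ref_raw]),
    unweighted_scaled = quintile_cuts(scores$unweighted_scaled[ref_all]),
    weighted_scaled = quintile_cuts(scores$weighted_scaled[ref_all])
  )
  scores$q_unweighted <- assign_quintile(scores$unweighted, cuts$unweighted)
  scores$q_weighted <- assign_quintile(scores$weighted_bp, cuts$weighted)
  scores$q_unweighted_scaled <-
    assign_quintile(scores$unweighted_scaled, cuts$unweighted_scaled)
  scores$q_weighted_scaled <-
    assign_quintile(scores$weighted_scaled, cuts$weighted_scaled)
  list(scores = scores, cuts = cuts, analysis = analysis,
       stage_system = if (analysis == "survival") stage_system else NA_character_)
}
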