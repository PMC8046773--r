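#' Construct a SNP instrument panel
#'
#' A `snp_panel` holds the biallelic SNPs used as genetic instruments for
#' leukocyte telomere length (LTL): identifiers, gene labels, major/minor
#' alleles, the effect allele (the allele associated with longer telomeres),
#' the minor allele frequency, and an optional per-allele effect on LTL in
#' base pairs (the score weight).
#'
#' @param rsid character vector of unique rs identifiers.
#' @param gene character vector of gene labels.
#' @param major_allele,minor_allele single-character nucleotide labels.
#' @param effect_allele nucleotide label; must equal the major or the minor
#'   allele at each SNP.
#' @param maf minor allele frequencies in (0, 0.5].
#' @param weight_bp optional nonnegative per-allele effects on LTL in base
#'   pairs; `NA` when not yet configured.
#' @return A data frame of class `snp_panel` with one row per SNP and an
#'   additional column `effect_allele_freq` (population frequency of the
#'   effect allele implied by `maf` and the effect-allele identity).
#' @seealso [builtin_panel()], [set_panel_weights()]
#' @export
snp_panel <- function(rsid, gene, major_allele, minor_allele, effect_allele,
                      maf, weight_bp = NA_real_) {
  rsid <- as.character(rsid)
  if (anyDuplicated(rsid)) {
    stop("duplicated rsid in panel: ",
         paste(unique(rsid[duplicated(rsid)]), collapse = ", "))
  }
  n <- length(rsid)
  major_allele <- toupper(as.character(major_allele))
  minor_allele <- toupper(as.character(minor_allele))
  effect_allele <- toupper(as.character(effect_allele))
  maf <- as.numeric(maf)
  weight_bp <- rep_len(as.numeric(weight_bp), n)
  stopifnot(length(gene) == n, length(major_allele) == n,
            length(minor_allele) == n, length(effect_allele) == n,
            length(maf) == n)
  bad <- effect_allele != major_allele & effect_allele != minor_allele
  if (any(bad)) {
    stop("effect allele not among panel alleles for: ",
         paste(rsid[bad], collapse = ", "))
  }
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  if (any(!is.na(weight_bp) & weight_bp < 0)) {
    stop("weight_bp must be nonnegative")
  }
  panel <- data.frame(
    rsid = rsid, gene = as.character(gene),
    major_allele = major_allele, minor_allele = minor_allele,
    effect_allele = effect_allele, maf = maf, weight_bp = weight_bp,
    effect_allele_freq = ifelse(effect_allele == minor_allele, maf, 1 - maf),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' The built-in 11-SNP telomere-length panel
#'
#' Returns the 11 GWAS-identified SNPs used to build the teloscore, with the
#' gene, major/minor alleles, minor allele frequency and long-telomere effect
#' allele as reported for the source case-control study. Per-allele base-pair
#' weights are intentionally left unconfigured (`NA`): they come from
#' external GWAS estimates and must be supplied via
#' [set_panel_weights()] or a weights configuration file.
#'
#' @return A [snp_panel()] with 11 rows.
#' @examples
#' p <- builtin_panel()
#' nrow(p)        # 11
#' p[p$rsid == "rs2736100", ]
#' @export
builtin_panel <- function() {
  snp_panel(
    rsid = c("rs11125529", "rs6772228", "rs10936599", "rs7675998",
             "rs2736100", "rs9420907", "rs3027234", "rs8105767",
             "rs412658", "rs6028466", "rs755017"),
    gene = c("ACYP2", "PXK", "TERC", "NAF1", "TERT", "OBFC1", "CTC1",
             "ZNF208", "ZNF676", "DHX35", "ZBTB46"),
    major_allele = c("C", "T", "C", "G", "A", "A", "C", "A", "C", "G", "A"),
    minor_allele = c("A", "A", "T", "A", "C", "C", "T", "G", "T", "A", "G"),
    effect_allele = c("A", "T", "C", "G", "C", "C", "C", "G", "T", "A", "G"),
    maf = c(0.11, 0.04, 0.24, 0.24, 0.50, 0.13, 0.22, 0.28, 0.35, 0.07, 0.12)
  )
}

#' Attach per-allele base-pair weights to a panel
#'
#' @param panel a [snp_panel()].
#' @param weights named numeric vector (names are rsids) of nonnegative
#'   per-allele effects on LTL in base pairs, or a path to a YAML file with a
#'   top-level `weights:` mapping keyed by rsid (optionally a sibling
#'   `weight_se:` mapping of standard errors).
#' @return The panel with `weight_bp` (and, if provided, `weight_se_bp`)
#'   filled in.
#' @export
set_panel_weights <- function(panel, weights) {
  stopifnot(inherits(panel, "snp_panel"))
  weight_se <- NULL
  if (is.character(weights) && length(weights) == 1L && file.exists(weights)) {
    cfg <- yaml::read_yaml(weights)
    if (is.null(cfg$weights)) stop("weights file lacks a 'weights:' mapping")
    weight_se <- unlist(cfg$weight_se)
    weights <- unlist(cfg$weights)
  }
  if (is.null(names(weights))) stop("weights must be named by rsid")
  missing_rs <- setdiff(panel$rsid, names(weights))
  if (length(missing_rs)) {
    stop("no weight supplied for: ", paste(missing_rs, collapse = ", "))
  }
  w <- as.numeric(weights[panel$rsid])
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be nonnegative")
  panel$weight_bp <- w
  if (!is.null(weight_se)) {
    panel$weight_se_bp <- as.numeric(weight_se[panel$rsid])
  }
  panel
}

#' Path to the bundled synthetic example weight configuration
#'
#' The package does not hard-code per-allele base-pair effects: published
#' GWAS estimates must be supplied by the user. For simulation, examples and
#' tests the package bundles a synthetic weight set in the 48-120 bp range
#' typical of telomere-length GWAS loci. These are synthetic placeholder
#' values, not published estimates.
#'
#' @return File path of the YAML weight configuration.
#' @export
synthetic_weights_path <- function() {
  system.file("extdata", "synthetic_weights.yaml", package = "teloscore",
              mustWork = TRUE)
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP instrument panel: %d SNPs (%s weights)\n", nrow(x),
              if (all(is.na(x$weight_bp))) "unconfigured" else "configured"))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# Bonferroni threshold for the per-SNP scan: two inheritance models per SNP.
#' Multiple-testing threshold for the per-SNP association scan
#'
#' Each SNP is tested under two inheritance models (allelic and codominant),
#' so the Bonferroni-corrected significance threshold is
#' `alpha / (2 * nrow(panel))` — 0.05/22 for the default 11-SNP panel.
#'
#' @param panel a [snp_panel()].
#' @param alpha family-wise significance level (default 0.05).
#' @param n_models number of inheritance models per SNP (default 2).
#' @return The corrected threshold, a single number.
#' @export
bonferroni_threshold <- function(panel, alpha = 0.05, n_models = 2L) {
  stopifnot(inherits(panel, "snp_panel"), alpha > 0, n_models >= 1)
  alpha / (nrow(panel) * n_models)
}
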