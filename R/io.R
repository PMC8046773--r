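#' Construct a genotype matrix of effect-allele dosages
#'
#' @param dosage integer matrix, subjects in rows and panel SNPs in columns;
#'   entries are counts of the long-telomere (effect) allele in `{0, 1, 2}`
#'   or `NA` for missing calls.
#' @param subject_ids character vector of row identifiers.
#' @param panel a [snp_panel()]; column order must match.
#' @return A matrix of class `genotype_matrix` with subject ids as row names
#'   and panel rsids as column names.
#' @export
genotype_matrix <- function(dosage, subject_ids, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(panel)) {
    stop("dosage has ", ncol(dosage), " columns but panel has ",
         nrow(panel), " SNPs")
  }
  if (length(subject_ids) != nrow(dosage)) {
    stop("subject_ids length does not match number of rows")
  }
  storage.mode(dosage) <- "integer"
  ok <- is.na(dosage) | dosage %in% 0:2
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(as.character(subject_ids), panel$rsid)
  class(dosage) <- c("genotype_matrix", class(dosage))
  dosage
}

MISSING_TOKENS <- c("", "NA", "./.", "--", ".")

# Count effect alleles in a two-character call like "CT"; NA if the pair is
# inconsistent with the panel alleles.
.pair_to_dosage <- function(calls, major, minor, effect) {
  calls <- toupper(calls)
  a1 <- substr(calls, 1L, 1L)
  a2 <- substr(calls, 2L, 2L)
  valid <- nchar(calls) == 2L & a1 %in% c(major, minor) & a2 %in% c(major, minor)
  out <- ifelse(valid, (a1 == effect) + (a2 == effect), NA_integer_)
  list(dosage = as.integer(out), invalid = !valid)
}

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Load a genotype table or VCF, oriented to the effect allele
#'
#' Genotype calls are converted to counts of the long-telomere effect allele
#' of each panel SNP. Delimited tables carry one row per subject, a
#' `subject_id` column, and one column per panel rsid holding either
#' two-character allele pairs (`"CT"`) or integer effect-allele dosages;
#' the encoding is auto-detected per column. VCF input uses the `GT` field
#' with panel SNPs located by ID; only strictly biallelic records are
#' accepted. Missing encodings: empty, `NA`, `./.`, `--`.
#'
#' Allele pairs inconsistent with the panel alleles become missing with a
#' warning; if more than half of a column's non-missing calls are
#' inconsistent an error is raised, since that signals a strand or allele
#' labelling mismatch rather than sporadic bad calls.
#'
#' @param path path to the genotype file.
#' @param panel a [snp_panel()].
#' @param format `"auto"` (by file extension), `"table"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, panel, format = c("auto", "table", "vcf")) {
  stopifnot(file.exists(path), inherits(panel, "snp_panel"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "table"
  }
  if (format == "vcf") .load_genotypes_vcf(path, panel) else
    .load_genotypes_table(path, panel)
}

.load_genotypes_table <- function(path, panel) {
  tab <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(tab)) stop("genotype table lacks a subject_id column")
  geno_cols <- setdiff(names(tab), "subject_id")
  unknown <- setdiff(geno_cols, panel$rsid)
  if (length(unknown)) {
    stop("unknown rsID column(s) in genotype table: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(panel$rsid, geno_cols)
  if (length(absent)) {
    stop("panel SNP(s) missing from genotype table: ",
         paste(absent, collapse = ", "))
  }
  n <- nrow(tab)
  dosage <- matrix(NA_integer_, n, nrow(panel))
  for (j in seq_len(nrow(panel))) {
    raw <- trimws(tab[[panel$rsid[j]]])
    miss <- raw %in% MISSING_TOKENS | is.na(raw)
    vals <- raw[!miss]
    col <- rep(NA_integer_, n)
    if (length(vals) && all(grepl("^[012]$", vals))) {
      col[!miss] <- as.integer(vals)
    } else {
      conv <- .pair_to_dosage(vals, panel$major_allele[j],
                              panel$minor_allele[j], panel$effect_allele[j])
      if (any(conv$invalid)) {
        if (mean(conv$invalid) > 0.5) {
          stop("more than 50% of calls at ", panel$rsid[j],
               " are inconsistent with panel alleles ",
               panel$major_allele[j], "/", panel$minor_allele[j],
               " - likely strand or allele mismatch")
        }
        warning(sum(conv$invalid), " call(s) at ", panel$rsid[j],
                " inconsistent with panel alleles; set to missing")
      }
      col[!miss] <- conv$dosage
    }
    dosage[, j] <- col
  }
  genotype_matrix(dosage, tab$subject_id, panel)
}

.load_genotypes_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) fix else matrix(fix, nrow = 1,
                                             dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  idx <- match(panel$rsid, ids)
  if (anyNA(idx)) {
    stop("panel SNP(s) not locatable by ID in VCF: ",
         paste(panel$rsid[is.na(idx)], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  dosage <- matrix(NA_integer_, length(samples), nrow(panel))
  for (j in seq_len(nrow(panel))) {
    i <- idx[j]
    ref <- toupper(fix[i, "REF"]); alt <- toupper(fix[i, "ALT"])
    if (grepl(",", alt)) {
      stop("multi-allelic VCF record at ", panel$rsid[j],
           " (panel is strictly biallelic)")
    }
    alleles <- c(ref, alt)
    if (!setequal(alleles, c(panel$major_allele[j], panel$minor_allele[j]))) {
      stop("VCF REF/ALT (", ref, "/", alt, ") at ", panel$rsid[j],
           " do not match panel alleles ", panel$major_allele[j], "/",
           panel$minor_allele[j])
    }
    effect_code <- which(alleles == panel$effect_allele[j]) - 1L
    calls <- gt[i, ]
    for (s in seq_along(calls)) {
      if (is.na(calls[s])) next
      codes <- strsplit(calls[s], "[/|]")[[1]]
      if (any(codes == ".")) next
      dosage[s, j] <- sum(as.integer(codes) == effect_code)
    }
  }
  genotype_matrix(dosage, samples, panel)
}

#' Write a genotype matrix as a tab-delimited dosage table
#'
#' The written table round-trips through [load_genotypes()] exactly,
#' including missing calls.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(subject_id = rownames(g), unclass(g),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

COHORT_FIELDS <- c("subject_id", "status", "sex", "age", "country",
                   "stage_ds", "stage_iss", "therapy", "vital", "os_time")

.parse_factor <- function(x, levels) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% tolower(MISSING_TOKENS)] <- NA
  out <- ifelse(x %in% levels, x, NA_character_)
  list(value = out, bad = sum(!is.na(x) & is.na(out)))
}

.parse_num <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% MISSING_TOKENS] <- NA
  out <- suppressWarnings(as.numeric(x))
  list(value = out, bad = sum(!is.na(x) & is.na(out)))
}

#' Load a phenotype/outcome table
#'
#' Reads a delimited text file with a header naming the cohort fields:
#' `subject_id`, `status` (case/control), `sex`, `age`, `country`,
#' `stage_ds`, `stage_iss` (1-3), `therapy` (new/old), `vital`
#' (alive/deceased), `os_time` (months from diagnosis, > 0).
#' Unparseable cells become missing; their count is reported via `message()`.
#'
#' @param path path to the delimited file (comma or tab separated).
#' @return A data frame of class `cohort_table`.
#' @export
load_cohort <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  mandatory <- c("subject_id", "status")
  absent <- setdiff(mandatory, names(tab))
  if (length(absent)) {
    stop("cohort table lacks mandatory column(s): ",
         paste(absent, collapse = ", "))
  }
  n <- nrow(tab)
  get <- function(col) if (col %in% names(tab)) tab[[col]] else rep(NA_character_, n)
  bad <- 0L
  take <- function(parsed) { bad <<- bad + parsed$bad; parsed$value }
  out <- data.frame(
    subject_id = as.character(tab$subject_id),
    status = take(.parse_factor(tab$status, c("case", "control"))),
    sex = take(.parse_factor(get("sex"), c("male", "female"))),
    age = take(.parse_num(get("age"))),
    country = { x <- trimws(get("country")); x[x %in% MISSING_TOKENS] <- NA; x },
    stage_ds = take(.parse_num(get("stage_ds"))),
    stage_iss = take(.parse_num(get("stage_iss"))),
    therapy = take(.parse_factor(get("therapy"), c("new", "old"))),
    vital = take(.parse_factor(get("vital"), c("alive", "deceased"))),
    os_time = take(.parse_num(get("os_time"))),
    stringsAsFactors = FALSE
  )
  for (col in c("stage_ds", "stage_iss")) {
    oos <- !is.na(out[[col]]) & !out[[col]] %in% 1:3
    bad <- bad + sum(oos)
    out[[col]][oos] <- NA
    out[[col]] <- as.integer(out[[col]])
  }
  if (bad > 0) message(bad, " unparseable cell(s) set to missing")
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a cohort table as tab-delimited text
#'
#' @param cohort a `cohort_table` (or compatible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
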