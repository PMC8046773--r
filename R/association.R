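#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around the binomial GLM with strict preconditions and Wald
#' inference, used by every case-control model in the package. The design
#' matrix is checked for full column rank and perfect separation is raised
#' as an error naming the offending term rather than returned as a silently
#' diverged fit.
#'
#' @param y binary 0/1 (or logical) response.
#' @param X optional numeric design matrix of covariate columns (an
#'   intercept is always added); `NULL` fits the intercept-only model.
#' @return List with `coef`, `se`, `vcov`, `or` (`exp(coef)`), `ci_low`,
#'   `ci_high` (Wald 95%), `p` (Wald), `n` and `converged`.
#' @examples
#' fit_logistic(rep(c(1, 0), c(25, 75)))$coef  # log(25/75)
#' @export
fit_logistic <- function(y, X = NULL) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("response is constant; cannot fit logistic model")
  n <- length(y)
  Xf <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    Xf <- cbind(Xf, X)
  }
  qr_x <- qr(Xf)
  if (qr_x$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qr_x$pivot[(qr_x$rank + 1):ncol(Xf)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(Xf, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (!fit$converged) stop("logistic model did not converge in 100 iterations")
  coefs <- fit$coefficients
  if (any(abs(coefs) > 15)) {
    stop("apparent perfect separation at term(s): ",
         paste(names(coefs)[abs(coefs) > 15], collapse = ", "))
  }
  w <- fit$weights
  vc <- solve(crossprod(Xf * sqrt(w)))
  dimnames(vc) <- list(colnames(Xf), colnames(Xf))
  se <- sqrt(diag(vc))
  z <- coefs / se
  list(coef = coefs, se = se, vcov = vc, or = exp(coefs),
       ci_low = exp(coefs - 1.96 * se), ci_high = exp(coefs + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)), n = n, converged = TRUE)
}

#' Fit a Cox proportional-hazards model
#'
#' Wrapper around [survival::coxph()] with Breslow tie handling by default
#' (monthly follow-up times make ties common; Efron is available via
#' `ties`), Wald confidence intervals and p-values, and non-convergence
#' raised as an error.
#'
#' @param time positive follow-up times.
#' @param event binary event indicator (1 = death).
#' @param X optional numeric design matrix.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List with `coef`, `se`, `vcov`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `n`, `n_events` and `converged`.
#' @export
fit_cox <- function(time, event, X = NULL, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  time <- as.numeric(time); event <- as.numeric(event)
  stopifnot(all(time > 0), all(event %in% c(0, 1)),
            length(time) == length(event))
  if (sum(event) < 1) stop("no events; cannot fit Cox model")
  if (is.null(X)) stop("Cox model requires at least one covariate column")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  dat <- data.frame(.time = time, .event = event, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info, collapse = " "))) {
    stop("Cox model did not converge")
  }
  coefs <- stats::coef(fit)
  names(coefs) <- gsub("`", "", names(coefs))
  if (anyNA(coefs)) {
    stop("Cox coefficients undetermined for term(s): ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "))
  }
  if (any(abs(coefs) > 15)) {
    warning("monotone likelihood suspected (|coef| > 15); estimate flagged ",
            "non-converged")
  }
  se <- sqrt(diag(fit$var))
  names(se) <- names(coefs)
  z <- coefs / se
  list(coef = coefs, se = se, vcov = fit$var, hr = exp(coefs),
       ci_low = exp(coefs - 1.96 * se), ci_high = exp(coefs + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)), n = fit$n, n_events = fit$nevent,
       converged = !any(abs(coefs) > 15))
}

# Expand categorical covariates to reference-coded indicator columns
# (reference = first level alphabetically) and keep numeric ones as-is.
# Covariates with a single observed level are dropped.
.covariate_matrix <- function(co, covariates) {
  cols <- list()
  for (v in covariates) {
    x <- co[[v]]
    if (v %in% c("sex", "country", "therapy", "stage_ds", "stage_iss")) {
      x <- factor(x)
      if (nlevels(droplevels(x[!is.na(x)])) < 2) next
      mm <- stats::model.matrix(~ x)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, sub("^x", "", colnames(mm)))
      full <- matrix(NA_real_, nrow(co), ncol(mm), dimnames = list(NULL, colnames(mm)))
      full[!is.na(x), ] <- mm
      cols[[v]] <- full
    } else {
      cols[[v]] <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, v))
    }
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

# Drop covariate columns that are constant within the analysis stratum
# (e.g. a country with no subjects left after filtering).
.drop_constant <- function(X) {
  if (is.null(X) || ncol(X) == 0) return(NULL)
  keep <- apply(X, 2, function(col) length(unique(col[!is.na(col)])) > 1)
  if (!any(keep)) return(NULL)
  X[, keep, drop = FALSE]
}

# Run a model fit, degrading to NULL with a warning so a degenerate SNP or
# quintile (separation, monotone likelihood) does not abort the whole scan.
.try_fit <- function(expr, label) {
  tryCatch(expr, error = function(e) {
    warning("model skipped for ", label, ": ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
}

.assoc_row <- function(rsid, model, term, est, se, eff, lo, hi, p, n) {
  data.frame(term = unname(term), rsid = unname(rsid), model = unname(model),
             estimate = unname(est), se = unname(se), effect = unname(eff),
             ci_low = unname(lo), ci_high = unname(hi), p = unname(p),
             n_used = unname(n), stringsAsFactors = FALSE)
}

#' Per-SNP case-control association models
#'
#' For each panel SNP fits an allelic (log-additive) model with genotype
#' coded as the rare-allele dosage, and a codominant model with heterozygote
#' and rare-homozygote indicators against the common-homozygote reference.
#' The reported odds ratios are per copy of (or per genotype carrying) the
#' MINOR allele; since the genotype matrix stores effect-allele dosages,
#' SNPs whose long-telomere allele is the common one are recoded internally.
#' All models adjust for the requested covariates (default age, sex,
#' country).
#'
#' @param g a [genotype_matrix()].
#' @param cohort a `cohort_table` with cases and controls.
#' @param panel the matching [snp_panel()].
#' @param covariates covariate names from the cohort table.
#' @return Data frame of association rows (`rsid`, `model` one of
#'   `allelic`, `codominant-het`, `codominant-hom`, estimate/OR/CI/p,
#'   `n_used`), with the Bonferroni threshold for the two-model scan in
#'   `attr(, "threshold")`.
#' @export
snp_models <- function(g, cohort, panel,
                       covariates = c("age", "sex", "country")) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(panel, "snp_panel"))
  idx <- match(rownames(g), cohort$subject_id)
  if (anyNA(idx)) stop("genotyped subject(s) absent from cohort table")
  co <- cohort[idx, ]
  if (!all(c("case", "control") %in% co$status)) {
    stop("cohort must contain both cases and controls")
  }
  y <- as.numeric(co$status == "case")
  covX <- .covariate_matrix(co, covariates)
  res <- list()
  for (j in seq_len(nrow(panel))) {
    d_eff <- unclass(g)[, j]
    minor_dosage <- if (panel$effect_allele[j] == panel$minor_allele[j])
      d_eff else 2L - d_eff
    use <- !is.na(minor_dosage) & !is.na(y) &
      (if (is.null(covX)) TRUE else stats::complete.cases(covX))
    md <- minor_dosage[use]
    if (length(unique(md)) < 2) {
      warning("monomorphic SNP skipped: ", panel$rsid[j])
      next
    }
    Xc <- if (is.null(covX)) NULL else .drop_constant(covX[use, , drop = FALSE])
    fa <- .try_fit(fit_logistic(y[use], cbind(dosage = md, Xc)),
                   paste0(panel$rsid[j], " allelic"))
    if (!is.null(fa)) {
      res[[length(res) + 1]] <- .assoc_row(
        panel$rsid[j], "allelic", "dosage", fa$coef["dosage"], fa$se["dosage"],
        fa$or["dosage"], fa$ci_low["dosage"], fa$ci_high["dosage"],
        fa$p["dosage"], fa$n)
    }
    het <- as.numeric(md == 1); hom <- as.numeric(md == 2)
    if (sum(hom) == 0) {
      warning("no rare homozygotes at ", panel$rsid[j],
              "; codominant hom term dropped")
      Xg <- cbind(het = het, Xc)
      keep_terms <- "het"
    } else {
      Xg <- cbind(het = het, hom = hom, Xc)
      keep_terms <- c("het", "hom")
    }
    fc <- .try_fit(fit_logistic(y[use], Xg),
                   paste0(panel$rsid[j], " codominant"))
    if (is.null(fc) && length(keep_terms) == 2) {
      # retry without the sparse rare-homozygote term
      warning("rare-homozygote term unstable at ", panel$rsid[j],
              "; dropped")
      keep_terms <- "het"
      fc <- .try_fit(fit_logistic(y[use], cbind(het = het, Xc)),
                     paste0(panel$rsid[j], " codominant-het"))
    }
    if (!is.null(fc)) {
      for (tm in keep_terms) {
        res[[length(res) + 1]] <- .assoc_row(
          panel$rsid[j], paste0("codominant-", tm), tm, fc$coef[tm], fc$se[tm],
          fc$or[tm], fc$ci_low[tm], fc$ci_high[tm], fc$p[tm], fc$n)
      }
    }
  }
  out <- do.call(rbind, res)
  attr(out, "threshold") <- bonferroni_threshold(panel)
  out
}

#' Teloscore quintile models for case-control risk
#'
#' For each score variant fits (a) a categorical logistic model with
#' indicators for quintiles 2-5 against quintile 1 and (b) a continuous
#' model with the quintile index 1..5 as a numeric covariate (the estimate
#' is the increase in risk per one-quintile increase). Adjusted for age,
#' sex and country by default.
#'
#' @param scored result of [score_cohort()] in risk mode.
#' @param cohort the `cohort_table`.
#' @param covariates covariate names.
#' @param variants score variants to analyse.
#' @return Data frame of association rows; per-variant quintile occupancy
#'   (controls/cases/total) is attached as `attr(, "counts")`.
#' @export
score_risk_models <- function(scored, cohort,
                              covariates = c("age", "sex", "country"),
                              variants = c("unweighted", "weighted",
                                           "unweighted_scaled",
                                           "weighted_scaled")) {
  scores <- scored$scores
  idx <- match(scores$subject_id, cohort$subject_id)
  co <- cohort[idx, ]
  y <- as.numeric(co$status == "case")
  covX <- .covariate_matrix(co, covariates)
  res <- list(); counts <- list()
  for (v in variants) {
    q <- scores[[paste0("q_", sub("_bp$", "", v))]]
    use0 <- !is.na(q) & !is.na(y) &
      (if (is.null(covX)) TRUE else stats::complete.cases(covX))
    counts[[v]] <- as.data.frame(table(quintile = q[use0],
                                       status = co$status[use0]))
    present <- sort(unique(q[use0]))
    if (!1 %in% present) {
      warning("no subjects in reference quintile 1 for ", v, "; skipped")
      next
    }
    if (length(setdiff(2:5, present))) {
      warning("empty quintile(s) ", paste(setdiff(2:5, present), collapse = ","),
              " for ", v, "; contrast omitted")
    }
    qi <- matrix(0, sum(use0), length(intersect(2:5, present)),
                 dimnames = list(NULL, paste0("quintile-", intersect(2:5, present))))
    for (k in intersect(2:5, present)) qi[, paste0("quintile-", k)] <- q[use0] == k
    Xc <- if (is.null(covX)) NULL else
      .drop_constant(covX[use0, , drop = FALSE])
    fcat <- .try_fit(fit_logistic(y[use0], cbind(qi, Xc)),
                     paste0(v, " categorical"))
    if (!is.null(fcat)) {
      for (tm in colnames(qi)) {
        res[[length(res) + 1]] <- .assoc_row(
          v, tm, tm, fcat$coef[tm], fcat$se[tm], fcat$or[tm],
          fcat$ci_low[tm], fcat$ci_high[tm], fcat$p[tm], fcat$n)
      }
    }
    fcon <- .try_fit(fit_logistic(y[use0], cbind(quintile = q[use0], Xc)),
                     paste0(v, " continuous"))
    if (!is.null(fcon)) {
      res[[length(res) + 1]] <- .assoc_row(
        v, "quintile-continuous", "quintile", fcon$coef["quintile"],
        fcon$se["quintile"], fcon$or["quintile"], fcon$ci_low["quintile"],
        fcon$ci_high["quintile"], fcon$p["quintile"], fcon$n)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "counts") <- counts
  out
}

#' Overall-survival endpoint from the cohort table
#'
#' Overall survival is the time from diagnosis to death (event) or last
#' follow-up (censored). Cases missing vital status or follow-up time are
#' excluded with a messaged count; nonpositive times are dropped with a
#' warning.
#'
#' @param cohort a `cohort_table`.
#' @return Data frame `subject_id`, `time` (months), `event` (1 = deceased).
#' @export
os_endpoint <- function(cohort) {
  cases <- cohort[!is.na(cohort$status) & cohort$status == "case", ]
  has <- !is.na(cases$vital) & !is.na(cases$os_time)
  if (any(!has)) {
    message(sum(!has), " case(s) without vital status or follow-up excluded")
  }
  cases <- cases[has, ]
  pos <- cases$os_time > 0
  if (any(!pos)) {
    warning(sum(!pos), " case(s) with nonpositive follow-up time dropped")
    cases <- cases[pos, ]
  }
  data.frame(subject_id = cases$subject_id, time = cases$os_time,
             event = as.numeric(cases$vital == "deceased"),
             stringsAsFactors = FALSE)
}

.survival_frame <- function(cohort, stage_system) {
  ep <- os_endpoint(cohort)
  idx <- match(ep$subject_id, cohort$subject_id)
  co <- cohort[idx, ]
  stage <- if (stage_system == "ds") co$stage_ds else co$stage_iss
  keep <- !is.na(stage) & !is.na(co$therapy)
  co <- co[keep, ]; ep <- ep[keep, ]
  co$stage <- if (stage_system == "ds") co$stage_ds else co$stage_iss
  list(endpoint = ep, covars = co)
}

#' Cox models for overall survival: per-SNP and teloscore-quintile
#'
#' Restricted to cases with complete stage (chosen system), first-line
#' therapy and survival data; adjusted for age, sex, country, stage and
#' therapy. With a [genotype_matrix()] input, fits allelic and codominant
#' Cox models per SNP; with a [score_cohort()] result, fits categorical
#' (quintiles 2-5 vs 1) and continuous quintile models per score variant.
#'
#' @param x a `genotype_matrix` or the result of
#'   `score_cohort(..., analysis = "survival")`.
#' @param cohort the `cohort_table`.
#' @param panel the [snp_panel()] (required for genotype input).
#' @param stage_system `"ds"` or `"iss"` stage adjustment.
#' @param covariates baseline covariates in addition to stage and therapy.
#' @return Data frame of association rows (hazard-ratio scale).
#' @export
survival_models <- function(x, cohort, panel = NULL,
                            stage_system = c("ds", "iss"),
                            covariates = c("age", "sex", "country")) {
  stage_system <- match.arg(stage_system)
  sf <- .survival_frame(cohort, stage_system)
  if (nrow(sf$endpoint) < 2 || sum(sf$endpoint$event) < 2) {
    stop("survival stratum too small: fewer than 2 events")
  }
  covs <- c(covariates, if (stage_system == "ds") "stage_ds" else "stage_iss",
            "therapy")
  covX <- .covariate_matrix(sf$covars, covs)
  res <- list()
  if (inherits(x, "genotype_matrix")) {
    stopifnot(inherits(panel, "snp_panel"))
    gidx <- match(sf$endpoint$subject_id, rownames(x))
    if (anyNA(gidx)) stop("survival subject(s) missing from genotype matrix")
    for (j in seq_len(nrow(panel))) {
      d_eff <- unclass(x)[gidx, j]
      md <- if (panel$effect_allele[j] == panel$minor_allele[j])
        d_eff else 2L - d_eff
      use <- !is.na(md) & stats::complete.cases(covX)
      if (length(unique(md[use])) < 2) {
        warning("monomorphic SNP skipped in survival scan: ", panel$rsid[j])
        next
      }
      Xc <- .drop_constant(covX[use, , drop = FALSE])
      fa <- .try_fit(fit_cox(sf$endpoint$time[use], sf$endpoint$event[use],
                             cbind(dosage = md[use], Xc)),
                     paste0(panel$rsid[j], " allelic"))
      if (!is.null(fa)) {
        res[[length(res) + 1]] <- .assoc_row(
          panel$rsid[j], "allelic", "dosage", fa$coef["dosage"],
          fa$se["dosage"], fa$hr["dosage"], fa$ci_low["dosage"],
          fa$ci_high["dosage"], fa$p["dosage"], fa$n)
      }
      het <- as.numeric(md[use] == 1); hom <- as.numeric(md[use] == 2)
      terms <- if (sum(hom) == 0) {
        warning("no rare homozygotes at ", panel$rsid[j],
                "; codominant hom term dropped")
        "het"
      } else c("het", "hom")
      Xg <- if (identical(terms, "het")) cbind(het = het, Xc) else
        cbind(het = het, hom = hom, Xc)
      fc <- .try_fit(fit_cox(sf$endpoint$time[use], sf$endpoint$event[use],
                             Xg),
                     paste0(panel$rsid[j], " codominant"))
      if (is.null(fc) && length(terms) == 2) {
        warning("rare-homozygote term unstable at ", panel$rsid[j],
                "; dropped")
        terms <- "het"
        fc <- .try_fit(fit_cox(sf$endpoint$time[use],
                               sf$endpoint$event[use],
                               cbind(het = het, Xc)),
                       paste0(panel$rsid[j], " codominant-het"))
      }
      if (!is.null(fc)) {
        for (tm in terms) {
          res[[length(res) + 1]] <- .assoc_row(
            panel$rsid[j], paste0("codominant-", tm), tm, fc$coef[tm],
            fc$se[tm], fc$hr[tm], fc$ci_low[tm], fc$ci_high[tm], fc$p[tm],
            fc$n)
        }
      }
    }
  } else if (is.list(x) && !is.null(x$scores)) {
    scores <- x$scores
    sidx <- match(sf$endpoint$subject_id, scores$subject_id)
    if (anyNA(sidx)) stop("survival subject(s) missing from score set")
    for (v in c("unweighted", "weighted", "unweighted_scaled",
                "weighted_scaled")) {
      q <- scores[[paste0("q_", sub("_bp$", "", v))]][sidx]
      use <- !is.na(q) & stats::complete.cases(covX)
      if (sum(sf$endpoint$event[use]) < 2) {
        warning("too few events for score variant ", v, "; skipped")
        next
      }
      present <- sort(unique(q[use]))
      ks <- intersect(2:5, present)
      Xc <- .drop_constant(covX[use, , drop = FALSE])
      if (length(ks)) {
        qi <- matrix(0, sum(use), length(ks),
                     dimnames = list(NULL, paste0("quintile-", ks)))
        for (k in ks) qi[, paste0("quintile-", k)] <- q[use] == k
        fcat <- .try_fit(fit_cox(sf$endpoint$time[use],
                                 sf$endpoint$event[use], cbind(qi, Xc)),
                         paste0(v, " categorical"))
        if (!is.null(fcat)) {
          for (tm in colnames(qi)) {
            res[[length(res) + 1]] <- .assoc_row(
              v, tm, tm, fcat$coef[tm], fcat$se[tm], fcat$hr[tm],
              fcat$ci_low[tm], fcat$ci_high[tm], fcat$p[tm], fcat$n)
          }
        }
      }
      fcon <- .try_fit(fit_cox(sf$endpoint$time[use], sf$endpoint$event[use],
                               cbind(quintile = q[use], Xc)),
                       paste0(v, " continuous"))
      if (!is.null(fcon)) {
        res[[length(res) + 1]] <- .assoc_row(
          v, "quintile-continuous", "quintile", fcon$coef["quintile"],
          fcon$se["quintile"], fcon$hr["quintile"], fcon$ci_low["quintile"],
          fcon$ci_high["quintile"], fcon$p["quintile"], fcon$n)
      }
    }
  } else {
    stop("x must be a genotype_matrix or a score_cohort() result")
  }
  do.call(rbind, res)
}
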