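#' Per-SNP summary statistics for two-sample Mendelian randomization
#'
#' @param rsid instrument identifiers.
#' @param bx instrument-exposure effects (telomere length per effect
#'   allele; the unit — bp or kb — is the caller's declaration and carries
#'   through to the causal-slope scale).
#' @param bxse standard errors of `bx` (strictly positive).
#' @param by instrument-outcome effects (log-OR for risk, log-HR for
#'   survival), oriented to the same effect allele as `bx`.
#' @param byse standard errors of `by` (strictly positive).
#' @return Data frame of class `mr_summary_set`.
#' @export
mr_summary_set <- function(rsid, bx, bxse, by, byse) {
  out <- data.frame(rsid = as.character(rsid), bx = as.numeric(bx),
                    bxse = as.numeric(bxse), by = as.numeric(by),
                    byse = as.numeric(byse), stringsAsFactors = FALSE)
  if (nrow(out) < 1) stop("need at least one instrument")
  if (any(!is.finite(as.matrix(out[-1])))) stop("non-finite summary statistic")
  if (any(out$bxse <= 0) || any(out$byse <= 0)) {
    stop("standard errors must be strictly positive")
  }
  class(out) <- c("mr_summary_set", "data.frame")
  out
}

#' Build MR inputs from per-SNP association results and panel weights
#'
#' Bridges the per-SNP allelic association scan (odds or hazard ratios per
#' MINOR allele with 95% CIs) and the panel's per-allele telomere-length
#' weights into an [mr_summary_set()]. Outcome effects are re-oriented to
#' the long-telomere effect allele (the log-ratio is negated where the
#' effect allele is the common one); `byse` is recovered from the CI width
#' on the log scale, `(log(hi) - log(lo)) / (2 * 1.96)`.
#'
#' @param snp_assoc data frame of allelic association rows with columns
#'   `rsid`, `effect`, `ci_low`, `ci_high` (rows with `model == "allelic"`
#'   are selected if a `model` column is present).
#' @param panel a [snp_panel()] with configured `weight_bp` (and optionally
#'   `weight_se_bp`).
#' @param exposure_unit `"kb"` (default) or `"bp"`: unit in which the
#'   exposure effects enter the MR, hence the per-unit scale of the causal
#'   slope.
#' @return An [mr_summary_set()]; SNPs with missing CIs are dropped with a
#'   warning. When the panel has no weight standard errors, `bxse` defaults
#'   to 10% of the weight (forest/I2GX diagnostics only; IVW and Egger point
#'   estimates do not use `bxse`).
#' @export
summary_from_tables <- function(snp_assoc, panel,
                                exposure_unit = c("kb", "bp")) {
  exposure_unit <- match.arg(exposure_unit)
  stopifnot(inherits(panel, "snp_panel"))
  if (anyNA(panel$weight_bp)) stop("panel weights are not configured")
  if ("model" %in% names(snp_assoc)) {
    snp_assoc <- snp_assoc[snp_assoc$model == "allelic", ]
  }
  idx <- match(panel$rsid, snp_assoc$rsid)
  keep <- !is.na(idx)
  if (any(!keep)) {
    warning("no allelic estimate for: ",
            paste(panel$rsid[!keep], collapse = ", "), "; dropped")
  }
  pa <- panel[keep, ]; sa <- snp_assoc[idx[keep], ]
  ok <- is.finite(sa$effect) & is.finite(sa$ci_low) & is.finite(sa$ci_high) &
    sa$effect > 0 & sa$ci_low > 0
  if (any(!ok)) {
    warning("missing or invalid CI for: ", paste(pa$rsid[!ok], collapse = ", "),
            "; dropped")
    pa <- pa[ok, ]; sa <- sa[ok, ]
  }
  by_minor <- log(sa$effect)
  flip <- pa$effect_allele == pa$major_allele
  by <- ifelse(flip, -by_minor, by_minor)
  byse <- (log(sa$ci_high) - log(sa$ci_low)) / (2 * 1.96)
  scale <- if (exposure_unit == "kb") 1 / 1000 else 1
  bx <- pa$weight_bp * scale
  bxse <- if ("weight_se_bp" %in% names(pa) && !anyNA(pa$weight_se_bp)) {
    pa$weight_se_bp * scale
  } else {
    0.1 * pmax(bx, .Machine$double.eps)
  }
  mr_summary_set(pa$rsid, bx, bxse, by, byse)
}

#' Single-instrument Wald ratio
#'
#' @param bx,bxse,by,byse scalar summary statistics.
#' @return List with `estimate = by / bx` and first-order
#'   `se = |byse / bx|` (exposure-side error ignored, the standard
#'   forest-plot convention).
#' @export
wald_ratio <- function(bx, bxse, by, byse) {
  if (bx == 0) stop("Wald ratio undefined for bx = 0")
  list(estimate = by / bx, se = abs(byse / bx))
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' through the origin with weights `byse^-2`: the slope is
#' `sum(w bx by) / sum(w bx^2)`. The fixed-effect standard error is
#' `(sum(w bx^2))^-1/2`; the multiplicative random-effects standard error
#' inflates it by `max(1, sqrt(Q / (K - 1)))` where Q is Cochran's
#' heterogeneity statistic about the fitted slope. The two modes share the
#' same point estimate.
#'
#' @param s an [mr_summary_set()].
#' @param mode `"fixed"` or `"mre"` (multiplicative random effects).
#' @return List of class `mr_result` with `method`, `slope`, `slope_se`,
#'   `slope_ci95`, `slope_p`, `Q`, `Q_df`, `Q_p` (for K >= 2) and `K`.
#' @export
mr_ivw <- function(s, mode = c("fixed", "mre")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "mr_summary_set"))
  if (all(s$bx == 0)) stop("all exposure effects are zero")
  w <- s$byse^-2
  slope <- sum(w * s$bx * s$by) / sum(w * s$bx^2)
  se_fixed <- 1 / sqrt(sum(w * s$bx^2))
  K <- nrow(s)
  if (K >= 2) {
    q <- cochran_q(s, slope, df = K - 1)
  } else {
    q <- list(Q = NA_real_, df = NA_integer_, p = NA_real_)
  }
  se <- if (mode == "mre") {
    if (K < 2) stop("multiplicative random effects require K >= 2")
    se_fixed * max(1, sqrt(q$Q / (K - 1)))
  } else se_fixed
  z <- slope / se
  structure(list(
    method = paste0("ivw-", mode), slope = slope, slope_se = se,
    slope_ci95 = c(slope - 1.96 * se, slope + 1.96 * se),
    slope_p = 2 * stats::pnorm(-abs(z)),
    Q = q$Q, Q_df = q$df, Q_p = q$p, K = K), class = "mr_result")
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept, weights `byse^-2`. Instruments are first
#' oriented so every exposure effect is nonnegative (pairs with `bx < 0`
#' have both `bx` and `by` negated), the standard formulation under which
#' the intercept estimates directional pleiotropy. Standard errors are
#' inflated by `max(1, sqrt(Q_egger / (K - 2)))`; the Bowden I2GX
#' instrument-strength statistic is attached.
#'
#' @param s an [mr_summary_set()] with at least 3 instruments and
#'   non-constant `bx`.
#' @return List of class `mr_result` with slope and intercept estimates,
#'   standard errors, 95% CIs and p-values, `Q` (about the Egger fit,
#'   `K - 2` df), and `i2_gx`.
#' @export
mr_egger <- function(s) {
  stopifnot(inherits(s, "mr_summary_set"))
  K <- nrow(s)
  if (K < 3) stop("MR-Egger requires at least 3 instruments")
  flip <- s$bx < 0
  bx <- ifelse(flip, -s$bx, s$bx)
  by <- ifelse(flip, -s$by, s$by)
  if (length(unique(bx)) < 2) {
    stop("exposure effects are all equal after orientation; ",
         "Egger slope and intercept are not separable")
  }
  w <- s$byse^-2
  X <- cbind(intercept = 1, bx = bx)
  xtwx <- crossprod(X * sqrt(w))
  beta <- solve(xtwx, crossprod(X * w, by))
  resid <- by - X %*% beta
  q_egger <- sum(w * resid^2)
  inflate <- max(1, sqrt(q_egger / (K - 2)))
  vc <- solve(xtwx) * inflate^2
  est <- drop(beta); se <- sqrt(diag(vc))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  i2 <- i2_gx(bx, s$bxse)
  structure(list(
    method = "egger",
    slope = est["bx"], slope_se = se["bx"],
    slope_ci95 = c(est["bx"] - 1.96 * se["bx"], est["bx"] + 1.96 * se["bx"]),
    slope_p = p["bx"],
    intercept = est["intercept"], intercept_se = se["intercept"],
    intercept_ci95 = c(est["intercept"] - 1.96 * se["intercept"],
                       est["intercept"] + 1.96 * se["intercept"]),
    intercept_p = p["intercept"],
    Q = q_egger, Q_df = K - 2,
    Q_p = stats::pchisq(q_egger, K - 2, lower.tail = FALSE),
    i2_gx = i2, K = K), class = "mr_result")
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(byse^-2 (by - slope * bx)^2)` about a fitted causal slope, with
#' K - 1 degrees of freedom for the through-origin (IVW) fit or K - 2 when
#' the residuals come from the Egger fit.
#'
#' @param s an [mr_summary_set()].
#' @param slope fitted causal slope.
#' @param df degrees of freedom (default `K - 1`).
#' @return List with `Q`, `df` and the upper chi-square tail `p`.
#' @export
cochran_q <- function(s, slope, df = nrow(s) - 1L) {
  stopifnot(inherits(s, "mr_summary_set"))
  if (df <= 0) stop("Cochran Q requires positive degrees of freedom")
  Q <- sum(s$byse^-2 * (s$by - slope * s$bx)^2)
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Bowden I2GX instrument-strength statistic for MR-Egger
#'
#' The fraction of variation among the exposure effects not attributable to
#' their estimation error: with `Q_GX = sum(bxse^-2 (bx - bxbar)^2)` about
#' the `bxse^-2`-weighted mean, `I2GX = max(0, (Q_GX - (K-1)) / Q_GX)`.
#' Values near 1 indicate that regression-dilution bias of the Egger slope
#' is negligible.
#'
#' @param bx exposure effects (K >= 2).
#' @param bxse their standard errors (> 0).
#' @param weights optional alternative weights replacing `bxse^-2` (e.g.
#'   outcome-side weights for an outcome-weighted variant).
#' @return Fraction in `[0, 1]`; 0 with a weak-instrument warning when the
#'   exposure effects are identical.
#' @export
i2_gx <- function(bx, bxse, weights = NULL) {
  stopifnot(length(bx) >= 2, length(bxse) == length(bx), all(bxse > 0))
  w <- if (is.null(weights)) bxse^-2 else weights
  bxbar <- sum(w * bx) / sum(w)
  q_gx <- sum(bxse^-2 * (bx - bxbar)^2)
  if (q_gx == 0) {
    warning("identical exposure effects: weak instrument for MR-Egger ",
            "(I2GX = 0)")
    return(0)
  }
  max(0, (q_gx - (length(bx) - 1)) / q_gx)
}

#' Full Mendelian-randomization report
#'
#' Runs fixed-effect and multiplicative-random-effects IVW, MR-Egger with
#' intercept, Cochran's Q and both I2GX weighting variants, and assembles
#' scatter- and forest-plot data tables.
#'
#' @param s an [mr_summary_set()] with K >= 3.
#' @return List of class `mr_report` with elements `ivw_fixed`, `ivw_mre`,
#'   `egger`, `i2_gx` (exposure-weighted), `i2_gx_outcome_weighted`,
#'   `scatter` (per-SNP bx/by with error bars and fitted lines) and
#'   `forest` (per-SNP Wald ratios plus the pooled estimates).
#' @export
mr_report <- function(s) {
  stopifnot(inherits(s, "mr_summary_set"))
  if (nrow(s) < 3) stop("mr_report requires at least 3 instruments")
  ivw_f <- mr_ivw(s, "fixed")
  ivw_m <- mr_ivw(s, "mre")
  egger <- mr_egger(s)
  flip <- s$bx < 0
  bx_or <- ifelse(flip, -s$bx, s$bx)
  i2_out <- i2_gx(bx_or, s$bxse, weights = s$byse^-2)
  wr <- mapply(function(bx, bxse, by, byse) {
    unlist(wald_ratio(bx, bxse, by, byse))
  }, s$bx, s$bxse, s$by, s$byse)
  forest <- data.frame(
    label = c(s$rsid, "IVW (fixed)", "IVW (mre)", "MR-Egger"),
    estimate = c(wr["estimate", ], ivw_f$slope, ivw_m$slope, egger$slope),
    se = c(wr["se", ], ivw_f$slope_se, ivw_m$slope_se, egger$slope_se),
    stringsAsFactors = FALSE
  )
  forest$ci_low <- forest$estimate - 1.96 * forest$se
  forest$ci_high <- forest$estimate + 1.96 * forest$se
  scatter <- data.frame(
    rsid = s$rsid, bx = s$bx, bxse = s$bxse, by = s$by, byse = s$byse,
    fitted_ivw = ivw_f$slope * s$bx,
    fitted_egger = ifelse(s$bx < 0, -1, 1) * egger$intercept +
      egger$slope * s$bx,
    stringsAsFactors = FALSE
  )
  structure(list(ivw_fixed = ivw_f, ivw_mre = ivw_m, egger = egger,
                 i2_gx = egger$i2_gx, i2_gx_outcome_weighted = i2_out,
                 scatter = scatter, forest = forest, K = nrow(s)),
            class = "mr_report")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: slope = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$method, x$slope, x$slope_se, x$slope_ci95[1], x$slope_ci95[2],
              x$slope_p))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_ci95[1],
                x$intercept_ci95[2], x$intercept_p))
    cat(sprintf("  I2GX = %.1f%%\n", 100 * x$i2_gx))
  }
  if (!is.null(x$Q) && !is.na(x$Q)) {
    cat(sprintf("  Q = %.3f on %d df, p = %.3g\n", x$Q, x$Q_df, x$Q_p))
  }
  invisible(x)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("Mendelian randomization with %d instruments\n", x$K))
  print(x$ivw_fixed); print(x$ivw_mre); print(x$egger)
  cat(sprintf("I2GX: %.1f%% (exposure-weighted), %.1f%% (outcome-weighted)\n",
              100 * x$i2_gx, 100 * x$i2_gx_outcome_weighted))
  invisible(x)
}
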