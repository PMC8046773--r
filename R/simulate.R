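#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the multicentre myeloma case-control study the package
#' is modelled on: 2407 cases and 1741 controls with the printed country
#' margins, 11 independent biallelic SNPs in Hardy-Weinberg equilibrium at
#' the printed minor allele frequencies, telomere length linear in
#' effect-allele counts with the score explaining 2.28% of its variance,
#' case status from a logistic liability on telomere length (in kb), a
#' Weibull proportional-hazards survival model on telomere length, stage
#' and therapy, and 3.7% per-call missingness (96.3% mean call rate).
#'
#' @param n_cases,n_controls cohort arm sizes.
#' @param panel a [snp_panel()] with weights; default is the built-in panel
#'   carrying the bundled synthetic weights.
#' @param target_score_r2 fraction of telomere-length variance explained by
#'   the weighted score (default 0.0228).
#' @param baseline_tl mean telomere length, bp (default 7000, a typical
#'   adult leukocyte value).
#' @param theta_risk log-odds of case status per kb of telomere length
#'   (default 0.3, i.e. OR about 1.35/kb, matching the published effect
#'   scale; 0 gives a null cohort).
#' @param gamma_os log-hazard per kb of telomere length (default -0.2:
#'   longer telomeres, better survival; 0 gives a null cohort).
#' @param beta_age,beta_sex log-odds per year of age / for male sex in the
#'   case-control liability (default 0: no confounding).
#' @param stage_loghr,therapy_loghr log-hazard per stage step and for
#'   new-class first-line therapy (defaults 0.4 and -0.3).
#' @param missing_rate per-call missingness probability (default 0.037).
#' @param weibull_shape,weibull_scale baseline Weibull event-time
#'   parameters, months (defaults 1.2 and 80).
#' @param censor_rate exponential censoring rate per month (default 1/90).
#' @param admin_cap administrative censoring horizon, months (default 120).
#' @param p_stage_ds,p_stage_iss,p_os availability probabilities of
#'   Durie-Salmon stage, ISS stage (given DS available / not) and survival
#'   data among cases, defaulting to the printed completeness fractions.
#' @param pleiotropy optional per-SNP direct log-odds effects on case
#'   status (default all zero; named by rsid or in panel order).
#' @param seed integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cases = 2407, n_controls = 1741,
                       panel = set_panel_weights(builtin_panel(),
                                                 synthetic_weights_path()),
                       target_score_r2 = 0.0228, baseline_tl = 7000,
                       theta_risk = 0.3, gamma_os = -0.2,
                       beta_age = 0, beta_sex = 0,
                       stage_loghr = 0.4, therapy_loghr = -0.3,
                       missing_rate = 0.037,
                       weibull_shape = 1.2, weibull_scale = 80,
                       censor_rate = 1 / 90, admin_cap = 120,
                       p_stage_ds = 1235 / 2407,
                       p_stage_iss = c(984 / 1235, 38 / 1172),
                       p_os = 1273 / 2407,
                       pleiotropy = NULL, seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            target_score_r2 > 0, target_score_r2 < 1,
            missing_rate >= 0, missing_rate < 1,
            inherits(panel, "snp_panel"))
  if (is.null(pleiotropy)) {
    pleiotropy <- stats::setNames(rep(0, nrow(panel)), panel$rsid)
  } else if (!is.null(names(pleiotropy))) {
    pleiotropy <- stats::setNames(
      ifelse(panel$rsid %in% names(pleiotropy),
             as.numeric(pleiotropy[panel$rsid]), 0), panel$rsid)
  } else {
    pleiotropy <- stats::setNames(rep_len(pleiotropy, nrow(panel)), panel$rsid)
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls, panel = panel,
    target_score_r2 = target_score_r2, baseline_tl = baseline_tl,
    theta_risk = theta_risk, gamma_os = gamma_os,
    beta_age = beta_age, beta_sex = beta_sex,
    stage_loghr = stage_loghr, therapy_loghr = therapy_loghr,
    missing_rate = missing_rate, weibull_shape = weibull_shape,
    weibull_scale = weibull_scale, censor_rate = censor_rate,
    admin_cap = admin_cap, p_stage_ds = p_stage_ds,
    p_stage_iss = p_stage_iss, p_os = p_os,
    pleiotropy = pleiotropy, seed = as.integer(seed)), class = "sim_config")
}

#' Simulate complete genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP's effect-allele dosage is Binomial(2, effect-allele frequency),
#' independent across SNPs and subjects — the HWE null structure the QC
#' module tests against.
#'
#' @param n number of subjects.
#' @param cfg a [sim_config()].
#' @param seed optional seed (`NULL` leaves the RNG stream untouched).
#' @return A complete [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  panel <- cfg$panel
  dosage <- vapply(panel$effect_allele_freq,
                   function(f) stats::rbinom(n, 2L, f), integer(n))
  genotype_matrix(matrix(dosage, nrow = n), sprintf("S%05d", seq_len(n)),
                  panel)
}

#' Simulate telomere length linear in the weighted score
#'
#' `TL_i = baseline + score_i + e_i` with Gaussian noise scaled so the
#' score explains `target_score_r2` of the telomere-length variance:
#' `var(e) = var(score) * (1 / r2 - 1)`, computed from the realized score
#' variance.
#'
#' @param g a complete [genotype_matrix()].
#' @param cfg a [sim_config()].
#' @param seed optional seed.
#' @return Numeric telomere lengths in bp.
#' @export
simulate_ltl <- function(g, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- cfg$panel$weight_bp
  if (anyNA(w)) stop("panel weights are not configured")
  score <- as.numeric(unclass(g) %*% w)
  v <- stats::var(score)
  if (!is.finite(v) || v == 0) {
    stop("degenerate weights: score variance is zero")
  }
  sigma <- sqrt(v * (1 / cfg$target_score_r2 - 1))
  cfg$baseline_tl + score + stats::rnorm(nrow(g), 0, sigma)
}

#' Simulate case/control status from a logistic liability
#'
#' `P(case) = plogis(alpha0 + theta_risk * (TL - mean(TL)) / 1000 +`
#' covariate terms `+` per-SNP pleiotropic terms`)`, with the intercept
#' root-solved so the expected case fraction matches the configured arm
#' sizes.
#'
#' @param tl telomere lengths, bp.
#' @param covariates data frame with `age` and `sex` (used when the
#'   corresponding effects are nonzero); may be `NULL`.
#' @param cfg a [sim_config()].
#' @param g optional genotype matrix supplying the pleiotropic direct
#'   effects (required only when some `pleiotropy` is nonzero).
#' @param seed optional seed.
#' @return Character vector `"case"`/`"control"`.
#' @export
simulate_status <- function(tl, covariates = NULL, cfg, g = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.finite(cfg$theta_risk))
  lp <- cfg$theta_risk * (tl - mean(tl)) / 1000
  if (!is.null(covariates)) {
    if (cfg$beta_age != 0) lp <- lp + cfg$beta_age * (covariates$age - mean(covariates$age))
    if (cfg$beta_sex != 0) lp <- lp + cfg$beta_sex * (covariates$sex == "male")
  }
  if (any(cfg$pleiotropy != 0)) {
    if (is.null(g)) stop("pleiotropy configured but no genotypes supplied")
    lp <- lp + as.numeric(unclass(g) %*% cfg$pleiotropy)
  }
  target <- cfg$n_cases / (cfg$n_cases + cfg$n_controls)
  f <- function(a) mean(stats::plogis(a + lp)) - target
  if (f(-30) > 0 || f(30) < 0) stop("unattainable case fraction")
  alpha0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  status <- ifelse(stats::runif(length(tl)) < stats::plogis(alpha0 + lp),
                   "case", "control")
  attr(status, "alpha0") <- alpha0
  status
}

#' Simulate overall survival under a Weibull proportional-hazards model
#'
#' Event times follow a Weibull with log-hazard
#' `gamma_os * (TL - mean) / 1000 + stage_loghr * (stage - 2) +
#' therapy_loghr * (therapy == "new")`; censoring is independent
#' exponential plus an administrative horizon.
#'
#' @param tl telomere lengths (bp) of the patients.
#' @param stage integer stage 1-3.
#' @param therapy `"new"`/`"old"`.
#' @param cfg a [sim_config()].
#' @param seed optional seed.
#' @return Data frame `os_time` (months) and `vital`
#'   (`"deceased"`/`"alive"`).
#' @export
simulate_survival <- function(tl, stage, therapy, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.finite(cfg$gamma_os))
  n <- length(tl)
  lp <- cfg$gamma_os * (tl - mean(tl)) / 1000 +
    cfg$stage_loghr * (stage - 2) +
    cfg$therapy_loghr * (therapy == "new")
  u <- stats::runif(n)
  t_event <- cfg$weibull_scale *
    (-log(u) * exp(-lp))^(1 / cfg$weibull_shape)
  t_cens <- pmin(stats::rexp(n, cfg$censor_rate), cfg$admin_cap)
  os_time <- pmin(t_event, t_cens)
  data.frame(os_time = pmax(os_time, 0.1),
             vital = ifelse(t_event <= t_cens, "deceased", "alive"),
             stringsAsFactors = FALSE)
}

#' Inject missing-completely-at-random genotype calls
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [sim_config()] (uses `missing_rate`).
#' @param seed optional seed.
#' @return The genotype matrix with calls independently set missing.
#' @export
inject_missing <- function(g, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$missing_rate == 0) return(g)
  drop <- matrix(stats::runif(length(g)) < cfg$missing_rate,
                 nrow(g), ncol(g))
  g[drop] <- NA_integer_
  g
}

#' Simulate a full case-control + survival study
#'
#' Draws genotypes, telomere length, covariates, case status, case-only
#' clinical variables (latent severity drives both staging systems and the
#' hazard), survival, data-availability masks and genotype missingness, and
#' returns the generative truth alongside the observed data.
#'
#' @param cfg a [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()] with missingness),
#'   `cohort` (a `cohort_table`), and `truth` (generative parameters plus
#'   the latent telomere lengths, complete scores and liability intercept).
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cases + cfg$n_controls
  g_complete <- simulate_genotypes(n, cfg, seed = NULL)
  tl <- simulate_ltl(g_complete, cfg, seed = NULL)
  margins <- cohort_margins()
  country <- sample(margins$country, n, replace = TRUE,
                    prob = margins$cases + margins$controls)
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  age0 <- stats::rnorm(n, 57, 12)
  covars <- data.frame(age = age0, sex = sex, stringsAsFactors = FALSE)
  status <- simulate_status(tl, covars, cfg, g = g_complete, seed = NULL)
  is_case <- status == "case"
  # With no age effect in the liability, draw age conditional on status to
  # mimic the younger control arm of the reference study.
  if (cfg$beta_age == 0) {
    covars$age <- ifelse(is_case, stats::rnorm(n, 61.5, 9.6),
                         stats::rnorm(n, 52.6, 17))
  }
  n_case <- sum(is_case)
  severity <- sample(1:3, n_case, replace = TRUE,
                     prob = c(179, 299, 757) / 1235)
  jitter <- sample(c(-1L, 0L, 1L), n_case, replace = TRUE,
                   prob = c(0.15, 0.7, 0.15))
  stage_iss_full <- pmin(3L, pmax(1L, severity + jitter))
  therapy <- ifelse(stats::runif(n_case) < 0.5, "new", "old")
  surv <- simulate_survival(tl[is_case], severity, therapy, cfg, seed = NULL)
  has_ds <- stats::runif(n_case) < cfg$p_stage_ds
  has_iss <- ifelse(has_ds, stats::runif(n_case) < cfg$p_stage_iss[1],
                    stats::runif(n_case) < cfg$p_stage_iss[2])
  has_os <- stats::runif(n_case) < cfg$p_os
  cohort <- data.frame(
    subject_id = rownames(g_complete), status = status,
    sex = covars$sex, age = covars$age, country = country,
    stage_ds = NA_integer_, stage_iss = NA_integer_,
    therapy = NA_character_, vital = NA_character_, os_time = NA_real_,
    stringsAsFactors = FALSE
  )
  cohort$stage_ds[is_case][has_ds] <- severity[has_ds]
  cohort$stage_iss[is_case][has_iss] <- stage_iss_full[has_iss]
  cohort$therapy[is_case] <- therapy
  cohort$vital[is_case][has_os] <- surv$vital[has_os]
  cohort$os_time[is_case][has_os] <- surv$os_time[has_os]
  class(cohort) <- c("cohort_table", "data.frame")
  g_obs <- inject_missing(g_complete, cfg, seed = NULL)
  truth <- list(
    config = cfg,
    alpha0 = attr(status, "alpha0"),
    tl = tl,
    complete_score_bp = as.numeric(unclass(g_complete) %*% cfg$panel$weight_bp),
    severity = severity
  )
  list(genotypes = g_obs, cohort = cohort, truth = truth)
}
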