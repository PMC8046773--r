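test_that("intercept-only logistic matches the closed form", {
  fit <- fit_logistic(rep(c(1, 0), c(25, 75)))
  expect_equal(unname(fit$coef), log(25 / 75), tolerance = 1e-8)
  expect_equal(fit$n, 100)
})

test_that("saturated 2x2 logistic reproduces the cross-product odds ratio", {
  # arbitrary 2x2 margins, oracle = cross-product ratio
  counts <- list(c(a = 30, b = 70, c = 55, d = 45),
                 c(a = 12, b = 88, c = 40, d = 160))
  for (ct in counts) {
    y <- rep(c(1, 0, 1, 0), ct)
    x <- rep(c(1, 1, 0, 0), ct)
    fit <- fit_logistic(y, cbind(exposed = x))
    oracle <- (ct["a"] * ct["d"]) / (ct["b"] * ct["c"])
    expect_equal(unname(fit$or["exposed"]), unname(oracle),
                 tolerance = 1e-7)
  }
})

test_that("logistic preconditions and failure modes raise errors", {
  expect_error(fit_logistic(rep(1, 10)), "constant")
  y <- rep(c(0, 1), each = 10)
  X <- cbind(a = rnorm(20))
  expect_error(fit_logistic(y, cbind(X, b = 2 * X[, 1])), "collinear")
  # perfect separation: x fully predicts y
  expect_error(fit_logistic(y, cbind(sep = y)), "separation")
})

test_that("logistic estimates are invariant to subject order and affine recoding", {
  set.seed(71)
  n <- 300
  x <- rnorm(n); z <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x - 0.3 * z))
  f1 <- fit_logistic(y, cbind(x = x, z = z))
  perm <- sample(n)
  f2 <- fit_logistic(y[perm], cbind(x = x[perm], z = z[perm]))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  # affine recoding x -> (x - 10) / 2 doubles the slope, p unchanged
  f3 <- fit_logistic(y, cbind(x = (x - 10) / 2, z = z))
  expect_equal(unname(f3$coef["x"]), unname(2 * f1$coef["x"]),
               tolerance = 1e-6)
  expect_equal(unname(f3$p["x"]), unname(f1$p["x"]), tolerance = 1e-8)
})

test_that("Cox partial likelihood matches the analytic three-subject toy", {
  fit <- fit_cox(time = c(1, 2, 3), event = c(1, 1, 1),
                 X = cbind(x = c(1, 0, 1)))
  expect_equal(unname(fit$coef["x"]), -log(2) / 2, tolerance = 1e-6)
  expect_equal(unname(fit$hr["x"]), 2^(-1 / 2), tolerance = 1e-6)
})

test_that("Cox returns HR 1 for exchangeable groups and errors without events", {
  fit <- fit_cox(time = rep(c(5, 10, 15), 2), event = rep(1, 6),
                 X = cbind(g = rep(c(0, 1), each = 3)))
  expect_equal(unname(fit$hr["g"]), 1, tolerance = 1e-8)
  expect_error(fit_cox(time = 1:4, event = rep(0, 4), X = cbind(x = 1:4)),
               "no events")
})

test_that("Cox estimates are invariant to subject order", {
  set.seed(72)
  n <- 200
  x <- rnorm(n)
  t <- rexp(n, exp(0.5 * x) / 20)
  e <- rbinom(n, 1, 0.7)
  f1 <- fit_cox(t, e, cbind(x = x))
  perm <- sample(n)
  f2 <- fit_cox(t[perm], e[perm], cbind(x = x[perm]))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
})

test_that("Wald type-I error is calibrated under the null", {
  set.seed(73)
  reps <- 500; n <- 2000
  p_log <- p_cox <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.4)
    p_log[r] <- fit_logistic(y, cbind(x = x))$p["x"]
    t <- rexp(n, 1 / 30); e <- rbinom(n, 1, 0.6)
    p_cox[r] <- fit_cox(t, e, cbind(x = x))$p["x"]
  }
  band <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(p_log < 0.05) - 0.05), band)
  expect_lt(abs(mean(p_cox < 0.05) - 0.05), band)
})

test_that("per-SNP scan fits allelic and codominant models with the 0.05/22 threshold", {
  p <- weighted_builtin()
  study <- simulate_study(sim_config(n_cases = 400, n_controls = 400,
                                     panel = p, seed = 41))
  res <- suppressWarnings(snp_models(study$genotypes, study$cohort, p))
  expect_equal(attr(res, "threshold"), 0.05 / 22)
  expect_true(all(res$model %in% c("allelic", "codominant-het",
                                   "codominant-hom")))
  expect_true(all(res$effect > 0))
  # allelic rows exist for every SNP at this sample size
  expect_setequal(res$rsid[res$model == "allelic"], p$rsid)
  # CI spans the effect
  expect_true(all(res$ci_low <= res$effect & res$effect <= res$ci_high))
})

test_that("monomorphic SNPs are skipped and absent rare homozygotes drop the hom term", {
  p <- tiny_panel()
  set.seed(42)
  n <- 120
  d <- cbind(rep(2L, n),                        # monomorphic in minor coding
             rbinom(n, 1, 0.5))                 # no rare homozygotes
  g <- genotype_matrix(d, sprintf("S%03d", 1:n), p)
  co <- as_cohort(data.frame(
    subject_id = sprintf("S%03d", 1:n),
    status = rep(c("case", "control"), n / 2),
    sex = "male", age = rnorm(n, 60, 5), country = "Poland",
    stage_ds = NA_integer_, stage_iss = NA_integer_,
    therapy = NA_character_, vital = NA_character_, os_time = NA_real_,
    stringsAsFactors = FALSE))
  expect_warning(expect_warning(res <- snp_models(g, co, p), "monomorphic"),
                 "hom term dropped")
  expect_false("rs1" %in% res$rsid)
  expect_false("codominant-hom" %in% res$model[res$rsid == "rs2"])
})

test_that("continuous quintile model recovers an injected per-quintile log-odds", {
  set.seed(43)
  n <- 6000
  q <- sample(1:5, n, TRUE)
  delta <- 0.25
  y <- rbinom(n, 1, plogis(-1 + delta * q))
  fit <- fit_logistic(y, cbind(quintile = q))
  expect_lt(abs(fit$coef["quintile"] - delta), 2 * fit$se["quintile"])
})

test_that("score quintile risk models are null-calibrated and bookkept", {
  p <- weighted_builtin()
  study <- simulate_study(sim_config(n_cases = 500, n_controls = 500,
                                     panel = p, theta_risk = 0, seed = 44))
  sc <- score_cohort(study$genotypes, p, "risk", study$cohort)
  res <- score_risk_models(sc, study$cohort)
  q5 <- res[res$rsid == "weighted_scaled" & res$model == "quintile-5", ]
  expect_true(q5$ci_low <= 1 && q5$ci_high >= 1 || q5$p > 0.01)
  counts <- attr(res, "counts")$weighted_scaled
  # quintile indicator occupancy sums to the model n
  expect_equal(sum(counts$Freq),
               res$n_used[res$rsid == "weighted_scaled"][1])
})

test_that("os_endpoint encodes deceased as events and filters incomplete cases", {
  co <- as_cohort(data.frame(
    subject_id = c("a", "b", "c", "d", "e"),
    status = c("case", "case", "case", "case", "control"),
    sex = "male", age = 60, country = "Poland",
    stage_ds = 2L, stage_iss = 2L, therapy = "new",
    vital = c("deceased", "alive", NA, "deceased", NA),
    os_time = c(24, 60, 10, -1, NA), stringsAsFactors = FALSE))
  expect_warning(expect_message(ep <- os_endpoint(co), "excluded"),
                 "nonpositive")
  expect_equal(ep$subject_id, c("a", "b"))
  expect_equal(ep$time, c(24, 60))
  expect_equal(ep$event, c(1, 0))
})

test_that("survival scan recovers an injected per-quintile hazard and respects strata", {
  p <- weighted_builtin()
  study <- simulate_study(sim_config(n_cases = 1500, n_controls = 300,
                                     panel = p, gamma_os = -0.8, seed = 45))
  sc_ds <- score_cohort(study$genotypes, p, "survival", study$cohort, "ds")
  res_ds <- suppressWarnings(survival_models(sc_ds, study$cohort,
                                             stage_system = "ds"))
  cont <- res_ds[res_ds$model == "quintile-continuous" &
                   res_ds$rsid == "weighted_scaled", ]
  # strong protective telomere effect must push the quintile trend below 1
  expect_lt(cont$effect, 1)
  res_iss <- suppressWarnings(survival_models(sc_ds, study$cohort,
                                              stage_system = "iss"))
  cont_iss <- res_iss[res_iss$model == "quintile-continuous" &
                        res_iss$rsid == "weighted_scaled", ]
  # DS and ISS strata have different completeness, hence different n
  expect_false(cont$n_used == cont_iss$n_used)
})

test_that("survival scan on a null cohort gives hazard ratios near 1", {
  p <- weighted_builtin()
  study <- simulate_study(sim_config(n_cases = 1200, n_controls = 200,
                                     panel = p, gamma_os = 0, seed = 46))
  sc <- score_cohort(study$genotypes, p, "survival", study$cohort, "ds")
  res <- suppressWarnings(survival_models(sc, study$cohort,
                                          stage_system = "ds"))
  cont <- res[res$model == "quintile-continuous" &
                res$rsid == "weighted_scaled", ]
  expect_true(cont$ci_low <= 1 && cont$ci_high >= 1 || cont$p > 0.01)
})

test_that("survival models error when the stratum has too few events", {
  co <- as_cohort(data.frame(
    subject_id = c("a", "b"), status = "case", sex = "male", age = 60,
    country = "Poland", stage_ds = 2L, stage_iss = 2L, therapy = "new",
    vital = c("alive", "alive"), os_time = c(10, 20),
    stringsAsFactors = FALSE))
  p <- tiny_panel()
  g <- genotype_matrix(matrix(1L, 2, 2), c("a", "b"), p)
  expect_error(survival_models(g, co, p, "ds"), "fewer than 2 events")
})
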