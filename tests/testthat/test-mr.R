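# Independent oracles: weighted least squares through the origin and with
# intercept, solved directly from the normal equations.
wls_origin <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)
wls_intercept <- function(bx, by, w) {
  X <- cbind(1, bx)
  solve(t(X) %*% (w * X), t(X) %*% (w * by))[, 1]
}

test_that("outcome effects are recovered from printed ratio CIs", {
  assoc <- data.frame(rsid = "rs10936599", effect = 1.20,
                      ci_low = 1.00, ci_high = 1.43, model = "allelic",
                      stringsAsFactors = FALSE)
  p <- weighted_builtin()[3, ]
  class(p) <- c("snp_panel", "data.frame")
  s <- summary_from_tables(assoc, p, exposure_unit = "kb")
  # rs10936599 effect allele is the common C, printed HR is per rare T:
  # by is the negated log-ratio
  expect_equal(s$by, -log(1.20), tolerance = 1e-10)
  expect_equal(s$byse, (log(1.43) - log(1.00)) / (2 * 1.96),
               tolerance = 1e-10)
  expect_equal(s$bx, p$weight_bp / 1000)

  # ratio of exactly 1 gives a zero outcome effect
  assoc$effect <- 1; assoc$ci_low <- 0.9; assoc$ci_high <- 1.11
  expect_equal(summary_from_tables(assoc, p)$by, 0)
})

test_that("instruments with missing CIs are dropped with a warning", {
  p <- weighted_builtin()[1:3, ]
  class(p) <- c("snp_panel", "data.frame")
  assoc <- data.frame(rsid = p$rsid, effect = c(1.1, 1.2, NA),
                      ci_low = c(0.9, NA, NA), ci_high = c(1.3, 1.4, NA),
                      model = "allelic", stringsAsFactors = FALSE)
  expect_warning(s <- summary_from_tables(assoc, p), "invalid CI")
  expect_equal(nrow(s), 1)
})

test_that("Wald ratio and its first-order standard error", {
  expect_equal(wald_ratio(0.1, 0.02, 0.2, 0.05)$estimate, 2)
  wr <- wald_ratio(0.1, 0.02, 0, 0.05)
  expect_equal(wr$estimate, 0)
  expect_equal(wr$se, 0.5)
  expect_error(wald_ratio(0, 0.02, 0.2, 0.05), "bx = 0")
})

test_that("IVW slope is inverse-variance weighted regression through the origin", {
  s <- mr_summary_set(c("a", "b"), bx = c(1, 1), bxse = c(0.1, 0.1),
                      by = c(1, 3), byse = c(1, 1))
  expect_equal(mr_ivw(s, "fixed")$slope, 2)
  s2 <- mr_summary_set(c("a", "b"), bx = c(1, 1), bxse = c(0.1, 0.1),
                       by = c(1, 3), byse = c(1, 2))
  expect_equal(mr_ivw(s2, "fixed")$slope, 1.4)
  # single instrument reduces to the Wald ratio
  s1 <- mr_summary_set("a", 0.5, 0.05, 0.2, 0.1)
  expect_equal(mr_ivw(s1, "fixed")$slope, 0.4)
  # noiseless proportional effects recover theta with Q = 0
  s3 <- mr_summary_set(letters[1:4], bx = c(1, 2, 3, 4), bxse = rep(0.1, 4),
                       by = 0.7 * c(1, 2, 3, 4), byse = c(1, 2, 1, 2))
  iv3 <- mr_ivw(s3, "fixed")
  expect_equal(iv3$slope, 0.7, tolerance = 1e-12)
  expect_equal(iv3$Q, 0, tolerance = 1e-12)
})

test_that("IVW fixed and multiplicative-random-effects share the point estimate", {
  set.seed(81)
  s <- mr_summary_set(letters[1:6], rnorm(6), abs(rnorm(6)) + 0.1,
                      rnorm(6), abs(rnorm(6)) + 0.1)
  f <- mr_ivw(s, "fixed"); m <- mr_ivw(s, "mre")
  expect_equal(f$slope, m$slope)
  expect_gte(m$slope_se, f$slope_se)
  expect_equal(m$slope_se, f$slope_se * max(1, sqrt(f$Q / (nrow(s) - 1))))
})

test_that("IVW and Egger match brute-force WLS oracles on random instances", {
  set.seed(82)
  for (i in 1:25) {
    K <- sample(3:10, 1)
    bx <- rnorm(K); by <- rnorm(K)
    byse <- runif(K, 0.2, 2); bxse <- runif(K, 0.05, 0.5)
    s <- mr_summary_set(paste0("rs", seq_len(K)), bx, bxse, by, byse)
    w <- byse^-2
    expect_equal(mr_ivw(s, "fixed")$slope, wls_origin(bx, by, w),
                 tolerance = 1e-10)
    flip <- bx < 0
    oracle <- wls_intercept(ifelse(flip, -bx, bx), ifelse(flip, -by, by), w)
    e <- mr_egger(s)
    expect_equal(unname(e$intercept), unname(oracle[1]), tolerance = 1e-10)
    expect_equal(unname(e$slope), unname(oracle[2]), tolerance = 1e-10)
  }
})

test_that("Egger recovers slope and intercept exactly from collinear points", {
  s <- mr_summary_set(c("a", "b", "c"), bx = c(1, 2, 3), bxse = rep(0.1, 3),
                      by = c(2, 3, 4), byse = rep(1, 3))
  e <- mr_egger(s)
  expect_equal(unname(e$slope), 1, tolerance = 1e-12)
  expect_equal(unname(e$intercept), 1, tolerance = 1e-12)
  expect_error(mr_egger(mr_summary_set(c("a", "b", "c"), rep(1, 3),
                                       rep(0.1, 3), 1:3, rep(1, 3))),
               "not separable")
  expect_error(mr_egger(mr_summary_set(c("a", "b"), 1:2, rep(0.1, 2),
                                       1:2, rep(1, 2))),
               "at least 3")
})

test_that("Cochran Q matches the hand-computed example", {
  s <- mr_summary_set(c("a", "b"), bx = c(1, 1), bxse = c(0.1, 0.1),
                      by = c(1, 3), byse = c(1, 1))
  q <- cochran_q(s, slope = 2)
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1)
  expect_equal(q$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  # permutation invariance
  s2 <- s[2:1, ]; class(s2) <- class(s)
  expect_equal(cochran_q(s2, 2)$Q, q$Q)
  expect_error(cochran_q(s, 2, df = 0), "positive degrees")
})

test_that("I2GX handles the boundary and degenerate cases", {
  # Q_GX = K - 1 exactly gives 0
  expect_equal(i2_gx(c(1, 2, 3), rep(1, 3)), 0)
  expect_warning(out <- i2_gx(c(1, 1, 1), rep(0.5, 3)), "weak instrument")
  expect_equal(out, 0)
  # strong instruments: tiny bxse gives I2GX near 1
  expect_gt(i2_gx(c(0.05, 0.08, 0.12), rep(0.001, 3)), 0.99)
})

test_that("MR estimates are scale equivariant in the exposure", {
  set.seed(83)
  K <- 8
  s <- mr_summary_set(paste0("rs", 1:K), rnorm(K, 0.1, 0.05),
                      runif(K, 0.01, 0.02), rnorm(K, 0.05, 0.1),
                      runif(K, 0.02, 0.1))
  c_scale <- 1000
  s2 <- s; s2$bx <- s$bx * c_scale; s2$bxse <- s$bxse * c_scale
  f1 <- mr_ivw(s, "fixed"); f2 <- mr_ivw(s2, "fixed")
  expect_equal(f2$slope * c_scale, f1$slope, tolerance = 1e-10)
  expect_equal(f1$Q, f2$Q, tolerance = 1e-10)
  e1 <- mr_egger(s); e2 <- mr_egger(s2)
  expect_equal(e2$slope * c_scale, e1$slope, tolerance = 1e-10)
  expect_equal(unname(e1$intercept), unname(e2$intercept), tolerance = 1e-10)
  expect_equal(e1$intercept_p, e2$intercept_p, tolerance = 1e-10)
})

test_that("joint sign flips of (bx, by) leave IVW and Egger unchanged", {
  set.seed(84)
  K <- 9
  s <- mr_summary_set(paste0("rs", 1:K), rnorm(K), runif(K, 0.05, 0.2),
                      rnorm(K), runif(K, 0.1, 0.5))
  flip <- sample(c(TRUE, FALSE), K, TRUE)
  s2 <- s
  s2$bx[flip] <- -s2$bx[flip]; s2$by[flip] <- -s2$by[flip]
  expect_equal(mr_ivw(s, "fixed")$slope, mr_ivw(s2, "fixed")$slope,
               tolerance = 1e-12)
  e1 <- mr_egger(s); e2 <- mr_egger(s2)
  expect_equal(unname(e1$slope), unname(e2$slope), tolerance = 1e-12)
  expect_equal(unname(e1$intercept), unname(e2$intercept), tolerance = 1e-12)
})

test_that("IVW recovers a simulated causal slope and Egger detects pleiotropy", {
  set.seed(85)
  panel <- weighted_builtin()
  bx <- panel$weight_bp / 1000
  bxse <- panel$weight_se_bp / 1000
  theta <- 1.2
  reps <- 300
  byse <- rep(0.05, 11)
  cover <- logical(reps)
  egger_p_null <- ivw_bias <- numeric(reps)
  for (r in seq_len(reps)) {
    by <- theta * bx + rnorm(11, 0, byse)
    s <- mr_summary_set(panel$rsid, bx, bxse, by, byse)
    iv <- mr_ivw(s, "fixed")
    cover[r] <- iv$slope_ci95[1] <= theta && iv$slope_ci95[2] >= theta
    ivw_bias[r] <- iv$slope - theta
    egger_p_null[r] <- mr_egger(s)$intercept_p
  }
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
  expect_lt(abs(mean(ivw_bias)), 0.1 * sd(ivw_bias))
  # null pleiotropy: Egger intercept p roughly uniform
  expect_lt(abs(mean(egger_p_null < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / reps) + 0.02)

  # injected directional pleiotropy biases IVW and is detected by Egger
  pleio <- 0.12
  detected <- biased <- logical(reps)
  for (r in seq_len(reps)) {
    by <- theta * bx + pleio + rnorm(11, 0, byse)
    s <- mr_summary_set(panel$rsid, bx, bxse, by, byse)
    detected[r] <- mr_egger(s)$intercept_p < 0.05
    biased[r] <- mr_ivw(s, "fixed")$slope > theta
  }
  expect_gt(mean(detected), 0.5)
  expect_gt(mean(biased), 0.9)
})

test_that("mr_report bundles estimators and plot data consistently", {
  set.seed(86)
  panel <- weighted_builtin()
  bx <- panel$weight_bp / 1000
  by <- 1.0 * bx + rnorm(11, 0, 0.04)
  s <- mr_summary_set(panel$rsid, bx, panel$weight_se_bp / 1000, by,
                      rep(0.04, 11))
  rep_ <- mr_report(s)
  expect_equal(rep_$ivw_fixed$slope, rep_$ivw_mre$slope)
  expect_equal(nrow(rep_$forest), 11 + 3)
  expect_equal(nrow(rep_$scatter), 11)
  expect_equal(rep_$forest$estimate[1:11], s$by / s$bx, tolerance = 1e-12)
  expect_equal(rep_$scatter$fitted_ivw, rep_$ivw_fixed$slope * s$bx)
  expect_true(rep_$i2_gx >= 0 && rep_$i2_gx <= 1)
  expect_error(mr_report(s[1:2, ]), "at least 3")
})
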