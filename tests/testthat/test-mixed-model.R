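test_that("with no study heterogeneity the fit collapses to weighted least squares", {
  db <- simulate_kex_db(kex_sim_config(
    n_studies = 10, records_per_study = c(4L, 4L), tau = 0, sigma = 25,
    weight_range = c(1L, 1L), seed = 21))
  fit <- kexmm(k_ur ~ k_intake, db)
  expect_true(fit$boundary)
  ols <- lm(k_ur ~ k_intake, data = db)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-6)
})

test_that("weights enter only as relative precisions", {
  db <- simulate_kex_db(kex_sim_config(seed = 8))
  fit1 <- kexmm(k_ur ~ k_intake, db)
  db2 <- db
  db2$n_obs <- db2$n_obs * 2L
  fit2 <- kexmm(k_ur ~ k_intake, db2)
  # doubling every weight rescales the unit-weight residual variance by 2
  # and leaves the fit itself (coefficients, tau2, per-record variances,
  # SEs, BLUPs) unchanged
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-6)
  expect_equal(fit2$sigma2, 2 * fit1$sigma2, tolerance = 1e-6)
  expect_equal(fit2$tau2, fit1$tau2, tolerance = 1e-5)
  expect_equal(fit2$se, fit1$se, tolerance = 1e-6)
  expect_equal(fit2$study_blups, fit1$study_blups, tolerance = 1e-6)
})

test_that("fixed-effect prediction is the affine map b0 + b1 x", {
  fit <- kexmm(k_ur ~ k_intake, simulate_kex_db(kex_sim_config(seed = 4)))
  x <- c(105.3, 316.6, 686.0)
  expect_equal(predict(fit, x), coef(fit)[[1]] + coef(fit)[[2]] * x)
  # affine in x: predict(a x + b) = b1 a x + (b1 b + b0), exactly
  a <- 2.5
  b <- -40
  expect_equal(predict(fit, a * x + b),
               coef(fit)[[2]] * a * x + (coef(fit)[[2]] * b + coef(fit)[[1]]),
               tolerance = 1e-12)
  # zero-slope and x = 0 limits
  fit0 <- fit
  fit0$coefficients <- c("(Intercept)" = 1.08, k_intake = 0.65)
  expect_equal(predict(fit0, 316.6), 206.87)
  expect_equal(predict(fit0, 0), 1.08)
  fit0$coefficients[2] <- 0
  expect_equal(predict(fit0, x), rep(1.08, 3))
  # missing predictor values propagate
  expect_true(is.na(predict(fit, c(100, NA))[2]))
})

test_that("estimates agree with an independent mixed-model oracle", {
  skip_if_not_installed("lme4")
  set.seed(2024)
  n_checked <- 0
  for (rep in 1:25) {
    cfg <- kex_sim_config(
      n_studies = sample(6:12, 1), records_per_study = c(3L, 5L),
      beta0 = runif(1, -20, 80), beta1 = runif(1, 0.1, 2),
      tau = runif(1, 15, 50), sigma = runif(1, 10, 40),
      seed = 1000 + rep)
    db <- suppressWarnings(simulate_kex_db(cfg))
    fit <- kexmm(k_ur ~ k_intake, db)
    ref <- suppressMessages(suppressWarnings(
      lme4::lmer(k_ur ~ k_intake + (1 | study_id), data = db,
                 weights = n_obs, REML = TRUE)))
    vc <- as.data.frame(lme4::VarCorr(ref))
    tau2_ref <- vc$vcov[1]
    sigma2_ref <- vc$vcov[2]
    if (fit$boundary || tau2_ref < 1e-6 * sigma2_ref) {
      # boundary fits: both estimators must agree the study variance is nil
      expect_true(fit$boundary == (tau2_ref < 1e-6 * sigma2_ref))
      next
    }
    n_checked <- n_checked + 1
    expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)),
                 tolerance = 1e-4)
    expect_equal(fit$tau2, tau2_ref, tolerance = 1e-4)
    expect_equal(fit$sigma2, sigma2_ref, tolerance = 1e-4)
    expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
                 tolerance = 1e-4)
  }
  expect_gte(n_checked, 15)
})

test_that("the profiled REML criterion is a global optimum over a dense grid", {
  for (seed in c(2, 9)) {
    db <- simulate_kex_db(kex_sim_config(n_studies = 8, seed = seed))
    fit <- kexmm(k_ur ~ k_intake, db)
    d <- fit$data
    X <- cbind(1, d$x)
    crit_hat <- kexmeta:::.kexmm_profile(fit$theta, d$y, X, d$w, d$study)$crit
    grid <- exp(seq(log(1e-8), log(1e4), length.out = 100))
    crit_grid <- vapply(grid, function(th) {
      kexmeta:::.kexmm_profile(th, d$y, X, d$w, d$study)$crit
    }, numeric(1))
    expect_lte(crit_hat, min(crit_grid) + 1e-8)
  }
})

test_that("BLUPs are precision-shrunken and centered", {
  db <- simulate_kex_db(kex_sim_config(seed = 14))
  fit <- kexmm(k_ur ~ k_intake, db)
  expect_gt(fit$tau2, 0)
  expect_equal(sum(fit$study_blups), 0, tolerance = 1e-8)
  expect_equal(length(fit$study_blups), fit$n_studies)
  # shrinkage: each BLUP is smaller in magnitude than the raw weighted
  # study-mean residual it shrinks
  d <- fit$data
  r <- d$y - predict(fit, d$x)
  raw <- tapply(r * d$w, d$study, sum) / tapply(d$w, d$study, sum)
  expect_true(all(abs(fit$study_blups[names(raw)]) <= abs(raw) + 1e-10))
})

test_that("degenerate designs are rejected with informative errors", {
  rec <- toy_records()
  rec$dmi <- NA_real_
  rec$dietary_k <- NA_real_
  rec$k_intake <- 300                # constant predictor
  db <- kex_db(rec, response_name = "k_ur")
  expect_error(kexmm(k_ur ~ k_intake, db), "constant")

  rec2 <- toy_records()
  rec2$k_intake[3:6] <- NA           # complete cases span one study
  db2 <- kex_db(rec2, response_name = "k_ur")
  expect_error(kexmm(k_ur ~ k_intake, db2), "fewer than 2 studies")

  expect_error(kexmm(k_ur ~ k_ur, toy_db()), "differ")
})

test_that("marginal R2 reaches its perfect-fit and null limits", {
  noiseless <- simulate_kex_db(kex_sim_config(tau = 0, sigma = 1e-6,
                                              seed = 31))
  fit <- kexmm(k_ur ~ k_intake, noiseless)
  expect_gt(fit$r2_marginal, 1 - 1e-3)

  r2_null <- vapply(1:100, function(s) {
    db <- suppressWarnings(simulate_kex_db(
      kex_sim_config(beta0 = 200, beta1 = 0, seed = 4000 + s)))
    kexmm(k_ur ~ k_intake, db)$r2_marginal
  }, numeric(1))
  expect_lte(mean(r2_null), 0.05)
})

test_that("marginal R2 recovers a calibrated design value", {
  # calibration: Var_f = b1^2 var(x) ~ 302, tau^2 = 196, mean residual
  # variance ~ 13.9 -> design R2m ~ 0.59, matching the share of fecal
  # variation the K-intake equation explains
  r2 <- vapply(1:200, function(s) {
    db <- suppressWarnings(simulate_kex_db(kex_sim_config(
      beta0 = 6.93, beta1 = 0.126, tau = 14, sigma = 8.91,
      predictor_range = c(105.3, 583.0), response = "k_fa",
      seed = 5000 + s)))
    kexmm(k_fa ~ k_intake, db)$r2_marginal
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.59), 0.05)
})

test_that("fit accessors, simulation and reporting are coherent", {
  db <- simulate_kex_db(kex_sim_config(seed = 16))
  fit <- kexmm(k_ur ~ k_intake, db)
  expect_equal(fit$n_used, nrow(db))
  expect_s3_class(summary(fit), "summary.kexmm")
  expect_match(equation_text(fit), "k_ur = .*× k_intake")
  expect_equal(residuals(fit, "marginal") - residuals(fit, "conditional"),
               unname(fit$study_blups[fit$data$study]))
  expect_equal(fitted(fit) + residuals(fit, "conditional"), fit$data$y)

  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n_used, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))

  js <- jsonlite::fromJSON(kexmm_json(fit))
  expect_equal(js$coefficients$k_intake, coef(fit)[[2]])
  expect_equal(js$n_used, fit$n_used)

  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$reml_loglik)
})
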