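test_that("MSPE decomposition reproduces hand-computed cases", {
  # r = 1, half-amplitude predictions: all error is slope bias
  m <- mspe_decompose(c(1, 2, 3), c(1.5, 2, 2.5))
  expect_equal(m$mspe, 1 / 6)
  expect_equal(m$mb, 0)
  expect_equal(m$sb, (sqrt(1 / 6) - sqrt(2 / 3))^2)
  expect_equal(m$sb, 1 / 6)
  expect_equal(m$ed, 0)
  expect_equal(m$mb_pct + m$sb_pct + m$ed_pct, 100)
  expect_equal(m$ccc, 0.8)

  # perfect agreement
  obs <- c(3, 7, 11, 2)
  p0 <- mspe_decompose(obs, obs)
  expect_equal(p0$mspe, 0)
  expect_equal(p0$mb + p0$sb + p0$ed, 0)
  expect_equal(p0$ccc, 1)
  expect_equal(p0$rsr, 0)

  # perfectly anti-correlated: everything is slope bias, CCC = -1
  m2 <- mspe_decompose(c(1, 2, 3), c(3, 2, 1))
  expect_equal(m2$pearson_r, -1)
  expect_equal(m2$mb, 0)
  expect_equal(m2$ed, 0)
  expect_equal(m2$sb, 8 / 3)
  expect_equal(m2$mspe, 8 / 3)
  expect_equal(m2$ccc, -1)
})

test_that("the decomposition identity holds on random pair sets", {
  set.seed(71)
  for (i in 1:1000) {
    pr <- random_pairs()
    m <- mspe_decompose(pr$obs, pr$pred)
    expect_lt(abs(m$mb + m$sb + m$ed - m$mspe), 1e-10 * max(m$mspe, 1))
    expect_lt(abs(m$mb_pct + m$sb_pct + m$ed_pct - 100), 1e-6)
  }
})

test_that("concordance matches the hand-derived cases and |CCC| <= |r|", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(1.5, 2, 2.5)), 0.8)
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(lin_ccc(c(1, 2, 3), c(2, 2, 2)), "constant")
  set.seed(72)
  for (i in 1:200) {
    pr <- random_pairs()
    expect_lte(abs(lin_ccc(pr$obs, pr$pred)),
               abs(cor(pr$obs, pr$pred)) + 1e-12)
  }
})

test_that("concordance agrees with an independent brute-force transcription", {
  set.seed(73)
  for (i in 1:1000) {
    pr <- random_pairs()
    expect_lt(abs(lin_ccc(pr$obs, pr$pred) - ccc_bruteforce(pr$obs, pr$pred)),
              1e-12)
  }
})

test_that("degenerate prediction sets are flagged, not crashed", {
  # constant predictions: r treated as 0, CCC undefined
  m <- mspe_decompose(c(1, 2, 3, 4), c(2, 2, 2, 2))
  expect_true(m$degenerate)
  expect_equal(m$pearson_r, 0)
  expect_equal(m$sb, 0)                      # (0 - 0 * So)^2
  expect_equal(m$ed, m$sd_obs_pop^2)
  expect_true(is.na(m$ccc))
  expect_lt(abs(m$mb + m$sb + m$ed - m$mspe), 1e-12)

  expect_error(mspe_decompose(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(mspe_decompose(c(1, 2), c(1, 2)), "at least 3")
})

test_that("leave-one-study-out folds are independent of the held-out study", {
  db <- simulate_kex_db(kex_sim_config(n_studies = 5, seed = 42))
  cv <- loso_cv(db, k_ur ~ k_intake)
  expect_equal(attr(cv, "n_folds"), 5L)
  expect_setequal(cv$record_id, db$record_id)     # every case exactly once
  expect_equal(anyDuplicated(cv$record_id), 0L)

  # perturbing the responses of one study must not move its own predictions
  s <- unique(db$study_id)[2]
  db2 <- db
  db2$k_ur[db2$study_id == s] <- db2$k_ur[db2$study_id == s] * 3
  cv2 <- loso_cv(kex_db(as.data.frame(db2), response_name = "k_ur"),
                 k_ur ~ k_intake)
  expect_equal(cv2$predicted[cv2$study_id == s],
               cv$predicted[cv$study_id == s])
  expect_false(isTRUE(all.equal(cv2$predicted[cv2$study_id != s],
                                cv$predicted[cv$study_id != s])))
})

test_that("cross-validation performs one fit per study", {
  db <- simulate_kex_db(kex_sim_config(n_studies = 6, seed = 43))
  fits <- 0L
  orig_kexmm <- kexmeta::kexmm
  testthat::local_mocked_bindings(
    kexmm = function(...) {
      fits <<- fits + 1L
      orig_kexmm(...)
    },
    .package = "kexmeta"
  )
  cv <- loso_cv(db, k_ur ~ k_intake)
  expect_equal(fits, 6L)
})

test_that("a perfect generating model is recovered by cross-validation", {
  db <- simulate_kex_db(kex_sim_config(tau = 0, sigma = 1e-6, seed = 44))
  cv <- loso_cv(db, k_ur ~ k_intake)
  expect_equal(cv$predicted, cv$observed, tolerance = 1e-4)
  m <- mspe_decompose(cv$observed, cv$predicted)
  expect_lt(m$rsr, 1e-4)
  expect_gt(m$ccc, 1 - 1e-6)
})

test_that("metrics are invariant to record order", {
  set.seed(75)
  pr <- random_pairs(30)
  m1 <- mspe_decompose(pr$obs, pr$pred)
  idx <- sample(30)
  m2 <- mspe_decompose(pr$obs[idx], pr$pred[idx])
  expect_equal(m2$rmspe_pct, m1$rmspe_pct)
  expect_equal(m2$rsr, m1$rsr)
  expect_equal(m2$ccc, m1$ccc)
})

test_that("models rank by RSR with CCC and RMSPE% tie-breaks", {
  mk <- function(name, rsr, ccc, rmspe_pct = 40) {
    structure(list(predictor = name, n = 45L, rsr = rsr, ccc = ccc,
                   rmspe_pct = rmspe_pct, mb_pct = 0, sb_pct = 0,
                   ed_pct = 100, r2_marginal = NA_real_),
              class = "kex_metrics")
  }
  # the published contrast: K intake (RSR 0.28) beats DMI (RSR 0.98)
  r <- rank_models(list(mk("dmi", 0.98, 0.28), mk("k_intake", 0.28, 0.97)))
  expect_equal(r$model, c("k_intake", "dmi"))

  r2 <- rank_models(list(mk("a", 0.5, 0.2), mk("b", 0.5, 0.9)))
  expect_equal(r2$model[1], "b")

  r3 <- rank_models(list(mk("a", 0.5, 0.9, 41), mk("b", 0.5, 0.9, 40)))
  expect_equal(r3$model[1], "b")

  r4 <- rank_models(list(mk("b", 0.5, 0.9), mk("a", 0.5, 0.9)))
  expect_equal(r4$model, c("a", "b"))        # lexicographic last resort

  expect_equal(rank_models(list(mk("solo", 0.3, 0.9)))$model, "solo")
})

test_that("plot data carries points, identity line and fitted trends", {
  db <- simulate_kex_db(kex_sim_config(n_studies = 6, seed = 46))
  cv <- loso_cv(db, k_ur ~ k_intake)
  pd <- cv_plot_data(cv)
  expect_equal(nrow(pd$points), nrow(cv))
  expect_equal(pd$points$residual, pd$points$observed - pd$points$predicted)
  expect_equal(pd$lines$slope[pd$lines$line == "identity"], 1)
  tr <- coef(lm(cv$observed ~ cv$predicted))
  expect_equal(pd$lines$intercept[pd$lines$line == "observed_trend"],
               unname(tr[1]))
})
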