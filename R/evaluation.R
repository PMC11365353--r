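#' Leave-one-study-out cross-validation
#'
#' Cross-validation with study as the fold: each iteration holds out every
#' treatment mean of one study, refits the model on the remaining studies,
#' and predicts the held-out means from the fixed effects alone (the random
#' intercept of an unseen study has expectation zero). Pairs are assembled in
#' input-record order; every complete case appears exactly once.
#'
#' @param db a [kex_db()].
#' @param formula model formula as in [kexmm()]; defaults to
#'   `response ~ predictor` built from `predictor`.
#' @param predictor predictor name used when `formula` is `NULL`.
#' @param weighted passed to [kexmm()].
#' @return A `kex_cv`: data frame with columns `record_id`, `study_id`,
#'   `observed`, `predicted`, with attributes `response`, `predictor` and
#'   `n_folds` (the number of distinct studies among complete cases).
#' @export
loso_cv <- function(db, formula = NULL, predictor = NULL, weighted = TRUE) {
  stopifnot(inherits(db, "kex_db"))
  response <- attr(db, "response_name")
  if (is.null(formula)) {
    if (is.null(predictor)) stop("give either a formula or a predictor name")
    formula <- stats::as.formula(paste(response, "~", predictor))
  }
  vars <- all.vars(formula)
  response <- vars[1]
  predictor <- vars[2]

  ok <- !is.na(db[[response]]) & !is.na(db[[predictor]])
  cc <- db[ok, , drop = FALSE]
  studies <- unique(cc$study_id)
  if (length(studies) < 3L) {
    stop("leave-one-study-out CV needs at least 3 studies among complete cases")
  }

  predicted <- rep(NA_real_, nrow(cc))
  for (s in studies) {
    hold <- cc$study_id == s
    train <- cc[!hold, , drop = FALSE]
    fit <- tryCatch(
      kexmm(formula, train, weighted = weighted),
      error = function(e) {
        stop(sprintf("training fold without study '%s' failed: %s",
                     s, conditionMessage(e)))
      })
    predicted[hold] <- predict(fit, newdata = cc[[predictor]][hold],
                               re = "none")
  }
  out <- data.frame(record_id = cc$record_id, study_id = cc$study_id,
                    observed = cc[[response]], predicted = predicted,
                    stringsAsFactors = FALSE)
  structure(out, response = response, predictor = predictor,
            n_folds = length(studies), class = c("kex_cv", "data.frame"))
}

#' Decompose the mean square prediction error
#'
#' Computes MSPE over observed/predicted pairs and its exact decomposition
#' into mean bias \eqn{MB = (\bar P - \bar O)^2}, slope bias
#' \eqn{SB = (S_p - r S_o)^2} and error due to random sources
#' \eqn{ED = (1 - r^2) S_o^2}, where \eqn{S_o, S_p} are POPULATION standard
#' deviations (divide by n) and \eqn{r} the Pearson correlation — population
#' moments make \eqn{MB + SB + ED = MSPE} an exact identity. Also reported:
#' RMSPE as a percentage of the observed mean, the RSR (RMSPE divided by the
#' SAMPLE standard deviation of the observed values), Lin's concordance
#' correlation coefficient, and bias-significance p-values from regressing
#' the residuals (observed - predicted) on the mean-centered predictions
#' (intercept t-test: mean bias; slope t-test: slope bias).
#'
#' @param observed,predicted numeric vectors of equal length (>= 3 pairs);
#'   observed must be non-constant. Constant predictions are handled by
#'   treating `r` as 0 with a degeneracy flag.
#' @return A `kex_metrics` list: `n`, `mean_obs`, `mean_pred`, `sd_obs_pop`,
#'   `sd_pred_pop`, `pearson_r`, `mspe`, `rmspe`, `rmspe_pct`, `mb`, `sb`,
#'   `ed`, `mb_pct`, `sb_pct`, `ed_pct`, `rsr`, `ccc`, `p_mean_bias`,
#'   `p_slope_bias`, `degenerate`.
#' @export
mspe_decompose <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]
  p <- predicted[ok]
  n <- length(o)
  if (n < 3L) stop("need at least 3 observed/predicted pairs")
  if (stats::var(o) == 0) stop("observed values are constant")

  mo <- mean(o)
  mp <- mean(p)
  so <- sqrt(mean((o - mo)^2))
  sp <- sqrt(mean((p - mp)^2))
  degenerate <- sp == 0
  r <- if (degenerate) 0 else stats::cor(o, p)

  mspe <- mean((o - p)^2)
  mb <- (mp - mo)^2
  sb <- (sp - r * so)^2
  ed <- (1 - r^2) * so^2
  rmspe <- sqrt(mspe)
  ccc_v <- if (degenerate) NA_real_ else lin_ccc(o, p)

  resid <- o - p
  pc <- p - mp
  if (mspe == 0) {
    p_mb <- NA_real_
    p_sb <- NA_real_
  } else if (degenerate) {
    p_mb <- stats::t.test(resid)$p.value
    p_sb <- NA_real_
  } else {
    # summary.lm warns on exact fits, which legitimately arise in
    # noiseless synthetic checks
    bias_fit <- suppressWarnings(summary(stats::lm(resid ~ pc)))$coefficients
    p_mb <- bias_fit["(Intercept)", "Pr(>|t|)"]
    p_sb <- bias_fit["pc", "Pr(>|t|)"]
  }

  structure(list(
    n = n, mean_obs = mo, mean_pred = mp,
    sd_obs_pop = so, sd_pred_pop = sp, pearson_r = r,
    mspe = mspe, rmspe = rmspe, rmspe_pct = 100 * rmspe / mo,
    mb = mb, sb = sb, ed = ed,
    mb_pct = if (mspe > 0) 100 * mb / mspe else NA_real_,
    sb_pct = if (mspe > 0) 100 * sb / mspe else NA_real_,
    ed_pct = if (mspe > 0) 100 * ed / mspe else NA_real_,
    rsr = rmspe / stats::sd(o),
    ccc = ccc_v,
    p_mean_bias = p_mb, p_slope_bias = p_sb,
    degenerate = degenerate
  ), class = "kex_metrics")
}

#' @export
print.kex_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Prediction adequacy over %d pairs\n", x$n))
  cat(sprintf("  RMSPE = %.*f (%.1f%% of observed mean)  RSR = %.*f  CCC = %.*f\n",
              digits, x$rmspe, x$rmspe_pct, digits, x$rsr, digits,
              if (is.na(x$ccc)) NA_real_ else x$ccc))
  cat(sprintf("  MSPE = %.*f: mean bias %.1f%%, slope bias %.1f%%, random %.1f%%\n",
              digits, x$mspe, x$mb_pct, x$sb_pct, x$ed_pct))
  cat(sprintf("  bias significance: mean P = %.3g, slope P = %.3g\n",
              x$p_mean_bias, x$p_slope_bias))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of predictions with the identity line:
#' \deqn{CCC = \frac{2 r S_o S_p}{S_o^2 + S_p^2 + (\bar O - \bar P)^2}}
#' with population standard deviations. Ranges over \eqn{[-1, 1]}; negative
#' values indicate systematic discordance and \eqn{|CCC| \le |r|}.
#'
#' @param observed,predicted numeric vectors (>= 3 pairs, both non-constant).
#' @return CCC in \eqn{[-1, 1]}.
#' @export
lin_ccc <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]
  p <- predicted[ok]
  if (length(o) < 3L) stop("need at least 3 pairs")
  so2 <- mean((o - mean(o))^2)
  sp2 <- mean((p - mean(p))^2)
  if (so2 == 0 || sp2 == 0) stop("CCC undefined for a constant sequence")
  r <- stats::cor(o, p)
  2 * r * sqrt(so2) * sqrt(sp2) / (so2 + sp2 + (mean(o) - mean(p))^2)
}

#' Evaluate a model by leave-one-study-out cross-validation
#'
#' Convenience wrapper: runs [loso_cv()] and [mspe_decompose()] and attaches
#' the full-data fit's marginal R-squared and sample size.
#'
#' @param db a [kex_db()].
#' @param predictor predictor name.
#' @param weighted passed to [kexmm()].
#' @return A `kex_metrics` with extra fields `predictor`, `r2_marginal`,
#'   `n_folds`, and attribute `cv` (the prediction set).
#' @export
evaluate_model <- function(db, predictor, weighted = TRUE) {
  response <- attr(db, "response_name")
  formula <- stats::as.formula(paste(response, "~", predictor))
  fit <- kexmm(formula, db, weighted = weighted)
  cv <- loso_cv(db, formula, weighted = weighted)
  m <- mspe_decompose(cv$observed, cv$predicted)
  m$predictor <- predictor
  m$r2_marginal <- fit$r2_marginal
  m$n_folds <- attr(cv, "n_folds")
  attr(m, "cv") <- cv
  attr(m, "fit") <- fit
  m
}

#' Rank candidate models by cross-validated adequacy
#'
#' Deterministic total order: ascending RSR (the headline selection metric),
#' ties broken by descending CCC, then ascending RMSPE%, then predictor name.
#'
#' @param metrics list of `kex_metrics` objects, each carrying a `predictor`
#'   field (as returned by [evaluate_model()]), or a named list.
#' @return Data frame of models in rank order with the headline metrics.
#' @export
rank_models <- function(metrics) {
  stopifnot(length(metrics) > 0L)
  rows <- lapply(seq_along(metrics), function(i) {
    m <- metrics[[i]]
    nm <- if (!is.null(m$predictor)) m$predictor else
      if (!is.null(names(metrics))) names(metrics)[i] else as.character(i)
    data.frame(model = nm, n = m$n,
               r2_marginal = if (is.null(m$r2_marginal)) NA_real_ else m$r2_marginal,
               rmspe_pct = m$rmspe_pct, mb_pct = m$mb_pct,
               sb_pct = m$sb_pct, ed_pct = m$ed_pct,
               rsr = m$rsr, ccc = m$ccc, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$rsr, -tab$ccc, tab$rmspe_pct, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("rank", setdiff(names(tab), "rank"))]
}

#' Observed/predicted plot data for a cross-validated model
#'
#' Emits the per-record table behind the standard observed-versus-predicted
#' and residual-versus-predicted display, plus the identity line and the
#' fitted observed~predicted and residual~predicted trend coefficients.
#'
#' @param cv a `kex_cv` prediction set.
#' @return List with `points` (record_id, study_id, predicted, observed,
#'   residual) and `lines` (identity plus fitted trends, as intercept/slope
#'   rows).
#' @export
cv_plot_data <- function(cv) {
  stopifnot(inherits(cv, "kex_cv"))
  pts <- data.frame(record_id = cv$record_id, study_id = cv$study_id,
                    predicted = cv$predicted, observed = cv$observed,
                    residual = cv$observed - cv$predicted,
                    stringsAsFactors = FALSE)
  obs_fit <- stats::coef(stats::lm(observed ~ predicted, data = pts))
  res_fit <- stats::coef(stats::lm(residual ~ predicted, data = pts))
  lines <- data.frame(
    line = c("identity", "observed_trend", "residual_trend"),
    intercept = c(0, obs_fit[1], res_fit[1]),
    slope = c(1, obs_fit[2], res_fit[2]),
    stringsAsFactors = FALSE)
  list(points = pts, lines = lines)
}
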