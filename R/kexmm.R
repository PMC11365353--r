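#' Weighted random-intercept linear mixed model for treatment means
#'
#' Fits the meta-analytic model
#' \deqn{y_{ij} = \beta_0 + \beta_1 x_{ij} + s_i + e_{ij}}
#' to study-level treatment means, where \eqn{s_i \sim N(0, \tau^2)} is the
#' random intercept shared by all means from study \eqn{i} and
#' \eqn{e_{ij} \sim N(0, \sigma^2 / w_{ij})} with \eqn{w_{ij}} the number of
#' observations behind mean \eqn{j} of study \eqn{i}. Weights act as relative
#' residual precisions, the standard treatment-mean weighting when replication
#' is known.
#'
#' Estimation is restricted maximum likelihood with the single variance ratio
#' \eqn{\theta = \tau^2/\sigma^2} profiled on \eqn{[0, \infty)}: at each
#' \eqn{\theta} the fixed effects are generalized least squares and
#' \eqn{\sigma^2} has a closed form, so the REML criterion is a smooth
#' one-dimensional function of \eqn{\theta}. It is minimized by a coarse
#' log-scale grid followed by bounded golden-section/parabolic refinement;
#' the boundary \eqn{\tau^2 = 0} is a legal solution, reported rather than
#' treated as an error. Standard errors come from the inverse weighted normal
#' equations at the optimum and the slope p-value from its Wald statistic.
#'
#' @param formula two-sided formula `response ~ predictor` with exactly one
#'   predictor, e.g. `k_ur ~ k_intake`.
#' @param data a [kex_db()] or data frame containing the model variables,
#'   the study identifier and the weight column.
#' @param study name of the study-identifier column (default `"study_id"`).
#' @param weights name of the weight column (default `"n_obs"`), or `NULL`
#'   for an unweighted fit.
#' @param weighted set `FALSE` to force unit weights even when a weight
#'   column is present.
#' @return A `kexmm` object: coefficients, their standard errors, variance
#'   components `tau2` and `sigma2` (unit-weight residual variance), study
#'   BLUPs, marginal R-squared, the restricted log-likelihood and the data
#'   used. Methods: [print.kexmm()], [summary.kexmm()], `coef`, `vcov`,
#'   [predict.kexmm()], `fitted`, [residuals.kexmm()], [simulate.kexmm()],
#'   [plot.kexmm()], `logLik`.
#' @examples
#' db <- simulate_kex_db(kex_sim_config(seed = 7))
#' fit <- kexmm(k_ur ~ k_intake, db)
#' summary(fit)
#' @export
kexmm <- function(formula, data, study = "study_id", weights = "n_obs",
                  weighted = TRUE) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  if (!is.name(formula[[2]]) || !is.name(formula[[3]])) {
    stop("formula must be 'response ~ predictor' with a single predictor")
  }
  response <- as.character(formula[[2]])
  predictor <- as.character(formula[[3]])
  if (response == predictor) stop("predictor must differ from response")
  data <- as.data.frame(data)
  for (v in c(response, predictor, study)) {
    if (!v %in% names(data)) stop("column not found: ", v)
  }

  y_all <- data[[response]]
  x_all <- data[[predictor]]
  ok <- !is.na(y_all) & !is.na(x_all)
  y <- y_all[ok]
  x <- x_all[ok]
  sid <- as.character(data[[study]][ok])
  w <- if (weighted && !is.null(weights)) {
    if (!weights %in% names(data)) stop("column not found: ", weights)
    as.numeric(data[[weights]][ok])
  } else rep(1, length(y))
  if (any(is.na(w) | w <= 0)) stop("weights must be positive")
  n <- length(y)
  if (length(unique(sid)) < 2L) {
    stop(sprintf("complete cases for %s ~ %s span fewer than 2 studies",
                 response, predictor))
  }
  if (stats::var(x) == 0) {
    stop(sprintf("predictor %s is constant across complete cases ",
                 predictor), "(rank-deficient design)")
  }

  fit <- .kexmm_reml(y, x, w, sid)
  if (!is.finite(fit$crit)) {
    stop(sprintf("REML fit failed to converge for %s ~ %s",
                 response, predictor))
  }

  yhat_fixed <- fit$beta[1] + fit$beta[2] * x
  var_f <- mean((yhat_fixed - mean(yhat_fixed))^2)
  sigma2_bar <- fit$sigma2 * mean(1 / w)
  r2m <- if (var_f > 0) var_f / (var_f + fit$tau2 + sigma2_bar) else 0

  z <- fit$beta[2] / fit$se[2]
  structure(list(
    formula = formula, response = response, predictor = predictor,
    coefficients = stats::setNames(fit$beta, c("(Intercept)", predictor)),
    se = stats::setNames(fit$se, c("(Intercept)", predictor)),
    vcov = fit$vcov,
    tau2 = fit$tau2, sigma2 = fit$sigma2, theta = fit$theta,
    boundary = fit$boundary,
    study_blups = fit$blups,
    n_used = n, n_studies = length(unique(sid)),
    reml_loglik = fit$loglik,
    r2_marginal = r2m, r2_degenerate = var_f == 0,
    wald_p = stats::setNames(2 * stats::pnorm(-abs(fit$beta / fit$se)),
                             c("(Intercept)", predictor)),
    wald_p_beta1 = unname(2 * stats::pnorm(-abs(z))),
    weighted = weighted && !is.null(weights),
    data = data.frame(y = y, x = x, w = w, study = sid,
                      stringsAsFactors = FALSE)
  ), class = "kexmm")
}

## Profiled REML criterion at variance ratio theta = tau2/sigma2.
## Block structure: V0_i = W_i^{-1} + theta * 1 1', inverted by
## Sherman-Morrison, so everything reduces to per-study weighted sums.
.kexmm_profile <- function(theta, y, X, w, sid) {
  n <- length(y)
  p <- ncol(X)
  wX <- X * w
  Sw <- rowsum(w, sid)                      # per-study sum of weights
  u <- rowsum(wX, sid)                      # per-study X' w
  shrink <- theta / (1 + theta * Sw[, 1])
  A <- crossprod(X, wX) - crossprod(u * sqrt(shrink))
  b <- crossprod(X, w * y) -
    crossprod(u * shrink, rowsum(w * y, sid))
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(list(crit = Inf))
  r <- y - X %*% beta
  tstudy <- rowsum(w * as.vector(r), sid)
  rVr <- sum(w * r^2) - sum(shrink * tstudy^2)
  if (rVr <= 0) return(list(crit = Inf))
  sigma2 <- rVr / (n - p)
  logdetV0 <- sum(log1p(theta * Sw)) - sum(log(w))
  crit <- (n - p) * log(sigma2) + logdetV0 +
    determinant(A, logarithm = TRUE)$modulus[1]
  list(crit = crit, beta = as.vector(beta), sigma2 = sigma2, A = A,
       shrink = shrink, Sw = Sw, tstudy = tstudy)
}

.kexmm_reml <- function(y, x, w, sid, grid_size = 81L,
                        theta_range = c(1e-10, 1e7)) {
  X <- cbind(1, x)
  n <- length(y)
  p <- 2L
  f <- function(lt) .kexmm_profile(exp(lt), y, X, w, sid)$crit

  lgrid <- seq(log(theta_range[1]), log(theta_range[2]), length.out = grid_size)
  crit_grid <- vapply(lgrid, f, numeric(1))
  i <- which.min(crit_grid)
  lo <- lgrid[max(1L, i - 1L)]
  hi <- lgrid[min(grid_size, i + 1L)]
  opt <- stats::optimize(f, interval = c(lo, hi), tol = 1e-10)
  theta <- exp(opt$minimum)
  crit <- opt$objective

  crit0 <- .kexmm_profile(0, y, X, w, sid)$crit
  boundary <- FALSE
  if (crit0 <= crit || theta < 1e-8) {
    theta <- 0
    crit <- crit0
    boundary <- TRUE
  }

  prof <- .kexmm_profile(theta, y, X, w, sid)
  vcov <- prof$sigma2 * solve(prof$A)
  blups <- theta * prof$tstudy[, 1] / (1 + theta * prof$Sw[, 1])
  names(blups) <- rownames(prof$Sw)
  loglik <- -0.5 * (crit + (n - p) * (1 + log(2 * pi)))
  list(theta = theta, beta = prof$beta, sigma2 = prof$sigma2,
       tau2 = theta * prof$sigma2, vcov = vcov,
       se = sqrt(diag(vcov)), blups = blups, crit = crit,
       loglik = loglik, boundary = boundary)
}

#' Render a fitted equation as text
#'
#' Formats a fitted model in the conventional report style
#' `"Y = b0 (±se) + b1 (±se) × predictor"`.
#'
#' @param object a `kexmm` fit.
#' @param digits significant digits for coefficients and SEs.
#' @return A character scalar.
#' @export
equation_text <- function(object, digits = 4) {
  stopifnot(inherits(object, "kexmm"))
  b <- object$coefficients
  s <- object$se
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  sprintf("%s = %s (±%s) %s %s (±%s) × %s",
          object$response, fmt(b[1]), fmt(s[1]),
          if (b[2] < 0) "−" else "+",
          fmt(abs(b[2])), fmt(s[2]), object$predictor)
}

#' @export
print.kexmm <- function(x, digits = 4, ...) {
  cat("Weighted random-intercept mixed model (REML)\n")
  cat("  ", equation_text(x, digits = digits), "\n", sep = "")
  cat(sprintf("  n = %d treatment means, %d studies%s\n", x$n_used,
              x$n_studies, if (x$weighted) ", weighted by n_obs" else ""))
  cat(sprintf("  tau^2 = %s  sigma^2 = %s  marginal R^2 = %.3f\n",
              formatC(x$tau2, digits = digits, format = "g"),
              formatC(x$sigma2, digits = digits, format = "g"),
              x$r2_marginal))
  invisible(x)
}

#' Summary of a fitted potassium-excretion model
#'
#' @param object a `kexmm` fit.
#' @param ... unused.
#' @return A `summary.kexmm` with the coefficient table (estimate, SE, Wald
#'   z, p), variance components, marginal R-squared and fit metadata.
#' @export
summary.kexmm <- function(object, ...) {
  z <- object$coefficients / object$se
  ctab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
                `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = ctab), class = "summary.kexmm")
}

#' @export
print.summary.kexmm <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, digits = digits, signif.stars = FALSE)
  cat(sprintf("\nRandom effects: study intercept SD = %s; residual SD (unit weight) = %s\n",
              formatC(sqrt(f$tau2), digits = digits, format = "g"),
              formatC(sqrt(f$sigma2), digits = digits, format = "g")))
  if (f$boundary) cat("Note: tau^2 estimated at the boundary (0).\n")
  cat(sprintf("Restricted log-likelihood: %.3f\n", f$reml_loglik))
  invisible(x)
}

#' @export
coef.kexmm <- function(object, ...) object$coefficients

#' @export
vcov.kexmm <- function(object, ...) object$vcov

#' @export
logLik.kexmm <- function(object, ...) {
  structure(object$reml_loglik, df = 4, class = "logLik")
}

#' Predict from a fitted model
#'
#' Fixed-effect predictions `b0 + b1 * x` by default — the only defensible
#' prediction for a study not in the training data, and the one used for
#' cross-validated evaluation. With `re = "study"`, the study BLUP is added
#' for studies seen in training (unknown studies get 0, the random-effect
#' expectation). Missing predictor values propagate as `NA`; predictions are
#' never clipped.
#'
#' @param object a `kexmm` fit.
#' @param newdata numeric vector of predictor values, or a data frame
#'   containing the predictor column (and the study column if `re = "study"`).
#'   Defaults to the training data.
#' @param re `"none"` (fixed effects only) or `"study"`.
#' @param ... unused.
#' @return Numeric vector of predicted responses (g/d).
#' @export
predict.kexmm <- function(object, newdata = NULL, re = c("none", "study"),
                          ...) {
  re <- match.arg(re)
  if (is.null(newdata)) {
    xv <- object$data$x
    sidv <- object$data$study
  } else if (is.numeric(newdata)) {
    xv <- newdata
    sidv <- rep(NA_character_, length(xv))
  } else {
    newdata <- as.data.frame(newdata)
    if (!object$predictor %in% names(newdata)) {
      stop("newdata lacks predictor column ", object$predictor)
    }
    xv <- newdata[[object$predictor]]
    sidv <- if ("study_id" %in% names(newdata)) {
      as.character(newdata$study_id)
    } else rep(NA_character_, length(xv))
  }
  yhat <- object$coefficients[1] + object$coefficients[2] * xv
  if (re == "study") {
    bl <- object$study_blups[sidv]
    bl[is.na(bl)] <- 0
    yhat <- yhat + unname(bl)
  }
  unname(yhat)
}

#' @export
fitted.kexmm <- function(object, ...) {
  nd <- data.frame(object$data$x, object$data$study,
                   stringsAsFactors = FALSE)
  names(nd) <- c(object$predictor, "study_id")
  predict(object, newdata = nd, re = "study")
}

#' Residuals of a fitted model
#'
#' @param object a `kexmm` fit.
#' @param type `"conditional"` (observed minus fixed + BLUP fit) or
#'   `"marginal"` (observed minus fixed-effect fit).
#' @param ... unused.
#' @return Numeric vector.
#' @export
residuals.kexmm <- function(object, type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  yhat_f <- object$coefficients[1] + object$coefficients[2] * object$data$x
  r <- object$data$y - yhat_f
  if (type == "conditional") {
    r <- r - unname(object$study_blups[object$data$study])
  }
  unname(r)
}

#' Simulate responses from a fitted model
#'
#' Draws new study intercepts and residuals at the estimated variance
#' components over the training design (same predictor values, weights and
#' study structure), i.e. a parametric-bootstrap draw of the response.
#'
#' @param object a `kexmm` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return Data frame with `nsim` columns `sim_1 ... sim_nsim`.
#' @export
simulate.kexmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  studies <- unique(d$study)
  mu <- object$coefficients[1] + object$coefficients[2] * d$x
  out <- replicate(nsim, {
    s <- stats::rnorm(length(studies), 0, sqrt(object$tau2))
    names(s) <- studies
    mu + s[d$study] + stats::rnorm(nrow(d), 0, sqrt(object$sigma2 / d$w))
  })
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plots for a fitted model
#'
#' Observed versus fitted values with the identity line, and residuals
#' versus fitted values — the standard adequacy display for excretion
#' prediction equations.
#'
#' @param x a `kexmm` fit.
#' @param which `1` observed vs fitted, `2` residuals vs fitted, or both.
#' @param re passed to [predict.kexmm()] (default fixed effects only).
#' @param ... passed to `plot`.
#' @export
plot.kexmm <- function(x, which = 1:2, re = "none", ...) {
  yhat <- predict(x, re = re)
  obs <- x$data$y
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    graphics::plot(yhat, obs, xlab = "Predicted (g/d)",
                   ylab = "Observed (g/d)",
                   main = equation_text(x, digits = 3), ...)
    graphics::abline(0, 1)
    graphics::abline(stats::lm(obs ~ yhat), lty = 2, col = 2)
  }
  if (2 %in% which) {
    res <- obs - yhat
    graphics::plot(yhat, res, xlab = "Predicted (g/d)",
                   ylab = "Observed - predicted (g/d)", ...)
    graphics::abline(h = 0)
    graphics::abline(stats::lm(res ~ yhat), lty = 2, col = 2)
  }
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param object a `kexmm` fit.
#' @param path optional output path.
#' @return JSON string (invisibly if written).
#' @export
kexmm_json <- function(object, path = NULL) {
  stopifnot(inherits(object, "kexmm"))
  payload <- list(
    equation = equation_text(object),
    response = object$response, predictor = object$predictor,
    coefficients = as.list(object$coefficients),
    se = as.list(object$se),
    tau2 = object$tau2, sigma2 = object$sigma2,
    r2_marginal = object$r2_marginal,
    wald_p_beta1 = object$wald_p_beta1,
    n_used = object$n_used, n_studies = object$n_studies,
    boundary = object$boundary,
    reml_loglik = object$reml_loglik,
    study_blups = as.list(object$study_blups)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
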