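## Shared fixtures: tiny hand-built databases and random pair sets.

toy_records <- function() {
  data.frame(
    record_id = paste0("r", 1:6),
    study_id = rep(c("A", "B", "C"), each = 2),
    n_obs = c(4, 6, 8, 8, 5, 7),
    dmi = c(15, 18, 20, 22, 12, 16),
    dietary_k = c(1.2, 1.5, 1.8, 2.0, 1.0, 1.4),
    k_intake = c(180, 270, 360, 440, 120, 224),
    k_ur = c(110, 170, 230, 280, 75, 140),
    stringsAsFactors = FALSE
  )
}

toy_db <- function(...) kex_db(toy_records(), response_name = "k_ur", ...)

## A database with mean/sd of selected columns pinned exactly: two records
## per variable at mean +/- sd/sqrt(2) give sample mean m and sample SD s.
two_point_db <- function(response, stats) {
  rec <- data.frame(record_id = c("p1", "p2"),
                    study_id = c("A", "B"), n_obs = c(5, 5),
                    stringsAsFactors = FALSE)
  for (v in names(stats)) {
    m <- stats[[v]][1]
    s <- stats[[v]][2]
    rec[[v]] <- m + c(-1, 1) * s / sqrt(2)
  }
  kex_db(rec, response_name = response)
}

random_pairs <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:40, 1)
  obs <- stats::rnorm(n, 100, 30)
  a <- stats::runif(1, -1, 2)
  b <- stats::runif(1, -50, 50)
  pred <- a * obs + b + stats::rnorm(n, 0, stats::runif(1, 0, 40))
  list(obs = obs, pred = pred)
}

## Independent literal transcription of Lin's concordance formula,
## loop-based, used only as a cross-check oracle.
ccc_bruteforce <- function(obs, pred) {
  n <- length(obs)
  mo <- sum(obs) / n
  mp <- sum(pred) / n
  so2 <- 0
  sp2 <- 0
  cov <- 0
  for (i in seq_len(n)) {
    so2 <- so2 + (obs[i] - mo)^2 / n
    sp2 <- sp2 + (pred[i] - mp)^2 / n
    cov <- cov + (obs[i] - mo) * (pred[i] - mp) / n
  }
  2 * cov / (so2 + sp2 + (mo - mp)^2)
}
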