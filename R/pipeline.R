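#' Pipeline configuration
#'
#' One response per run (the urinary and fecal databases are separate);
#' [kex_pipeline_both()] is the convenience wrapper that runs both.
#'
#' @param input path to a treatment-mean CSV, or a [kex_sim_config()] /
#'   list of them to generate the input instead.
#' @param response `"k_ur"` or `"k_fa"`.
#' @param predictors candidate predictors; defaults to the six urinary
#'   candidates for `k_ur` and the four fecal candidates (`dmi`, `k_intake`,
#'   `dietary_k`, `milk_yield`) for `k_fa`.
#' @param screening list with `variables` (NULL for the per-response
#'   default), `factor`, `blocklist_studies`.
#' @param out_dir output directory for report artifacts (created).
#' @param seed integer seed stamped on artifacts and used for generation.
#' @param skip_failing if `TRUE`, models whose fit or CV fails are dropped
#'   with a log line instead of aborting the run.
#' @param dry_run validate config and input, write nothing.
#' @return A validated `kex_pipeline_config`.
#' @export
kex_pipeline_config <- function(input, response = c("k_ur", "k_fa"),
                                predictors = NULL,
                                screening = list(variables = NULL,
                                                 factor = 1.5,
                                                 blocklist_studies = character()),
                                out_dir = "kexmeta_out", seed = 1L,
                                skip_failing = FALSE, dry_run = FALSE) {
  response <- match.arg(response)
  if (is.null(predictors)) {
    predictors <- if (response == "k_ur") {
      c("dmi", "k_intake", "dietary_k", "water_intake",
        "urine_volume", "milk_yield")
    } else {
      c("dmi", "k_intake", "dietary_k", "milk_yield")
    }
  }
  bad <- setdiff(predictors, .kex_predictors)
  if (length(bad) > 0L) stop("unknown predictors: ", paste(bad, collapse = ", "))
  if (is.null(screening$factor)) screening$factor <- 1.5
  if (is.null(screening$blocklist_studies)) {
    screening$blocklist_studies <- character()
  }
  structure(list(input = input, response = response, predictors = predictors,
                 screening = screening, out_dir = out_dir,
                 seed = as.integer(seed), skip_failing = isTRUE(skip_failing),
                 dry_run = isTRUE(dry_run)),
            class = "kex_pipeline_config")
}

## Rolling polynomial hash (mod 2^32) over the deparsed config: a stable
## content stamp for artifacts. Kept in doubles; 31 * 2^32 is exactly
## representable, so the arithmetic is deterministic across platforms.
.kex_config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.kex_log <- function(stage, fmt, ...) {
  message(sprintf("[kexmeta:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the end-to-end excretion-model pipeline
#'
#' Orchestrates load (or generate) -> derive K intake -> IQR screen -> fit
#' every candidate model -> leave-one-study-out CV -> adequacy metrics ->
#' ranking, and writes the report bundle: screening report (JSON), database
#' summary (CSV), fitted equations with SEs (CSV + JSON), per-model CV
#' metrics (CSV), ranked model list (CSV) and per-model observed/predicted
#' plot-data tables (CSV). Every artifact directory is stamped with the
#' config hash and seed; two runs with identical config and seed produce
#' byte-identical reports.
#'
#' @param config a [kex_pipeline_config()].
#' @return Invisibly, a list with the screened database, summary, fitted
#'   models, metrics, ranking, plot data, and the artifact manifest.
#' @export
kex_pipeline <- function(config) {
  stopifnot(inherits(config, "kex_pipeline_config"))

  db <- if (inherits(config$input, "kex_sim_config")) {
    .kex_log("load", "generating synthetic database (seed %d)", config$seed)
    cfg <- config$input
    cfg$seed <- config$seed
    simulate_kex_db(cfg)
  } else if (is.character(config$input)) {
    .kex_log("load", "reading %s", config$input)
    read_kex_db(config$input, response_name = config$response)
  } else {
    stop("input must be a CSV path or a kex_sim_config")
  }
  rejected <- attr(db, "rejected")
  .kex_log("load", "%d records, %d studies (%d rejected by validation)",
           nrow(db), length(unique(db$study_id)),
           if (is.null(rejected)) 0L else nrow(rejected))

  db <- derive_k_intake(db)

  scr <- screen_outliers(db,
                         variables = config$screening$variables,
                         factor = config$screening$factor,
                         blocklist_studies = config$screening$blocklist_studies)
  .kex_log("screen", "%d extreme mean(s) removed, %d blocklisted; %d remain",
           scr$report$n_removed, scr$report$n_blocklisted, nrow(scr$db))
  db <- scr$db

  if (config$dry_run) {
    .kex_log("dry-run", "config and input valid; nothing written")
    return(invisible(list(config = config, db = db, report = scr$report)))
  }

  summ <- kex_summarize(db)

  predictors <- config$predictors
  absent <- predictors[vapply(predictors,
                              function(p) all(is.na(db[[p]])), logical(1))]
  if (length(absent) > 0L) {
    .kex_log("fit", "no observed values for: %s; dropped from candidates",
             paste(absent, collapse = ", "))
    predictors <- setdiff(predictors, absent)
  }

  metrics <- list()
  fits <- list()
  for (p in predictors) {
    res <- tryCatch(evaluate_model(db, p), error = function(e) e)
    if (inherits(res, "error")) {
      if (config$skip_failing) {
        .kex_log("fit", "model %s ~ %s skipped: %s", config$response, p,
                 conditionMessage(res))
        next
      }
      stop(sprintf("model %s ~ %s failed: %s", config$response, p,
                   conditionMessage(res)))
    }
    fits[[p]] <- attr(res, "fit")
    metrics[[p]] <- res
    .kex_log("fit", "%s  [RSR %.2f, CCC %.2f]",
             equation_text(attr(res, "fit"), digits = 3), res$rsr, res$ccc)
  }
  if (length(metrics) == 0L) stop("no candidate model could be fitted")
  ranking <- rank_models(metrics)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = .kex_config_hash(config), seed = config$seed,
                response = config$response)
  paths <- list()
  wcsv <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    paths[[name]] <<- path
  }
  wcsv(summ$table, "summary.csv")
  screening_report_json(scr$report,
                        file.path(config$out_dir, "screening.json"))
  paths[["screening.json"]] <- file.path(config$out_dir, "screening.json")

  eqs <- do.call(rbind, lapply(names(fits), function(p) {
    f <- fits[[p]]
    data.frame(model = p, equation = equation_text(f),
               beta0 = unname(coef(f)[1]), se_beta0 = unname(f$se[1]),
               beta1 = unname(coef(f)[2]), se_beta1 = unname(f$se[2]),
               tau2 = f$tau2, sigma2 = f$sigma2,
               r2_marginal = f$r2_marginal, wald_p_beta1 = f$wald_p_beta1,
               n = f$n_used, n_studies = f$n_studies,
               stringsAsFactors = FALSE)
  }))
  wcsv(eqs, "models.csv")
  wcsv(ranking, "ranking.csv")
  for (p in names(metrics)) {
    pd <- cv_plot_data(attr(metrics[[p]], "cv"))
    wcsv(pd$points, sprintf("plotdata_%s.csv", p))
    wcsv(pd$lines, sprintf("plotlines_%s.csv", p))
  }
  bundle <- c(stamp, list(artifacts = names(paths)))
  writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE, pretty = TRUE),
             file.path(config$out_dir, "manifest.json"))
  paths[["manifest.json"]] <- file.path(config$out_dir, "manifest.json")
  .kex_log("report", "%d artifacts written to %s", length(paths),
           config$out_dir)

  invisible(list(config = config, db = db, summary = summ,
                 screening = scr$report, fits = fits, metrics = metrics,
                 ranking = ranking, stamp = stamp, paths = paths))
}

#' Run the pipeline for both responses
#'
#' @param input_k_ur,input_k_fa inputs as in [kex_pipeline_config()].
#' @param out_dir parent output directory; per-response subdirectories
#'   `k_ur/` and `k_fa/` are created.
#' @param ... passed through to [kex_pipeline_config()].
#' @return Invisibly, a list with both run results.
#' @export
kex_pipeline_both <- function(input_k_ur, input_k_fa,
                              out_dir = "kexmeta_out", ...) {
  res_ur <- kex_pipeline(kex_pipeline_config(
    input_k_ur, response = "k_ur",
    out_dir = file.path(out_dir, "k_ur"), ...))
  res_fa <- kex_pipeline(kex_pipeline_config(
    input_k_fa, response = "k_fa",
    out_dir = file.path(out_dir, "k_fa"), ...))
  invisible(list(k_ur = res_ur, k_fa = res_fa))
}
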