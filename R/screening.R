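#' Interquartile-range outlier fences
#'
#' Tukey-style fences `Q1 - factor * IQR` and `Q3 + factor * IQR` with
#' `IQR = Q3 - Q1`. Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7); fence membership depends on the quantile rule,
#' so it is fixed here rather than configurable.
#'
#' @param values numeric vector; missing values are dropped.
#' @param factor positive multiplier of the IQR; 1.5 flags extreme values.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
iqr_fences <- function(values, factor = 1.5) {
  stopifnot(is.numeric(values), factor >= 0)
  x <- values[!is.na(values)]
  if (length(x) < 4L) {
    stop("need at least 4 non-missing values for stable IQR fences, got ",
         length(x))
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - factor * iqr, upper = q[2] + factor * iqr)
}

#' Screen a database for extreme treatment means
#'
#' One pass of the interquartile-range rule over the listed variables: a
#' record strictly outside the fences on ANY listed variable is removed as a
#' whole (never field-wise). Optionally removes whole studies on a blocklist
#' first (data-specific exclusions such as implausible excretion values or
#' data reuse across papers). Record order is preserved; every removal is
#' listed in the report with its triggering variable and value.
#'
#' Screening is intentionally single-pass: fences are computed once on the
#' incoming data, and re-screening a screened set is not idempotent because
#' fences tighten.
#'
#' @param db a [kex_db()].
#' @param variables fields to screen; defaults to the response plus `dmi`,
#'   `k_intake` and, for the urinary database, `urine_volume`, keeping only
#'   variables with at least 4 observed values (fences are unstable below
#'   that). An explicitly supplied list is screened as given.
#' @param factor IQR multiplier (default 1.5).
#' @param blocklist_studies character vector of `study_id` values to drop
#'   before fence computation.
#' @return List with `db` (the screened `kex_db`) and `report` (a
#'   `kex_screening_report`: fences per variable, flagged records with the
#'   triggering variable and value, blocklisted records, and counts).
#' @export
screen_outliers <- function(db, variables = NULL, factor = 1.5,
                            blocklist_studies = character()) {
  stopifnot(inherits(db, "kex_db"))
  response <- attr(db, "response_name")
  if (is.null(variables)) {
    variables <- c(response, "dmi", "k_intake")
    if (response == "k_ur") variables <- c(variables, "urine_volume")
    # default screen covers only variables actually observed often enough
    # for stable fences; an explicit list is honoured (and may error)
    variables <- variables[vapply(variables, function(v) {
      sum(!is.na(db[[v]])) >= 4L
    }, logical(1))]
  }
  bad <- setdiff(variables, .kex_numeric_fields)
  if (length(bad) > 0L) stop("unknown variables: ", paste(bad, collapse = ", "))

  blocked <- db$study_id %in% blocklist_studies
  work <- db[!blocked, , drop = FALSE]
  if (length(unique(work$study_id)) < 2L) {
    stop("screening would leave fewer than 2 studies")
  }

  fences <- lapply(variables, function(v) iqr_fences(work[[v]], factor))
  names(fences) <- variables

  flags <- NULL
  for (v in variables) {
    x <- work[[v]]
    f <- fences[[v]]
    out <- !is.na(x) & (x < f["lower"] | x > f["upper"])
    if (any(out)) {
      flags <- rbind(flags, data.frame(
        record_id = work$record_id[out], study_id = work$study_id[out],
        variable = v, value = x[out],
        lower = unname(f["lower"]), upper = unname(f["upper"]),
        stringsAsFactors = FALSE))
    }
  }
  flagged_ids <- unique(flags$record_id)
  keep <- !(work$record_id %in% flagged_ids)
  screened <- work[keep, , drop = FALSE]
  rownames(screened) <- NULL
  if (length(unique(screened$study_id)) < 2L) {
    stop("screening would leave fewer than 2 studies")
  }
  out_db <- structure(screened,
                      response_name = response,
                      provenance = paste0(attr(db, "provenance"),
                                          " | screened (IQR factor ", factor, ")"),
                      rejected = attr(db, "rejected"),
                      class = c("kex_db", "data.frame"))
  report <- structure(list(
    variables = variables, factor = factor,
    fences = do.call(rbind, lapply(variables, function(v) {
      data.frame(variable = v, lower = unname(fences[[v]]["lower"]),
                 upper = unname(fences[[v]]["upper"]),
                 stringsAsFactors = FALSE)
    })),
    flags = if (is.null(flags)) {
      data.frame(record_id = character(), study_id = character(),
                 variable = character(), value = numeric(),
                 lower = numeric(), upper = numeric(),
                 stringsAsFactors = FALSE)
    } else flags,
    flagged_record_ids = flagged_ids,
    blocklisted_record_ids = db$record_id[blocked],
    n_removed = length(flagged_ids),
    n_blocklisted = sum(blocked)
  ), class = "kex_screening_report")
  list(db = out_db, report = report)
}

#' @export
print.kex_screening_report <- function(x, ...) {
  cat(sprintf("IQR screening (factor %.2f) on: %s\n", x$factor,
              paste(x$variables, collapse = ", ")))
  print(format(x$fences, digits = 4), row.names = FALSE)
  if (x$n_blocklisted > 0L) {
    cat(sprintf("%d record(s) removed by study blocklist\n", x$n_blocklisted))
  }
  if (x$n_removed == 0L) {
    cat("no extreme treatment means flagged\n")
  } else {
    cat(sprintf("%d treatment mean(s) flagged as extreme:\n", x$n_removed))
    print(format(x$flags, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a screening report to JSON
#'
#' @param report a `kex_screening_report`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
screening_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "kex_screening_report"))
  js <- jsonlite::toJSON(unclass(report), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
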