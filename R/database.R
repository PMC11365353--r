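#' @keywords internal
"_PACKAGE"

## Column layout of a treatment-mean database. Each row is one published
## group-level mean (one diet x one study); n_obs is the number of animals
## behind the mean and acts as the model weight.
.kex_numeric_fields <- c(
  "dmi", "k_intake", "dietary_k", "water_intake",
  "urine_volume", "milk_yield", "k_ur", "k_fa"
)
.kex_fields <- c("record_id", "study_id", "n_obs", "lactating", .kex_numeric_fields)
.kex_responses <- c("k_ur", "k_fa")
.kex_predictors <- c("dmi", "k_intake", "dietary_k", "water_intake",
                     "urine_volume", "milk_yield")

#' Construct a treatment-mean database
#'
#' A `kex_db` is a data frame of study-level treatment means, one row per
#' published group mean, carrying the response of interest (`k_ur` or `k_fa`,
#' g/d), the candidate predictors and the per-mean replication count `n_obs`
#' used as the model weight. Rows violating the record invariants are rejected
#' and returned in the `rejected` attribute rather than silently dropped.
#'
#' Record invariants: `n_obs >= 1`; all present quantities strictly positive;
#' at least one of `k_ur`, `k_fa` present; if `dmi`, `dietary_k` and
#' `k_intake` are all present, the reported K intake must agree with
#' `dmi * dietary_k * 10` (kg/d x %DM -> g/d) within `tol` relative.
#'
#' @param records data frame with columns `record_id`, `study_id`, `n_obs`
#'   and any of `lactating`, `dmi`, `k_intake`, `dietary_k`, `water_intake`,
#'   `urine_volume`, `milk_yield`, `k_ur`, `k_fa`. Missing cells are `NA`.
#' @param response_name `"k_ur"` (urinary) or `"k_fa"` (fecal).
#' @param provenance free-text metadata stored on the object.
#' @param tol relative tolerance for the K-intake consistency check.
#' @return A `kex_db`: the validated data frame with attributes
#'   `response_name`, `provenance` and `rejected` (a data frame of dropped
#'   rows with the reason for each).
#' @seealso [read_kex_db()], [derive_k_intake()], [kex_summarize()]
#' @export
kex_db <- function(records, response_name = c("k_ur", "k_fa"),
                   provenance = "", tol = 0.05) {
  response_name <- match.arg(response_name)
  stopifnot(is.data.frame(records))
  required <- c("record_id", "study_id", "n_obs")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (f in setdiff(.kex_fields, names(records))) {
    records[[f]] <- if (f == "lactating") NA else NA_real_
  }
  records <- records[, .kex_fields]
  records$record_id <- as.character(records$record_id)
  records$study_id <- as.character(records$study_id)
  records$n_obs <- as.integer(records$n_obs)
  for (f in .kex_numeric_fields) records[[f]] <- as.numeric(records[[f]])

  reasons <- vapply(seq_len(nrow(records)), function(i) {
    .validate_record(records[i, ], tol = tol)
  }, character(1))
  bad <- reasons != ""
  rejected <- records[bad, c("record_id", "study_id"), drop = FALSE]
  rejected$reason <- reasons[bad]
  rownames(rejected) <- NULL
  kept <- records[!bad, , drop = FALSE]
  rownames(kept) <- NULL

  if (anyDuplicated(kept$record_id)) {
    stop("record_id values must be unique")
  }
  if (length(unique(kept$study_id)) < 2L) {
    stop("fewer than 2 distinct studies after validation; ",
         "the study random effect is undefined")
  }
  structure(kept,
            response_name = response_name,
            provenance = provenance,
            rejected = rejected,
            class = c("kex_db", "data.frame"))
}

## One reason string per row; "" means the row passes all record invariants.
.validate_record <- function(row, tol = 0.05) {
  n <- row$n_obs
  if (is.na(n) || n < 1 || n != round(n)) {
    return("n_obs must be a positive integer")
  }
  vals <- unlist(row[.kex_numeric_fields])
  if (any(!is.na(vals) & vals <= 0)) {
    bad <- .kex_numeric_fields[!is.na(vals) & vals <= 0]
    return(paste0("non-positive value in ", paste(bad, collapse = ", ")))
  }
  if (is.na(row$k_ur) && is.na(row$k_fa)) {
    return("neither k_ur nor k_fa present")
  }
  if (!is.na(row$dmi) && !is.na(row$dietary_k) && !is.na(row$k_intake)) {
    expected <- row$dmi * row$dietary_k * 10
    if (abs(row$k_intake - expected) / row$k_intake > tol) {
      return(sprintf(
        "k_intake %.4g inconsistent with dmi x dietary_k x 10 = %.4g",
        row$k_intake, expected))
    }
  }
  ""
}

#' Read a treatment-mean database from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header row, `.` decimal separator) whose
#' columns follow the `kex_db` field layout, validates every row, and returns
#' the database. Invalid rows are reported via the `rejected` attribute.
#'
#' @param path CSV file path.
#' @param response_name `"k_ur"` or `"k_fa"`.
#' @param na strings treated as missing (besides empty cells).
#' @param tol relative tolerance for the K-intake consistency check.
#' @return A [kex_db()].
#' @export
read_kex_db <- function(path, response_name = c("k_ur", "k_fa"),
                        na = c("", "NA"), tol = 0.05) {
  response_name <- match.arg(response_name)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, na.strings = na, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  kex_db(raw, response_name = response_name,
         provenance = paste0("read_kex_db:", path), tol = tol)
}

#' Write a treatment-mean database to CSV
#'
#' Writes the same dialect [read_kex_db()] reads, so that a write/read
#' round-trip reproduces all numeric fields at full double precision.
#'
#' @param db a `kex_db`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kex_db <- function(db, path) {
  stopifnot(inherits(db, "kex_db"))
  out <- as.data.frame(db)
  for (f in .kex_numeric_fields) {
    out[[f]] <- ifelse(is.na(out[[f]]), "",
                       formatC(out[[f]], digits = 17, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Derive potassium intake from DMI and dietary concentration
#'
#' Where K intake was not reported in a source study it is computed from dry
#' matter intake and the dietary K concentration:
#' `k_intake [g/d] = dmi [kg/d] * dietary_k [% of DM] * 10`. Reported intakes
#' are never overwritten. Rows where the derivation is impossible (dmi or
#' dietary_k missing) are left unchanged and flagged.
#'
#' @param db a `kex_db` (or plain data frame with the same columns).
#' @return The database with `k_intake` filled in where derivable and a
#'   logical attribute `k_intake_underivable` marking rows where `k_intake`
#'   is missing and cannot be derived.
#' @export
derive_k_intake <- function(db) {
  stopifnot(is.data.frame(db))
  fill <- is.na(db$k_intake) & !is.na(db$dmi) & !is.na(db$dietary_k)
  db$k_intake[fill] <- db$dmi[fill] * db$dietary_k[fill] * 10
  attr(db, "k_intake_underivable") <- is.na(db$k_intake)
  db
}

#' Descriptive summary of a treatment-mean database
#'
#' Per-variable count of non-missing values, mean, sample SD (n - 1
#' denominator), minimum, maximum, and coefficient of variation
#' (`100 * sd / mean`), plus the excretion share of intake
#' (`100 * mean(response) / mean(k_intake)`), each moment over that
#' variable's own non-missing values.
#'
#' @param db a `kex_db`.
#' @param variables character vector of fields to summarize; defaults to the
#'   response plus every candidate predictor present in the database.
#' @return A `kex_summary`: list with `table` (data frame: variable, n, mean,
#'   sd, min, max, cv_pct), `share_pct`, and `response_name`. Variables with
#'   fewer than 2 values get `NA` sd and cv; zero values flag the whole row.
#' @export
kex_summarize <- function(db, variables = NULL) {
  stopifnot(inherits(db, "kex_db"))
  response <- attr(db, "response_name")
  if (is.null(variables)) {
    variables <- c(response, "dmi", "k_intake", "dietary_k",
                   "water_intake", "urine_volume", "milk_yield")
    variables <- variables[vapply(variables,
                                  function(v) any(!is.na(db[[v]])), logical(1))]
  }
  bad <- setdiff(variables, .kex_numeric_fields)
  if (length(bad) > 0L) stop("unknown variables: ", paste(bad, collapse = ", "))
  rows <- lapply(variables, function(v) {
    x <- db[[v]]
    x <- x[!is.na(x)]
    n <- length(x)
    m <- if (n > 0L) mean(x) else NA_real_
    s <- if (n > 1L) stats::sd(x) else NA_real_
    data.frame(variable = v, n = n, mean = m, sd = s,
               min = if (n > 0L) min(x) else NA_real_,
               max = if (n > 0L) max(x) else NA_real_,
               cv_pct = if (n > 1L && m != 0) 100 * s / m else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mean_resp <- mean(db[[response]], na.rm = TRUE)
  mean_intake <- mean(db$k_intake, na.rm = TRUE)
  share <- if (is.finite(mean_intake) && mean_intake > 0) {
    100 * mean_resp / mean_intake
  } else NA_real_
  structure(list(table = tab, share_pct = share, response_name = response,
                 n_records = nrow(db),
                 n_studies = length(unique(db$study_id))),
            class = "kex_summary")
}

#' @export
print.kex_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Treatment-mean database summary (%s): %d records, %d studies\n",
              x$response_name, x$n_records, x$n_studies))
  print(format(x$table, digits = digits), row.names = FALSE)
  if (is.finite(x$share_pct)) {
    cat(sprintf("Excretion share of K intake: %.1f%%\n", x$share_pct))
  }
  invisible(x)
}

#' Reference descriptive statistics of the published K excretion databases
#'
#' Published summary statistics (n, mean, SD, min, max) of the urinary and
#' fecal potassium excretion literature databases, used to calibrate the
#' synthetic-data generator and as fixture inputs. These are group-level
#' summaries; the underlying per-treatment raw database is not public.
#'
#' @param database `"urinary"` or `"fecal"`.
#' @return Data frame: variable, n, mean, sd, min, max.
#' @export
kex_reference_stats <- function(database = c("urinary", "fecal")) {
  database <- match.arg(database)
  path <- system.file("extdata", "k_excretion_reference_stats.csv",
                      package = "kexmeta", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab[tab$database == database, setdiff(names(tab), "database")]
}
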