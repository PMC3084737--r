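#' Read individual case-control records from CSV
#'
#' Expects the header `id,status,dosage,age,sex,smoking_status,cpd,
#' duration_years,family_history`. Enumerated columns are case-insensitive
#' (`status`: case/control; `smoking_status`: never/former/current; `sex`:
#' male/female). Never-smokers with a non-missing CPD are flagged via the
#' `"inconsistent_rows"` attribute rather than silently accepted.
#'
#' @param path Path to the CSV file.
#' @return A data frame of typed records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "status", "dosage", "age", "sex", "smoking_status",
              "cpd", "duration_years", "family_history")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("records file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("records file has no rows", call. = FALSE)
  df$status <- tolower(as.character(df$status))
  bad <- which(!df$status %in% c("case", "control"))
  if (length(bad))
    stop("unknown status value at line ", bad[1] + 1L, ": ",
         df$status[bad[1]], call. = FALSE)
  df$smoking_status <- tolower(as.character(df$smoking_status))
  bad <- which(!df$smoking_status %in% c("never", "former", "current"))
  if (length(bad))
    stop("unknown smoking_status value at line ", bad[1] + 1L, ": ",
         df$smoking_status[bad[1]], call. = FALSE)
  for (col in c("dosage", "age", "cpd", "duration_years")) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !(is.na(raw) | trimws(as.character(raw)) == ""))
    if (length(bad))
      stop(sprintf("non-numeric %s at line %d: %s", col, bad[1] + 1L,
                   raw[bad[1]]), call. = FALSE)
    df[[col]] <- v
  }
  if (any(!df$dosage %in% 0:2, na.rm = TRUE))
    stop("dosage must be 0, 1 or 2", call. = FALSE)
  df$family_history <- as.logical(df$family_history)
  incons <- which(df$smoking_status == "never" & !is.na(df$cpd))
  attr(df, "inconsistent_rows") <- incons
  if (length(incons))
    warning(length(incons), " never-smoker record(s) carry a CPD value",
            call. = FALSE)
  df
}

#' Write individual records to CSV
#'
#' Inverse of [read_records()].
#'
#' @param records Data frame of individual records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

report_schema_version <- "1.0"

#' Assemble an analysis report
#'
#' Bundles named result blocks with run metadata (schema version, package
#' version, timestamp, seed, input descriptions) for JSON serialization.
#'
#' @param results Named list of result objects (`or_result`,
#'   `trend_result`, `meta_result`, plain lists or numbers).
#' @param inputs Optional named character vector describing input files.
#' @param seed Optional integer seed used for stochastic steps.
#' @return An object of class `analysis_report`.
#' @export
analysis_report <- function(results, inputs = NULL, seed = NULL) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop("'results' must be a fully named list", call. = FALSE)
  structure(list(
    metadata = list(schema_version = report_schema_version,
                    package = "mediassoc",
                    version = as.character(utils::packageVersion("mediassoc")),
                    timestamp = format(Sys.time(), tz = "UTC",
                                       "%Y-%m-%dT%H:%M:%SZ"),
                    seed = seed, inputs = as.list(inputs)),
    results = results), class = "analysis_report")
}

#' Write an analysis report as deterministic JSON
#'
#' Keys are emitted in a fixed (sorted) order and numbers at full double
#' precision, so identical reports produce byte-identical files (the
#' timestamp is part of the metadata; supply reports built in the same
#' second, or compare the `results` block, when testing byte identity).
#'
#' @param report An [analysis_report()].
#' @param path Output path; `""` writes to stdout.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      x[order(names(x))]
    } else x
  }
  body <- list(metadata = strip(unclass(report$metadata)),
               results = strip(lapply(report$results, function(r)
                 if (is.list(r)) unclass(r) else r)))
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
  if (identical(path, "")) {
    cat(json, "\n")
  } else {
    writeLines(json, path)
  }
  invisible(path)
}

#' Read back an analysis report
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return An `analysis_report`; an unknown schema version is an error.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sv <- obj$metadata$schema_version
  if (is.null(sv) || !identical(sv, report_schema_version))
    stop("unsupported report schema version: ",
         if (is.null(sv)) "<missing>" else sv, call. = FALSE)
  structure(list(metadata = obj$metadata, results = obj$results),
            class = "analysis_report")
}
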