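#' Genotype count table for a single variant and stratum
#'
#' The unit of case-control association analysis: case and control counts
#' indexed by risk-allele dosage (0, 1, 2 copies of the risk allele). Dosage
#' coding is the caller's responsibility — for a variant whose risk allele is
#' the major allele the homozygous-risk genotype is dosage 2 regardless of
#' alphabetical order.
#'
#' @param label Variant identifier (e.g. an rs number).
#' @param cases Integer vector of length 3: case counts at dosage 0, 1, 2.
#' @param controls Integer vector of length 3: control counts at dosage 0, 1, 2.
#' @param risk_allele Risk allele as text (default `"?"`).
#' @param stratum Stratum label, e.g. `"smokers"` or `"never-smokers"`.
#' @return An object of class `genotype_table`.
#' @examples
#' gt <- genotype_table("rs12914385", cases = c(1230, 1973, 815),
#'                      controls = c(373, 413, 121),
#'                      risk_allele = "T", stratum = "smokers")
#' allele_frequencies(gt)
#' @export
genotype_table <- function(label, cases, controls, risk_allele = "?",
                           stratum = "all") {
  cases <- as.numeric(cases)
  controls <- as.numeric(controls)
  if (length(cases) != 3L || length(controls) != 3L)
    stop("'cases' and 'controls' must each give counts at dosage 0, 1, 2",
         call. = FALSE)
  if (anyNA(cases) || anyNA(controls))
    stop("counts must not be missing", call. = FALSE)
  if (any(cases < 0) || any(controls < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(cases != round(cases)) || any(controls != round(controls)))
    stop("counts must be whole numbers", call. = FALSE)
  if (sum(cases) <= 0 || sum(controls) <= 0)
    stop("need at least one case and one control", call. = FALSE)
  structure(
    list(label = as.character(label), cases = cases, controls = controls,
         risk_allele = as.character(risk_allele),
         stratum = as.character(stratum)),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype count table: %s (%s), risk allele %s\n",
              x$label, x$stratum, x$risk_allele))
  m <- rbind(cases = x$cases, controls = x$controls)
  colnames(m) <- paste0("dosage", 0:2)
  print(m)
  invisible(x)
}

#' Risk-allele frequencies of cases and controls
#'
#' Allele-counting frequencies \eqn{(n_1 + 2 n_2) / (2N)} per group.
#'
#' @param table A [genotype_table()].
#' @return A list with `raf_cases` and `raf_controls`, each in \[0, 1\].
#' @export
allele_frequencies <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  raf1 <- function(n) {
    if (sum(n) == 0) stop("empty group: cannot compute allele frequency",
                          call. = FALSE)
    (n[2] + 2 * n[3]) / (2 * sum(n))
  }
  list(raf_cases = raf1(table$cases), raf_controls = raf1(table$controls))
}

#' Read genotype count tables from TSV
#'
#' Expects a tab-separated file with header
#' `label risk_allele stratum cases_0 cases_1 cases_2 controls_0 controls_1
#' controls_2`; one table per row. Malformed rows are reported with their
#' line number.
#'
#' @param path Path to the TSV file.
#' @return A list of [genotype_table()] objects, named `label:stratum`.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("label", "risk_allele", "stratum",
              paste0("cases_", 0:2), paste0("controls_", 0:2))
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("count table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) stop("count table has no rows: ", path, call. = FALSE)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    counts <- suppressWarnings(as.numeric(row[c(paste0("cases_", 0:2),
                                                paste0("controls_", 0:2))]))
    if (anyNA(counts) || any(counts < 0))
      stop(sprintf("invalid counts at line %d (label %s): %s",
                   i + 1L, row$label,
                   paste(unlist(row[4:9]), collapse = ",")), call. = FALSE)
    out[[i]] <- genotype_table(row$label, counts[1:3], counts[4:6],
                               risk_allele = row$risk_allele,
                               stratum = row$stratum)
  }
  names(out) <- vapply(out, function(t) paste(t$label, t$stratum, sep = ":"),
                       character(1))
  out
}

#' Write genotype count tables to TSV
#'
#' Inverse of [read_count_table()].
#'
#' @param tables A list of [genotype_table()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(tables, path) {
  if (inherits(tables, "genotype_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(t)
    data.frame(label = t$label, risk_allele = t$risk_allele,
               stratum = t$stratum,
               cases_0 = t$cases[1], cases_1 = t$cases[2],
               cases_2 = t$cases[3],
               controls_0 = t$controls[1], controls_1 = t$controls[2],
               controls_2 = t$controls[3])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
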