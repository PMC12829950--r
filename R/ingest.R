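# Ingest & QC: dirty-token coercion, median/mode imputation, complete-case
# filtering and z-scoring of raw cohort tables.

default_dirty_tokens <- function() c("/", "empty value", "#DIV/0!", "", "NA", "NaN")

new_cleaning_report <- function(n_in) {
  list(n_rows_in = n_in, n_rows_out = n_in,
       coerced_cells = list(), imputed_cells = list(),
       dropped_rows = data.frame(patient_id = character(0),
                                 reason = character(0)),
       mappings = list())
}

# Map sex / binary-flag strings to {0,1}; returns list(values, mapping).
map_categorical <- function(x, column) {
  lx <- tolower(trimws(x))
  map <- c("0" = 0, "1" = 1, "male" = 0, "female" = 1, "m" = 0, "f" = 1,
           "no" = 0, "yes" = 1, "false" = 0, "true" = 1)
  out <- unname(map[lx])
  used <- unique(lx[!is.na(out) & !is.na(lx)])
  list(values = out,
       mapping = setNames(map[used], used))
}

#' Read a raw cohort table with dirty-token coercion
#'
#' Reads a CSV (UTF-8, comma, header) or XLSX (first worksheet) export and
#' coerces it to a numeric cohort table. In numeric columns every dirty
#' token (`/`, `empty value`, `#DIV/0!`, the empty string, whitespace-only
#' strings, and anything the spreadsheet emitted that is not a number) is
#' converted to `NA`, counted per column per token. Categorical columns
#' (sex and the comorbidity flags) are mapped to \{0, 1\} with the mapping
#' logged. Unknown headers are an error; a numeric cell that survives
#' coercion but is not a number is an error naming the cells.
#'
#' @param path CSV or XLSX file.
#' @param dialect `"csv"` or `"xlsx"`; default inferred from the extension.
#' @param tokens Dirty tokens (in addition to whitespace-only strings).
#' @return List: `table` (cohort data.frame), `report` (cleaning report with
#'   `coerced_cells` counts, categorical `mappings`).
#' @export
parse_raw <- function(path, dialect = NULL, tokens = default_dirty_tokens()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- if (dialect == "xlsx") {
    as.data.frame(readxl::read_excel(path, sheet = 1,
                                     col_types = "text"),
                  stringsAsFactors = FALSE)
  } else {
    read.csv(path, colClasses = "character", check.names = FALSE,
             fileEncoding = "UTF-8")
  }
  known <- cohort_all_columns()
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stopf("unknown column name(s): %s", paste(unknown, collapse = ", "))

  report <- new_cleaning_report(nrow(raw))
  out <- raw
  num_cols <- intersect(c(cohort_numeric_columns(), "cluster"), names(raw))
  cat_cols <- intersect(cohort_binary_columns(), names(raw))

  for (cn in num_cols) {
    cell <- trimws(raw[[cn]])
    is_dirty <- cell %in% tokens | grepl("^\\s*$", cell) | is.na(cell)
    vals <- suppressWarnings(as.numeric(cell))
    residue <- which(!is_dirty & is.na(vals))
    if (length(residue) > 0) {
      # Spreadsheet artifacts (dates, stray text) in numeric columns are
      # treated as dirty tokens too, but counted under their own label.
      is_dirty[residue] <- TRUE
    }
    counts <- table(cell[is_dirty])
    if (length(counts) > 0) {
      names(counts)[names(counts) == ""] <- "<empty>"
      report$coerced_cells[[cn]] <- as.list(counts)
    }
    vals[is_dirty] <- NA_real_
    out[[cn]] <- vals
  }
  for (cn in cat_cols) {
    cell <- trimws(raw[[cn]])
    is_dirty <- cell %in% tokens | grepl("^\\s*$", cell) | is.na(cell)
    m <- map_categorical(cell, cn)
    bad <- which(!is_dirty & is.na(m$values))
    if (length(bad) > 0)
      stopf("column %s: unmappable categorical value(s) in row(s) %s",
            cn, paste(head(bad, 5), collapse = ", "))
    v <- m$values
    v[is_dirty] <- NA_real_
    if (any(is_dirty)) {
      counts <- table(cell[is_dirty])
      names(counts)[names(counts) == ""] <- "<empty>"
      report$coerced_cells[[cn]] <- as.list(counts)
    }
    out[[cn]] <- v
    report$mappings[[cn]] <- m$mapping
  }
  list(table = out, report = report)
}

#' Median/mode imputation
#'
#' Numeric missing values become the column median of observed values
#' (even counts: mean of the two central order statistics); binary/
#' categorical missing values become the mode, ties broken toward the
#' smaller code. Observed values are never changed.
#'
#' @param table Cohort data.frame.
#' @param columns Columns to impute (default: all numeric/binary cohort
#'   columns present).
#' @return List: `table` (no missing left in imputed columns), `report`
#'   (`imputed_cells` count per column).
#' @export
impute <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(c(cohort_numeric_columns(), cohort_binary_columns()),
                         names(table))
  }
  report <- new_cleaning_report(nrow(table))
  for (cn in columns) {
    x <- table[[cn]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) stopf("column %s is entirely missing; cannot impute", cn)
    if (cn %in% cohort_binary_columns() || is_binary(x)) {
      tab <- table(x[!miss])
      # max() over codes achieving the max count, smallest code wins
      best <- names(tab)[tab == max(tab)]
      fill <- as.numeric(min(as.numeric(best)))
    } else {
      fill <- median(x[!miss])
    }
    # keep integer columns integer when the fill value allows it
    if (is.integer(x) && fill == round(fill)) fill <- as.integer(fill)
    x[miss] <- fill
    table[[cn]] <- x
    report$imputed_cells[[cn]] <- sum(miss)
  }
  list(table = table, report = report)
}

#' Complete-case filter on the required analysis columns
#'
#' Removes every row with a missing value in any required column — the
#' analysis-set definition (e.g. 150 collected minus incomplete records =
#' 84 analysed). Applied *before* imputation of the retained set; imputation
#' then only ever touches auxiliary columns.
#'
#' @param table Cohort data.frame.
#' @param required_columns Default: the 25 baseline features plus the two
#'   outcomes ([baseline_columns()] + GWW/GWE), user-overridable.
#' @return List: `table` (retained rows), `report` (dropped ids + reason).
#' @export
complete_case_filter <- function(table,
                                 required_columns = c(baseline_columns(),
                                                      outcome_columns())) {
  missing_cols <- setdiff(required_columns, names(table))
  if (length(missing_cols) > 0)
    stopf("required column(s) absent from table: %s",
          paste(missing_cols, collapse = ", "))
  report <- new_cleaning_report(nrow(table))
  keep <- complete.cases(table[, required_columns, drop = FALSE])
  if (!any(keep)) stopf("complete-case filter removed every row")
  if (any(!keep)) {
    bad <- table[!keep, required_columns, drop = FALSE]
    reason <- apply(bad, 1, function(r)
      paste("missing:", paste(required_columns[is.na(r)], collapse = ",")))
    ids <- if ("patient_id" %in% names(table)) table$patient_id[!keep]
           else as.character(which(!keep))
    report$dropped_rows <- data.frame(patient_id = ids, reason = reason,
                                      stringsAsFactors = FALSE)
  }
  report$n_rows_out <- sum(keep)
  list(table = table[keep, , drop = FALSE], report = report)
}

#' Z-score selected columns
#'
#' Centers and scales with the sample (n-1) standard deviation; the means
#' and sds are returned so the transform can be inverted.
#'
#' @param table Cohort data.frame.
#' @param columns Columns to standardize.
#' @return List: `table`, `means`, `sds`.
#' @export
zscore <- function(table, columns) {
  sds <- vapply(columns, function(cn) sd(table[[cn]]), numeric(1))
  if (any(is.na(sds)) || any(sds <= 0)) {
    bad <- columns[is.na(sds) | sds <= 0]
    stopf("zero-variance or missing column(s): %s", paste(bad, collapse = ", "))
  }
  means <- vapply(columns, function(cn) mean(table[[cn]]), numeric(1))
  for (cn in columns) table[[cn]] <- (table[[cn]] - means[[cn]]) / sds[[cn]]
  list(table = table, means = means, sds = sds)
}

#' Full QC pass: parse, filter, impute
#'
#' Convenience wrapper chaining [parse_raw()], [complete_case_filter()] and
#' [impute()] (imputation restricted to non-required columns), merging the
#' cleaning reports.
#'
#' @inheritParams parse_raw
#' @inheritParams complete_case_filter
#' @return List: `table`, `report`.
#' @export
ingest_qc <- function(path, dialect = NULL,
                      required_columns = c(baseline_columns(),
                                           outcome_columns())) {
  p <- parse_raw(path, dialect)
  f <- complete_case_filter(p$table, required_columns)
  aux <- setdiff(intersect(c(cohort_numeric_columns(), cohort_binary_columns()),
                           names(f$table)), required_columns)
  i <- if (length(aux)) impute(f$table, aux) else list(table = f$table,
                                                       report = new_cleaning_report(nrow(f$table)))
  report <- p$report
  report$n_rows_out <- f$report$n_rows_out
  report$dropped_rows <- f$report$dropped_rows
  report$imputed_cells <- i$report$imputed_cells
  list(table = i$table, report = report)
}
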