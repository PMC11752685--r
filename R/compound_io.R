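# Reading and writing the tabular compound schema.
#
# The input table carries, in exact column order: name, ID, SMILES,
# Doses max, Activity, FUB, and CLint. Binding is BY POSITION - header text
# is ignored - because spreadsheet exports vary in their header spelling.

COMPOUND_COLUMNS <- c("name", "chembl_id", "smiles", "dose_max", "activity",
                      "fub", "clint")

#' Read a compound table
#'
#' Reads a CSV or XLSX file whose first seven columns are, in order:
#' name, ID, SMILES, Doses max (mg/day), Activity (0/1), FUB and CLint
#' (uL/min/1e6 hepatocytes). Columns are bound by position; extra columns
#' are ignored with a warning. Blank cells and "NA"/"NaN" (any case) in
#' Doses max or Activity become absent values. Rows that fail validation
#' (unparseable SMILES, FUB outside (0,1], negative CLint, non-binary
#' Activity, non-positive Doses max) are rejected with a warning naming the
#' row, and reported in the `rejected` attribute.
#'
#' @param path File path.
#' @param format "auto" (by extension), "csv" or "xlsx". XLSX reads the
#'   first sheet.
#' @param header Skip the first row as a header (default TRUE).
#' @return Object of class `compound_table`: a data.frame with columns
#'   name, chembl_id, smiles, dose_max, activity, fub, clint, and
#'   attributes `source` and `rejected` (data.frame of row numbers and
#'   reasons).
#' @examples
#' path <- system.file("extdata", "example_compounds.csv",
#'                     package = "cholmech")
#' read_compound_table(path)
#' @export
read_compound_table <- function(path, format = c("auto", "csv", "xlsx"),
                                header = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xlsx = "xlsx", xls = "xlsx", "csv")
  }
  raw <- if (format == "xlsx") {
    as.data.frame(readxl::read_excel(path, col_names = FALSE,
                                     col_types = "text", sheet = 1))
  } else {
    utils::read.csv(path, header = FALSE, colClasses = "character",
                    check.names = FALSE, fileEncoding = "UTF-8")
  }
  if (header && nrow(raw) >= 1L) raw <- raw[-1L, , drop = FALSE]
  if (ncol(raw) < 7L) {
    stop(sprintf("compound table must have >= 7 columns (found %d)",
                 ncol(raw)))
  }
  if (ncol(raw) > 7L) {
    warning(sprintf("ignoring %d extra column(s) beyond the 7-column schema",
                    ncol(raw) - 7L))
    raw <- raw[, 1:7, drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("compound table has no data rows")
  names(raw) <- COMPOUND_COLUMNS
  build_compound_table(raw, source = path)
}

is_absent <- function(x) {
  is.na(x) | !nzchar(trimws(x)) | tolower(trimws(x)) %in% c("na", "nan")
}

num_or_na <- function(x) {
  out <- rep(NA_real_, length(x))
  keep <- !is_absent(x)
  out[keep] <- suppressWarnings(as.numeric(x[keep]))
  out
}

# Validate raw character columns row by row; returns a compound_table with
# invalid rows dropped and reported.
build_compound_table <- function(raw, source) {
  df <- data.frame(
    name = trimws(raw$name),
    chembl_id = trimws(raw$chembl_id),
    smiles = trimws(raw$smiles),
    dose_max = num_or_na(raw$dose_max),
    activity = num_or_na(raw$activity),
    fub = num_or_na(raw$fub),
    clint = num_or_na(raw$clint),
    stringsAsFactors = FALSE
  )
  reasons <- character(0); bad_rows <- integer(0)
  reject <- function(i, why) {
    bad_rows <<- c(bad_rows, i); reasons <<- c(reasons, why)
  }
  smiles_ok <- is_valid_smiles(df$smiles)
  for (i in seq_len(nrow(df))) {
    if (!smiles_ok[i]) {
      reject(i, sprintf("unparseable SMILES '%s'", df$smiles[i]))
    } else if (is.na(df$fub[i]) || df$fub[i] <= 0 || df$fub[i] > 1) {
      reject(i, sprintf("FUB out of range (0,1]: %s", raw$fub[i]))
    } else if (is.na(df$clint[i]) || df$clint[i] < 0) {
      reject(i, sprintf("CLint must be >= 0: %s", raw$clint[i]))
    } else if (!is.na(df$dose_max[i]) && df$dose_max[i] <= 0) {
      reject(i, sprintf("Doses max must be > 0 when present: %s",
                        raw$dose_max[i]))
    } else if (!is.na(df$activity[i]) && !df$activity[i] %in% c(0, 1)) {
      reject(i, sprintf("Activity must be 0 or 1: %s", raw$activity[i]))
    }
  }
  if (length(bad_rows)) {
    warning(sprintf("rejected %d row(s): %s", length(bad_rows),
                    paste(sprintf("row %d (%s)", bad_rows, reasons),
                          collapse = "; ")))
    df <- df[-bad_rows, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid compound rows remain after validation")
  df$activity <- as.integer(df$activity)
  rownames(df) <- NULL
  structure(df,
            class = c("compound_table", "data.frame"),
            source = source,
            rejected = data.frame(row = bad_rows, reason = reasons,
                                  stringsAsFactors = FALSE))
}

#' Construct a compound table from vectors
#'
#' In-memory constructor applying the same validation as
#' [read_compound_table()].
#'
#' @param name,chembl_id,smiles Character vectors.
#' @param dose_max Therapeutic dose, mg/day, > 0 or NA.
#' @param activity Binary cholestasis label, 0/1 or NA.
#' @param fub Unbound plasma fraction in (0, 1].
#' @param clint Intrinsic clearance, uL/min/1e6 hepatocytes, >= 0.
#' @return `compound_table`.
#' @export
compound_table <- function(name, chembl_id, smiles, dose_max, activity,
                           fub, clint) {
  raw <- data.frame(
    name = as.character(name), chembl_id = as.character(chembl_id),
    smiles = as.character(smiles), dose_max = as.character(dose_max),
    activity = as.character(activity), fub = as.character(fub),
    clint = as.character(clint), stringsAsFactors = FALSE
  )
  build_compound_table(raw, source = "inline")
}

#' Write a compound table in the seven-column CSV schema
#'
#' @param table `compound_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_csv <- function(table, path) {
  out <- as.data.frame(table)[, COMPOUND_COLUMNS]
  names(out) <- c("name", "ID", "SMILES", "Doses max", "Activity", "FUB",
                  "CLint")
  utils::write.csv(format_full_precision(out), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Write predictions to CSV
#'
#' One row per compound: all input fields, one `dose_<transporter>` column
#' per selected transporter with the K-corrected in vivo dose (mg/kg/day),
#' the predicted activity and the ranking score. Numerics are written with
#' full precision so re-reading reproduces them to at least 10 significant
#' digits.
#'
#' @param results `prediction_results` (or the data.frame from
#'   [as.data.frame.prediction_results()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_csv <- function(results, path) {
  df <- if (inherits(results, "prediction_results")) {
    as.data.frame(results)
  } else {
    results
  }
  if (is.null(df) || nrow(df) == 0) stop("no prediction results to write")
  ok <- tryCatch({
    utils::write.csv(format_full_precision(df), path, row.names = FALSE,
                     na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write prediction CSV to '%s'", path))
  invisible(path)
}

format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- df[[j]]
      s <- sprintf("%.15g", v)
      s[is.na(v)] <- NA_character_
      df[[j]] <- s
    }
  }
  df
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("Compound table: %d compound(s) from %s\n", nrow(x),
              attr(x, "source")))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej)) {
    cat(sprintf("  (%d input row(s) rejected)\n", nrow(rej)))
  }
  NextMethod()
}
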