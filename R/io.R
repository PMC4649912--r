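#' Read a long-format CT table from CSV
#'
#' Reads a CSV with one row per (platform, run, sample, miRNA, replicate)
#' qPCR measurement. Arbitrary column names are adapted through `dialect`;
#' CT cells equal to the undetermined sentinel (or empty) become
#' undetermined-flagged measurements (`NA`).
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Optional named character vector mapping canonical column
#'   names (`platform`, `run`, `user`, `sample`, `mirna`, `replicate`, `ct`)
#'   to the column names used in the file, e.g.
#'   `c(mirna = "Assay", ct = "Crt")`. Unmapped canonical names are looked up
#'   verbatim. `user` is optional.
#' @param undetermined_sentinel String marking reactions that never crossed
#'   threshold. Default `"Undetermined"` (vendor export convention); empty
#'   cells are always treated as undetermined.
#' @return A [ct_table].
#' @export
read_ct_table <- function(path, dialect = NULL,
                          undetermined_sentinel = "Undetermined") {
  if (!file.exists(path)) stop("read_ct_table: file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  canonical <- c("platform", "run", "user", "sample", "mirna", "replicate", "ct")
  resolve <- function(name) {
    if (!is.null(dialect) && name %in% names(dialect)) dialect[[name]] else name
  }
  required <- setdiff(canonical, "user")
  for (name in required) {
    if (!resolve(name) %in% names(raw)) {
      stop("read_ct_table: required column '", resolve(name),
           "' (", name, ") not found in ", path, call. = FALSE)
    }
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    platform = raw[[resolve("platform")]],
                    run = raw[[resolve("run")]],
                    sample = raw[[resolve("sample")]],
                    mirna = raw[[resolve("mirna")]],
                    replicate = raw[[resolve("replicate")]])
  out$user <- if (resolve("user") %in% names(raw)) {
    raw[[resolve("user")]]
  } else NA_character_
  ct_raw <- raw[[resolve("ct")]]
  und <- ct_raw == undetermined_sentinel | ct_raw == ""
  ct <- rep(NA_real_, length(ct_raw))
  parsed <- suppressWarnings(as.numeric(ct_raw[!und]))
  if (anyNA(parsed)) {
    bad <- which(!und)[which(is.na(parsed))]
    stop("read_ct_table: non-numeric CT value(s) other than the sentinel at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ct[!und] <- parsed
  out$ct <- ct
  ct_table(out)
}

#' Write a CT table to CSV
#'
#' Inverse of [read_ct_table()]: undetermined measurements are written as the
#' sentinel string. Round-tripping preserves identifiers exactly and CT
#' values to full double precision.
#'
#' @param table A [ct_table].
#' @param path Output CSV path.
#' @inheritParams read_ct_table
#' @export
write_ct_table <- function(table, path,
                           undetermined_sentinel = "Undetermined") {
  stopifnot(inherits(table, "ct_table"))
  df <- as.data.frame(table)
  df$ct <- ifelse(is.na(df$ct), undetermined_sentinel,
                  format(df$ct, digits = 15, trim = TRUE, scientific = FALSE))
  write_report(df, path)
  invisible(path)
}

#' Write an analysis report as a flat CSV
#'
#' Works for any of the package's tabular reports (fidelity, concordance,
#' replicate statistics, ...). Numeric columns survive a write/read
#' round trip to at least 6 significant digits.
#'
#' @param report A data.frame (or object coercible to one).
#' @param path Output CSV path.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_report: cannot write to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
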