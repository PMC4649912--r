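#' Construct a CT table
#'
#' A CT table is the canonical long-format container for raw qPCR cycle
#' threshold (CT/CRT) measurements: one row per
#' (platform, run, sample, miRNA, replicate). Reactions that never crossed
#' the detection threshold ("Undetermined" in vendor exports) are stored as
#' `NA` in the `ct` column; [is_undetermined()] exposes the flag.
#'
#' @param df A data.frame with columns `platform`, `run`, `sample`, `mirna`,
#'   `replicate`, `ct`, and optionally `user`. `replicate` must be a positive
#'   integer index; `ct` must be a positive finite number or `NA`
#'   (undetermined).
#' @return An object of class `ct_table` (a data.frame).
#' @examples
#' tab <- ct_table(data.frame(
#'   platform = "ViiA7", run = "run1", sample = "S1", mirna = "miR-16",
#'   replicate = 1:2, ct = c(18.2, 18.4)
#' ))
#' platforms(tab)
#' @export
ct_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("platform", "run", "sample", "mirna", "replicate", "ct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("ct_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"user" %in% names(df)) df$user <- rep(NA_character_, nrow(df))
  df <- df[, c("platform", "run", "user", "sample", "mirna", "replicate", "ct")]
  for (col in c("platform", "run", "user", "sample", "mirna")) {
    df[[col]] <- as.character(df[[col]])
  }
  rep_num <- suppressWarnings(as.numeric(df$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num))) {
    stop("ct_table: 'replicate' must be a positive integer index", call. = FALSE)
  }
  df$replicate <- as.integer(rep_num)
  df$ct <- as.numeric(df$ct)
  bad_ct <- !is.na(df$ct) & (!is.finite(df$ct) | df$ct <= 0)
  if (any(bad_ct)) {
    stop("ct_table: ct values must be positive and finite (or NA for undetermined); ",
         "offending row(s): ", paste(which(bad_ct), collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(df$platform, df$run, df$sample, df$mirna, df$replicate,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("ct_table: duplicate (platform, run, sample, mirna, replicate) key; ",
         "offending row(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("ct_table", "data.frame"))
}

#' @rdname ct_table
#' @param x A `ct_table`.
#' @export
platforms <- function(x) sort(unique(x$platform))

#' @rdname ct_table
#' @export
mirnas <- function(x) sort(unique(x$mirna))

#' @rdname ct_table
#' @export
samples <- function(x) sort(unique(x$sample))

#' @rdname ct_table
#' @export
is_undetermined <- function(x) {
  if (inherits(x, "ct_table")) is.na(x$ct) else is.na(x)
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf(
    "ct_table: %d measurements | %d platform(s), %d sample(s), %d miRNA(s), %d undetermined\n",
    nrow(x), length(platforms(x)), length(samples(x)), length(mirnas(x)),
    sum(is.na(x$ct))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

# Collapse replicates to one mean CT per (platform, sample, mirna) cell,
# pooling runs; undetermined replicates are excluded. Cells with no
# determined replicate get NA.
cell_means <- function(table, per_run = FALSE) {
  stopifnot(inherits(table, "ct_table"))
  keys <- c("platform", if (per_run) "run", "sample", "mirna")
  grp <- interaction(table[keys], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(table)), grp)
  out <- do.call(rbind, lapply(idx, function(i) {
    ct <- table$ct[i]
    det <- ct[!is.na(ct)]
    cbind(table[i[1L], keys, drop = FALSE],
          data.frame(n = length(ct), n_determined = length(det),
                     mean_ct = if (length(det)) mean(det) else NA_real_))
  }))
  rownames(out) <- NULL
  out
}
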