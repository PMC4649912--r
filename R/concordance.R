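#' Z-score CT values within each platform
#'
#' Raw CT/CRT values cannot be compared directly across platforms (different
#' chemistries, pre-amplification and dilution shift the whole scale), so
#' each platform is standardised to z-scores. Replicate CTs are first
#' collapsed to the group mean per (platform, sample, miRNA), pooling runs;
#' only cells determined on every compared platform are retained
#' (pairwise-complete matching), and z = (ct - platform mean) / platform sd
#' over those matched cells.
#'
#' @param table A [ct_table].
#' @param platforms Platforms to standardise and match; default all platforms
#'   in the table.
#' @return A data.frame of class `zscore_table` with columns `platform`,
#'   `sample`, `mirna`, `mean_ct`, `z`. Within each platform the z values
#'   have mean 0 and (sample) sd 1.
#' @export
platform_zscores <- function(table, platforms = NULL) {
  stopifnot(inherits(table, "ct_table"))
  if (is.null(platforms)) platforms <- sort(unique(table$platform))
  missing_pf <- setdiff(platforms, unique(table$platform))
  if (length(missing_pf) > 0L) {
    stop("platform_zscores: platform(s) not in table: ",
         paste(missing_pf, collapse = ", "), call. = FALSE)
  }
  cm <- cell_means(table[table$platform %in% platforms, , drop = FALSE])
  cm <- cm[!is.na(cm$mean_ct), , drop = FALSE]
  # keep only (sample, mirna) cells determined on all compared platforms
  cell <- paste(cm$sample, cm$mirna, sep = "\r")
  counts <- table(cell)
  matched <- names(counts)[counts == length(platforms)]
  cm <- cm[cell %in% matched, , drop = FALSE]
  n_cells <- length(matched)
  if (n_cells < 3L) {
    stop("platform_zscores: fewer than 3 matched (sample, miRNA) cells ",
         "determined on all compared platforms", call. = FALSE)
  }
  cm$z <- NA_real_
  for (pf in platforms) {
    i <- cm$platform == pf
    s <- stats::sd(cm$mean_ct[i])
    if (!is.finite(s) || s == 0) {
      stop("platform_zscores: platform '", pf,
           "' has zero variance across matched cells", call. = FALSE)
    }
    cm$z[i] <- (cm$mean_ct[i] - mean(cm$mean_ct[i])) / s
  }
  out <- cm[, c("platform", "sample", "mirna", "mean_ct", "z")]
  rownames(out) <- NULL
  structure(out, class = c("zscore_table", "data.frame"),
            platforms = platforms)
}

#' Pairwise cross-platform concordance on the z-score scale
#'
#' Ordinary least-squares regression of the comparison platform's z-scores
#' (y) on the reference platform's (x), plus Pearson correlation. A slope
#' below the ideal value of 1 indicates dynamic-range compression on the
#' comparison platform relative to the reference; above 1, expansion.
#'
#' @param z A `zscore_table` from [platform_zscores()].
#' @param reference Reference ("gold standard") platform id, plotted on x.
#' @param other Comparison platform id, plotted on y.
#' @return A one-row data.frame of class `concordance_stats`: `reference`,
#'   `platform`, `n_pairs`, `pearson_r`, `r_squared`, `slope`, `intercept`.
#' @export
pairwise_concordance <- function(z, reference, other) {
  stopifnot(inherits(z, "zscore_table"))
  for (pf in c(reference, other)) {
    if (!pf %in% z$platform) {
      stop("pairwise_concordance: platform '", pf, "' not in z-score table",
           call. = FALSE)
    }
  }
  a <- z[z$platform == reference, c("sample", "mirna", "z")]
  b <- z[z$platform == other, c("sample", "mirna", "z")]
  m <- merge(a, b, by = c("sample", "mirna"), suffixes = c("_ref", "_oth"))
  if (nrow(m) < 3L) {
    stop("pairwise_concordance: fewer than 3 matched z pairs", call. = FALSE)
  }
  x <- m$z_ref; y <- m$z_oth
  if (stats::var(x) == 0) {
    stop("pairwise_concordance: reference platform has zero variance",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  out <- data.frame(reference = reference, platform = other,
                    n_pairs = nrow(m), pearson_r = r, r_squared = r^2,
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]))
  structure(out, class = c("concordance_stats", "data.frame"))
}

#' All pairwise concordances against one reference platform
#'
#' Convenience wrapper: for each comparison platform, z-scores are computed
#' pairwise-complete for that (reference, comparison) pair and the
#' concordance statistics collected into one table.
#'
#' @inheritParams platform_zscores
#' @param reference Reference platform id.
#' @param others Comparison platforms; default all non-reference platforms.
#' @return A data.frame with one row per comparison platform.
#' @export
concordance_table <- function(table, reference, others = NULL) {
  stopifnot(inherits(table, "ct_table"))
  if (!reference %in% table$platform) {
    stop("concordance_table: reference platform '", reference,
         "' not in table", call. = FALSE)
  }
  if (is.null(others)) others <- setdiff(sort(unique(table$platform)), reference)
  res <- lapply(others, function(pf) {
    z <- platform_zscores(table, platforms = c(reference, pf))
    pairwise_concordance(z, reference, pf)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
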