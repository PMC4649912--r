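#' Replicate-level summary statistics
#'
#' Summarises each replicate group — by default one group per
#' (platform, run, sample, miRNA) — with mean CT, standard deviation
#' (sample, n-1 denominator), coefficient of variation on the CT scale
#' (CV% = 100 * sd / mean), replicate range (max - min) and expression tier
#' of the group mean. Undetermined replicates are excluded from the
#' statistics; groups left with fewer than two determined values are
#' returned with `sd_ct`/`cv_pct`/`range_ct` of `NA` and `flagged = TRUE`.
#'
#' @param table A [ct_table].
#' @param pool_runs If `TRUE`, replicates from all runs of a platform are
#'   pooled into one group per (platform, sample, miRNA); the default keeps
#'   runs separate, since within-run fidelity and across-run reproducibility
#'   are distinct questions.
#' @return A data.frame with one row per replicate group.
#' @export
replicate_stats <- function(table, pool_runs = FALSE) {
  stopifnot(inherits(table, "ct_table"))
  keys <- c("platform", if (!pool_runs) "run", "sample", "mirna")
  if (nrow(table) == 0L) {
    out <- table[0, keys, drop = FALSE]
    out$n <- integer(); out$n_determined <- integer()
    out$mean_ct <- out$sd_ct <- out$cv_pct <- out$range_ct <- numeric()
    out$tier <- character(); out$flagged <- logical()
    return(out)
  }
  grp <- interaction(table[keys], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(table)), grp)
  out <- do.call(rbind, lapply(idx, function(i) {
    ct <- table$ct[i]
    det <- ct[!is.na(ct)]
    rec <- table[i[1L], keys, drop = FALSE]
    rec$n <- length(ct)
    rec$n_determined <- length(det)
    if (length(det) >= 2L) {
      rec$mean_ct <- mean(det)
      rec$sd_ct <- stats::sd(det)
      rec$cv_pct <- 100 * rec$sd_ct / rec$mean_ct
      rec$range_ct <- max(det) - min(det)
      rec$flagged <- FALSE
    } else {
      rec$mean_ct <- if (length(det) == 1L) det else NA_real_
      rec$sd_ct <- rec$cv_pct <- rec$range_ct <- NA_real_
      rec$flagged <- TRUE
    }
    rec$tier <- if (is.na(rec$mean_ct)) NA_character_ else
      as.character(assign_tier(rec$mean_ct))
    rec
  }))
  rownames(out) <- NULL
  out
}

#' Expression tier of a CT value
#'
#' Bins CT values into abundance tiers: ultra-high (< 10 cycles),
#' high (10 to 20), moderate (above 20 up to 30) and low (> 30). Lower CT
#' means more template, so "ultra_high" is the most abundant tier. The
#' half-open boundaries close the hundredth-of-a-cycle gaps left by the
#' conventional printed intervals (10.01-20.00, 20.01-30.00).
#'
#' @param ct Numeric vector of determined CT values (finite, > 0).
#' @return A factor with levels `ultra_high`, `high`, `moderate`, `low`.
#' @examples
#' assign_tier(c(5, 20, 20.005, 35))
#' @export
assign_tier <- function(ct) {
  if (anyNA(ct)) {
    stop("assign_tier: undetermined (NA) CT values cannot be tiered; ",
         "filter or impute first", call. = FALSE)
  }
  if (any(!is.finite(ct) | ct <= 0)) {
    stop("assign_tier: CT values must be finite and > 0", call. = FALSE)
  }
  levels <- c("ultra_high", "high", "moderate", "low")
  tier <- ifelse(ct < 10, "ultra_high",
          ifelse(ct <= 20, "high",
          ifelse(ct <= 30, "moderate", "low")))
  factor(tier, levels = levels)
}

#' Fidelity scoring of replicate groups
#'
#' Fidelity at a cutoff c is the percentage of replicate groups whose CT
#' range (max - min) is strictly below c cycles; "deviation from fidelity"
#' is its complement. A 3-cycle spread between replicates corresponds to
#' roughly an 8-fold difference in apparent transcript abundance, so the
#' default cutoffs of 1, 2 and 3 cycles grade platforms from strict to
#' permissive.
#'
#' @inheritParams replicate_stats
#' @param cutoffs Cycle thresholds; default `c(1, 2, 3)`.
#' @param undetermined_policy How to score groups that contain an
#'   undetermined replicate: `"fail_all"` (default) counts such a group as
#'   exceeding every cutoff — a dropout is a worse-than-8-fold discordance —
#'   while `"exclude"` drops undetermined values and scores the remaining
#'   replicates if at least two are determined.
#' @return A data.frame with columns `platform`, `cutoff`, `n_groups`,
#'   `fidelity_pct`, `deviation_pct`. Platforms with no scorable group are
#'   omitted with a warning.
#' @export
fidelity_report <- function(table, cutoffs = c(1, 2, 3),
                            undetermined_policy = c("fail_all", "exclude"),
                            pool_runs = FALSE) {
  stopifnot(inherits(table, "ct_table"), all(cutoffs > 0))
  undetermined_policy <- match.arg(undetermined_policy)
  keys <- c("platform", if (!pool_runs) "run", "sample", "mirna")
  grp <- interaction(table[keys], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(table)), grp)
  groups <- do.call(rbind, lapply(idx, function(i) {
    ct <- table$ct[i]
    det <- ct[!is.na(ct)]
    has_und <- anyNA(ct)
    if (undetermined_policy == "fail_all") {
      scorable <- length(ct) >= 2L
      rng <- if (has_und) Inf else if (length(det) >= 2L) max(det) - min(det) else Inf
    } else {
      scorable <- length(det) >= 2L
      rng <- if (scorable) max(det) - min(det) else NA_real_
    }
    data.frame(platform = table$platform[i[1L]], scorable = scorable,
               range_ct = rng)
  }))
  out <- list()
  omitted <- character()
  for (pf in sort(unique(groups$platform))) {
    g <- groups[groups$platform == pf & groups$scorable, , drop = FALSE]
    if (nrow(g) == 0L) {
      omitted <- c(omitted, pf)
      next
    }
    out[[pf]] <- data.frame(
      platform = pf, cutoff = cutoffs, n_groups = nrow(g),
      fidelity_pct = vapply(cutoffs,
                            function(cc) 100 * mean(g$range_ct < cc),
                            numeric(1)))
  }
  if (length(omitted) > 0L) {
    warning("fidelity_report: no scorable replicate group for platform(s) ",
            paste(omitted, collapse = ", "), "; omitted", call. = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(platform = character(), cutoff = numeric(),
                      n_groups = integer(), fidelity_pct = numeric(),
                      deviation_pct = numeric()))
  }
  res <- do.call(rbind, out)
  res$deviation_pct <- 100 - res$fidelity_pct
  rownames(res) <- NULL
  res
}

#' Convert a CT difference to a fold change
#'
#' Under ideal (efficiency 1) amplification each cycle is a doubling, so a
#' difference of `delta_ct` cycles corresponds to `2^delta_ct`-fold
#' difference in template abundance; 3 cycles is ~8-fold.
#'
#' @param delta_ct CT difference in cycles (finite numeric).
#' @return `2^delta_ct`, dimensionless.
#' @export
fold_change <- function(delta_ct) {
  if (any(!is.finite(delta_ct))) {
    stop("fold_change: delta_ct must be finite", call. = FALSE)
  }
  2^delta_ct
}

#' Replicate variation stratified by expression tier
#'
#' Bins replicate groups by the expression tier of their mean CT and
#' summarises the replicate range within each (platform, tier) cell:
#' low-abundance tiers are where Poisson partitioning of scarce template
#' copies inflates replicate scatter, especially at nanoliter volumes.
#'
#' @inheritParams replicate_stats
#' @return A data.frame with one row per (platform, tier): `n`, `median`,
#'   `q1`, `q3`, `min`, `max` of `range_ct`. Empty cells have `n = 0` and
#'   `NA` summaries.
#' @export
tiered_variation <- function(table, pool_runs = FALSE) {
  rs <- replicate_stats(table, pool_runs = pool_runs)
  rs <- rs[!rs$flagged & !is.na(rs$tier), , drop = FALSE]
  tiers <- c("ultra_high", "high", "moderate", "low")
  pfs <- sort(unique(rs$platform))
  out <- expand.grid(platform = pfs, tier = tiers,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_cols <- t(mapply(function(pf, tr) {
    v <- rs$range_ct[rs$platform == pf & rs$tier == tr]
    if (length(v) == 0L) return(c(n = 0, median = NA, q1 = NA, q3 = NA,
                                  min = NA, max = NA))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
      min = min(v), max = max(v))
  }, out$platform, out$tier))
  cbind(out, as.data.frame(stats_cols))
}

#' Inter-run reproducibility
#'
#' For each (platform, miRNA) present in both runs, averages over shared
#' samples the difference between the run-mean CTs: `mean_abs_diff` is the
#' mean of |mean CT in run_a - mean CT in run_b| and `mean_signed_diff`
#' retains the sign (run_a minus run_b) to expose systematic shifts between
#' repeats.
#'
#' @inheritParams replicate_stats
#' @param run_a,run_b Run identifiers to compare.
#' @param sample_class Optional named character vector mapping sample ids to
#'   a class (e.g. cellular vs serum); when given, results are additionally
#'   stratified by class.
#' @return A data.frame with columns `platform`, `mirna` (and `class`),
#'   `n_samples`, `mean_abs_diff`, `mean_signed_diff`. miRNAs with no shared
#'   determined sample in both runs are omitted with a warning.
#' @export
inter_run_difference <- function(table, run_a, run_b, sample_class = NULL) {
  stopifnot(inherits(table, "ct_table"))
  runs <- unique(table$run)
  if (!all(c(run_a, run_b) %in% runs)) {
    stop("inter_run_difference: run '",
         setdiff(c(run_a, run_b), runs)[1], "' not present", call. = FALSE)
  }
  cm <- cell_means(table[table$run %in% c(run_a, run_b), , drop = FALSE],
                   per_run = TRUE)
  cm <- cm[!is.na(cm$mean_ct), , drop = FALSE]
  cm$class <- if (is.null(sample_class)) "all" else
    unname(sample_class[cm$sample])
  a <- cm[cm$run == run_a, ]
  b <- cm[cm$run == run_b, ]
  m <- merge(a, b, by = c("platform", "mirna", "sample", "class"),
             suffixes = c("_a", "_b"))
  all_keys <- unique(cm[, c("platform", "mirna")])
  grp <- interaction(m$platform, m$mirna, m$class, drop = TRUE)
  idx <- split(seq_len(nrow(m)), grp)
  out <- do.call(rbind, lapply(idx, function(i) {
    d <- m$mean_ct_a[i] - m$mean_ct_b[i]
    data.frame(platform = m$platform[i[1]], mirna = m$mirna[i[1]],
               class = m$class[i[1]], n_samples = length(d),
               mean_abs_diff = mean(abs(d)), mean_signed_diff = mean(d))
  }))
  shared <- unique(m[, c("platform", "mirna")])
  dropped <- nrow(merge(all_keys, shared, all.x = TRUE)) - nrow(shared)
  missing_keys <- !paste(all_keys$platform, all_keys$mirna) %in%
    paste(shared$platform, shared$mirna)
  if (any(missing_keys)) {
    warning("inter_run_difference: omitted (platform, miRNA) with no shared ",
            "determined sample in both runs: ",
            paste(all_keys$mirna[missing_keys], collapse = ", "),
            call. = FALSE)
  }
  if (is.null(sample_class)) out$class <- NULL
  rownames(out) <- NULL
  out
}
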