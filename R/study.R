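#' Configure a full platform-comparison study
#'
#' @param table A [ct_table] to analyse, or `NULL` to simulate one.
#' @param sim A [simulation_config()] used when `table` is `NULL`; default
#'   the packaged study conditions with the given `seed`.
#' @param reference Reference ("gold standard") platform id.
#' @param cutoffs Fidelity cutoffs, cycles.
#' @param mojena_const Mojena stopping-rule constant.
#' @param missing_threshold Missingness filter for clustering.
#' @param panel Optional ordered signature panel (>= 3 miRNA ids).
#' @param out_dir Optional output directory; when given, every report is
#'   written as CSV plus a machine-readable `summary.json`.
#' @param seed Master seed (drives the simulation when `table` is `NULL`).
#' @return A list of class `study_config`.
#' @export
study_config <- function(table = NULL, sim = NULL, reference = "ViiA7",
                         cutoffs = c(1, 2, 3), mojena_const = 1.25,
                         missing_threshold = 0.15, panel = NULL,
                         out_dir = NULL, seed = 1) {
  if (is.null(table) && is.null(sim)) sim <- simulation_config(seed = seed)
  structure(list(table = table, sim = sim, reference = reference,
                 cutoffs = cutoffs, mojena_const = mojena_const,
                 missing_threshold = missing_threshold, panel = panel,
                 out_dir = out_dir, seed = seed),
            class = "study_config")
}

#' Run the full cross-platform comparison study
#'
#' Orchestrates the pipeline: obtain a CT table (simulated or provided),
#' replicate variability and fidelity scoring, tier-stratified variation,
#' inter-run reproducibility, z-score concordance against the reference
#' platform, per-platform clustering with cluster concordance, and — when a
#' panel is supplied — signature profile comparison. Deterministic given the
#' seed.
#'
#' @param config A [study_config()].
#' @return A list of class `study_bundle` with elements `table`,
#'   `replicate_stats`, `fidelity`, `tiered_variation`, `inter_run`,
#'   `concordance`, `clusters`, `cluster_concordance`, `signature`,
#'   `summary` (the flat machine-readable summary). Written to
#'   `config$out_dir` when set.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  table <- config$table
  sim <- NULL
  if (is.null(table)) {
    sim <- config$sim
    sim$seed <- as.integer(config$seed)
    sim_out <- simulate_study(sim)
    table <- sim_out$table
  }
  if (!config$reference %in% table$platform) {
    stop("run_study: reference platform '", config$reference,
         "' absent from the data", call. = FALSE)
  }

  rs <- replicate_stats(table)
  fid <- fidelity_report(table, cutoffs = config$cutoffs)
  tiers <- tiered_variation(table)
  runs <- sort(unique(table$run))
  inter_run <- if (length(runs) >= 2L) {
    inter_run_difference(table, runs[1], runs[2])
  } else NULL

  conc <- concordance_table(table, config$reference)

  pfs <- sort(unique(table$platform))
  clusters <- lapply(pfs, function(pf) {
    cluster_platform(table, pf, missing_threshold = config$missing_threshold,
                     k_const = config$mojena_const)
  })
  names(clusters) <- pfs
  others <- setdiff(pfs, config$reference)
  cc <- lapply(others, function(pf) {
    cluster_concordance(clusters[[config$reference]], clusters[[pf]])
  })
  names(cc) <- others

  signature <- NULL
  if (!is.null(config$panel)) {
    signature <- list()
    for (smp in sort(unique(table$sample))) {
      ref_prof <- extract_signature(table, config$panel, config$reference, smp)
      signature[[smp]] <- lapply(others, function(pf) {
        compare_profiles(extract_signature(table, config$panel, pf, smp),
                         ref_prof)
      })
      names(signature[[smp]]) <- others
    }
  }

  median_cv <- vapply(pfs, function(pf) {
    stats::median(rs$cv_pct[rs$platform == pf & !rs$flagged], na.rm = TRUE)
  }, numeric(1))
  summary <- list(
    seed = config$seed,
    reference = config$reference,
    n_measurements = nrow(table),
    platforms = pfs,
    median_cv_pct = as.list(median_cv),
    fidelity = fid,
    concordance = conc,
    mojena_k = lapply(clusters, function(x) x$k),
    misassigned_pct = lapply(cc, function(x) x$misassigned_pct)
  )

  bundle <- structure(list(table = table, truth = if (!is.null(sim)) sim_out$truth,
                           replicate_stats = rs, fidelity = fid,
                           tiered_variation = tiers, inter_run = inter_run,
                           concordance = conc, clusters = clusters,
                           cluster_concordance = cc, signature = signature,
                           summary = summary),
                      class = "study_bundle")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ct_table(table, file.path(config$out_dir, "ct_table.csv"))
    write_report(rs, file.path(config$out_dir, "replicate_stats.csv"))
    write_report(fid, file.path(config$out_dir, "fidelity.csv"))
    write_report(tiers, file.path(config$out_dir, "tiered_variation.csv"))
    if (!is.null(inter_run)) {
      write_report(inter_run, file.path(config$out_dir, "inter_run.csv"))
    }
    write_report(conc, file.path(config$out_dir, "concordance.csv"))
    assign_df <- do.call(rbind, lapply(clusters, function(x) {
      data.frame(platform = x$platform, mirna = names(x$assignment),
                 cluster = unname(x$assignment), k = x$k)
    }))
    write_report(assign_df, file.path(config$out_dir, "clusters.csv"))
    cc_df <- do.call(rbind, lapply(cc, function(x) {
      data.frame(reference = x$reference_platform,
                 platform = x$comparison_platform,
                 n_shared = x$n_shared, misassigned_pct = x$misassigned_pct)
    }))
    write_report(cc_df, file.path(config$out_dir, "cluster_concordance.csv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  bundle
}
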