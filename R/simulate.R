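#' Poisson probability mass function for template copy counts
#'
#' At limiting dilution the number of template copies landing in a reaction
#' is Poisson-distributed with mean proportional to the reaction volume.
#' With an average of one copy per reaction, ~37% of reactions receive no
#' template at all (stochastic dropout), ~37% one copy and ~18% two.
#'
#' @param k Non-negative integer copy count(s).
#' @param lam Mean copies per reaction (>= 0).
#' @return `P(K = k)` for `K ~ Poisson(lam)`.
#' @examples
#' round(100 * poisson_pmf(0:2, 1))  # 37, 37, 18
#' @export
poisson_pmf <- function(k, lam) {
  if (any(k < 0) || any(k != round(k))) {
    stop("poisson_pmf: k must be a non-negative integer", call. = FALSE)
  }
  if (any(lam < 0)) stop("poisson_pmf: lam must be >= 0", call. = FALSE)
  stats::dpois(k, lam)
}

#' Simulate Poisson partitioning of template copies into reactions
#'
#' Independent `Poisson(lam)` draws, one per reaction, reproducible under
#' the seed. For a platform, `lam = concentration * reaction_volume /
#' dilution_factor`.
#'
#' @param lam Mean copies per reaction (>= 0).
#' @param n_rxn Number of reactions (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of copy counts, length `n_rxn`.
#' @export
simulate_copy_partition <- function(lam, n_rxn, seed) {
  stopifnot(lam >= 0, n_rxn >= 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  stats::rpois(n_rxn, lam)
}

#' Define a qPCR platform for simulation
#'
#' Captures the physics that differ between platforms: reaction volume,
#' pre-amplification cycles, post-pre-amp dilution, amplification
#' efficiency, and the platform's intrinsic cycle noise.
#'
#' @param name Platform identifier.
#' @param reaction_volume Reaction volume in liters (> 0).
#' @param preamp_cycles Pre-amplification cycles (non-negative integer).
#' @param dilution_factor Post-pre-amp dilution (>= 1; 40 means 1:40).
#' @param noise_sd Gaussian CT noise, cycles (>= 0).
#' @param efficiency Per-cycle amplification efficiency in (0, 1]; 1 is a
#'   perfect doubling per cycle.
#' @return A list of class `platform_spec`.
#' @export
platform_spec <- function(name, reaction_volume, preamp_cycles,
                          dilution_factor, noise_sd, efficiency = 0.95) {
  stopifnot(reaction_volume > 0, dilution_factor >= 1,
            preamp_cycles >= 0, preamp_cycles == round(preamp_cycles),
            noise_sd >= 0, efficiency > 0, efficiency <= 1)
  structure(list(name = name, reaction_volume = reaction_volume,
                 preamp_cycles = as.integer(preamp_cycles),
                 dilution_factor = dilution_factor,
                 noise_sd = noise_sd, efficiency = efficiency),
            class = "platform_spec")
}

#' Default four-platform roster
#'
#' The study conditions emulated by the simulator: a 5 µl 96-well platform
#' (ViiA7), a 1 µl microfluidic card (TLDA), a 33 nl through-hole array (OA)
#' and a 15 nl integrated fluidic circuit (DA). Pre-amplification is 12
#' cycles with 1:40 dilution except the DA protocol (16 cycles, 1:10).
#' Noise standard deviations (0.10 / 1.10 / 0.33 / 1.15 cycles) reflect the
#' observed ordering of replicate CV across these platform classes: tightest
#' on the 96-well format, loosest on the 15 nl circuit.
#'
#' @return A named list of [platform_spec()] objects.
#' @export
default_platforms <- function() {
  list(
    ViiA7 = platform_spec("ViiA7", 5e-6,  12, 40, noise_sd = 0.10),
    TLDA  = platform_spec("TLDA",  1e-6,  12, 40, noise_sd = 1.10),
    OA    = platform_spec("OA",    33e-9, 12, 40, noise_sd = 0.33),
    DA    = platform_spec("DA",    15e-9, 16, 10, noise_sd = 1.15)
  )
}

#' Default ground-truth abundance profile
#'
#' 42 miRNAs (including 3 housekeeping controls) across 4 samples (2
#' cellular, 2 serum), organised in four abundance/pattern groups so the
#' clustering pipeline has a planted structure to recover:
#' cellular-enriched, serum-enriched, ubiquitously high (housekeeping-like)
#' and uniformly low-abundance. Concentrations are copies per liter of
#' undiluted template stock; per-miRNA abundances are log-spaced within each
#' group with reproducible lognormal jitter.
#'
#' @param seed Integer seed for the jitter.
#' @return A data.frame of class `truth_profile` with columns `sample`,
#'   `mirna`, `concentration`, `group`, `sample_class`.
#' @export
default_truth_profile <- function(seed = 20150602) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed %% .Machine$integer.max)
  samples <- c(cell_A = "cellular", cell_B = "cellular",
               serum_A = "serum", serum_B = "serum")
  groups <- list(
    cellular_enriched = list(n = 11, lam_range = c(1e3, 1e5),
                             offsets = c(2.5, 2.5, -2.5, -2.5)),
    serum_enriched    = list(n = 11, lam_range = c(1e3, 1e5),
                             offsets = c(-2.5, -2.5, 2.5, 2.5)),
    ubiquitous_high   = list(n = 10, lam_range = c(1e6, 1e8),
                             offsets = c(0, 0, 0, 0)),
    low_abundance     = list(n = 10, lam_range = c(8, 600),
                             offsets = c(0, 0, 0, 0))
  )
  # lambda on the 5 µl / 1:40 reference platform; convert to copies/L stock
  ref_factor <- 5e-6 / 40
  rows <- list()
  idx <- 0L
  for (g in names(groups)) {
    spec <- groups[[g]]
    base_lam <- 10^seq(log10(spec$lam_range[1]), log10(spec$lam_range[2]),
                       length.out = spec$n)
    base_lam <- base_lam * 2^stats::rnorm(spec$n, 0, 0.4)
    for (j in seq_len(spec$n)) {
      idx <- idx + 1L
      mir <- if (g == "ubiquitous_high" && j <= 3) {
        c("U6", "RNU44", "RNU48")[j]
      } else sprintf("miR-%03d", idx)
      lam_per_sample <- base_lam[j] * 2^spec$offsets
      rows[[length(rows) + 1L]] <- data.frame(
        sample = names(samples), mirna = mir,
        concentration = lam_per_sample / ref_factor,
        group = g, sample_class = unname(samples))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("truth_profile", "data.frame"))
}

#' Assemble a simulation configuration
#'
#' @param platforms Named list of [platform_spec()]s.
#' @param truth A `truth_profile` data.frame (`sample`, `mirna`,
#'   `concentration` in copies/L of template stock).
#' @param replicates Replicates per (platform, run, sample, miRNA).
#' @param runs Number of runs (each run gets its own Gaussian CT offset per
#'   platform, emulating run-to-run shifts).
#' @param run_shift_sd SD of the per-(platform, run) CT offset, cycles.
#' @param ct_one_copy CT at which a single effective (post-pre-amp) template
#'   copy crosses threshold, cycles.
#' @param max_cycles Detection limit; reactions crossing later are reported
#'   undetermined.
#' @param seed Master seed; all randomness (partition, noise, run shifts)
#'   flows from it through named substreams.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(platforms = default_platforms(),
                              truth = default_truth_profile(),
                              replicates = 4, runs = 2,
                              run_shift_sd = 0.5,
                              ct_one_copy = 44, max_cycles = 40,
                              seed = 1) {
  stopifnot(length(platforms) >= 1, replicates >= 1, runs >= 1,
            run_shift_sd >= 0, max_cycles > 0, ct_one_copy > 0,
            all(c("sample", "mirna", "concentration") %in% names(truth)),
            all(truth$concentration >= 0))
  structure(list(platforms = platforms, truth = truth,
                 replicates = as.integer(replicates), runs = as.integer(runs),
                 run_shift_sd = run_shift_sd, ct_one_copy = ct_one_copy,
                 max_cycles = max_cycles, seed = as.integer(seed)),
            class = "simulation_config")
}

#' CT value of a reaction given its template copy count
#'
#' Zero copies can never amplify: the reaction is undetermined. Otherwise
#' the copies are pre-amplified deterministically to
#' `N = copies * (1 + efficiency)^preamp_cycles` effective copies, and
#' `ct = ct_one_copy - log(N) / log(1 + efficiency) + Gaussian(0, noise_sd)`;
#' each doubling of template lowers CT by one cycle at efficiency 1. CTs
#' beyond `max_cycles` are censored to undetermined.
#'
#' @param copies Integer copy count(s) (>= 0).
#' @param spec A [platform_spec()].
#' @param ct_one_copy CT of a single effective copy, cycles.
#' @param max_cycles Detection limit, cycles.
#' @param noise Optional pre-drawn Gaussian noise vector (cycles), same
#'   length as `copies`; default draws from the current RNG stream.
#' @return Numeric vector of CTs with `NA` for undetermined reactions.
#' @export
simulate_ct <- function(copies, spec, ct_one_copy, max_cycles = 40,
                        noise = NULL) {
  stopifnot(inherits(spec, "platform_spec"), all(copies >= 0))
  if (is.null(noise)) noise <- stats::rnorm(length(copies), 0, spec$noise_sd)
  stopifnot(length(noise) == length(copies))
  base <- 1 + spec$efficiency
  ct <- rep(NA_real_, length(copies))
  amp <- copies > 0
  # log(N)/log(base) with N = copies * base^preamp, computed in log space
  ct[amp] <- ct_one_copy -
    (log(copies[amp]) / log(base) + spec$preamp_cycles) + noise[amp]
  ct[!is.na(ct) & ct > max_cycles] <- NA_real_
  ct
}

#' Simulate a full multi-platform qPCR study
#'
#' Composes the Poisson copy-partitioning, pre-amplification/CT and
#' run-shift models over every (platform, run, sample, miRNA, replicate)
#' combination in the configuration. The mean copies per reaction for a
#' platform is `concentration * reaction_volume / dilution_factor`, so at a
#' fixed concentration the dropout probability `exp(-lambda)` grows as the
#' reaction volume shrinks — the simulator's core behaviour.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_study`: `table` (a [ct_table]), `truth`
#'   (ground-truth ledger with `lambda`, `copies` and the noiseless
#'   `ct_true` per measurement), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))

  truth <- config$truth
  pfs <- config$platforms
  n_cell <- nrow(truth)
  n_rep <- config$replicates
  n_run <- config$runs

  # named substreams off the master seed
  set.seed(.substream_seed(config$seed, "runshift"))
  shifts <- matrix(stats::rnorm(length(pfs) * n_run, 0, config$run_shift_sd),
                   nrow = length(pfs),
                   dimnames = list(names(pfs), paste0("run", seq_len(n_run))))

  out <- vector("list", length(pfs))
  for (p in seq_along(pfs)) {
    spec <- pfs[[p]]
    lam <- truth$concentration * spec$reaction_volume / spec$dilution_factor
    n_total <- n_cell * n_run * n_rep
    set.seed(.substream_seed(config$seed, paste0("partition_", spec$name)))
    copies <- stats::rpois(n_total, rep(lam, each = n_run * n_rep))
    set.seed(.substream_seed(config$seed, paste0("noise_", spec$name)))
    noise <- stats::rnorm(n_total, 0, spec$noise_sd)

    run <- rep(rep(paste0("run", seq_len(n_run)), each = n_rep), times = n_cell)
    rec <- data.frame(
      platform = spec$name,
      run = run,
      user = ifelse(run == "run1", "user1", "user2"),
      sample = rep(truth$sample, each = n_run * n_rep),
      mirna = rep(truth$mirna, each = n_run * n_rep),
      replicate = rep(seq_len(n_rep), times = n_cell * n_run),
      lambda = rep(lam, each = n_run * n_rep),
      copies = copies)
    ct_true <- simulate_ct(copies, spec, config$ct_one_copy,
                           max_cycles = Inf,
                           noise = rep(0, n_total))
    ct <- simulate_ct(copies, spec, config$ct_one_copy,
                      max_cycles = Inf, noise = noise) +
      shifts[spec$name, rec$run]
    ct[!is.na(ct) & ct > config$max_cycles] <- NA_real_
    # guard: noise or shift could push a CT non-positive at extreme abundance
    ct[!is.na(ct) & ct <= 0] <- NA_real_
    rec$ct_true <- ct_true
    rec$ct <- ct
    out[[p]] <- rec
  }
  ledger <- do.call(rbind, out)
  rownames(ledger) <- NULL
  tab <- ct_table(ledger[, c("platform", "run", "user", "sample", "mirna",
                             "replicate", "ct")])
  structure(list(table = tab, truth = ledger, config = config),
            class = "sim_study")
}

# -- RNG plumbing -------------------------------------------------------------

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# deterministic 32-bit substream seed from (master seed, stream name)
.substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 2654435 + h * 97 + 12345) %% 2147483647)
}
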