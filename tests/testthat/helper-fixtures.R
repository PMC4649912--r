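# Shared fixture builders for the test suite.

# minimal long-format table: one platform/run unless overridden
toy_table <- function(ct, platform = "P1", run = "run1", sample = "S1",
                      mirna = "miR-1") {
  n <- length(ct)
  ct_table(data.frame(platform = platform, run = run, sample = sample,
                      mirna = mirna, replicate = seq_len(n), ct = ct))
}

# table of replicate groups from a named list: name -> vector of replicate CTs
groups_table <- function(groups, platform = "P1") {
  rows <- lapply(seq_along(groups), function(i) {
    ct <- groups[[i]]
    data.frame(platform = platform, run = "run1", sample = "S1",
               mirna = names(groups)[i], replicate = seq_along(ct), ct = ct)
  })
  ct_table(do.call(rbind, rows))
}

# two-platform table from matched (sample, mirna) cell values, one replicate
matched_table <- function(values_a, values_b, platform_a = "A",
                          platform_b = "B") {
  stopifnot(length(values_a) == length(values_b))
  n <- length(values_a)
  mirna <- sprintf("miR-%02d", seq_len(n))
  ct_table(data.frame(
    platform = rep(c(platform_a, platform_b), each = n),
    run = "run1", sample = "S1", mirna = rep(mirna, 2),
    replicate = 1L, ct = c(values_a, values_b)))
}

# exhaustive Ward oracle: at each agglomeration evaluate the increase in
# within-cluster sum of squares for every candidate pair and merge the
# minimum; returns the sequence of partitions (list of membership vectors)
ward_oracle_partitions <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  partitions <- list()
  ess <- function(idx) {
    if (length(idx) == 1L) return(0)
    centered <- sweep(x[idx, , drop = FALSE], 2,
                      colMeans(x[idx, , drop = FALSE]))
    sum(centered^2)
  }
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    membership <- integer(nrow(x))
    for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- membership
  }
  partitions
}

# canonical form of a partition so label permutations compare equal
canon_partition <- function(membership) {
  match(membership, unique(membership))
}

# planted 4-group matrix: centers at 6*e_i in 4-d, unit intra-group sd
planted_matrix <- function(per_group = 6, sep = 6, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- diag(4) * sep
  x <- do.call(rbind, lapply(1:4, function(g) {
    matrix(stats::rnorm(per_group * 4, 0, sd), per_group, 4) +
      matrix(centers[g, ], per_group, 4, byrow = TRUE)
  }))
  rownames(x) <- sprintf("miR-%02d", seq_len(nrow(x)))
  colnames(x) <- paste0("S", 1:4)
  list(x = x, truth = rep(1:4, each = per_group))
}
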