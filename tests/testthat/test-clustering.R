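test_that("missingness filter and row-mean imputation follow the rules", {
  # miRNA m2 missing 2 of 4 sample cells on the only platform (50% > 15%)
  df <- expand.grid(platform = "P", run = "r", sample = paste0("S", 1:4),
                    mirna = c("m1", "m2", "m3"), replicate = 1L,
                    stringsAsFactors = FALSE)
  df$ct <- 20 + seq_len(nrow(df))
  df$ct[df$mirna == "m2" & df$sample %in% c("S1", "S2")] <- NA
  m <- build_expression_matrix(ct_table(df), "P")
  expect_equal(sort(rownames(m$values)), c("m1", "m3"))
  expect_false(any(is.na(m$values)))
  expect_false(any(m$mask))

  # a single missing cell (25% per-platform, but 12.5% pooled over two
  # platforms) survives the pooled filter and is imputed with the row mean
  base <- expand.grid(platform = c("P", "Q"), run = "r",
                      sample = paste0("S", 1:4), mirna = c("m1", "m2", "m3"),
                      replicate = 1L, stringsAsFactors = FALSE)
  base$ct <- 20 + seq_len(nrow(base))
  df2 <- base
  df2$ct[df2$platform == "Q" & df2$mirna == "m2" & df2$sample == "S1"] <- NA
  m2 <- build_expression_matrix(ct_table(df2), "Q", zscore = FALSE)
  expect_true(m2$mask["m2", "S1"])
  obs <- m2$values["m2", c("S2", "S3", "S4")]
  expect_equal(unname(m2$values["m2", "S1"]), mean(obs))

  # row {1, NA, 3} imputes the middle to 2 (on the raw scale)
  df3 <- data.frame(platform = "P", run = "r",
                    sample = c("S1", "S2", "S3"), mirna = "m1",
                    replicate = 1L, ct = c(1, NA, 3))
  df3 <- rbind(df3, transform(df3, mirna = "m2", ct = c(4, 5, 6)),
               transform(df3, mirna = "m3", ct = c(7, 8, 9)))
  m3 <- build_expression_matrix(ct_table(df3), "P", missing_threshold = 0.35,
                                zscore = FALSE)
  expect_equal(unname(m3$values["m1", ]), c(1, 2, 3))

  expect_error(build_expression_matrix(ct_table(df3), "P",
                                       missing_threshold = -0.1),
               "every miRNA exceeds")
})

test_that("Ward merges agree with exhaustive evaluation of the Ward objective", {
  set.seed(21)
  for (n in c(4, 5, 7)) {
    x <- matrix(rnorm(n * 3), n, 3)
    rownames(x) <- paste0("m", seq_len(n))
    dend <- ward_dendrogram(x)
    oracle <- ward_oracle_partitions(x)
    for (step in seq_len(n - 1L)) {
      k <- n - step
      if (k < 1L) break
      got <- canon_partition(stats::cutree(dend, k = max(k, 1L)))
      want <- canon_partition(oracle[[step]])
      expect_equal(got, unname(want),
                   label = sprintf("n=%d, step=%d hclust partition", n, step))
    }
  }
})

test_that("dendrogram degenerate cases behave", {
  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  d2 <- ward_dendrogram(two)
  expect_equal(length(d2$height), 1L)
  expect_gt(d2$height, 0)

  # identical rows merge at height zero; heights are non-decreasing
  same <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  ds <- ward_dendrogram(same)
  expect_equal(ds$height, c(0, 0))

  # three close collinear points plus one distant: first merge joins the
  # closest pair (checked against the exhaustive oracle too)
  x <- matrix(c(0, 0.1, 0.25, 10), 4, 1,
              dimnames = list(paste0("m", 1:4), NULL))
  dend <- ward_dendrogram(x)
  expect_equal(canon_partition(stats::cutree(dend, 3)),
               canon_partition(c(1, 1, 2, 3)))
  expect_true(all(diff(dend$height) >= 0))

  expect_error(ward_dendrogram(matrix(1, 1, 2)), "at least 2 rows")
  expect_error(ward_dendrogram(matrix(c(1, NA), 2, 1)), "missing entries")
})

test_that("heights are non-decreasing on random matrices", {
  set.seed(8)
  for (i in 1:10) {
    x <- matrix(rnorm(sample(6:20, 1) * 4), ncol = 4)
    rownames(x) <- paste0("m", seq_len(nrow(x)))
    expect_true(all(diff(ward_dendrogram(x)$height) >= -1e-12))
  }
})

test_that("the Mojena rule finds well-separated groups and is monotone", {
  pl <- planted_matrix(per_group = 6, seed = 31)
  dend <- ward_dendrogram(pl$x)
  expect_equal(mojena_k(dend), 4L)

  # all points identical: every fusion height 0, one cluster
  same <- matrix(2, 5, 3, dimnames = list(paste0("m", 1:5), NULL))
  expect_equal(mojena_k(ward_dendrogram(same)), 1L)

  # increasing the constant never increases k
  set.seed(32)
  x <- matrix(rnorm(60), 15, 4, dimnames = list(paste0("m", 1:15), NULL))
  dx <- ward_dendrogram(x)
  ks <- vapply(c(0, 0.5, 1, 1.25, 2, 4), function(kc) mojena_k(dx, kc),
               integer(1))
  expect_true(all(diff(ks) <= 0))

  # n = 2 degenerate: single height, sd treated as 0, no exceedance
  expect_equal(mojena_k(ward_dendrogram(matrix(c(0, 5), 2, 1,
                 dimnames = list(c("a", "b"), NULL)))), 1L)
})

test_that("k-means refinement keeps the Ward partition on separated data", {
  pl <- planted_matrix(per_group = 5, seed = 41)
  dend <- ward_dendrogram(pl$x)
  res <- assign_clusters(pl$x, 4, dend)
  expect_equal(canon_partition(unname(res$assignment)),
               canon_partition(pl$truth))
  expect_false(res$trace$reseeded)
  expect_equal(sort(unique(res$assignment)), 1:4)

  # degenerate k
  n <- nrow(pl$x)
  expect_equal(unname(assign_clusters(pl$x, 1, dend)$assignment), rep(1L, n))
  expect_equal(unname(assign_clusters(pl$x, n, dend)$assignment), seq_len(n))
  expect_error(assign_clusters(pl$x, n + 1, dend), "k exceeds")
})

test_that("full pipeline recovers a planted 4-group partition across seeds", {
  hits <- 0L
  n_runs <- 100L
  for (seed in seq_len(n_runs)) {
    pl <- planted_matrix(per_group = 6, seed = seed)
    dend <- ward_dendrogram(pl$x)
    k <- mojena_k(dend)
    if (k != 4L) next
    res <- assign_clusters(pl$x, k, dend)
    truth <- structure(list(platform = "truth", k = 4L,
                            assignment = stats::setNames(pl$truth,
                                                         rownames(pl$x)),
                            trace = list()), class = "cluster_result")
    cc <- cluster_concordance(truth, res)
    if (cc$misassigned_pct == 0) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("cluster concordance is label-invariant and counts misassignments", {
  assignment <- stats::setNames(rep(1:4, each = 9), sprintf("m%02d", 1:36))
  mk <- function(a, pf = "X") structure(
    list(platform = pf, k = length(unique(a)), assignment = a, trace = list()),
    class = "cluster_result")
  ref <- mk(assignment, "ref")

  expect_equal(cluster_concordance(ref, ref)$misassigned_pct, 0)

  # permuted labels: still 0% misassigned via optimal matching
  permuted <- mk(stats::setNames(c(3L, 4L, 1L, 2L)[assignment],
                                 names(assignment)))
  expect_equal(cluster_concordance(ref, permuted)$misassigned_pct, 0)

  # one of 36 miRNAs moved: 1/36 = 2.78%
  moved <- assignment
  moved["m01"] <- 2L
  cc <- cluster_concordance(ref, mk(moved))
  expect_equal(cc$misassigned_pct, 100 / 36, tolerance = 1e-9)
  expect_equal(round(cc$misassigned_pct, 2), 2.78)
  expect_false(cc$concordant[["m01"]])
  expect_equal(sum(!cc$concordant), 1L)

  # random relabelings of both partitions never change the score
  set.seed(51)
  noisy <- assignment
  noisy[sample(36, 7)] <- sample(4L, 7, replace = TRUE)
  base <- cluster_concordance(ref, mk(noisy))$misassigned_pct
  for (i in 1:5) {
    pa <- sample(4); pb <- sample(4)
    ref_p <- mk(stats::setNames(pa[assignment], names(assignment)), "ref")
    oth_p <- mk(stats::setNames(pb[noisy], names(noisy)))
    expect_equal(cluster_concordance(ref_p, oth_p)$misassigned_pct, base)
  }

  # shared set too small
  tiny <- mk(stats::setNames(1L, "zzz"))
  expect_error(cluster_concordance(ref, tiny), "fewer than 2")
})

test_that("literal at-least-two-comembers mode scores concordance", {
  assignment <- stats::setNames(rep(1:2, each = 4), sprintf("m%d", 1:8))
  mk <- function(a, pf = "X") structure(
    list(platform = pf, k = length(unique(a)), assignment = a, trace = list()),
    class = "cluster_result")
  ref <- mk(assignment, "ref")
  # one miRNA moved into the other cluster: it has no comember sharing both
  # its reference and comparison cluster, everyone else still does
  moved <- assignment
  moved["m1"] <- 2L
  cc <- cluster_concordance(ref, mk(moved), mode = "literal")
  expect_false(cc$concordant[["m1"]])
  expect_true(all(cc$concordant[-1]))
})

test_that("optimal matching maximises overlap when cluster counts differ", {
  ref <- structure(list(platform = "ref", k = 3L,
                        assignment = stats::setNames(rep(1:3, each = 4),
                                                     sprintf("m%02d", 1:12)),
                        trace = list()), class = "cluster_result")
  # comparison splits reference cluster 3 into two
  oth_assign <- rep(c(1L, 2L, 3L), each = 4)
  oth_assign[11:12] <- 4L
  oth <- structure(list(platform = "oth", k = 4L,
                        assignment = stats::setNames(oth_assign,
                                                     sprintf("m%02d", 1:12)),
                        trace = list()), class = "cluster_result")
  cc <- cluster_concordance(ref, oth)
  expect_equal(cc$misassigned_pct, 100 * 2 / 12, tolerance = 1e-9)
  expect_true(is.na(cc$mapping[["4"]]) || cc$mapping[["4"]] != 3)
})
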