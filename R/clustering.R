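#' Build a per-platform expression matrix for clustering
#'
#' Rows are miRNAs, columns are samples, entries are z-scored mean CTs
#' (standardised within the platform over its own determined cells). miRNAs
#' whose missingness — pooled over all platforms in the table by default —
#' exceeds `missing_threshold` are excluded; remaining missing entries are
#' replaced by the row (miRNA) mean of the observed entries, and a mask
#' records which cells were imputed.
#'
#' @param table A [ct_table].
#' @param platform Platform whose matrix to build.
#' @param missing_threshold Maximum tolerated missing fraction per miRNA
#'   (default 0.15).
#' @param pooled_filter If `TRUE` (default) the missingness filter pools
#'   cells across all platforms in the table; if `FALSE` it uses only the
#'   requested platform's cells.
#' @param zscore If `TRUE` (default) entries are z-scored within the
#'   platform before imputation; `FALSE` clusters raw mean CTs.
#' @return A list of class `expression_matrix`: `values` (numeric matrix,
#'   no missing entries), `mask` (logical matrix, `TRUE` where imputed),
#'   `platform`.
#' @export
build_expression_matrix <- function(table, platform, missing_threshold = 0.15,
                                    pooled_filter = TRUE, zscore = TRUE) {
  stopifnot(inherits(table, "ct_table"))
  if (!platform %in% table$platform) {
    stop("build_expression_matrix: platform '", platform, "' not in table",
         call. = FALSE)
  }
  cm <- cell_means(table)
  all_samples <- sort(unique(cm$sample))
  all_mirnas <- sort(unique(cm$mirna))
  # missing fraction per miRNA over (platform x sample) cells
  filter_pf <- if (pooled_filter) sort(unique(cm$platform)) else platform
  n_cells <- length(filter_pf) * length(all_samples)
  present <- cm[cm$platform %in% filter_pf & !is.na(cm$mean_ct), ]
  n_obs <- table(factor(present$mirna, levels = all_mirnas))
  miss_frac <- 1 - as.numeric(n_obs) / n_cells
  keep <- all_mirnas[miss_frac <= missing_threshold]
  if (length(keep) == 0L) {
    stop("build_expression_matrix: every miRNA exceeds the missingness ",
         "threshold", call. = FALSE)
  }
  pf <- cm[cm$platform == platform & cm$mirna %in% keep, ]
  if (zscore) {
    obs <- pf$mean_ct[!is.na(pf$mean_ct)]
    s <- stats::sd(obs)
    if (!is.finite(s) || s == 0) {
      stop("build_expression_matrix: zero variance on platform '", platform,
           "'", call. = FALSE)
    }
    pf$value <- (pf$mean_ct - mean(obs)) / s
  } else {
    pf$value <- pf$mean_ct
  }
  values <- matrix(NA_real_, nrow = length(keep), ncol = length(all_samples),
                   dimnames = list(keep, all_samples))
  values[cbind(pf$mirna, pf$sample)] <- pf$value
  mask <- is.na(values)
  if (any(rowSums(!mask) == 0L)) {
    bad <- rownames(values)[rowSums(!mask) == 0L]
    warning("build_expression_matrix: miRNA(s) entirely missing on '",
            platform, "' dropped: ", paste(bad, collapse = ", "),
            call. = FALSE)
    values <- values[rowSums(!mask) > 0L, , drop = FALSE]
    mask <- mask[rownames(values), , drop = FALSE]
  }
  for (i in seq_len(nrow(values))) {
    if (any(mask[i, ])) {
      values[i, mask[i, ]] <- mean(values[i, !mask[i, ]])
    }
  }
  structure(list(values = values, mask = mask, platform = platform),
            class = "expression_matrix")
}

#' Ward dendrogram of miRNA expression profiles
#'
#' Agglomerative hierarchical clustering of the matrix rows under Ward's
#' minimum-variance criterion on Euclidean distances (`hclust` method
#' `"ward.D2"`, whose merge heights are monotone non-decreasing).
#'
#' @param matrix An `expression_matrix` from [build_expression_matrix()],
#'   or a numeric matrix with row names.
#' @return An `hclust` object.
#' @export
ward_dendrogram <- function(matrix) {
  x <- if (inherits(matrix, "expression_matrix")) matrix$values else matrix
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("ward_dendrogram: matrix has missing entries",
                     call. = FALSE)
  if (nrow(x) < 2L) stop("ward_dendrogram: need at least 2 rows",
                         call. = FALSE)
  stats::hclust(stats::dist(x), method = "ward.D2")
}

#' Mojena stopping rule for the number of clusters
#'
#' Scans the fusion heights of the dendrogram and flags the first merge
#' (lowest in the tree) whose height exceeds `mean(heights) + k_const *
#' sd(heights)`; the number of clusters present just before that merge is
#' returned. If no height exceeds the bound, all items form one cluster.
#'
#' @param dendrogram An `hclust` object (e.g. from [ward_dendrogram()]).
#' @param k_const Mojena constant; 1.25 is the classical recommendation.
#' @return Integer cluster count `k >= 1`.
#' @export
mojena_k <- function(dendrogram, k_const = 1.25) {
  stopifnot(inherits(dendrogram, "hclust"), k_const >= 0)
  h <- dendrogram$height
  n <- length(h) + 1L
  s <- if (length(h) >= 2L) stats::sd(h) else 0
  bound <- mean(h) + k_const * s
  exceeds <- which(h > bound)
  if (length(exceeds) == 0L) return(1L)
  # clusters present just before merge j is n - j + 1
  as.integer(n - min(exceeds) + 1L)
}

#' Cluster assignment by k-means refined from the Ward partition
#'
#' Cuts the Ward dendrogram into `k` groups, then runs k-means on the matrix
#' rows initialised at the centroids of those groups — a deterministic
#' refinement (no random restarts). If k-means degenerates (an empty
#' cluster), the Ward partition itself is returned and the trace records the
#' re-seed.
#'
#' @inheritParams ward_dendrogram
#' @param k Number of clusters, `1 <= k <= nrow`.
#' @param dendrogram The `hclust` object for the same matrix.
#' @return A list of class `cluster_result`: `platform`, `k`, `assignment`
#'   (named integer vector, labels in `1..k`), `trace` (list with
#'   `kmeans_iter`, `reseeded`, and optionally `mojena_const`).
#' @export
assign_clusters <- function(matrix, k, dendrogram) {
  x <- if (inherits(matrix, "expression_matrix")) matrix$values else matrix
  platform <- if (inherits(matrix, "expression_matrix")) matrix$platform else NA_character_
  n <- nrow(x)
  if (k > n) stop("assign_clusters: k exceeds the number of rows",
                  call. = FALSE)
  stopifnot(k >= 1)
  ward_labels <- stats::cutree(dendrogram, k = k)
  if (k == 1L || k == n) {
    assignment <- if (k == 1L) stats::setNames(rep(1L, n), rownames(x)) else
      stats::setNames(seq_len(n), rownames(x))
    return(structure(list(platform = platform, k = as.integer(k),
                          assignment = assignment,
                          trace = list(kmeans_iter = 0L, reseeded = FALSE)),
                     class = "cluster_result"))
  }
  centroids <- rowsum(x, ward_labels) / as.vector(table(ward_labels))
  km <- tryCatch(
    suppressWarnings(stats::kmeans(x, centers = centroids, iter.max = 100L)),
    error = function(e) NULL)
  if (is.null(km) || any(km$size == 0L)) {
    assignment <- stats::setNames(as.integer(ward_labels), rownames(x))
    trace <- list(kmeans_iter = 0L, reseeded = TRUE)
  } else {
    assignment <- stats::setNames(as.integer(km$cluster), rownames(x))
    trace <- list(kmeans_iter = km$iter, reseeded = FALSE)
  }
  structure(list(platform = platform, k = as.integer(k),
                 assignment = assignment, trace = trace),
            class = "cluster_result")
}

#' Full per-platform clustering pipeline
#'
#' Expression matrix -> Ward dendrogram -> Mojena k -> k-means refinement.
#'
#' @inheritParams build_expression_matrix
#' @param k_const Mojena constant (see [mojena_k()]).
#' @param k Optional fixed cluster count overriding the Mojena rule.
#' @return A `cluster_result` (see [assign_clusters()]) with the dendrogram
#'   attached as `$dendrogram` and the Mojena constant in the trace.
#' @export
cluster_platform <- function(table, platform, missing_threshold = 0.15,
                             k_const = 1.25, k = NULL,
                             pooled_filter = TRUE, zscore = TRUE) {
  m <- build_expression_matrix(table, platform,
                               missing_threshold = missing_threshold,
                               pooled_filter = pooled_filter, zscore = zscore)
  dend <- ward_dendrogram(m)
  if (is.null(k)) k <- mojena_k(dend, k_const = k_const)
  res <- assign_clusters(m, k, dend)
  res$trace$mojena_const <- k_const
  res$dendrogram <- dend
  res
}

# all permutations of 1..k (k <= 8 guard lives in the caller)
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

#' Cluster concordance between two platforms
#'
#' Matches the comparison platform's clusters to the reference platform's by
#' the one-to-one assignment maximising total shared membership on the
#' contingency table (exhaustive over label permutations), then scores each
#' shared miRNA as concordant iff its comparison cluster maps to its
#' reference cluster. `misassigned_pct` is the percentage of shared miRNAs
#' that are not concordant. The `"literal"` mode instead declares a miRNA
#' concordant iff at least two miRNAs share both its reference and its
#' comparison cluster (the at-least-two-comembers reading).
#'
#' @param reference,other `cluster_result` objects covering a shared miRNA
#'   set (intersection of at least 2).
#' @param mode `"optimal"` (default) or `"literal"`.
#' @return A list of class `cluster_concordance`: `reference_platform`,
#'   `comparison_platform`, `mapping` (comparison label -> reference label;
#'   `NA` for unmapped labels when cluster counts differ), `concordant`
#'   (named logical per shared miRNA), `n_shared`, `misassigned_pct`.
#' @export
cluster_concordance <- function(reference, other,
                                mode = c("optimal", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "cluster_result"),
            inherits(other, "cluster_result"))
  shared <- intersect(names(reference$assignment), names(other$assignment))
  if (length(shared) < 2L) {
    stop("cluster_concordance: shared miRNA set has fewer than 2 members",
         call. = FALSE)
  }
  ref <- reference$assignment[shared]
  oth <- other$assignment[shared]
  tab <- table(factor(ref, levels = seq_len(reference$k)),
               factor(oth, levels = seq_len(other$k)))
  if (mode == "optimal") {
    k <- max(reference$k, other$k)
    if (k > 8L) {
      stop("cluster_concordance: exhaustive matching supports at most 8 ",
           "clusters", call. = FALSE)
    }
    sq <- matrix(0L, k, k)
    sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    perms <- .permutations(k)
    overlap <- apply(perms, 1L, function(p) sum(sq[cbind(p, seq_len(k))]))
    best <- perms[which.max(overlap), ]
    # best[j] = reference cluster matched to comparison cluster j
    mapping <- stats::setNames(best[seq_len(other$k)], seq_len(other$k))
    mapping[mapping > reference$k] <- NA_integer_
    concordant <- !is.na(mapping[oth]) & mapping[oth] == ref
  } else {
    mapping <- NULL
    concordant <- tab[cbind(as.character(ref), as.character(oth))] >= 2L
  }
  concordant <- stats::setNames(as.logical(concordant), shared)
  structure(list(reference_platform = reference$platform,
                 comparison_platform = other$platform,
                 mapping = mapping, concordant = concordant,
                 n_shared = length(shared),
                 misassigned_pct = 100 * mean(!concordant)),
            class = "cluster_concordance")
}
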