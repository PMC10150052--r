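#' Contingency table between two clonal partitions
#'
#' @param A,B [ClonalPartition][new_clonal_partition] objects over the same
#'   set of record ids.
#' @return An integer matrix of co-occurrence counts (clusters of `A` in
#'   rows, clusters of `B` in columns).
#' @export
partition_contingency <- function(A, B) {
  stopifnot(inherits(A, "ClonalPartition"), inherits(B, "ClonalPartition"))
  ids <- names(A$assignment)
  if (length(ids) != length(B$assignment) ||
      !all(sort(ids) == sort(names(B$assignment)))) {
    stop("partitions cover different record sets", call. = FALSE)
  }
  table(A$assignment[ids], B$assignment[ids])
}

partition_entropy <- function(sizes) {
  p <- sizes / sum(sizes)
  -sum(p * log(p))
}

#' Mutual information between two clonal partitions (nats)
#'
#' \deqn{MI = \sum_{ij} \frac{n_{ij}}{n}
#' \log\frac{n\, n_{ij}}{a_i b_j}} over the contingency table of shared
#' records, where \eqn{a_i, b_j} are the cluster sizes. `MI` is non-negative
#' and bounded by `min(H(A), H(B))`; it equals `H(A)` when the partitions are
#' identical and 0 when one partition is a single cluster.
#'
#' @param A,B [ClonalPartition][new_clonal_partition] objects over the same
#'   records.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(A, B) {
  ct <- partition_contingency(A, B)
  n <- sum(ct)
  ai <- rowSums(ct); bj <- colSums(ct)
  nz <- which(ct > 0, arr.ind = TRUE)
  nij <- ct[nz]
  sum(nij / n * log(n * nij / (ai[nz[, 1]] * bj[nz[, 2]])))
}

# Exact expected MI under the permutation (hypergeometric) model with fixed
# marginals. Computed over unique (a_i, b_j) size pairs with multiplicities,
# so repertoires with thousands of singleton clusters stay fast.
expected_mutual_information <- function(ai, bj, n) {
  ta <- table(ai); tb <- table(bj)
  av <- as.numeric(names(ta)); aw <- as.numeric(ta)
  bv <- as.numeric(names(tb)); bw <- as.numeric(tb)
  lf <- lfactorial
  emi <- 0
  for (u in seq_along(av)) {
    a <- av[u]
    for (v in seq_along(bv)) {
      b <- bv[v]
      lo <- max(1, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      nij <- lo:hi
      lprob <- lf(a) + lf(b) + lf(n - a) + lf(n - b) - lf(n) -
        lf(nij) - lf(a - nij) - lf(b - nij) - lf(n - a - b + nij)
      emi <- emi + aw[u] * bw[v] *
        sum(nij / n * log(n * nij / (a * b)) * exp(lprob))
    }
  }
  emi
}

#' Adjusted mutual information between two clonal partitions
#'
#' Chance-corrected mutual information,
#' \deqn{AMI = \frac{MI - E\{MI\}}{\max(H(A), H(B)) - E\{MI\}},}
#' where the expected MI is computed exactly under the permutation model of
#' random labelings with the observed cluster sizes (hypergeometric cell
#' distributions), not by Monte Carlo. AMI is 1 iff the partitions are
#' identical up to relabeling and concentrates near 0 for independent
#' partitions regardless of the number of clusters. Two trivial partitions
#' (both a single cluster, entropy 0) are identical and return 1 by
#' convention.
#'
#' @param A,B [ClonalPartition][new_clonal_partition] objects over the same
#'   records.
#' @return AMI value (at most 1; can be slightly negative for
#'   anti-correlated partitions).
#' @export
adjusted_mutual_information <- function(A, B) {
  ct <- partition_contingency(A, B)
  n <- sum(ct)
  ai <- rowSums(ct); bj <- colSums(ct)
  ha <- partition_entropy(ai); hb <- partition_entropy(bj)
  if (ha == 0 && hb == 0) return(1)
  mi <- mutual_information(A, B)
  emi <- expected_mutual_information(ai, bj, n)
  denom <- max(ha, hb) - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

#' Singleton / non-singleton labels of a partition
#'
#' A record is a singleton when its clone has exactly one member (in
#' collapsed representatives).
#'
#' @param partition A [ClonalPartition][new_clonal_partition].
#' @return Named character vector over record ids with values `"singleton"`
#'   or `"non_singleton"`.
#' @export
singleton_labels <- function(partition) {
  stopifnot(inherits(partition, "ClonalPartition"))
  sizes <- table(partition$assignment)
  lab <- ifelse(sizes[partition$assignment] == 1, "singleton", "non_singleton")
  stats::setNames(as.character(lab), names(partition$assignment))
}

#' Spearman rank agreement between per-sample diversity values
#'
#' Given one diversity value per sample and method, computes the pairwise
#' Spearman rank correlation between methods (average ranks for ties). A
#' correlation close to 1 means the methods rank the samples' diversity the
#' same way even if the absolute index values differ.
#'
#' @param values A numeric matrix or data frame, samples in rows, methods in
#'   columns (at least 3 samples).
#' @return Symmetric matrix of Spearman rho per method pair; columns with
#'   constant values yield `NA` with a warning.
#' @export
spearman_rank_agreement <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("need at least 3 samples", call. = FALSE)
  const <- apply(values, 2, function(x) length(unique(x)) == 1)
  if (any(const)) {
    warning("constant diversity values for method(s): ",
            paste(colnames(values)[const], collapse = ", "),
            "; Spearman rho undefined", call. = FALSE)
  }
  suppressWarnings(stats::cor(values, method = "spearman"))
}

#' Scan Hill orders for the best cross-method rank agreement
#'
#' For every order `alpha` on a regular grid, computes the Hill diversity of
#' each sample under each clonal identification method, the Spearman rank
#' correlation between each pair of methods across samples, and the mean
#' correlation over method pairs. Returns the full curve and the first
#' `alpha` attaining the maximum mean correlation.
#'
#' @param abundances_by_method Named list (one element per method) of lists
#'   of [AbundanceVector][abundance_vector]s (one per sample, same sample
#'   order in every method).
#' @param alpha_min,alpha_max,step Grid specification (defaults 0, 100,
#'   0.01).
#' @return A list with `alpha_opt` (first argmax), `rho_opt` and `curve` (a
#'   tibble with columns `alpha` and `mean_rho`).
#' @export
optimal_alpha_scan <- function(abundances_by_method, alpha_min = 0,
                               alpha_max = 100, step = 0.01) {
  stopifnot(length(abundances_by_method) >= 2)
  n_samples <- length(abundances_by_method[[1]])
  if (n_samples < 3) stop("need at least 3 samples", call. = FALSE)
  stopifnot(all(lengths(abundances_by_method) == n_samples))
  alphas <- seq(alpha_min, alpha_max, by = step)
  # one matrix (alpha x sample) of Hill values per method
  hills <- lapply(abundances_by_method, function(samples) {
    vapply(samples, function(ab) hill_diversity(ab, alphas),
           numeric(length(alphas)))
  })
  pairs <- utils::combn(length(hills), 2)
  rho_sum <- numeric(length(alphas))
  for (pq in seq_len(ncol(pairs))) {
    x <- hills[[pairs[1, pq]]]
    y <- hills[[pairs[2, pq]]]
    rho_sum <- rho_sum + vapply(seq_along(alphas), function(i) {
      suppressWarnings(stats::cor(x[i, ], y[i, ], method = "spearman"))
    }, numeric(1))
  }
  mean_rho <- rho_sum / ncol(pairs)
  best <- which.max(mean_rho)
  list(alpha_opt = alphas[best], rho_opt = mean_rho[best],
       curve = tibble::tibble(alpha = alphas, mean_rho = mean_rho))
}
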