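#' Complete-linkage agglomerative clustering cut at a distance threshold
#'
#' Hierarchical agglomerative clustering under the complete-linkage criterion
#' (the distance between two clusters is the maximum pairwise distance between
#' their members), stopped as soon as the smallest inter-cluster distance
#' exceeds `h`. The returned flat partition therefore contains every merge
#' with height `<= h`, and within any resulting cluster all pairwise
#' distances are at most `h`.
#'
#' Ties in merge height are broken deterministically: among tied pairs, the
#' pair whose lowest original member index is smallest is merged first (then
#' by the second index). The result is thus a pure function of the distance
#' matrix, independent of floating-point library quirks in dendrogram
#' reordering.
#'
#' @param d Symmetric numeric distance matrix (zero diagonal).
#' @param h Cut height; merges with height `<= h` are performed.
#' @return Integer vector of cluster labels (1-based, numbered by first
#'   appearance) with one entry per row of `d`.
#' @export
hac_complete_cut <- function(d, h) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n == ncol(d))
  if (n == 1) return(1L)
  lab <- seq_len(n)
  D <- d
  diag(D) <- Inf
  repeat {
    m <- min(D)
    if (!is.finite(m) || m > h) break
    idx <- which(D == m, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pick <- idx[order(idx[, 1], idx[, 2])[1], ]
    i <- pick[1]; j <- pick[2]
    merged <- pmax(D[i, ], D[j, ])
    D[i, ] <- merged
    D[, i] <- merged
    D[i, i] <- Inf
    D[j, ] <- Inf
    D[, j] <- Inf
    lab[lab == j] <- i
  }
  match(lab, unique(lab))
}
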