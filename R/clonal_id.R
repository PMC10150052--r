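#' Clonal partitions
#'
#' A `ClonalPartition` assigns every record of a repertoire to a clone label.
#' Labels are opaque; only the induced set partition is meaningful.
#'
#' @param assignment Named character vector mapping `sequence_id` to clone
#'   label.
#' @param method One of `"junction_only"`, `"vj_junction"`,
#'   `"alignment_free"`, `"truth"` or `"imported"`.
#' @param threshold Distance threshold used (or `NULL`).
#' @param params List of method parameters (k, L, delta, linkage, seed, ...).
#' @return An object of class `ClonalPartition`.
#' @export
new_clonal_partition <- function(assignment, method, threshold = NULL,
                                 params = list()) {
  stopifnot(is.character(assignment), !is.null(names(assignment)))
  if (anyDuplicated(names(assignment))) {
    stop("duplicate record ids in partition", call. = FALSE)
  }
  structure(list(assignment = assignment, method = method,
                 threshold = threshold, params = params),
            class = "ClonalPartition")
}

#' @export
print.ClonalPartition <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("ClonalPartition (%s): %d records in %d clones\n",
              x$method, length(x$assignment), length(sizes)))
  cat(sprintf("  singletons: %d | largest clone: %d | threshold: %s\n",
              sum(sizes == 1), max(sizes),
              if (is.null(x$threshold)) "none" else format(x$threshold)))
  invisible(x)
}

#' Junction-only clonal identification
#'
#' Records belong to the same clone if and only if their junctions are
#' string-identical. This is the strictest definition: any somatic
#' hypermutation inside the junction splits a lineage into several clones.
#'
#' @param rep A [Repertoire][new_repertoire].
#' @return A [ClonalPartition][new_clonal_partition].
#' @export
cluster_junction_only <- function(rep) {
  stopifnot(inherits(rep, "Repertoire"))
  jx <- rep$records$junction
  lab <- paste0("J", match(jx, unique(jx)))
  new_clonal_partition(stats::setNames(lab, rep$records$sequence_id),
                       method = "junction_only")
}

#' Calibrate a clustering threshold from negation sequences
#'
#' Negation sequences come from unrelated individuals and are therefore
#' assumed clonally unrelated to the repertoire. For each negation sequence
#' the distance to its nearest neighbor in the repertoire is computed; the
#' threshold is the empirical lower `delta`-quantile (the order statistic at
#' index `ceiling(delta * N)`) of those nearest-neighbor distances, so that
#' roughly a fraction `delta` of clonally unrelated sequences would fall
#' below it — a specificity of about `1 - delta`.
#'
#' For `metric = "normalized_levenshtein"` the nearest-neighbor search is
#' restricted to repertoire records with the same V and J call (mirroring the
#' V/J-restricted clustering); a negation sequence without any same-V/J
#' counterpart contributes distance 1. For `metric = "cosine"` the search is
#' unrestricted, with negation sequences vectorized against the repertoire's
#' fixed tf-idf corpus (idf weights are not altered by the negation set).
#'
#' @param rep A [Repertoire][new_repertoire] (the repertoire to be clustered).
#' @param neg A [Repertoire][new_repertoire] of negation sequences.
#' @param metric `"normalized_levenshtein"` or `"cosine"`.
#' @param delta False-positive tolerance in (0, 1); default 0.01.
#' @param k,L tf-idf parameters for the cosine metric.
#' @return An object of class `ThresholdCalibration` with fields `threshold`,
#'   `method = "negation"`, `delta` and `negation_nn_distances`.
#' @export
calibrate_threshold_negation <- function(rep, neg,
                                         metric = c("normalized_levenshtein",
                                                    "cosine"),
                                         delta = 0.01, k = 7L, L = 130L) {
  stopifnot(inherits(rep, "Repertoire"), inherits(neg, "Repertoire"))
  metric <- match.arg(metric)
  if (nrow(neg$records) == 0) {
    stop("negation set is empty; cannot calibrate threshold", call. = FALSE)
  }
  stopifnot(delta > 0, delta < 1)
  if (metric == "normalized_levenshtein") {
    key_rep <- paste(rep$records$v_call, rep$records$j_call, sep = "|")
    key_neg <- paste(neg$records$v_call, neg$records$j_call, sep = "|")
    nn <- vapply(seq_len(nrow(neg$records)), function(i) {
      ix <- which(key_rep == key_neg[i])
      if (length(ix) == 0) return(1)
      min(normalized_levenshtein_matrix(neg$records$junction[i],
                                        rep$records$junction[ix]))
    }, numeric(1))
    if (all(nn == 1)) {
      stop("no negation sequence has a same-V/J counterpart in the ",
           "repertoire; consider the alignment-free (cosine) metric",
           call. = FALSE)
    }
  } else {
    vec <- tfidf_vectorize(rep$records$sequence, k = k, L = L)
    proj <- tfidf_project(vec, neg$records$sequence)
    d <- cosine_distance_matrix(proj, vec$weights)
    nn <- apply(d, 1, min)
  }
  thr <- negation_threshold(nn, delta)
  structure(list(threshold = unname(thr), method = "negation", delta = delta,
                 negation_nn_distances = nn, within_nn_distances = NULL),
            class = "ThresholdCalibration")
}

# lower empirical delta-quantile: order statistic at index ceiling(delta * N)
negation_threshold <- function(nn, delta) {
  stopifnot(length(nn) > 0, delta > 0, delta < 1)
  unname(sort(nn)[max(1L, ceiling(delta * length(nn)))])
}

# density valley between the two highest modes of a nearest-neighbor
# distance sample; errors when the density has no interior minimum
bimodal_valley <- function(nn) {
  dens <- stats::density(nn, bw = "nrd0")
  y <- dens$y
  is_max <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) {
    stop("nearest-neighbor distance density is unimodal; ",
         "use the negation-based calibration instead", call. = FALSE)
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  if (valley == top2[1] || valley == top2[2]) {
    stop("no interior density minimum between modes; ",
         "use the negation-based calibration instead", call. = FALSE)
  }
  dens$x[valley]
}

#' Calibrate a clustering threshold from nearest-neighbor bimodality
#'
#' The distribution of within-repertoire nearest-neighbor distances is
#' expected to be a mixture of two modes: small distances between members of
#' the same clone and large distances between unrelated sequences. The
#' threshold is placed at the minimum of a Gaussian kernel density (Silverman
#' bandwidth) between the two highest modes. This calibration needs no
#' negation sequences but fails on unimodal distributions, in which case the
#' negation method is recommended.
#'
#' @inheritParams calibrate_threshold_negation
#' @param min_n Minimum number of nearest-neighbor distances required
#'   (default 50).
#' @return A `ThresholdCalibration` (method `"bimodal"`) with the
#'   `within_nn_distances` used.
#' @export
calibrate_threshold_bimodal <- function(rep,
                                        metric = c("normalized_levenshtein",
                                                   "cosine"),
                                        k = 7L, L = 130L, min_n = 50L) {
  stopifnot(inherits(rep, "Repertoire"))
  metric <- match.arg(metric)
  n <- nrow(rep$records)
  if (n < min_n) {
    stop("need at least ", min_n, " records for bimodal calibration",
         call. = FALSE)
  }
  if (metric == "normalized_levenshtein") {
    key <- paste(rep$records$v_call, rep$records$j_call, sep = "|")
    nn <- rep(1, n)
    for (ix in split(seq_len(n), key)) {
      if (length(ix) < 2) next
      d <- normalized_levenshtein_matrix(rep$records$junction[ix])
      diag(d) <- Inf
      nn[ix] <- apply(d, 1, min)
    }
  } else {
    vec <- tfidf_vectorize(rep$records$sequence, k = k, L = L)
    d <- cosine_distance_matrix(vec$weights)
    diag(d) <- Inf
    nn <- apply(d, 1, min)
  }
  structure(list(threshold = bimodal_valley(nn), method = "bimodal", delta = NA,
                 negation_nn_distances = NULL, within_nn_distances = nn),
            class = "ThresholdCalibration")
}

#' V/J-restricted clonal clustering on junction distances
#'
#' Records are first grouped by their (V gene, J gene) call pair; within each
#' group, complete-linkage hierarchical agglomerative clustering is applied to
#' the normalized Levenshtein distances between junctions and cut at
#' `threshold`. Clones never span V/J groups, and within any clone every
#' pairwise junction distance is at most `threshold`.
#'
#' @param rep A [Repertoire][new_repertoire] with resolved V/J calls.
#' @param threshold Distance threshold in \[0, 1\]; note this is a
#'   *distance*, so the conventional "90% junction similarity" corresponds to
#'   `threshold = 0.1`.
#' @return A [ClonalPartition][new_clonal_partition].
#' @export
cluster_vj_junction <- function(rep, threshold) {
  stopifnot(inherits(rep, "Repertoire"), threshold >= 0, threshold <= 1)
  rec <- rep$records
  key <- paste(rec$v_call, rec$j_call, sep = "|")
  lab <- character(nrow(rec))
  for (g in unique(key)) {
    ix <- which(key == g)
    if (length(ix) == 1) {
      lab[ix] <- paste0(g, "#1")
    } else {
      d <- normalized_levenshtein_matrix(rec$junction[ix])
      cl <- hac_complete_cut(d, threshold)
      lab[ix] <- paste0(g, "#", cl)
    }
  }
  new_clonal_partition(stats::setNames(lab, rec$sequence_id),
                       method = "vj_junction", threshold = threshold,
                       params = list(linkage = "complete"))
}

#' Alignment-free clonal clustering on tf-idf k-mer vectors
#'
#' Full-length sequences are truncated to their 3'-anchored window of `L`
#' nucleotides, tf-idf vectorized over `k`-mers (corpus = the repertoire
#' itself plus any `extra_corpus` sequences), and clustered over the whole
#' repertoire — without any V/J pre-grouping — by complete-linkage HAC on
#' cosine distances, cut at `threshold`. Because idf weights are
#' corpus-dependent, the partition can change when unrelated sequences are
#' added to the corpus.
#'
#' @inheritParams cluster_vj_junction
#' @param k k-mer length (default 7).
#' @param L 3'-anchored truncation length (default 130).
#' @param extra_corpus Optional character vector of additional sequences that
#'   enter the idf statistics without being clustered.
#' @return A [ClonalPartition][new_clonal_partition].
#' @export
cluster_alignment_free <- function(rep, threshold, k = 7L, L = 130L,
                                   extra_corpus = NULL) {
  stopifnot(inherits(rep, "Repertoire"), threshold >= 0, threshold <= 1)
  seqs <- rep$records$sequence
  vec <- tfidf_vectorize(c(seqs, extra_corpus), k = k, L = L)
  w <- vec$weights[seq_along(seqs), , drop = FALSE]
  d <- cosine_distance_matrix(w)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  cl <- hac_complete_cut(d, threshold)
  new_clonal_partition(
    stats::setNames(paste0("AF#", cl), rep$records$sequence_id),
    method = "alignment_free", threshold = threshold,
    params = list(k = k, L = L, linkage = "complete")
  )
}

#' Expand a partition from collapsed representatives to member sequences
#'
#' Clonal identification runs on junction-collapsed repertoires, but
#' partition comparisons (e.g. AMI between methods, or against a read-level
#' ground truth) are defined over the original sequences. This maps every
#' member id in the repertoire's `collapse_map` to its representative's
#' clone label; ids without a map entry keep their own label.
#'
#' @param partition A [ClonalPartition][new_clonal_partition] over the
#'   collapsed representatives.
#' @param rep The collapsed [Repertoire][new_repertoire] the partition was
#'   computed on.
#' @return A `ClonalPartition` over the member-level ids.
#' @export
expand_partition <- function(partition, rep) {
  stopifnot(inherits(partition, "ClonalPartition"), inherits(rep, "Repertoire"))
  if (!rep$collapsed || length(rep$collapse_map) == 0) return(partition)
  reps <- names(rep$collapse_map)
  members <- rep$collapse_map
  lab <- base::rep(partition$assignment[reps], lengths(members))
  new_clonal_partition(stats::setNames(unname(lab),
                                       unlist(members, use.names = FALSE)),
                       method = partition$method,
                       threshold = partition$threshold,
                       params = partition$params)
}

#' Ground-truth partition of a simulated repertoire
#'
#' @param rep A [Repertoire][new_repertoire] carrying `truth_clone` labels.
#' @return A [ClonalPartition][new_clonal_partition] with method `"truth"`.
#' @export
truth_partition <- function(rep) {
  stopifnot(inherits(rep, "Repertoire"))
  if (any(is.na(rep$records$truth_clone))) {
    stop("repertoire has records without truth_clone labels", call. = FALSE)
  }
  new_clonal_partition(
    stats::setNames(rep$records$truth_clone, rep$records$sequence_id),
    method = "truth"
  )
}

#' Identify clones with calibration and full provenance
#'
#' Dispatch wrapper over the three clonal identification methods. For the
#' threshold-based methods the threshold is either given explicitly or
#' calibrated from the negation set (default, tolerance `delta`) or from
#' nearest-neighbor bimodality.
#'
#' @param rep A [Repertoire][new_repertoire].
#' @param method `"junction_only"`, `"vj_junction"` or `"alignment_free"`.
#' @param neg Optional negation [Repertoire][new_repertoire] (required for
#'   `calibration = "negation"` unless `threshold` is given).
#' @param threshold Optional fixed distance threshold; skips calibration.
#' @param calibration `"negation"` (default) or `"bimodal"`.
#' @param delta Negation tolerance (default 0.01).
#' @param k,L Alignment-free tf-idf parameters.
#' @return A [ClonalPartition][new_clonal_partition]; the calibration (if
#'   any) is stored in `params$calibration`.
#' @export
identify_clones <- function(rep,
                            method = c("junction_only", "vj_junction",
                                       "alignment_free"),
                            neg = NULL, threshold = NULL,
                            calibration = c("negation", "bimodal"),
                            delta = 0.01, k = 7L, L = 130L) {
  method <- match.arg(method)
  calibration <- match.arg(calibration)
  if (method == "junction_only") return(cluster_junction_only(rep))
  metric <- if (method == "vj_junction") "normalized_levenshtein" else "cosine"
  calib <- NULL
  if (is.null(threshold)) {
    calib <- if (calibration == "negation") {
      if (is.null(neg)) stop("negation set required to calibrate threshold",
                             call. = FALSE)
      calibrate_threshold_negation(rep, neg, metric = metric, delta = delta,
                                   k = k, L = L)
    } else {
      calibrate_threshold_bimodal(rep, metric = metric, k = k, L = L)
    }
    threshold <- calib$threshold
  }
  part <- if (method == "vj_junction") {
    cluster_vj_junction(rep, threshold)
  } else {
    cluster_alignment_free(rep, threshold, k = k, L = L)
  }
  part$params$calibration <- calib
  part$params$delta <- delta
  part
}
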