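#' Sequencing-depth subsampling analysis
#'
#' Emulates reduced sequencing depth: reads (collapsed representatives
#' expanded by their copy numbers) are drawn without replacement at each
#' sampling ratio, the full pipeline is re-run on the subsample — clustering
#' with the chosen method at a threshold fixed from the full-depth data,
#' abundances, diversity indices — and the fold change of every index
#' relative to its full-depth value is recorded per repetition.
#'
#' @param rep A [Repertoire][new_repertoire] (collapsed or not).
#' @param method Clonal identification method (see [identify_clones()]).
#' @param ratios Sampling ratios in (0, 1].
#' @param reps Number of repetitions per ratio.
#' @param seed Integer seed.
#' @param indices Indices to track (see [diversity_indices()]).
#' @param alphas Optional Hill orders to track alongside the named indices.
#' @param threshold Fixed distance threshold; if `NULL` it is calibrated once
#'   at full depth from `neg`.
#' @param neg Optional negation repertoire for full-depth calibration.
#' @param delta,k,L Calibration / method parameters.
#' @param weight Abundance weighting (see [abundance_from_partition()]).
#' @return A list of class `SubsamplingResult` with `fold_changes` (tibble:
#'   `index`, `ratio`, `mean_fc`, `sd_fc`), `full_values` (named numeric at
#'   full depth), `per_repetition` (tibble of raw fold changes), `ratios`,
#'   `repetitions` and `threshold`.
#' @export
subsample_analysis <- function(rep, method = "vj_junction",
                               ratios = c(0.01, 0.05, 0.1, 0.25, 0.5, 1),
                               reps = 10L, seed = 1L,
                               indices = c("richness", "shannon", "simpson",
                                           "dominance", "chao1",
                                           "chao_shannon"),
                               alphas = NULL, threshold = NULL, neg = NULL,
                               delta = 0.01, k = 7L, L = 130L,
                               weight = "representatives") {
  stopifnot(inherits(rep, "Repertoire"), all(ratios > 0), all(ratios <= 1),
            reps >= 1)
  if (is.null(threshold) && method != "junction_only") {
    metric <- if (method == "vj_junction") "normalized_levenshtein" else "cosine"
    threshold <- calibrate_threshold_negation(rep, neg, metric = metric,
                                              delta = delta, k = k,
                                              L = L)$threshold
  }
  run_indices <- function(r) {
    part <- identify_clones(r, method = method, threshold = threshold,
                            k = k, L = L)
    ab <- abundance_from_partition(part, r, weight = weight)
    diversity_indices(ab, indices = indices, alphas = alphas)
  }
  full <- run_indices(rep)
  reads <- base::rep(seq_len(nrow(rep$records)), times = rep$records$count)
  n_reads <- length(reads)

  set.seed(seed)
  rows <- list()
  for (r in ratios) {
    m <- round(r * n_reads)
    for (it in seq_len(reps)) {
      if (r == 1) {
        vals <- full
      } else {
        if (m < 2) {
          warning("ratio ", r, " yields fewer than 2 reads; skipped",
                  call. = FALSE)
          break
        }
        take <- reads[sample.int(n_reads, m)]
        cnt <- tabulate(take, nbins = nrow(rep$records))
        sub <- subset_repertoire(rep, which(cnt > 0))
        sub$records$count <- cnt[cnt > 0]
        vals <- run_indices(sub)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        index = names(full), ratio = r, repetition = it,
        value = unname(vals), fold_change = unname(vals / full)
      )
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- stats::aggregate(fold_change ~ index + ratio, data = per_rep,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  fc <- tibble::tibble(index = agg$index, ratio = agg$ratio,
                       mean_fc = agg$fold_change[, "mean"],
                       sd_fc = agg$fold_change[, "sd"])
  structure(list(fold_changes = fc, full_values = full,
                 per_repetition = per_rep, ratios = ratios,
                 repetitions = reps, threshold = threshold, method = method),
            class = "SubsamplingResult")
}

#' Remove the 5' end of every sequence
#'
#' Emulates reads missing the first part of the V gene segment (e.g. primers
#' binding within FR1): the first `n_nt` nucleotides are removed from each
#' full-length sequence. Junctions are left untouched. Records whose sequence
#' would become empty are dropped with a warning.
#'
#' @param rep A [Repertoire][new_repertoire].
#' @param n_nt Number of 5' nucleotides to remove (default 70).
#' @return The truncated `Repertoire`.
#' @export
truncate_v_region <- function(rep, n_nt = 70L) {
  stopifnot(inherits(rep, "Repertoire"), n_nt >= 0)
  rec <- rep$records
  rec$sequence <- substr(rec$sequence, n_nt + 1L, nchar(rec$sequence))
  empty <- nchar(rec$sequence) == 0
  if (any(empty)) {
    warning(sum(empty), " record(s) shorter than ", n_nt,
            " nt dropped after truncation", call. = FALSE)
    rec <- rec[!empty, , drop = FALSE]
  }
  cmap <- rep$collapse_map[names(rep$collapse_map) %in% rec$sequence_id]
  structure(list(records = rec, collapsed = rep$collapsed, collapse_map = cmap),
            class = "Repertoire")
}

#' Rate of ambiguous V / J gene calls
#'
#' A call is ambiguous when the annotator reported two or more germline genes
#' with equal top alignment score (tracked in `v_tied_n` / `j_tied_n`).
#'
#' @param rep A [Repertoire][new_repertoire].
#' @return Named numeric vector `c(v_rate =, j_rate =)` of fractions in
#'   \[0, 1\].
#' @export
ambiguous_call_rate <- function(rep) {
  stopifnot(inherits(rep, "Repertoire"))
  c(v_rate = mean(rep$records$v_tied_n >= 2),
    j_rate = mean(rep$records$j_tied_n >= 2))
}

#' Potential false-negative singletons under alternative V/J calls
#'
#' For every singleton of a V/J-restricted partition, each alternative (V, J)
#' annotation pair (Cartesian product of the top `top_n` V and J candidates,
#' primary calls included) is tried: the singleton is a *potential false
#' negative* if, under some alternative annotation, it would join an existing
#' clone — operationalized as its junction lying within `threshold`
#' (normalized Levenshtein, complete linkage: the maximum distance to all
#' clone members) of a clone annotated with that V/J pair. These are
#' sequences the alignment-based method calls singletons although a slightly
#' different germline assignment would place them inside a clone.
#'
#' @param partition A [ClonalPartition][new_clonal_partition] from
#'   [cluster_vj_junction()].
#' @param rep The [Repertoire][new_repertoire] the partition was computed on
#'   (with `v_alternatives`/`j_alternatives` populated).
#' @param top_n Number of top-ranked candidates per gene to try (default 6).
#' @param threshold Junction distance threshold (defaults to the partition's
#'   own threshold).
#' @param rescue_partition Optional second partition (e.g. alignment-free);
#'   the fraction of potential false negatives it labels non-singleton is
#'   reported as `rescue_by_other_method`.
#' @return A list of class `FalseNegativeReport`: `n_singletons`,
#'   `n_potential_false_negative`, `rate`, `rescue_by_other_method` (or
#'   `NA`), and the ids of the flagged singletons.
#' @export
false_negative_singletons <- function(partition, rep, top_n = 6L,
                                      threshold = NULL,
                                      rescue_partition = NULL) {
  stopifnot(inherits(partition, "ClonalPartition"), inherits(rep, "Repertoire"))
  if (is.null(threshold)) threshold <- partition$threshold
  if (is.null(threshold)) stop("no threshold available", call. = FALSE)
  rec <- rep$records
  lab <- partition$assignment[rec$sequence_id]
  sizes <- table(lab)
  singles <- which(sizes[lab] == 1)
  if (length(singles) == 0) {
    return(structure(list(n_singletons = 0L, n_potential_false_negative = 0L,
                          rate = 0, rescue_by_other_method = NA_real_,
                          flagged_ids = character(0)),
                     class = "FalseNegativeReport"))
  }
  if (all(rec$v_alternatives == "" & rec$j_alternatives == "")) {
    warning("no alternative gene calls available; rate undefined",
            call. = FALSE)
    return(structure(list(n_singletons = length(singles),
                          n_potential_false_negative = NA_integer_,
                          rate = NA_real_, rescue_by_other_method = NA_real_,
                          flagged_ids = character(0)),
                     class = "FalseNegativeReport"))
  }
  # clones (size >= 2) indexed by their V/J pair
  clone_rows <- split(seq_len(nrow(rec)), lab)
  clone_rows <- clone_rows[lengths(clone_rows) >= 2]
  clone_key <- vapply(clone_rows, function(ix)
    paste(rec$v_call[ix[1]], rec$j_call[ix[1]], sep = "|"), character(1))

  top_cands <- function(primary, alts) {
    utils::head(unique(c(primary,
                         strsplit(alts, ",", fixed = TRUE)[[1]])), top_n)
  }
  flagged <- logical(length(singles))
  for (s in seq_along(singles)) {
    i <- singles[s]
    vs <- top_cands(rec$v_call[i], rec$v_alternatives[i])
    js <- top_cands(rec$j_call[i], rec$j_alternatives[i])
    keys <- as.vector(outer(vs, js, paste, sep = "|"))
    cand_clones <- which(clone_key %in% keys)
    for (cc in cand_clones) {
      dmax <- max(normalized_levenshtein_matrix(
        rec$junction[i], rec$junction[clone_rows[[cc]]]))
      if (dmax <= threshold) { flagged[s] <- TRUE; break }
    }
  }
  flagged_ids <- rec$sequence_id[singles[flagged]]
  rescue <- NA_real_
  if (!is.null(rescue_partition) && sum(flagged) > 0) {
    other <- singleton_labels(rescue_partition)
    rescue <- mean(other[flagged_ids] == "non_singleton")
  }
  structure(list(n_singletons = length(singles),
                 n_potential_false_negative = sum(flagged),
                 rate = mean(flagged),
                 rescue_by_other_method = rescue,
                 flagged_ids = flagged_ids),
            class = "FalseNegativeReport")
}

#' V-call mismatch rate between two annotation passes
#'
#' Fraction of records whose primary V call differs between two repertoires
#' holding the same record ids (e.g. an original and a 5'-truncated,
#' re-annotated version of the same data).
#'
#' @param annotated_truncated,annotated_full [Repertoire][new_repertoire]
#'   objects with identical `sequence_id` sets.
#' @return Mismatch fraction in \[0, 1\].
#' @export
mismatch_rate_vs_reference <- function(annotated_truncated, annotated_full) {
  stopifnot(inherits(annotated_truncated, "Repertoire"),
            inherits(annotated_full, "Repertoire"))
  a <- annotated_truncated$records
  b <- annotated_full$records
  if (!all(sort(a$sequence_id) == sort(b$sequence_id))) {
    stop("the two repertoires hold different record ids", call. = FALSE)
  }
  mean(a$v_call != b$v_call[match(a$sequence_id, b$sequence_id)])
}
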