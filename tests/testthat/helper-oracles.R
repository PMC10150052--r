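# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations, kept separate from the package's code
# paths.

# plain dynamic-programming Levenshtein distance
dp_levenshtein <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in 1:n) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in 1:m) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[m + 1]
}

random_dna_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive complete-linkage agglomeration: repeatedly merge the pair of clusters
# with the smallest maximum pairwise member distance, lowest member index
# first on ties, while that distance is <= h
oracle_complete_linkage <- function(d, h) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) < 2) break
    best <- NULL; best_d <- Inf
    for (x in seq_along(clusters)) {
      for (y in seq_along(clusters)) {
        if (x >= y) next
        dl <- max(d[clusters[[x]], clusters[[y]], drop = FALSE])
        key <- c(min(clusters[[x]][1], clusters[[y]][1]),
                 max(clusters[[x]][1], clusters[[y]][1]))
        if (dl < best_d ||
            (dl == best_d && (key[1] < best$key[1] ||
                              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best_d <- dl
          best <- list(x = x, y = y, key = key)
        }
      }
    }
    if (best_d > h) break
    merged <- sort(c(clusters[[best$x]], clusters[[best$y]]))
    clusters <- clusters[-c(best$x, best$y)]
    clusters <- c(clusters, list(merged))
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  # renumber by first appearance for comparability
  match(lab, unique(lab))
}

# expected MI by exhaustive enumeration over all label permutations
enumerate_emi <- function(a_lab, b_lab) {
  n <- length(a_lab)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  mi_of <- function(a, b) {
    ct <- table(a, b)
    tot <- sum(ct)
    ai <- rowSums(ct); bj <- colSums(ct)
    nz <- which(ct > 0, arr.ind = TRUE)
    nij <- ct[nz]
    sum(nij / tot * log(tot * nij / (ai[nz[, 1]] * bj[nz[, 2]])))
  }
  mean(vapply(perms(b_lab), function(p) mi_of(a_lab, p), numeric(1)))
}

partition_from_labels <- function(labels, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(labels))
  new_clonal_partition(stats::setNames(as.character(labels), ids),
                       method = "imported")
}

random_partition_labels <- function(n, k) {
  sample(seq_len(k), n, replace = TRUE)
}

# tiny repertoire builder for handcrafted cases
make_repertoire <- function(junctions, v = "IGHV1-1", j = "IGHJ1",
                            sequence = NULL, productive = TRUE, count = 1L,
                            truth = NA_character_) {
  n <- length(junctions)
  if (is.null(sequence)) {
    sequence <- paste0(strrep("A", 20), junctions, strrep("G", 10))
  }
  new_repertoire(tibble::tibble(
    sequence_id = paste0("r", seq_len(n)),
    sequence = rep_len(sequence, n),
    v_call = rep_len(v, n), j_call = rep_len(j, n),
    junction = junctions,
    productive = rep_len(productive, n),
    count = rep_len(count, n),
    truth_clone = rep_len(truth, n)
  ))
}
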