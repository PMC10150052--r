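#' Simulation configuration for ground-truth repertoires
#'
#' Describes a synthetic BCR heavy-chain repertoire: clonal families grown
#' from founder sequences along lineage trees with somatic hypermutation
#' (SHM), plus unrelated singleton founders and, separately, negation
#' sequences. Every full-length sequence is laid out as
#' `[V stub | junction | J stub]`, with one fixed random stub per germline
#' gene name, so that V/J calls, junction extraction and 3'-anchored
#' truncation all behave like annotated real data.
#'
#' @param n_clones Number of clonal families.
#' @param clone_size Clone-size distribution: `list("powerlaw", exponent)`
#'   (sizes 1..`max_clone_size` with probability proportional to
#'   size^-exponent), `list("geometric", p)` or `list("fixed", m)`.
#' @param singleton_fraction Fraction of final records that are unrelated
#'   singleton founders, in \[0, 1).
#' @param shm_rate Per-nucleotide substitution probability per lineage-tree
#'   edge.
#' @param tree_shape `"random_binary"` (random Yule-type splitting) or
#'   `"star"` (every cell one mutation step from the founder).
#' @param junction_length_range Integer pair of junction lengths (nt),
#'   drawn uniformly per founder.
#' @param v_gene_pool,j_gene_pool Germline gene name pools.
#' @param n_negation Number of negation sequences for
#'   [simulate_negation_set()].
#' @param seed Integer seed; the same config and seed give bit-identical
#'   output.
#' @param v_stub_len,j_stub_len Lengths (nt) of the V and J stubs flanking
#'   the junction (defaults 210 and 40, so a 130 nt 3'-anchored window
#'   always retains the junction).
#' @param max_clone_size Upper support of the power-law clone sizes.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_clones = 200L,
                              clone_size = list("powerlaw", 2),
                              singleton_fraction = 0.3,
                              shm_rate = 0.01,
                              tree_shape = c("random_binary", "star"),
                              junction_length_range = c(27L, 60L),
                              v_gene_pool = sprintf("IGHV%d-%d",
                                                    rep(1:5, each = 3),
                                                    rep(c(2, 18, 69), 5)),
                              j_gene_pool = paste0("IGHJ", 1:6),
                              n_negation = 200L,
                              seed = 1L,
                              v_stub_len = 210L, j_stub_len = 40L,
                              max_clone_size = 50L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_clones >= 1, shm_rate >= 0, shm_rate <= 1,
            singleton_fraction >= 0, singleton_fraction < 1,
            length(junction_length_range) == 2,
            junction_length_range[1] <= junction_length_range[2],
            length(v_gene_pool) > 0, length(j_gene_pool) > 0)
  structure(list(n_clones = as.integer(n_clones), clone_size = clone_size,
                 singleton_fraction = singleton_fraction, shm_rate = shm_rate,
                 tree_shape = tree_shape,
                 junction_length_range = as.integer(junction_length_range),
                 v_gene_pool = v_gene_pool, j_gene_pool = j_gene_pool,
                 n_negation = as.integer(n_negation), seed = as.integer(seed),
                 v_stub_len = as.integer(v_stub_len),
                 j_stub_len = as.integer(j_stub_len),
                 max_clone_size = as.integer(max_clone_size)),
            class = "SimulationConfig")
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# one fixed random stub per germline gene name, derived from config$seed only
gene_stubs <- function(config) {
  set.seed(config$seed)
  v <- vapply(config$v_gene_pool, function(g) random_dna(config$v_stub_len),
              character(1))
  j <- vapply(config$j_gene_pool, function(g) random_dna(config$j_stub_len),
              character(1))
  list(v = v, j = j)
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

draw_clone_sizes <- function(config) {
  cs <- config$clone_size
  n <- config$n_clones
  switch(cs[[1]],
         powerlaw = {
           supp <- seq_len(config$max_clone_size)
           sample(supp, n, replace = TRUE, prob = supp^(-cs[[2]]))
         },
         geometric = 1L + stats::rgeom(n, cs[[2]]),
         fixed = base::rep(as.integer(cs[[2]]), n),
         stop("unknown clone size distribution: ", cs[[1]], call. = FALSE))
}

# grow a lineage from a founder; returns leaf sequences and parent pointers
grow_lineage <- function(founder, m, shm_rate, shape) {
  if (m == 1) {
    return(list(leaves = founder, tree = data.frame(node = 1L, parent = 0L)))
  }
  if (shape == "star") {
    leaves <- vapply(seq_len(m), function(i) mutate_seq(founder, shm_rate),
                     character(1))
    return(list(leaves = leaves,
                tree = data.frame(node = seq_len(m + 1L) ,
                                  parent = c(0L, base::rep(1L, m)))))
  }
  seqs <- founder
  parent <- 0L
  is_leaf <- TRUE
  while (sum(is_leaf) < m) {
    leaf_ids <- which(is_leaf)
    split_id <- leaf_ids[sample.int(length(leaf_ids), 1)]
    for (child in 1:2) {
      seqs <- c(seqs, mutate_seq(seqs[split_id], shm_rate))
      parent <- c(parent, split_id)
      is_leaf <- c(is_leaf, TRUE)
    }
    is_leaf[split_id] <- FALSE
  }
  list(leaves = seqs[is_leaf],
       tree = data.frame(node = seq_along(seqs), parent = parent))
}

#' Simulate a ground-truth repertoire
#'
#' For every clonal family a founder is drawn (random V and J gene from the
#' pools, random junction of random length), a lineage tree of the drawn
#' clone size is grown, and each tree edge mutates every position of the
#' full-length sequence independently with probability `shm_rate` — so
#' mutations fall in junction and non-junction positions alike. Tree leaves
#' become sequence records annotated with the *true* V/J calls and the true
#' clone label; junctions are extracted from the mutated sequence by
#' position. Unrelated singleton founders are appended at the configured
#' fraction, each its own truth clone.
#'
#' @param config A [simulation_config()].
#' @return A list with `repertoire` (a [Repertoire][new_repertoire]) and
#'   `truth` (class `GroundTruth`: `assignment`, a named id -> label vector,
#'   and `trees`, per-clone parent-pointer tables).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  stubs <- gene_stubs(config)     # also seeds the RNG with config$seed
  sizes <- draw_clone_sizes(config)
  jlr <- config$junction_length_range

  rows <- list(); trees <- list()
  counter <- 0L
  for (ci in seq_along(sizes)) {
    v <- sample(config$v_gene_pool, 1)
    j <- sample(config$j_gene_pool, 1)
    jlen <- sample(jlr[1]:jlr[2], 1)
    founder <- paste0(stubs$v[v], random_dna(jlen), stubs$j[j])
    lin <- grow_lineage(founder, sizes[ci], config$shm_rate, config$tree_shape)
    clone_lab <- sprintf("C%04d", ci)
    trees[[clone_lab]] <- lin$tree
    for (leaf in lin$leaves) {
      counter <- counter + 1L
      rows[[counter]] <- list(
        sequence_id = sprintf("S%06d", counter), sequence = leaf,
        v_call = v, j_call = j,
        junction = substr(leaf, config$v_stub_len + 1L,
                          config$v_stub_len + jlen),
        productive = TRUE, count = 1L, truth_clone = clone_lab
      )
    }
  }
  n_clonal <- counter
  f <- config$singleton_fraction
  n_singletons <- if (f > 0) round(f / (1 - f) * n_clonal) else 0L
  for (si in seq_len(n_singletons)) {
    counter <- counter + 1L
    v <- sample(config$v_gene_pool, 1)
    j <- sample(config$j_gene_pool, 1)
    jlen <- sample(jlr[1]:jlr[2], 1)
    seq <- paste0(stubs$v[v], random_dna(jlen), stubs$j[j])
    lab <- sprintf("SG%05d", si)
    rows[[counter]] <- list(
      sequence_id = sprintf("S%06d", counter), sequence = seq,
      v_call = v, j_call = j,
      junction = substr(seq, config$v_stub_len + 1L, config$v_stub_len + jlen),
      productive = TRUE, count = 1L, truth_clone = lab
    )
    trees[[lab]] <- data.frame(node = 1L, parent = 0L)
  }
  records <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  repx <- new_repertoire(records)
  truth <- structure(
    list(assignment = stats::setNames(records$truth_clone,
                                      records$sequence_id),
         trees = trees),
    class = "GroundTruth")
  list(repertoire = repx, truth = truth)
}

#' Simulate a negation set
#'
#' Draws `n_negation` founder-style sequences — the same germline stub pools
#' as the repertoire, fresh random junctions — from an independent seed
#' stream, emulating sequences sampled from unrelated individuals. Junctions
#' identical to a junction of `rep` (if given) are rejection-sampled away, so
#' the negation set is clonally unrelated by construction.
#'
#' @param config The [simulation_config()] used for the repertoire.
#' @param rep Optional [Repertoire][new_repertoire] whose junctions must be
#'   avoided.
#' @return A [Repertoire][new_repertoire] of negation records (ids prefixed
#'   `NEG`).
#' @export
simulate_negation_set <- function(config, rep = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  stubs <- gene_stubs(config)
  set.seed((config$seed + 999983L) %% .Machine$integer.max)
  forbidden <- if (is.null(rep)) character(0) else unique(rep$records$junction)
  jlr <- config$junction_length_range
  n <- config$n_negation
  if (n == 0) {
    return(new_repertoire(tibble::tibble(
      sequence_id = character(0), sequence = character(0),
      v_call = character(0), j_call = character(0),
      junction = character(0), productive = logical(0))))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- sample(config$v_gene_pool, 1)
    j <- sample(config$j_gene_pool, 1)
    repeat {
      jx <- random_dna(sample(jlr[1]:jlr[2], 1))
      if (!(jx %in% forbidden)) break
    }
    rows[[i]] <- list(sequence_id = sprintf("NEG%05d", i),
                      sequence = paste0(stubs$v[v], jx, stubs$j[j]),
                      v_call = v, j_call = j, junction = jx,
                      productive = TRUE, count = 1L)
  }
  new_repertoire(do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE))))
}

#' Inject V-call ambiguity and corruption
#'
#' Emulates the annotation artifacts of 5'-truncated reads: with probability
#' `v_ambiguous_rate` a record gains 1-5 additional top-score-tied V
#' candidates (the true call stays primary); with probability `corrupt_rate`
#' the primary V call is replaced by a uniformly drawn *different* gene from
#' the repertoire's gene pool and the true call is demoted to the head of the
#' alternatives. Truth labels and sequences are untouched, so alignment-free
#' clustering is unaffected by construction.
#'
#' @param rep A [Repertoire][new_repertoire].
#' @param v_ambiguous_rate,corrupt_rate Rates in \[0, 1\].
#' @param seed Integer seed.
#' @return The modified `Repertoire`.
#' @export
inject_annotation_ambiguity <- function(rep, v_ambiguous_rate = 0,
                                        corrupt_rate = 0, seed = 1L) {
  stopifnot(inherits(rep, "Repertoire"),
            v_ambiguous_rate >= 0, v_ambiguous_rate <= 1,
            corrupt_rate >= 0, corrupt_rate <= 1)
  rec <- rep$records
  pool <- unique(rec$v_call)
  set.seed(seed)
  for (i in seq_len(nrow(rec))) {
    if (v_ambiguous_rate > 0 && stats::runif(1) < v_ambiguous_rate) {
      n_extra <- sample(1:5, 1)
      others <- setdiff(pool, rec$v_call[i])
      extra <- sample(others, min(n_extra, length(others)))
      rec$v_alternatives[i] <- paste(
        c(extra, if (rec$v_alternatives[i] != "") rec$v_alternatives[i]),
        collapse = ",")
      rec$v_tied_n[i] <- 1L + length(extra)
    }
    if (corrupt_rate > 0 && stats::runif(1) < corrupt_rate) {
      others <- setdiff(pool, rec$v_call[i])
      if (length(others) > 0) {
        wrong <- sample(others, 1)
        rec$v_alternatives[i] <- paste(
          c(rec$v_call[i], if (rec$v_alternatives[i] != "") rec$v_alternatives[i]),
          collapse = ",")
        rec$v_call[i] <- wrong
      }
    }
  }
  structure(list(records = rec, collapsed = rep$collapsed,
                 collapse_map = rep$collapse_map), class = "Repertoire")
}
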