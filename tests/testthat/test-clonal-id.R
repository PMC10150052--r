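test_that("junction-only clustering groups exact junction matches", {
  rep <- make_repertoire(c("TGTAAA", "TGTAAA", "TGTCCC"))
  p <- cluster_junction_only(rep)
  sizes <- sort(as.vector(table(p$assignment)))
  expect_equal(sizes, c(1, 2))
  # all distinct -> all singletons
  p2 <- cluster_junction_only(make_repertoire(c("TGTAAA", "TGTCCC", "TGTGGG")))
  expect_true(all(table(p2$assignment) == 1))
  # after collapsing, every clone has exactly one representative
  col <- collapse_identical_junctions(make_repertoire(rep("TGTAAA", 4)), 1)
  expect_true(all(table(cluster_junction_only(col)$assignment) == 1))
})

test_that("the negation threshold is the lower delta-quantile", {
  nn <- seq(0.30, 0.50, length.out = 100)
  expect_equal(clonediv:::negation_threshold(nn, 0.01), 0.30)
  expect_equal(clonediv:::negation_threshold(nn, 0.05), sort(nn)[5])
  # delta -> 0 gives (at most) the minimum
  expect_lte(clonediv:::negation_threshold(nn, 1e-9), min(nn))
  expect_equal(clonediv:::negation_threshold(rep(0.4, 50), 0.01), 0.4)
})

test_that("negation calibration searches nearest neighbors within V/J groups", {
  rep <- make_repertoire(c("TGTGCGAGAGGG", "TGTGCGAGATTT"),
                         v = c("IGHV1-1", "IGHV2-2"))
  neg <- make_repertoire(c("TGTGCGAGAGGT", "TGTACGTACGTT"),
                         v = c("IGHV1-1", "IGHV5-5"))
  neg$records$sequence_id <- c("n1", "n2")
  cal <- calibrate_threshold_negation(rep, neg, "normalized_levenshtein",
                                      delta = 0.4)
  # n1 has a same-V/J neighbor at 1 edit; n2 has no group -> distance 1
  expect_equal(sort(cal$negation_nn_distances),
               c(normalized_levenshtein("TGTGCGAGAGGT", "TGTGCGAGAGGG"), 1))
  expect_equal(cal$threshold, min(cal$negation_nn_distances))
  expect_error(calibrate_threshold_negation(rep, simulate_negation_set(
    simulation_config(n_negation = 0)), "normalized_levenshtein"),
    "empty")
})

test_that("bimodal calibration finds the valley between two modes", {
  set.seed(9)
  nn <- c(rnorm(300, 0.05, 0.01), rnorm(300, 0.45, 0.02))
  thr <- clonediv:::bimodal_valley(nn)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.4)
  # invariant under input order
  expect_equal(thr, clonediv:::bimodal_valley(sample(nn)))
  # a single tight mode fails with guidance
  expect_error(clonediv:::bimodal_valley(rnorm(300, 0.3, 0.01)), "negation")
})

test_that("V/J-restricted clustering respects the group constraint", {
  # identical junctions, same V/J -> one clone
  same <- make_repertoire(c("TGTGCGAGA", "TGTGCGAGA"))
  expect_length(unique(cluster_vj_junction(same, 0.1)$assignment), 1)
  # identical junctions, different V genes -> separate clones
  diffv <- make_repertoire(c("TGTGCGAGA", "TGTGCGAGA"),
                           v = c("IGHV1-1", "IGHV2-2"))
  expect_length(unique(cluster_vj_junction(diffv, 0.1)$assignment), 2)
})

test_that("within-group clustering follows complete linkage", {
  # distances about {0.05, 0.05, 0.3}: pair merges, distant third stays out
  jx <- c(strrep("ACGT", 10),
          paste0(substr(strrep("ACGT", 10), 1, 39), "A"),
          paste0(substr(strrep("ACGT", 10), 1, 38), "AA"))
  far <- paste0(strrep("TTGG", 7), "ACGTACGTACGT")
  rep <- make_repertoire(c(jx[1], jx[2], far))
  p <- cluster_vj_junction(rep, 0.1)
  expect_equal(p$assignment[["r1"]], p$assignment[["r2"]])
  expect_false(p$assignment[["r3"]] == p$assignment[["r1"]])
})

test_that("V/J clustering partitions match a naive agglomeration oracle", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    jx <- vapply(seq_len(n), function(.) random_dna_string(sample(6:14, 1)),
                 character(1))
    rep <- make_repertoire(jx)
    h <- runif(1)
    p <- cluster_vj_junction(rep, h)
    d <- normalized_levenshtein_matrix(jx)
    oracle <- oracle_complete_linkage(d, h)
    mine <- as.integer(factor(p$assignment[rep$records$sequence_id],
                              levels = unique(p$assignment[rep$records$sequence_id])))
    expect_equal(outer(mine, mine, "=="), outer(oracle, oracle, "=="),
                 ignore_attr = TRUE)
  }
})

test_that("alignment-free clustering keeps identical sequences together and
           never merges k-mer-disjoint families", {
  seqs <- c(rep(strrep("ACGT", 40), 5), strrep("TTTTGGGG", 20))
  rep <- make_repertoire(vapply(seq_along(seqs), function(.)
    random_dna_string(12), character(1)), sequence = seqs)
  p <- cluster_alignment_free(rep, threshold = 0.5, k = 7, L = 130)
  expect_length(unique(p$assignment[paste0("r", 1:5)]), 1)
  expect_false(p$assignment[["r6"]] %in% p$assignment[paste0("r", 1:5)])
})

test_that("alignment-free partitions depend on the idf corpus", {
  set.seed(44)
  base <- vapply(1:8, function(.) random_dna_string(60), character(1))
  rep <- make_repertoire(vapply(1:8, function(.) random_dna_string(12),
                                character(1)), sequence = base)
  p1 <- cluster_alignment_free(rep, 0.7, k = 5, L = 40)
  extras <- vapply(1:30, function(.) random_dna_string(60), character(1))
  p2 <- cluster_alignment_free(rep, 0.7, k = 5, L = 40, extra_corpus = extras)
  # the partition is allowed to change; distances certainly do
  v1 <- tfidf_vectorize(base, k = 5, L = 40)
  v2 <- tfidf_vectorize(c(base, extras), k = 5, L = 40)
  expect_false(isTRUE(all.equal(v1$idf_weights,
                                v2$idf_weights[names(v1$idf_weights)])))
})

test_that("identify_clones is deterministic and records provenance", {
  cfg <- simulation_config(n_clones = 15, n_negation = 40, seed = 2)
  sim <- simulate_repertoire(cfg)
  neg <- simulate_negation_set(cfg, sim$repertoire)
  rc <- collapse_identical_junctions(sim$repertoire, seed = 1)
  a <- identify_clones(rc, "vj_junction", neg = neg)
  b <- identify_clones(rc, "vj_junction", neg = neg)
  expect_identical(a$assignment, b$assignment)
  expect_equal(a$params$calibration$delta, 0.01)
  expect_true(!is.null(a$threshold))
  # junction_only ignores thresholds entirely
  jo <- identify_clones(rc, "junction_only")
  expect_null(jo$threshold)
})

test_that("with no hypermutation every method recovers the ground truth", {
  cfg <- simulation_config(n_clones = 12, shm_rate = 0, n_negation = 60,
                           seed = 8, singleton_fraction = 0.2)
  sim <- simulate_repertoire(cfg)
  neg <- simulate_negation_set(cfg, sim$repertoire)
  truth <- new_clonal_partition(sim$truth$assignment, "truth")
  rc <- collapse_identical_junctions(sim$repertoire, 1)
  for (m in c("junction_only", "vj_junction", "alignment_free")) {
    p <- expand_partition(identify_clones(rc, m, neg = neg), rc)
    expect_equal(adjusted_mutual_information(p, truth), 1,
                 tolerance = 1e-10)
  }
})

test_that("junction-only refines the V/J method when V/J calls are
           clone-consistent", {
  cfg <- simulation_config(n_clones = 20, n_negation = 60, seed = 13)
  sim <- simulate_repertoire(cfg)
  neg <- simulate_negation_set(cfg, sim$repertoire)
  rc <- collapse_identical_junctions(sim$repertoire, 1)
  jo <- expand_partition(cluster_junction_only(rc), rc)
  vjj <- expand_partition(identify_clones(rc, "vj_junction", neg = neg), rc)
  ids <- names(jo$assignment)
  # every junction-only clone lies inside a single vjj clone
  split_by <- split(ids, jo$assignment[ids])
  for (grp in split_by) {
    expect_length(unique(vjj$assignment[grp]), 1)
  }
})
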