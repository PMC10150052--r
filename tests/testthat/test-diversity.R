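test_that("abundances derived from partitions count what they should", {
  rep <- make_repertoire(c("TGTAAA", "TGTAAC", "TGTCCC"),
                         count = c(3L, 1L, 1L))
  p <- partition_from_labels(c("c1", "c1", "c2"), rep$records$sequence_id)
  ab <- abundance_from_partition(p, rep, weight = "representatives")
  expect_equal(sort(ab$p), c(1 / 3, 2 / 3))
  expect_equal(ab$f1, 1); expect_equal(ab$f2, 1)
  abw <- abundance_from_partition(p, rep, weight = "copy_counts")
  expect_equal(sort(abw$p), c(0.2, 0.8))
  # two records with copy numbers {3, 1} in separate clones
  two <- make_repertoire(c("TGTAAA", "TGTCCC"), count = c(3L, 1L))
  p2 <- partition_from_labels(c("a", "b"), two$records$sequence_id)
  expect_equal(sort(abundance_from_partition(p2, two, "copy_counts")$p),
               c(0.25, 0.75))
  single <- abundance_from_partition(
    partition_from_labels(c("c", "c", "c"), rep$records$sequence_id), rep)
  expect_equal(single$S_obs, 1)
  expect_equal(single$p, 1)
})

test_that("Hill numbers recover the classical indices", {
  ab <- abundance_vector(c(2, 1, 1))       # p = (0.5, 0.25, 0.25)
  expect_equal(hill_diversity(ab, 0), 3)                    # richness
  expect_equal(hill_diversity(ab, 1), 2^1.5)                # exp(H)
  expect_equal(hill_diversity(ab, 2), 1 / simpson_index(ab))
  expect_equal(hill_diversity(ab, Inf), 1 / dominance(ab))
  expect_equal(shannon_entropy(ab), 1.5 * log(2))
  expect_equal(simpson_index(ab), 0.375)
  expect_equal(dominance(ab), 0.5)
  expect_equal(richness(ab), 3)
  # uniform abundances: every order gives S
  u <- abundance_vector(rep(4, 7))
  expect_true(all(abs(hill_diversity(u, c(0, 0.5, 1, 2, 10, Inf)) - 7) < 1e-9))
  # two even clones at order 2
  expect_equal(hill_diversity(abundance_vector(c(5, 5)), 2), 2)
  expect_error(hill_diversity(ab, -1), "non-negative")
})

test_that("Hill numbers are bounded, monotone in alpha and continuous at 1", {
  set.seed(71)
  alphas <- c(0, 0.25, 0.5, 0.9, 1, 1.1, 2, 5, 20, 60, 200, Inf)
  for (i in 1:200) {
    S <- sample(2:40, 1)
    ab <- abundance_vector(as.numeric(sample(1:50, S, replace = TRUE)))
    d <- hill_diversity(ab, alphas)
    expect_true(all(d >= 1 - 1e-9))
    expect_true(all(d <= ab$S_obs + 1e-9))
    expect_true(all(diff(d) <= 1e-9))     # non-increasing in alpha
  }
  ab <- abundance_vector(c(7, 3, 2, 1))
  eh <- exp(shannon_entropy(ab))
  expect_lt(abs(hill_diversity(ab, 1 + 1e-6) - eh), 1e-6 * eh)
  expect_lt(abs(hill_diversity(ab, 1 - 1e-6) - eh), 1e-6 * eh)
  expect_equal(log(hill_diversity(ab, 1)), shannon_entropy(ab))
  # Simpson consistency on random vectors
  set.seed(72)
  for (i in 1:20) {
    ab <- abundance_vector(as.numeric(sample(1:30, 10, replace = TRUE)))
    expect_equal(simpson_index(ab) * hill_diversity(ab, 2), 1)
  }
})

test_that("evenness behaves like a normalized Hill ratio", {
  expect_equal(evenness(abundance_vector(rep(3, 5))), 1)
  ab <- abundance_vector(c(2, 1, 1))
  expect_equal(evenness(ab, 1, 0), 2^1.5 / 3)
  expect_equal(evenness(ab, 2, 1), (1 / 0.375) / 2^1.5)
  # dominated repertoire approaches 1/S
  dom <- abundance_vector(c(1e6, rep(1, 9)))
  expect_lt(evenness(dom), 0.11)
  expect_gte(evenness(dom), 1 / 10)
  expect_error(evenness(ab, 1, 1), "a > b")
  set.seed(73)
  for (i in 1:20) {
    ab <- abundance_vector(as.numeric(sample(1:40, 8, replace = TRUE)))
    e <- evenness(ab)
    expect_gte(e, 1 / ab$S_obs - 1e-12)
    expect_lte(e, 1 + 1e-12)
  }
})

test_that("diversity profiles span richness to inverse dominance", {
  ab <- abundance_vector(c(8, 4, 2, 1, 1))
  prof <- diversity_profile(ab, N = 41)
  expect_equal(nrow(prof), 41)
  expect_equal(prof$D[1], richness(ab))
  expect_equal(prof$D[41], 1 / dominance(ab))
  mid <- which(prof$A == 0)
  expect_equal(prof$D[mid], exp(shannon_entropy(ab)))
  expect_true(all(diff(prof$alpha) > 0))
  expect_true(all(diff(prof$D) <= 1e-9))
  u <- diversity_profile(abundance_vector(rep(2, 6)), N = 11)
  expect_true(all(abs(u$D - 6) < 1e-9))
})

test_that("Chao1 follows the bias-corrected formula", {
  # independent arithmetic: S_obs + f1(f1-1)/(2(f2+1))
  expect_equal(chao1_richness(abundance_vector(c(rep(1, 3), rep(2, 1), 3:8))),
               10 + 3 * 2 / (2 * 2))
  expect_equal(chao1_richness(abundance_vector(c(1, 1, 3, 4, 5))),
               5 + 2 * 1 / 2)  # f1 = 2, f2 = 0
  # f1 = 0 -> S_obs exactly
  no_singletons <- abundance_vector(c(2, 3, 4))
  expect_equal(chao1_richness(no_singletons), 3)
  set.seed(74)
  for (i in 1:50) {
    ab <- abundance_vector(as.numeric(sample(1:6, 15, replace = TRUE)))
    expect_gte(chao1_richness(ab), richness(ab))
    if (ab$f1 <= 1) expect_equal(chao1_richness(ab), richness(ab))
  }
})

test_that("the coverage-adjusted Shannon estimator matches direct evaluation", {
  # single clone observed n times: coverage 1, p-tilde 1, estimate 0
  expect_equal(chao_shannon(abundance_vector(10)), 0)
  # all singletons: coverage 0 -> undefined
  expect_error(chao_shannon(abundance_vector(c(1, 1, 1))), "singletons")
  # counts (5,3,2): f1 = 0, C = 1; term-wise oracle
  ab <- abundance_vector(c(5, 3, 2))
  p <- c(0.5, 0.3, 0.2)
  oracle <- sum(-p * log(p) / (1 - (1 - p)^10))
  expect_equal(chao_shannon(ab), oracle)
  # with singletons the correction only increases the estimate
  set.seed(75)
  for (i in 1:50) {
    S <- sample(5:30, 1)
    pr <- rgamma(S, 0.6); pr <- pr / sum(pr)
    x <- table(factor(sample(S, 60, TRUE, pr), levels = 1:S))
    x <- as.numeric(x[x > 0])
    ab <- abundance_vector(x)
    if (ab$f1 > 0 && ab$f1 < ab$n) {
      expect_gte(chao_shannon(ab), shannon_entropy(ab))
    }
  }
  # the quotient variant is available but differs
  ab2 <- abundance_vector(c(4, 2, 1))
  expect_false(isTRUE(all.equal(chao_shannon(ab2),
                                chao_shannon(ab2, adjust = "quotient"))))
})

test_that("clonal composition fractions partition the repertoire", {
  cs <- clonal_composition_summary(abundance_vector(c(6, 3, 1)))
  expect_equal(cs$dominant, 0.6)
  expect_equal(cs$expanded, 0.4)
  expect_equal(cs$non_expanded, 0)
  flat <- clonal_composition_summary(abundance_vector(rep(1, 200)))
  expect_equal(flat$dominant, 0.005)
  expect_equal(flat$expanded, 0)
  expect_equal(flat$non_expanded, 0.995)
  set.seed(76)
  for (i in 1:30) {
    ab <- abundance_vector(as.numeric(sample(1:100, 20, replace = TRUE)))
    cs <- clonal_composition_summary(ab)
    expect_equal(cs$dominant + cs$expanded + cs$non_expanded, 1)
  }
})
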