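airr_fixture <- function(path, extra = NULL) {
  df <- data.frame(
    sequence_id = c("a1", "a2", "a3"),
    sequence = c("ACGTACGTAAACCGT", "ACGTTCGTAAACCGA", "TTTTACGTAAACCGG"),
    v_call = c("IGHV1-2*01", "IGHV1-2*02", "IGHV3-11*01,IGHV3-23*01"),
    j_call = c("IGHJ4*02", "IGHJ4*02", "IGHJ6*01"),
    junction = c("TGTGCGAGATGG", "TGTGCGAGATGG", "TGTGCGAAATGG"),
    productive = c("T", "T", "F"),
    duplicate_count = c(2, 1, 1),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- extra(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("AIRR TSV ingestion preserves rows, order and copy numbers", {
  f <- airr_fixture(withr::local_tempfile(fileext = ".tsv"))
  rep <- read_repertoire(f)
  expect_s3_class(rep, "Repertoire")
  expect_false(rep$collapsed)
  expect_equal(rep$records$sequence_id, c("a1", "a2", "a3"))
  expect_equal(rep$records$count, c(2L, 1L, 1L))
  # allele suffixes stripped by default
  expect_equal(rep$records$v_call[1], "IGHV1-2")
  expect_equal(rep$records$v_call[3], "IGHV3-11,IGHV3-23")
  expect_equal(rep$records$v_tied_n, c(1L, 1L, 2L))
})

test_that("schema violations are reported by name", {
  f <- airr_fixture(withr::local_tempfile(fileext = ".tsv"),
                    extra = function(df) df[, setdiff(names(df), "junction")])
  expect_error(read_repertoire(f), "junction")

  f2 <- airr_fixture(withr::local_tempfile(fileext = ".tsv"),
                     extra = function(df) { df$sequence_id[2] <- "a1"; df })
  expect_error(read_repertoire(f2), "a1")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sequence_id\tsequence", f3)
  expect_error(read_repertoire(f3), "empty")
})

test_that("fasta+table dialect matches sequences by id", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  df <- data.frame(sequence_id = c("s1", "s2"), v_call = "IGHV1-2",
                   j_call = "IGHJ4", junction = c("TGTAAA", "TGTCCC"),
                   productive = "T")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(">s1", "ACGTACGT", ">s2", "GGGTACGT"), fa)
  rep <- read_repertoire(tsv, dialect = "fasta_table", fasta = fa)
  expect_equal(rep$records$sequence, c("ACGTACGT", "GGGTACGT"))
})

test_that("productive filtering keeps order and tolerates empty results", {
  rep <- make_repertoire(c("TGTAAA", "TGTCCC", "TGTGGG"),
                         productive = c(TRUE, FALSE, TRUE))
  out <- filter_productive(rep)
  expect_equal(out$records$sequence_id, c("r1", "r3"))
  expect_length(filter_productive(filter_productive(rep)), 2)
  none <- make_repertoire("TGTAAA", productive = FALSE)
  expect_message(empty <- filter_productive(none), "no productive")
  expect_length(empty, 0)
})

test_that("tied gene calls resolve to the alphabetically first candidate", {
  rep <- make_repertoire(c("TGTAAA", "TGTCCC"),
                         v = c("IGHV3-23,IGHV3-11", "IGHV1-2"))
  out <- resolve_ambiguous_calls(rep)
  expect_equal(out$records$v_call, c("IGHV3-11", "IGHV1-2"))
  expect_equal(out$records$v_alternatives[1], "IGHV3-23")
  expect_equal(out$records$v_tied_n, c(2L, 1L))
  # three-way tie
  rep3 <- make_repertoire("TGTAAA", v = "IGHV9-9,IGHV2-5,IGHV4-4")
  expect_equal(resolve_ambiguous_calls(rep3)$records$v_call, "IGHV2-5")
  # single candidate untouched
  expect_identical(resolve_ambiguous_calls(rep3)$records$j_call, "IGHJ1")
})

test_that("junction collapsing merges duplicates and conserves copy number", {
  rep <- make_repertoire(c("TGTAAA", "TGTCCC", "TGTAAA", "TGTGGG"),
                         count = c(1L, 2L, 3L, 1L))
  col <- collapse_identical_junctions(rep, seed = 1)
  expect_true(col$collapsed)
  expect_length(col, 3)
  expect_false(anyDuplicated(col$records$junction) > 0)
  expect_equal(sum(col$records$count), sum(rep$records$count))
  expect_equal(sum(lengths(col$collapse_map)), length(rep))
  expect_equal(sort(col$collapse_map[[which(col$records$junction == "TGTAAA")]]),
               c("r1", "r3"))
  expect_error(collapse_identical_junctions(col, seed = 1), "already collapsed")
})

test_that("collapse group structure is seed-independent", {
  rep <- make_repertoire(rep(c("TGTAAA", "TGTCCC"), each = 4))
  a <- collapse_identical_junctions(rep, seed = 1)
  b <- collapse_identical_junctions(rep, seed = 99)
  expect_equal(unname(lapply(a$collapse_map, sort)),
               unname(lapply(b$collapse_map, sort)))
})

test_that("filtering and collapsing commute on the productive subset", {
  # collapsing after filtering groups the productive ids exactly as
  # collapsing everything and then restricting each group to productive ids
  set.seed(7)
  for (i in 1:5) {
    jx <- sample(c("TGTAAA", "TGTCCC", "TGTGGG", "TGTTTT"), 12, replace = TRUE)
    rep <- make_repertoire(jx, productive = sample(c(TRUE, FALSE), 12, TRUE))
    prod_ids <- rep$records$sequence_id[rep$records$productive]
    a <- collapse_identical_junctions(filter_productive(rep), seed = 3)
    groups_a <- lapply(a$collapse_map, sort)
    all_groups <- collapse_identical_junctions(rep, seed = 3)$collapse_map
    groups_b <- Filter(length, lapply(all_groups,
                                      function(g) sort(intersect(g, prod_ids))))
    canon <- function(gs) sort(vapply(gs, paste, character(1), collapse = "+"))
    expect_equal(canon(groups_a), canon(groups_b), ignore_attr = TRUE)
  }
})

test_that("partitions round-trip through TSV", {
  p <- partition_from_labels(c("x", "x", "y"), ids = c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(p, f)
  q <- read_partition(f)
  expect_equal(q$assignment, p$assignment)
  empty <- new_clonal_partition(setNames(character(0), character(0)),
                                method = "imported")
  write_partition(empty, f)
  expect_equal(nrow(read.delim(f)), 0)
})

test_that("repertoires round-trip through AIRR-style TSV", {
  rep <- make_repertoire(c("TGTAAA", "TGTCCC"), count = c(3L, 1L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire(rep, f)
  back <- read_repertoire(f)
  expect_equal(back$records$junction, rep$records$junction)
  expect_equal(back$records$count, rep$records$count)
  expect_equal(back$records$productive, rep$records$productive)
})
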