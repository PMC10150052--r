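#' Read an annotated repertoire table
#'
#' Reads an AIRR Rearrangement TSV (or a FASTA file paired with an annotation
#' table) into a [Repertoire][new_repertoire]. The AIRR dialect expects the
#' columns `sequence_id`, `sequence`, `v_call`, `j_call`, `junction` and
#' `productive`; `duplicate_count` (copy number), `v_alternatives`,
#' `j_alternatives` and `truth_clone` are honored when present. Comma-separated
#' gene calls ("IGHV1-2*01,IGHV1-3*02") are interpreted as top-score-tied
#' candidates and can be resolved with [resolve_ambiguous_calls()].
#'
#' @param path Path to the TSV file (for `dialect = "airr_tsv"`) or to the
#'   annotation TSV whose sequences live in `fasta` (for
#'   `dialect = "fasta_table"`; the table then needs no `sequence` column and
#'   sequences are matched by `sequence_id` against FASTA headers).
#' @param dialect Input dialect, `"airr_tsv"` (default) or `"fasta_table"`.
#' @param fasta FASTA path, required for `dialect = "fasta_table"`.
#' @param collapse_alleles Strip "*01"-style allele suffixes so that clones are
#'   defined at the gene level (default `TRUE`).
#' @return A [Repertoire][new_repertoire] with `collapsed = FALSE`; row order
#'   of the input is preserved.
#' @export
read_repertoire <- function(path, dialect = c("airr_tsv", "fasta_table"),
                            fasta = NULL, collapse_alleles = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0) stop("empty repertoire file: ", path, call. = FALSE)

  if (dialect == "fasta_table") {
    if (is.null(fasta)) stop("dialect 'fasta_table' requires `fasta`", call. = FALSE)
    seqs <- read_fasta(fasta)
    if (!"sequence_id" %in% names(tab)) {
      stop("missing required column(s): sequence_id", call. = FALSE)
    }
    miss <- setdiff(tab$sequence_id, names(seqs))
    if (length(miss) > 0) {
      stop("sequence_id not found in FASTA: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    tab$sequence <- unname(seqs[tab$sequence_id])
  }

  required <- c("sequence_id", "sequence", "v_call", "j_call", "junction",
                "productive")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab$productive <- toupper(tab$productive) %in% c("T", "TRUE", "1", "YES")
  if ("duplicate_count" %in% names(tab) && !"count" %in% names(tab)) {
    tab$count <- as.integer(tab$duplicate_count)
  }
  if (collapse_alleles) {
    for (col in intersect(c("v_call", "j_call", "v_alternatives",
                            "j_alternatives"), names(tab))) {
      tab[[col]] <- strip_alleles(tab[[col]])
    }
  }
  # comma-separated primary calls are annotator ties; record their multiplicity
  tab$v_tied_n <- lengths(strsplit(tab$v_call, ",", fixed = TRUE))
  tab$j_tied_n <- lengths(strsplit(tab$j_call, ",", fixed = TRUE))

  keep <- nchar(tab$junction) > 0 & !is.na(tab$junction)
  if (any(!keep)) {
    message(sum(!keep), " record(s) with empty junction excluded")
    tab <- tab[keep, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("no records left after excluding empty junctions",
                           call. = FALSE)
  rep <- new_repertoire(tab)
  # ties embedded in the primary call keep v_call/j_call as the full list
  # until resolve_ambiguous_calls() is applied
  rep
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    s <- as.character(x)
    names(s) <- sub("\\s.*$", "", names(x))
    return(s)
  }
  lines <- readLines(path)
  idx <- cumsum(startsWith(lines, ">"))
  headers <- sub("^>", "", sub("\\s.*$", "", lines[startsWith(lines, ">")]))
  body <- vapply(split(lines[!startsWith(lines, ">")], idx[!startsWith(lines, ">")]),
                 paste0, character(1), collapse = "")
  stats::setNames(toupper(unname(body)), headers)
}

#' Keep only productive records
#'
#' Drops every record not classified as productive by the upstream annotator,
#' preserving record order. An all-unproductive input yields a valid empty
#' repertoire (with a message).
#'
#' @param rep A [Repertoire][new_repertoire].
#' @return The filtered `Repertoire`.
#' @export
filter_productive <- function(rep) {
  stopifnot(inherits(rep, "Repertoire"))
  keep <- rep$records$productive
  if (!any(keep)) message("no productive records remain")
  out <- rep$records[keep, , drop = FALSE]
  cmap <- rep$collapse_map[names(rep$collapse_map) %in% out$sequence_id]
  structure(list(records = out, collapsed = rep$collapsed, collapse_map = cmap),
            class = "Repertoire")
}

#' Resolve tied V/J gene calls alphabetically
#'
#' When an annotator reports several germline genes with equal top alignment
#' score (encoded as a comma-separated `v_call`/`j_call`), the primary call
#' becomes the lexicographically first candidate; the remaining candidates are
#' moved to `v_alternatives`/`j_alternatives` in their original rank order,
#' ahead of any lower-ranked alternatives already present. The number of tied
#' candidates is kept in `v_tied_n`/`j_tied_n` so that ambiguity rates remain
#' computable after resolution.
#'
#' @param rep A [Repertoire][new_repertoire].
#' @return The `Repertoire` with single-gene `v_call`/`j_call` per record.
#' @export
resolve_ambiguous_calls <- function(rep) {
  stopifnot(inherits(rep, "Repertoire"))
  rec <- rep$records
  resolve_one <- function(calls, alts) {
    cand <- strsplit(calls, ",", fixed = TRUE)
    if (any(lengths(cand) == 0 | calls == "")) {
      stop("record with zero gene candidates", call. = FALSE)
    }
    primary <- vapply(cand, function(x) sort(x)[1], character(1))
    rest <- mapply(function(x, p) paste(x[x != p], collapse = ","),
                   cand, primary)
    new_alts <- ifelse(rest == "", alts,
                       ifelse(alts == "" | is.na(alts), rest,
                              paste(rest, alts, sep = ",")))
    list(primary = primary, alts = new_alts, tied = lengths(cand))
  }
  v <- resolve_one(rec$v_call, rec$v_alternatives)
  j <- resolve_one(rec$j_call, rec$j_alternatives)
  rec$v_call <- v$primary; rec$v_alternatives <- v$alts
  rec$v_tied_n <- pmax(rec$v_tied_n, v$tied)
  rec$j_call <- j$primary; rec$j_alternatives <- j$alts
  rec$j_tied_n <- pmax(rec$j_tied_n, j$tied)
  structure(list(records = rec, collapsed = rep$collapsed,
                 collapse_map = rep$collapse_map), class = "Repertoire")
}

#' Collapse records with identical junctions
#'
#' Records sharing an identical junction string are merged into a single
#' representative drawn uniformly at random among them; the representative's
#' copy number becomes the sum of the member copy numbers, and membership is
#' recorded in `collapse_map`. Identical junctions are taken as evidence of
#' clonal identity, so collapsing does not change any downstream clonal
#' partition, only the per-junction bookkeeping.
#'
#' @param rep A non-collapsed [Repertoire][new_repertoire].
#' @param seed Integer seed for the representative draw.
#' @return The collapsed `Repertoire` (`collapsed = TRUE`), representatives in
#'   order of first appearance of each junction.
#' @export
collapse_identical_junctions <- function(rep, seed = 1L) {
  stopifnot(inherits(rep, "Repertoire"))
  if (rep$collapsed) stop("repertoire is already collapsed", call. = FALSE)
  rec <- rep$records
  if (nrow(rec) == 0) {
    return(structure(list(records = rec, collapsed = TRUE, collapse_map = list()),
                     class = "Repertoire"))
  }
  groups <- split(seq_len(nrow(rec)), factor(rec$junction,
                                             levels = unique(rec$junction)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  rep_idx <- vapply(groups, function(ix) {
    if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
  }, integer(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  out <- rec[rep_idx, , drop = FALSE]
  out$count <- vapply(groups, function(ix) sum(rec$count[ix]), integer(1))
  cmap <- lapply(groups, function(ix) rec$sequence_id[ix])
  names(cmap) <- out$sequence_id
  structure(list(records = out, collapsed = TRUE, collapse_map = cmap),
            class = "Repertoire")
}

#' Write / read a clonal partition as TSV
#'
#' The on-disk format is a two-column tab-separated table (`sequence_id`,
#' `clone_id`) that round-trips losslessly.
#'
#' @param partition A [ClonalPartition][new_clonal_partition].
#' @param path Output path.
#' @return `write_partition` invisibly returns `path`; `read_partition`
#'   returns a `ClonalPartition` (method `"imported"`, no threshold).
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "ClonalPartition"))
  df <- data.frame(sequence_id = names(partition$assignment),
                   clone_id = unname(partition$assignment),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("sequence_id", "clone_id") %in% names(df))) {
    stop("partition file must have columns sequence_id, clone_id", call. = FALSE)
  }
  new_clonal_partition(stats::setNames(df$clone_id, df$sequence_id),
                       method = "imported", threshold = NULL, params = list())
}

#' Export a repertoire as AIRR-style TSV
#'
#' @param rep A [Repertoire][new_repertoire].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(inherits(rep, "Repertoire"))
  df <- as.data.frame(rep$records)
  df$productive <- ifelse(df$productive, "T", "F")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
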