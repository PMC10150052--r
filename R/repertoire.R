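#' Repertoire objects
#'
#' A `Repertoire` is an ordered collection of annotated BCR sequence records
#' together with bookkeeping about junction collapsing. Each record carries a
#' nucleotide sequence, its V and J gene calls (with any tied or lower-ranked
#' alternative calls), the junction (CDR3 plus anchors) nucleotide string, a
#' productivity flag, a copy number, and an optional ground-truth clone label.
#'
#' @param records A data frame with one row per sequence record. Required
#'   columns: `sequence_id`, `sequence`, `v_call`, `j_call`, `junction`,
#'   `productive`. Optional columns: `count` (default 1), `v_alternatives`,
#'   `j_alternatives` (comma-separated gene names, default empty), `v_tied_n`,
#'   `j_tied_n` (number of top-score-tied candidates including the primary
#'   call, default 1), `truth_clone` (default `NA`).
#' @param collapsed Logical; whether identical junctions have been collapsed.
#' @param collapse_map Named list mapping representative `sequence_id` to the
#'   character vector of member ids it represents.
#'
#' @return An object of class `Repertoire`.
#' @seealso [read_repertoire()], [collapse_identical_junctions()]
#' @export
new_repertoire <- function(records, collapsed = FALSE, collapse_map = list()) {
  records <- tibble::as_tibble(records)
  required <- c("sequence_id", "sequence", "v_call", "j_call", "junction",
                "productive")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"count" %in% names(records)) records$count <- 1L
  if (!"v_alternatives" %in% names(records)) records$v_alternatives <- ""
  if (!"j_alternatives" %in% names(records)) records$j_alternatives <- ""
  if (!"v_tied_n" %in% names(records)) records$v_tied_n <- 1L
  if (!"j_tied_n" %in% names(records)) records$j_tied_n <- 1L
  if (!"truth_clone" %in% names(records)) records$truth_clone <- NA_character_

  records$sequence_id <- as.character(records$sequence_id)
  records$sequence <- toupper(as.character(records$sequence))
  records$junction <- toupper(as.character(records$junction))
  records$productive <- as.logical(records$productive)
  records$count <- as.integer(records$count)

  dup <- records$sequence_id[duplicated(records$sequence_id)]
  if (length(dup) > 0) {
    stop("duplicate sequence_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(records$count)) || any(records$count < 1L)) {
    stop("count must be a positive integer for every record", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", records$sequence) | grepl("[^ACGTN]", records$junction)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence/junction for: ",
         paste(utils::head(records$sequence_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(records = records, collapsed = collapsed, collapse_map = collapse_map),
    class = "Repertoire"
  )
}

#' @export
print.Repertoire <- function(x, ...) {
  cat(sprintf("Repertoire: %d records (%s)\n", nrow(x$records),
              if (x$collapsed) "junction-collapsed" else "not collapsed"))
  cat(sprintf("  total copy number: %d\n", sum(x$records$count)))
  cat(sprintf("  productive: %d | distinct junctions: %d | V genes: %d | J genes: %d\n",
              sum(x$records$productive),
              length(unique(x$records$junction)),
              length(unique(x$records$v_call)),
              length(unique(x$records$j_call))))
  invisible(x)
}

#' @export
length.Repertoire <- function(x) nrow(x$records)

#' @export
as.data.frame.Repertoire <- function(x, ...) as.data.frame(x$records, ...)

#' Subset the records of a repertoire
#'
#' Keeps the collapse flag but drops the collapse map entries of removed
#' representatives.
#'
#' @param rep A [Repertoire][new_repertoire].
#' @param idx Logical or integer index into the record rows.
#' @return A `Repertoire` with the selected records, in their original order.
#' @keywords internal
subset_repertoire <- function(rep, idx) {
  records <- rep$records[idx, , drop = FALSE]
  cmap <- rep$collapse_map[names(rep$collapse_map) %in% records$sequence_id]
  new_repertoire(records, collapsed = rep$collapsed, collapse_map = cmap)
}

# drop "*01"-style allele suffixes from (possibly comma-separated) gene calls
strip_alleles <- function(calls) gsub("\\*[^,]*", "", calls)
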