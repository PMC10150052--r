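#' Normalized Levenshtein distance
#'
#' Length-normalized edit distance between two nucleotide strings,
#' \deqn{d(s_1, s_2) = \frac{2\,\mathrm{Lev}(s_1,s_2)}{|s_1| + |s_2| +
#' \mathrm{Lev}(s_1,s_2)},}
#' where Lev is the unit-cost Levenshtein distance. The normalization keeps
#' the distance in \[0, 1\] and reduces the bias of raw edit distance against
#' junctions of different lengths. Two empty strings have distance 0.
#'
#' @param s1,s2 Character vectors (recycled to common length).
#' @return Numeric vector of distances in \[0, 1\]; 0 iff the strings are
#'   equal, symmetric in its arguments.
#' @examples
#' normalized_levenshtein("AC", "AG")   # Lev = 1 -> 2/5 = 0.4
#' normalized_levenshtein("", "AAA")    # Lev = 3 -> 6/6 = 1
#' @export
normalized_levenshtein <- function(s1, s2) {
  lev <- as.numeric(diag_adist(s1, s2))
  denom <- nchar(s1) + nchar(s2) + lev
  ifelse(denom == 0, 0, 2 * lev / denom)
}

# elementwise (not cross) Levenshtein via utils::adist
diag_adist <- function(s1, s2) {
  n <- max(length(s1), length(s2))
  s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  vapply(seq_len(n), function(i) utils::adist(s1[i], s2[i])[1, 1], numeric(1))
}

#' Full normalized Levenshtein distance matrix
#'
#' @param a,b Character vectors; `b` defaults to `a`.
#' @return A `length(a) x length(b)` matrix of normalized Levenshtein
#'   distances.
#' @export
normalized_levenshtein_matrix <- function(a, b = a) {
  lev <- utils::adist(a, b)
  denom <- outer(nchar(a), nchar(b), "+") + lev
  d <- 2 * lev / denom
  d[denom == 0] <- 0
  d
}

#' tf-idf k-mer vectorization of nucleotide sequences
#'
#' Each sequence is first reduced to its 3'-anchored window of the last `L`
#' nucleotides (shorter sequences are kept whole) so that sequences truncated
#' at the 5' end of the V gene remain comparable and the junction region is
#' retained. The window is decomposed into overlapping k-mers; k-mers
#' containing `N` are skipped. The weight of k-mer \eqn{w} in sequence
#' \eqn{s} is \eqn{tf(w, s) \cdot idf(w)} with \eqn{tf} the raw occurrence
#' count in \eqn{s} and \eqn{idf(w) = \log(|S| / df(w))}, where \eqn{df(w)}
#' is the number of corpus sequences containing \eqn{w} (natural log). A
#' k-mer present in every sequence therefore receives weight 0 everywhere.
#'
#' The vocabulary and idf weights are corpus-dependent: the same sequence can
#' receive different vectors in different repertoires.
#'
#' @param sequences Character vector of nucleotide sequences (the corpus).
#' @param k k-mer length (default 7).
#' @param L 3'-anchored truncation length in nucleotides (default 130).
#' @param idf Either `"document"` (count each sequence containing the k-mer
#'   once; default) or `"occurrence"` (total occurrence count across the
#'   corpus in the idf denominator).
#' @return An object of class `kmer_matrix`: a list with `weights` (sparse
#'   `dgCMatrix`, one row per sequence, one column per vocabulary k-mer),
#'   `idf_weights` (named numeric), `k` and `L`.
#' @export
tfidf_vectorize <- function(sequences, k = 7L, L = 130L,
                            idf = c("document", "occurrence")) {
  idf <- match.arg(idf)
  stopifnot(k >= 1, L >= k, length(sequences) > 0)
  windows <- truncate_3prime(sequences, L)
  km <- lapply(windows, kmers_of, k = k)
  if (all(lengths(km) == 0)) {
    stop("empty vocabulary: no sequence yields a k-mer of length ", k,
         call. = FALSE)
  }
  counts <- lapply(km, function(x) table(x))
  vocab <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  i <- rep.int(seq_along(counts), vapply(counts, length, integer(1)))
  j <- match(unlist(lapply(counts, names), use.names = FALSE), vocab)
  tf <- Matrix::sparseMatrix(
    i = i, j = j, x = as.numeric(unlist(counts, use.names = FALSE)),
    dims = c(length(sequences), length(vocab)),
    dimnames = list(names(sequences), vocab)
  )
  n_seq <- length(sequences)
  df <- if (idf == "document") Matrix::colSums(tf > 0) else Matrix::colSums(tf)
  idf_w <- log(n_seq / df)
  idf_w[df == 0] <- 0
  w <- tf %*% Matrix::Diagonal(x = idf_w)
  colnames(w) <- vocab
  structure(list(weights = w, idf_weights = stats::setNames(idf_w, vocab),
                 k = as.integer(k), L = as.integer(L)),
            class = "kmer_matrix")
}

# keep the last L nucleotides of each sequence (3'-anchored window)
truncate_3prime <- function(sequences, L) {
  n <- nchar(sequences)
  substr(sequences, pmax(1L, n - L + 1L), n)
}

kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1), k:n)
  km[!grepl("N", km, fixed = TRUE)]
}

#' Vectorize new sequences against an existing tf-idf corpus
#'
#' Applies the vocabulary and idf weights learned by [tfidf_vectorize()] to
#' further sequences (e.g. negation sequences) without altering the corpus
#' statistics. k-mers outside the corpus vocabulary are dropped.
#'
#' @param vectors A `kmer_matrix` from [tfidf_vectorize()].
#' @param sequences Character vector of new sequences.
#' @return A sparse matrix with `length(sequences)` rows over the corpus
#'   vocabulary.
#' @export
tfidf_project <- function(vectors, sequences) {
  stopifnot(inherits(vectors, "kmer_matrix"))
  k <- vectors$k; L <- vectors$L
  idf_w <- vectors$idf_weights
  vocab <- names(idf_w)
  windows <- truncate_3prime(sequences, L)
  counts <- lapply(windows, function(s) table(kmers_of(s, k)))
  keep <- lapply(counts, function(ct) ct[names(ct) %in% vocab])
  i <- rep.int(seq_along(keep), vapply(keep, length, integer(1)))
  j <- match(unlist(lapply(keep, names), use.names = FALSE), vocab)
  x <- as.numeric(unlist(keep, use.names = FALSE))
  tf <- Matrix::sparseMatrix(i = i, j = j, x = x,
                             dims = c(length(sequences), length(vocab)),
                             dimnames = list(NULL, vocab))
  tf %*% Matrix::Diagonal(x = unname(idf_w))
}

#' Cosine distance between tf-idf vectors
#'
#' \eqn{1 - \frac{a \cdot b}{\|a\|\,\|b\|}}. With non-negative tf-idf weights
#' the distance lies in \[0, 1\]. By convention a zero vector has distance 1
#' to any nonzero vector and 0 to another zero vector, so degenerate vectors
#' cannot poison clustering with NaNs.
#'
#' @param a,b Numeric (possibly sparse) vectors over the same vocabulary.
#' @return A single distance in \[0, 1\].
#' @export
cosine_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(1)
  max(0, min(1, 1 - sum(a * b) / (na * nb)))
}

# row-normalized cosine distance matrix between two sparse matrices
cosine_distance_matrix <- function(A, B = A) {
  norm_a <- sqrt(Matrix::rowSums(A^2))
  norm_b <- sqrt(Matrix::rowSums(B^2))
  An <- A / pmax(norm_a, .Machine$double.eps)
  Bn <- B / pmax(norm_b, .Machine$double.eps)
  d <- 1 - as.matrix(Matrix::tcrossprod(An, Bn))
  d[norm_a == 0, norm_b != 0] <- 1
  d[norm_a != 0, norm_b == 0] <- 1
  d[norm_a == 0, norm_b == 0] <- 0
  pmin(pmax(d, 0), 1)
}

#' Pairwise distance matrix over a repertoire
#'
#' Computes the full symmetric distance matrix used by the clonal
#' identification methods: normalized Levenshtein between junctions, or
#' cosine distance between tf-idf k-mer vectors of the (3'-truncated) full
#' sequences.
#'
#' @param rep A [Repertoire][new_repertoire].
#' @param metric `"normalized_levenshtein"` (on junctions) or `"cosine"` (on
#'   tf-idf vectors of full sequences).
#' @param k,L tf-idf parameters, used for `metric = "cosine"`.
#' @return A list of class `DistanceMatrix` with fields `ids`, `values`
#'   (symmetric matrix, zero diagonal, entries in \[0, 1\]) and `metric`.
#' @export
pairwise_distances <- function(rep, metric = c("normalized_levenshtein", "cosine"),
                               k = 7L, L = 130L) {
  stopifnot(inherits(rep, "Repertoire"))
  metric <- match.arg(metric)
  ids <- rep$records$sequence_id
  if (metric == "normalized_levenshtein") {
    d <- normalized_levenshtein_matrix(rep$records$junction)
  } else {
    vec <- tfidf_vectorize(rep$records$sequence, k = k, L = L)
    d <- cosine_distance_matrix(vec$weights)
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, values = d, metric = metric),
            class = "DistanceMatrix")
}
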