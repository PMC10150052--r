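#' Abundance vectors
#'
#' An `AbundanceVector` holds clone counts and relative abundances, plus the
#' singleton/doubleton statistics driving the Chao estimators.
#'
#' @param counts Vector of positive integer clone sizes.
#' @return An object of class `AbundanceVector` with fields `counts`, `p`
#'   (relative abundances, summing to 1), `n` (total observations), `S_obs`
#'   (number of clones), `f1` and `f2` (number of clones observed exactly
#'   once / twice).
#' @export
abundance_vector <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("empty abundance vector", call. = FALSE)
  if (any(counts <= 0)) stop("clone counts must be positive", call. = FALSE)
  n <- sum(counts)
  structure(list(counts = counts, p = counts / n, n = n,
                 S_obs = length(counts),
                 f1 = sum(counts == 1), f2 = sum(counts == 2)),
            class = "AbundanceVector")
}

#' @export
print.AbundanceVector <- function(x, ...) {
  cat(sprintf("AbundanceVector: S_obs = %d, n = %g, f1 = %d, f2 = %d, p_max = %.4g\n",
              x$S_obs, x$n, x$f1, x$f2, max(x$p)))
  invisible(x)
}

#' Clone abundances induced by a clonal partition
#'
#' @param partition A [ClonalPartition][new_clonal_partition] covering `rep`.
#' @param rep The [Repertoire][new_repertoire] the partition was computed on.
#' @param weight `"representatives"` counts one unit per (collapsed) record;
#'   `"copy_counts"` weights each record by its copy number, so duplicate
#'   reads contribute to clone size.
#' @return An [AbundanceVector][abundance_vector] over the clones of the
#'   partition.
#' @export
abundance_from_partition <- function(partition, rep,
                                     weight = c("copy_counts",
                                                "representatives")) {
  stopifnot(inherits(partition, "ClonalPartition"), inherits(rep, "Repertoire"))
  weight <- match.arg(weight)
  if (length(partition$assignment) == 0) stop("empty partition", call. = FALSE)
  ids <- rep$records$sequence_id
  if (!all(ids %in% names(partition$assignment))) {
    stop("partition does not cover all repertoire records", call. = FALSE)
  }
  lab <- partition$assignment[ids]
  w <- switch(weight, representatives = base::rep(1, length(ids)),
              copy_counts = rep$records$count)
  counts <- tapply(w, lab, sum)
  abundance_vector(as.numeric(counts))
}

#' Hill diversity of order alpha
#'
#' The Hill number \eqn{{}^{\alpha}D = (\sum_i p_i^\alpha)^{1/(1-\alpha)}}
#' is a one-parameter family of effective clone numbers: `alpha = 0` gives
#' richness, the limit `alpha -> 1` gives `exp(H)` (the exponential Shannon
#' entropy), `alpha = 2` the inverse Simpson index and `alpha = Inf` the
#' inverse dominance `1/max(p)`. Small `alpha` weighs rare clones, large
#' `alpha` the common ones, and \eqn{1 \le {}^{\alpha}D \le S} always.
#' Orders away from the special cases are evaluated in log space
#' (log-sum-exp) for numerical stability at large `alpha`.
#'
#' @param ab An [AbundanceVector][abundance_vector].
#' @param alpha Non-negative order (vectorized); `Inf` allowed.
#' @return Numeric vector of Hill numbers, one per `alpha`.
#' @export
hill_diversity <- function(ab, alpha) {
  stopifnot(inherits(ab, "AbundanceVector"))
  if (any(alpha < 0)) stop("alpha must be non-negative", call. = FALSE)
  lp <- log(ab$p)
  vapply(alpha, function(a) {
    if (a == 0) return(as.numeric(ab$S_obs))
    if (is.infinite(a)) return(1 / max(ab$p))
    if (abs(a - 1) < 1e-10) return(exp(-sum(ab$p * lp)))
    # log-sum-exp of alpha * log(p), then the 1/(1-alpha) power in log space
    z <- a * lp
    zmax <- max(z)
    exp((zmax + log(sum(exp(z - zmax)))) / (1 - a))
  }, numeric(1))
}

#' Shannon entropy (nats)
#'
#' \eqn{H = -\sum_i p_i \log p_i}; `exp(H)` equals the Hill number of order 1.
#'
#' @param ab An [AbundanceVector][abundance_vector].
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(ab) {
  stopifnot(inherits(ab, "AbundanceVector"))
  -sum(ab$p * log(ab$p))
}

#' Simpson index, dominance and richness
#'
#' `simpson_index` returns \eqn{\lambda = \sum_i p_i^2}, the probability that
#' two randomly drawn sequences belong to the same clone (`1 / simpson_index`
#' is the Hill number of order 2). `dominance` is the relative abundance of
#' the most abundant clone (`1 / dominance` is the order-infinity Hill
#' number). `richness` is the number of observed clones (order 0).
#'
#' @param ab An [AbundanceVector][abundance_vector].
#' @return A single numeric value (integer for `richness`).
#' @export
simpson_index <- function(ab) {
  stopifnot(inherits(ab, "AbundanceVector"))
  sum(ab$p^2)
}

#' @rdname simpson_index
#' @export
dominance <- function(ab) {
  stopifnot(inherits(ab, "AbundanceVector"))
  max(ab$p)
}

#' @rdname simpson_index
#' @export
richness <- function(ab) {
  stopifnot(inherits(ab, "AbundanceVector"))
  ab$S_obs
}

#' Evenness E(a, b)
#'
#' Ratio of Hill numbers \eqn{E(a,b) = {}^{a}D / {}^{b}D} with `a > b`,
#' measuring the homogeneity of clone abundances; the common choice
#' `E(1, 0) = exp(H) / S` satisfies \eqn{1/S \le E \le 1}, reaching 1 for
#' perfectly even repertoires. `E(2, 1)` is preferred for small samples.
#'
#' @param ab An [AbundanceVector][abundance_vector].
#' @param a,b Orders with `a > b >= 0`; defaults `(1, 0)`.
#' @return Evenness value.
#' @export
evenness <- function(ab, a = 1, b = 0) {
  if (!(a > b) || b < 0) stop("evenness requires a > b >= 0", call. = FALSE)
  hill_diversity(ab, a) / hill_diversity(ab, b)
}

#' Hill diversity profile over a bounded grid
#'
#' Evaluates the Hill number along `N` orders obtained by mapping an evenly
#' spaced grid \eqn{A \in [-1, 1]} through \eqn{\alpha = \exp(\tan(A\pi/2))}.
#' The transform squeezes the whole range \eqn{\alpha \in [0, \infty]} into a
#' finite vector — the endpoints are assigned their exact limits, richness at
#' `A = -1` and inverse dominance at `A = +1` — and is symmetric around
#' `A = 0` (\eqn{\alpha = 1}, the Shannon point) in the weighting of rare
#' versus common clones.
#'
#' @param ab An [AbundanceVector][abundance_vector].
#' @param N Number of grid points (at least 3; default 101).
#' @return A tibble of class `DiversityProfile` with columns `A`, `alpha` and
#'   `D`.
#' @export
diversity_profile <- function(ab, N = 101L) {
  stopifnot(inherits(ab, "AbundanceVector"), N >= 3)
  A <- seq(-1, 1, length.out = N)
  alpha <- exp(tan(A * pi / 2))
  alpha[1] <- 0
  alpha[N] <- Inf
  out <- tibble::tibble(A = A, alpha = alpha, D = hill_diversity(ab, alpha))
  class(out) <- c("DiversityProfile", class(out))
  out
}

#' Bias-corrected Chao1 richness estimator
#'
#' \eqn{\hat S = S_{obs} + \frac{f_1 (f_1 - 1)}{2 (f_2 + 1)}}: many
#' singleton clones are evidence for unobserved clones. Always at least
#' `S_obs`, with equality when `f1 <= 1`. Counts must be raw observation
#' counts for the estimator to be meaningful.
#'
#' @param ab An [AbundanceVector][abundance_vector].
#' @return Estimated true clone richness.
#' @export
chao1_richness <- function(ab) {
  stopifnot(inherits(ab, "AbundanceVector"))
  ab$S_obs + ab$f1 * (ab$f1 - 1) / (2 * (ab$f2 + 1))
}

#' Coverage-adjusted Chao estimator of Shannon entropy (nats)
#'
#' Estimates sample coverage from singletons, \eqn{C = 1 - f_1/n}, shrinks
#' the plug-in abundances to \eqn{\tilde p_i = C\,p_i}, and corrects each
#' term for the probability of having observed the clone at all:
#' \deqn{\hat H = -\sum_i \frac{\tilde p_i \log \tilde p_i}
#' {1 - (1 - \tilde p_i)^n}.}
#' With no singletons (`C = 1`) this reduces to a mildly corrected plug-in
#' entropy; when every clone is a singleton the coverage is zero and the
#' estimator is undefined.
#'
#' @param ab An [AbundanceVector][abundance_vector] of raw observation
#'   counts.
#' @param adjust How the coverage adjustment enters: `"product"` (the
#'   standard coverage-shrunk \eqn{\tilde p = C p}; default) or
#'   `"quotient"` (\eqn{\tilde p = p / C}, capped at 1).
#' @return Estimated Shannon entropy in nats.
#' @export
chao_shannon <- function(ab, adjust = c("product", "quotient")) {
  stopifnot(inherits(ab, "AbundanceVector"))
  adjust <- match.arg(adjust)
  C <- 1 - ab$f1 / ab$n
  if (C <= 0) {
    stop("all clones are singletons (coverage = 0); the Chao-Shannon ",
         "estimator is undefined — sequence deeper or pool samples",
         call. = FALSE)
  }
  pt <- switch(adjust, product = ab$p * C, quotient = pmin(ab$p / C, 1))
  term <- -pt * log(pt) / (1 - (1 - pt)^ab$n)
  term[pt == 1] <- 0
  sum(term)
}

#' Clonal composition summary
#'
#' Splits the repertoire's sequences into the dominant clone, expanded clones
#' (abundance of at least 1%, excluding the dominant one) and non-expanded
#' clones (abundance below 1%). A clone sitting exactly at 1% counts as
#' expanded. The three fractions sum to 1.
#'
#' @param ab An [AbundanceVector][abundance_vector].
#' @param expanded_cutoff Abundance boundary between expanded and
#'   non-expanded clones (default 0.01).
#' @return A tibble with columns `dominant`, `expanded`, `non_expanded`,
#'   `n_expanded_clones` and `n_non_expanded_clones`.
#' @export
clonal_composition_summary <- function(ab, expanded_cutoff = 0.01) {
  stopifnot(inherits(ab, "AbundanceVector"))
  imax <- which.max(ab$p)
  rest <- ab$p[-imax]
  tibble::tibble(
    dominant = ab$p[imax],
    expanded = sum(rest[rest >= expanded_cutoff]),
    non_expanded = sum(rest[rest < expanded_cutoff]),
    n_expanded_clones = sum(rest >= expanded_cutoff),
    n_non_expanded_clones = sum(rest < expanded_cutoff)
  )
}

#' Compute a panel of diversity indices
#'
#' Convenience wrapper returning the named indices (and any Hill orders) for
#' one abundance vector.
#'
#' @param ab An [AbundanceVector][abundance_vector].
#' @param indices Character vector among `"richness"`, `"shannon"`,
#'   `"simpson"`, `"dominance"`, `"evenness"`, `"chao1"`, `"chao_shannon"`.
#' @param alphas Optional numeric vector of Hill orders, reported as
#'   `hill_<alpha>`.
#' @return A named numeric vector.
#' @export
diversity_indices <- function(ab,
                              indices = c("richness", "shannon", "simpson",
                                          "dominance", "evenness", "chao1",
                                          "chao_shannon"),
                              alphas = NULL) {
  fns <- list(richness = function(x) richness(x),
              shannon = shannon_entropy,
              simpson = simpson_index,
              dominance = dominance,
              evenness = function(x) evenness(x, 1, 0),
              chao1 = chao1_richness,
              chao_shannon = function(x) tryCatch(chao_shannon(x),
                                                  error = function(e) NA_real_))
  bad <- setdiff(indices, names(fns))
  if (length(bad)) stop("unknown index: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- vapply(indices, function(nm) as.numeric(fns[[nm]](ab)), numeric(1))
  if (!is.null(alphas)) {
    h <- hill_diversity(ab, alphas)
    names(h) <- paste0("hill_", alphas)
    out <- c(out, h)
  }
  out
}
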