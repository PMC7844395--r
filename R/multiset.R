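# Exact statistics of intersections among k gene sets drawn independently
# and uniformly from a finite universe. The distribution of
# |A_1 n ... n A_k| is built by chaining hypergeometric kernels: by
# exchangeability the running intersection after j sets is a uniform random
# subset of its size, so intersecting with the next n_{j+1}-subset mixes a
# Hypergeom(N, s, n_{j+1}) kernel over the current size distribution.

#' Exact PMF of a multi-set intersection size
#'
#' Distribution of the intersection cardinality of `k` independent uniform
#' random subsets of sizes `set_sizes` from an `N`-element universe.
#' `D_1` is a point mass at `n_1`;
#' `D_j(t) = sum_s D_{j-1}(s) P(Hypergeom(N, s, n_j) = t)`.
#' Chain states with mass below `1e-18` are pruned; the pruned mass is
#' asserted below `1e-12` in total.
#'
#' @param set_sizes integer vector of set sizes (length `k >= 1`).
#' @param N universe size; every size must be `<= N`.
#' @return numeric vector of probabilities over support `0..min(set_sizes)`
#'   (named by size), summing to 1 within `1e-10`.
#' @export
intersection_pmf <- function(set_sizes, N) {
  stopifnot(length(set_sizes) >= 1)
  if (N == 0 && any(set_sizes > 0)) stopf("N = 0 with non-empty sets")
  if (any(set_sizes > N)) stopf("set size exceeds universe N")
  if (any(set_sizes < 0)) stopf("negative set size")
  d <- numeric(set_sizes[1] + 1)            # index s+1 <-> size s
  d[set_sizes[1] + 1] <- 1
  pruned <- 0
  for (nj in set_sizes[-1]) {
    new_max <- min(length(d) - 1, nj)
    nxt <- numeric(new_max + 1)
    for (s in which(d > 0) - 1) {
      w <- d[s + 1]
      if (w < 1e-18) { pruned <- pruned + w; next }
      t <- 0:min(s, nj)
      nxt[t + 1] <- nxt[t + 1] + w * dhyper(t, s, N - s, nj)
    }
    d <- nxt
  }
  if (pruned >= 1e-12) stopf("pruned chain mass %.3g exceeds tolerance", pruned)
  names(d) <- seq_along(d) - 1
  d
}

#' Upper-tail p-value of an observed multi-set intersection
#'
#' `P(|A_1 n ... n A_k| >= observed)` under independent uniform sampling;
#' equals 1 when `observed = 0`.
#'
#' @param observed observed intersection size.
#' @param set_sizes integer vector of set sizes.
#' @param N universe size.
#' @return a probability in `(0, 1]`.
#' @export
intersection_pvalue <- function(observed, set_sizes, N) {
  if (observed > min(set_sizes)) stopf("observed exceeds the smallest set")
  if (observed <= 0) return(1.0)
  pmf <- intersection_pmf(set_sizes, N)
  min(1, sum(pmf[as.integer(names(pmf)) >= observed]))
}

#' Expected multi-set intersection size
#'
#' `N * prod(n_i / N)`: the mean intersection cardinality under independent
#' uniform sampling (each element survives all `k` draws independently with
#' probability `prod(n_i / N)`).
#'
#' @param set_sizes integer vector of set sizes.
#' @param N universe size (`> 0`).
#' @return non-negative expected size.
#' @export
expected_intersection_size <- function(set_sizes, N) {
  if (N <= 0) stopf("universe N must be positive")
  if (any(set_sizes > N)) stopf("set size exceeds universe N")
  N * prod(set_sizes / N)
}

#' Fold enrichment of an observed intersection
#'
#' @param observed observed intersection size.
#' @param expected expected size under the null.
#' @return `observed / expected`, or `NA` when `expected` is 0 (reported as
#'   missing, never infinity).
#' @export
fold_enrichment <- function(observed, expected) {
  if (expected == 0) return(NA_real_)
  observed / expected
}

#' Enumerate intersection statistics over all disease combinations
#'
#' One record per non-empty combination of diseases (`2^k - 1` in total),
#' ordered by degree (number of participating diseases) and then by the
#' combination's position in column order. Each record carries the observed
#' intersection, its expectation and fold enrichment under independent
#' uniform sampling from the universe, and the exact upper-tail p-value.
#' Degree-1 records describe the original lists (p-value 1).
#'
#' @param matrix a [disease_gene_matrix()].
#' @param N universe size; defaults to the number of genes in the matrix.
#'   Must be at least every disease-set size.
#' @return data.frame with columns `combination` (ampersand-joined disease
#'   names), `degree`, `observed`, `expected`, `fold_enrichment`, `p_value`,
#'   `member_genes` (semicolon-joined, degree >= 2 only).
#' @export
enumerate_intersections <- function(matrix, N = NULL) {
  stopifnot(inherits(matrix, "disease_gene_matrix"), ncol(matrix) >= 1)
  sets <- disease_gene_sets(matrix)
  sizes <- lengths(sets)
  N <- N %||% nrow(matrix)
  if (any(sizes > N)) {
    stopf("universe N = %d smaller than set '%s' (%d genes)",
          N, names(sizes)[which.max(sizes)], max(sizes))
  }
  k <- length(sets)
  recs <- list()
  for (deg in seq_len(k)) {
    combos <- combn(k, deg, simplify = FALSE)
    for (idx in combos) {
      members <- Reduce(intersect, sets[idx])
      obs <- length(members)
      exp_size <- expected_intersection_size(sizes[idx], N)
      pv <- if (deg == 1) 1.0 else intersection_pvalue(obs, sizes[idx], N)
      recs[[length(recs) + 1]] <- data.frame(
        combination = paste(colnames(matrix)[idx], collapse = " & "),
        degree = deg,
        observed = obs,
        expected = exp_size,
        fold_enrichment = fold_enrichment(obs, exp_size),
        p_value = pv,
        member_genes = if (deg >= 2) paste(sort(members), collapse = ";")
                       else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
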