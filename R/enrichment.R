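# Functional-profile encoding: each gene is represented by the -log10
# upper-tail hypergeometric p-values of its network-neighbor set against
# every annotation term. The neighbor set S(g), not the gene's own
# annotations, carries the signal: a gene surrounded by members of a term is
# scored as functionally tied to that term.

#' Network neighbor set of a gene
#'
#' `S(g)`: the direct neighbors of `gene` in the (already threshold-filtered)
#' network. The gene itself is excluded; a gene absent from the network has an
#' empty neighbor set.
#'
#' @param network a [functional_network()].
#' @param gene gene name.
#' @return character vector of neighbor gene names (possibly empty).
#' @export
neighbor_set <- function(network, gene) {
  nodes <- network_nodes(network)
  if (!(gene %in% nodes)) return(character())
  nb <- igraph::neighbors(network$graph, gene)
  setdiff(nb$name, gene)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= m)` for `X ~ Hypergeom(N, M, n)`: the probability that a uniform
#' random `n`-subset of an `N`-gene universe hits at least `m` of the `M`
#' genes annotated to a term. Computed as a log-gamma tail sum
#' `sum_{k=m}^{min(M,n)} C(M,k) C(N-M,n-k) / C(N,n)` accumulated through
#' log-sum-exp for numerical stability, clipped below at `1e-320`. All
#' arguments are vectorized.
#'
#' @param N universe size.
#' @param M number of universe genes annotated to the term.
#' @param n query-set size (`|S(g)|`).
#' @param m overlap (`|S(g)` intersect `term|`).
#' @return probabilities in `(0, 1]`; exactly 1 when `m = 0`.
#' @export
hypergeom_upper_tail <- function(N, M, n, m) {
  v <- cbind(N, M, n, m)
  N <- v[, 1]; M <- v[, 2]; n <- v[, 3]; m <- v[, 4]
  if (any(M > N | n > N)) stopf("M and n must not exceed N")
  if (any(m > pmin(M, n))) stopf("m must not exceed min(M, n)")
  if (any(m < pmax(0, n + M - N))) stopf("m below the feasible minimum")
  p <- vapply(seq_along(N), function(i) {
    if (m[i] == 0) return(1.0)
    k <- m[i]:min(M[i], n[i])
    lg <- lchoose(M[i], k) + lchoose(N[i] - M[i], n[i] - k) -
      lchoose(N[i], n[i])
    top <- max(lg)
    exp(top) * sum(exp(lg - top))
  }, 0.0)
  pmin(pmax(p, 1e-320), 1)
}

#' Enrichment score of a neighbor set against a term
#'
#' `-log10` of [hypergeom_upper_tail()]; 0 when the overlap is empty, always
#' finite via the probability clip.
#'
#' @inheritParams hypergeom_upper_tail
#' @return non-negative scores, vectorized like the inputs.
#' @export
enrichment_score <- function(N, M, n, m) {
  -log10(hypergeom_upper_tail(N, M, n, m))
}

#' Encode genes as functional enrichment profiles
#'
#' For every requested gene, scores its network neighborhood `S(g)` against
#' every catalog term: entry `(g, t)` is the `-log10` upper-tail
#' hypergeometric p-value of the overlap between `S(g)` and term `t`'s gene
#' set within the universe. Genes absent from the network (or with no
#' neighbors) get all-zero rows; terms with no gene in the universe give
#' all-zero columns with a warning. Column order follows the catalog.
#'
#' @param network a [functional_network()]; its node set is the gene universe.
#' @param catalog an [annotation_catalog()].
#' @param genes ordered character vector of genes to encode.
#' @param universe_size optional explicit universe count `N`; defaults to the
#'   number of network nodes. Must be at least the node count.
#' @param include_self if TRUE the gene itself is added to `S(g)`.
#' @param min_term_size if positive, terms with fewer universe genes than this
#'   are dropped from the feature set instead of yielding zero columns.
#' @return numeric matrix, genes x terms, of non-negative scores.
#' @export
encode_profiles <- function(network, catalog, genes,
                            universe_size = NULL, include_self = FALSE,
                            min_term_size = 0L) {
  stopifnot(length(genes) > 0)
  if (anyDuplicated(genes)) stopf("duplicate gene in encoding request")
  nodes <- network_nodes(network)
  N <- universe_size %||% length(nodes)
  if (N < length(nodes)) stopf("universe_size below the network node count")

  sets <- lapply(catalog$gene_sets, function(s) intersect(s, nodes))
  M <- lengths(sets)
  keep <- rep(TRUE, length(M))
  if (min_term_size > 0) keep <- M >= min_term_size
  if (any(M[keep] == 0)) {
    warnf("%d term(s) have no gene in the universe; zero columns emitted",
          sum(M[keep] == 0))
  }
  term_ids <- catalog$term_ids[keep]
  sets <- sets[keep]
  M <- M[keep]

  if (!length(sets)) {
    return(matrix(0, nrow = length(genes), ncol = 0,
                  dimnames = list(genes, character())))
  }

  g <- network$graph
  node_idx <- setNames(seq_along(nodes), nodes)
  # sparse node x term membership and node x node adjacency: the overlap
  # counts m(g, t) for every pair come from one sparse product
  ij <- do.call(rbind, lapply(seq_along(sets), function(j) {
    s <- sets[[j]]
    if (!length(s)) return(NULL)
    cbind(node_idx[s], j)
  }))
  if (is.null(ij)) {
    return(matrix(0, nrow = length(genes), ncol = length(sets),
                  dimnames = list(genes, term_ids)))
  }
  A <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                            dims = c(length(nodes), length(sets)))
  Adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  if (include_self) Adj <- Adj + Matrix::Diagonal(length(nodes))
  present <- genes[genes %in% nodes]
  scores <- matrix(0, nrow = length(genes), ncol = length(sets),
                   dimnames = list(genes, term_ids))
  if (length(present)) {
    mo <- as.matrix(Adj[node_idx[present], , drop = FALSE] %*% A)
    nq <- Matrix::rowSums(Adj)[node_idx[present]]
    # score only the distinct (M, n, m) triples, then scatter back
    Mm <- matrix(rep(M, each = length(present)), nrow = length(present))
    nn <- matrix(rep(nq, times = length(sets)), nrow = length(present))
    key <- paste(Mm, nn, mo)
    uk <- !duplicated(key)
    sc <- enrichment_score(N, Mm[uk], nn[uk], mo[uk])
    scores[present, ] <- sc[match(key, key[uk])]
  }
  scores
}
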