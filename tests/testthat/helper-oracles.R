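# Independent brute-force oracles used to validate the analytic routines.
# They enumerate explicitly and never share code with the implementation.

# sample one element of a vector (safe for length-1 vectors)
pick1 <- function(v) v[sample.int(length(v), 1)]

# P(|S cap A| >= m) for a uniform random n-subset S of 1..N, A = 1..M,
# by enumerating all C(N, n) subsets.
oracle_hyper_tail <- function(N, M, n, m) {
  if (n == 0) return(as.numeric(m == 0))
  subsets <- utils::combn(N, n)
  hits <- sum(apply(subsets, 2, function(s) sum(s <= M) >= m))
  hits / ncol(subsets)
}

# exact PMF of |A_1 cap ... cap A_k| over all subset tuples, sets as
# bitmasks (requires N <= 16; intended for N <= 8)
oracle_multiset_pmf <- function(sizes, N) {
  stopifnot(N <= 16)
  masks <- lapply(sizes, function(sz) {
    cols <- utils::combn(N, sz)
    apply(cols, 2, function(s) sum(bitwShiftL(1L, s - 1L)))
  })
  inter <- masks[[1]]
  for (j in seq_along(masks)[-1]) {
    inter <- as.vector(outer(inter, masks[[j]], bitwAnd))
  }
  popcount <- vapply(0:(2^N - 1), function(x) {
    sum(bitwAnd(bitwShiftR(x, 0:(N - 1)), 1L))
  }, 0L)
  sizes_seen <- popcount[inter + 1L]
  tab <- tabulate(sizes_seen + 1L, nbins = min(sizes) + 1L)
  p <- tab / length(sizes_seen)
  names(p) <- 0:min(sizes)
  p
}

# write a small disease-gene matrix TSV and return its path
write_toy_matrix <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "matrix.tsv")
  writeLines(lines, path)
  path
}

# small 8-disease membership matrix with known overlaps, built in code
toy_eight_disease_matrix <- function(n_genes = 40, seed = 42) {
  set.seed(seed)
  m <- matrix(rbinom(n_genes * 8, 1, 0.3), n_genes, 8,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("dz", 1:8)))
  # ensure every disease has at least one gene
  for (j in 1:8) if (sum(m[, j]) == 0) m[j, j] <- 1L
  disease_gene_matrix(m)
}
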