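# Monte Carlo feature selection: features are ranked by aggregating their
# information-gain contributions across many decision trees, each trained on
# a random projection (feature subset) and a random stratified train/test
# split. Significance comes from re-running the whole procedure on
# label-permuted data and taking a high quantile of the per-run maximum
# relative importance.

#' Monte Carlo feature-selection parameters
#'
#' @param s_projections number of random feature projections (default 1000).
#' @param m_projection_size features per projection; either an integer count
#'   or a fraction of the feature count `d` in `(0, 1)`. Default
#'   `max(ceiling(0.05 d), 2)`.
#' @param t_splits train/test splits (hence trees) per projection (default 5).
#' @param train_fraction fraction of each class assigned to training
#'   (default 2/3).
#' @param u exponent on the tree's weighted accuracy in the relative
#'   importance (default 1).
#' @param v exponent on the node sample fraction (default 1).
#' @param negative_sampling `"balanced"` (train part subsamples the majority
#'   class to the minority count; default) or `"full"`.
#' @param n_permutations label permutations for the significance cutoff
#'   (default 20).
#' @param alpha family-wise significance level of the cutoff (default 0.05).
#' @param min_leaf minimum samples per leaf in each tree (default 5; shallow
#'   trees damp the spurious-gain noise that deep splits on tiny nodes
#'   add to the importance aggregate).
#' @param seed master seed; all sub-streams are derived from it.
#' @return a list of class `mcfs_params`.
#' @export
mcfs_params <- function(s_projections = 1000L, m_projection_size = NULL,
                        t_splits = 5L, train_fraction = 2 / 3, u = 1,
                        v = 1, negative_sampling = c("balanced", "full"),
                        n_permutations = 20L, alpha = 0.05, min_leaf = 5L,
                        seed = 1L) {
  negative_sampling <- match.arg(negative_sampling)
  stopifnot(train_fraction > 0, train_fraction < 1,
            s_projections >= 1, t_splits >= 1, alpha > 0, alpha < 1)
  structure(list(s_projections = as.integer(s_projections),
                 m_projection_size = m_projection_size,
                 t_splits = as.integer(t_splits),
                 train_fraction = train_fraction, u = u, v = v,
                 negative_sampling = negative_sampling,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "mcfs_params")
}

# resolve the projection size against the actual feature count
projection_size <- function(params, d) {
  m <- params$m_projection_size
  if (is.null(m)) m <- max(ceiling(0.05 * d), 2)
  else if (m > 0 && m < 1) m <- max(ceiling(m * d), 2)
  m <- as.integer(m)
  if (m > d) stopf("projection size %d exceeds feature count %d", m, d)
  m
}

#' Draw a random feature projection
#'
#' Uniform random `m`-subset of the `d` feature indices, without
#' replacement, using the current RNG state.
#'
#' @param d total feature count.
#' @param m projection size (`1 <= m <= d`).
#' @return sorted integer vector of `m` feature indices.
#' @export
draw_projection <- function(d, m) {
  if (m > d) stopf("projection size m = %d exceeds d = %d", m, d)
  sort(sample.int(d, m))
}

#' Stratified train/test split with optional balancing
#'
#' Each class is split `train_fraction` / rest, guaranteeing at least one
#' sample of each class on each side. Under `"balanced"` sampling the
#' training part then subsamples the majority class down to the minority
#' training count; the test part keeps its natural class imbalance.
#'
#' @param y 0/1 class vector.
#' @param train_fraction fraction of each class used for training.
#' @param negative_sampling `"balanced"` or `"full"`.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(y, train_fraction = 2 / 3,
                             negative_sampling = "balanced") {
  classes <- sort(unique(y))
  if (length(classes) != 2) stopf("both classes must be present")
  parts <- lapply(classes, function(cl) {
    idx <- which(y == cl)
    if (length(idx) < 2) stopf("class %s has fewer than 2 members", cl)
    idx <- idx[sample.int(length(idx))]
    n_tr <- min(max(round(train_fraction * length(idx)), 1),
                length(idx) - 1)
    list(train = idx[seq_len(n_tr)], test = idx[-seq_len(n_tr)])
  })
  train <- lapply(parts, `[[`, "train")
  if (negative_sampling == "balanced") {
    b <- min(lengths(train))
    train <- lapply(train, function(tr) tr[seq_len(b)])
  }
  list(train = sort(unlist(train)),
       test = sort(unlist(lapply(parts, `[[`, "test"))))
}

#' Build a binary entropy-gain decision tree
#'
#' Greedy unpruned binary tree: at each node the (feature, midpoint
#' threshold) pair maximizing the Shannon information gain is chosen, with
#' ties broken by lowest feature index then lowest threshold. Growth stops
#' on pure nodes, nodes with fewer than `2 * min_leaf` samples, or when no
#' split has positive gain.
#'
#' @param X numeric sample x feature matrix.
#' @param y 0/1 class vector.
#' @param min_leaf minimum samples per leaf.
#' @return object of class `mcfs_tree`: a list of parallel node vectors
#'   (`feature` 1-based or 0 for leaves, `threshold`, `gain`, `n`, `left`,
#'   `right`, `pred`).
#' @export
build_tree <- function(X, y, min_leaf = 2L) {
  stopifnot(nrow(X) >= 1, ncol(X) >= 1, length(y) == nrow(X))
  tr <- .build_tree_cpp(as.matrix(X), as.integer(y), as.integer(min_leaf))
  structure(tr, class = "mcfs_tree")
}

#' @export
predict.mcfs_tree <- function(object, newdata, ...) {
  .predict_tree_cpp(unclass(object), as.matrix(newdata))
}

#' Weighted accuracy of a tree on a test set
#'
#' The unweighted mean of per-class recalls, so the score is insensitive to
#' class imbalance in the test part.
#'
#' @param tree an [build_tree()] result.
#' @param X_test,y_test test samples and 0/1 labels; both classes must be
#'   present.
#' @return a value in `[0, 1]`.
#' @export
weighted_accuracy <- function(tree, X_test, y_test) {
  if (length(unique(y_test)) != 2) stopf("test set must contain both classes")
  pred <- predict(tree, X_test)
  mean(vapply(sort(unique(y_test)),
              function(cl) mean(pred[y_test == cl] == cl), 0.0))
}

#' Aggregate relative importance over a forest
#'
#' `RI_g = sum_tau wAcc_tau^u * sum_{nodes of tau splitting on g}
#'  IG(node) * (n(node) / n(root))^v`. Features never used in any tree get
#' importance 0.
#'
#' @param trees list of `list(tree =, wacc =, features =)` entries, where
#'   `features` maps the tree's column indices to global feature indices.
#' @param d global feature count.
#' @param u,v exponents on weighted accuracy and node sample fraction.
#' @return numeric vector of `d` non-negative importances.
#' @export
relative_importance <- function(trees, d, u = 1, v = 1) {
  stopifnot(length(trees) >= 1)
  ri <- numeric(d)
  for (entry in trees) {
    tr <- entry$tree
    internal <- which(tr$feature != 0)
    if (!length(internal)) next
    w <- entry$wacc^u
    contrib <- tr$gain[internal] * (tr$n[internal] / tr$n[1])^v
    g <- entry$features[tr$feature[internal]]
    for (i in seq_along(g)) ri[g[i]] <- ri[g[i]] + w * contrib[i]
  }
  ri
}

#' Run Monte Carlo feature selection
#'
#' Trains `s_projections * t_splits` trees (a fresh projection per
#' projection round, a fresh stratified split per tree) and aggregates the
#' relative importance of every feature. Fully deterministic given
#' `params$seed`.
#'
#' @param X numeric sample x feature matrix (e.g. an enrichment-score
#'   matrix with genes as samples); column names become feature ids.
#' @param y 0/1 class vector (1 = positive / disease gene).
#' @param params an [mcfs_params()] object.
#' @return object of class `feature_ranking`: data.frame with `feature_id`,
#'   `RI`, `rank` (1 = most important; ties resolved by feature order),
#'   plus attributes `cutoff` (NA until [permutation_threshold()] is run)
#'   and `params`.
#' @export
run_mcfs <- function(X, y, params = mcfs_params()) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (length(unique(y)) != 2) stopf("both classes must be present")
  m <- projection_size(params, d)
  ri <- numeric(d)
  for (i in seq_len(params$s_projections)) {
    proj <- with_seed(derive_seed(params$seed, "projection", i),
                      draw_projection(d, m))
    Xp <- X[, proj, drop = FALSE]
    for (j in seq_len(params$t_splits)) {
      sp <- with_seed(derive_seed(params$seed, "split", i, j),
                      split_train_test(y, params$train_fraction,
                                       params$negative_sampling))
      tree <- build_tree(Xp[sp$train, , drop = FALSE], y[sp$train],
                         params$min_leaf)
      wacc <- weighted_accuracy(tree, Xp[sp$test, , drop = FALSE],
                                y[sp$test])
      internal <- which(tree$feature != 0)
      if (length(internal)) {
        contrib <- (wacc^params$u) * tree$gain[internal] *
          (tree$n[internal] / tree$n[1])^params$v
        g <- proj[tree$feature[internal]]
        for (kk in seq_along(g)) ri[g[kk]] <- ri[g[kk]] + contrib[kk]
      }
    }
  }
  feature_ids <- colnames(X) %||% paste0("f", seq_len(d))
  out <- data.frame(feature_id = feature_ids, RI = ri,
                    rank = rank(-ri, ties.method = "first"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("feature_ranking", "data.frame"),
            cutoff = NA_real_, params = params)
}

#' Permutation significance cutoff for relative importance
#'
#' Re-runs [run_mcfs()] on `n_permutations` label-permuted copies of the
#' data (fresh permutation and derived seed per run), records each run's
#' maximum relative importance, and returns the empirical `1 - alpha`
#' quantile of that max-RI sample. Under the null of no feature-label
#' association, the chance that any feature of a real run exceeds the
#' cutoff is approximately `alpha` (family-wise).
#'
#' @inheritParams run_mcfs
#' @return the cutoff (non-negative scalar) with attribute `max_ri`, the
#'   vector of per-permutation maxima.
#' @export
permutation_threshold <- function(X, y, params = mcfs_params()) {
  if (params$n_permutations < 2) stopf("need at least 2 permutations")
  maxes <- vapply(seq_len(params$n_permutations), function(b) {
    yp <- with_seed(derive_seed(params$seed, "perm-labels", b),
                    sample(y))
    pb <- params
    pb$seed <- derive_seed(params$seed, "perm-run", b)
    max(run_mcfs(X, yp, pb)$RI)
  }, 0.0)
  # order statistic with the (B + 1) permutation-test convention, so the
  # family-wise rate of a fresh null run exceeding the cutoff is ~alpha
  k <- min(params$n_permutations,
           ceiling((1 - params$alpha) * (params$n_permutations + 1)))
  cutoff <- sort(maxes)[max(k, 1)]
  structure(cutoff, max_ri = maxes)
}

#' Rank features and flag significance in one call
#'
#' Convenience wrapper: [run_mcfs()] plus [permutation_threshold()],
#' attaching the cutoff and a `significant` flag (`RI > cutoff`).
#'
#' @inheritParams run_mcfs
#' @return a `feature_ranking` data.frame with columns `feature_id`, `RI`,
#'   `rank`, `significant`, and attribute `cutoff`.
#' @export
mcfs_select <- function(X, y, params = mcfs_params()) {
  ranking <- run_mcfs(X, y, params)
  cutoff <- permutation_threshold(X, y, params)
  ranking$significant <- ranking$RI > as.numeric(cutoff)
  attr(ranking, "cutoff") <- as.numeric(cutoff)
  attr(ranking, "max_ri") <- attr(cutoff, "max_ri")
  ranking
}
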