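# End-to-end orchestration: encode genes once, select disease-discriminating
# features per disease, enumerate all disease-set intersections, report
# features shared between diseases, and extract a cross-talk subnetwork for
# the strongest shared feature.

#' Rank features for one disease
#'
#' Labels come from the disease's membership column (1 = positive / reported
#' gene, 0 = negative / other gene); the enrichment encoding is shared
#' across diseases and computed once upstream. The run's seed is derived
#' from the master seed and the disease name, so adding a disease never
#' perturbs the others' results.
#'
#' @param encoding genes x features enrichment matrix (rows aligned with the
#'   matrix's genes).
#' @param matrix a [disease_gene_matrix()].
#' @param disease disease name (a matrix column).
#' @param params an [mcfs_params()]; its seed is treated as the master seed.
#' @return a `feature_ranking` with `significant` flags (see
#'   [mcfs_select()]).
#' @export
run_disease_feature_selection <- function(encoding, matrix, disease,
                                          params = mcfs_params()) {
  if (!(disease %in% colnames(matrix))) {
    stopf("unknown disease '%s'; valid names: %s", disease,
          paste(colnames(matrix), collapse = ", "))
  }
  stopifnot(identical(rownames(encoding), rownames(matrix)))
  y <- as.integer(matrix[, disease])
  if (sum(y) == 0) stopf("disease '%s' has no positive genes", disease)
  if (sum(y) == nrow(matrix)) stopf("disease '%s' has no negatives", disease)
  p <- params
  p$seed <- derive_seed(params$seed, "disease", disease)
  mcfs_select(encoding, y, p)
}

#' Features selected in two or more diseases
#'
#' For every feature, collects the diseases in which it was selected
#' (significant features by default, or the top-`top_n` by rank) and keeps
#' features shared by at least two diseases, sorted by the number of
#' diseases (descending) then feature id.
#'
#' @param rankings named list of per-disease `feature_ranking` objects.
#' @param top_n `"significant"` (default) or an integer: select each
#'   disease's top `top_n` features by rank instead.
#' @return data.frame with columns `feature_id`, `n_diseases`, `diseases`
#'   (semicolon-joined).
#' @export
shared_feature_report <- function(rankings, top_n = "significant") {
  stopifnot(length(rankings) >= 2, !is.null(names(rankings)))
  selected <- lapply(rankings, function(r) {
    if (identical(top_n, "significant")) {
      if (is.null(r$significant)) stopf("ranking lacks significance flags")
      r$feature_id[r$significant]
    } else {
      r$feature_id[r$rank <= as.integer(top_n)]
    }
  })
  tab <- table(unlist(selected))
  shared <- names(tab)[tab >= 2]
  if (!length(shared)) {
    return(data.frame(feature_id = character(), n_diseases = integer(),
                      diseases = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(shared, function(f) {
    ds <- names(selected)[vapply(selected, function(s) f %in% s, TRUE)]
    data.frame(feature_id = f, n_diseases = length(ds),
               diseases = paste(ds, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_diseases, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-talk subnetwork between two diseases and a shared term
#'
#' Maps the genes of two diseases and of a shared functional term onto the
#' network and extracts the induced subgraph. Node categories follow the
#' precedence overlap (flagged in both diseases) > disease-only >
#' term-only, so a gene in both diseases is `overlap` regardless of term
#' membership.
#'
#' @param matrix a [disease_gene_matrix()].
#' @param diseaseA,diseaseB disease names (matrix columns).
#' @param term_genes character vector: the shared term's gene set.
#' @param network a [functional_network()].
#' @return object of class `crosstalk_subnetwork`: list with `nodes`
#'   (data.frame `gene`, `category`) and `edges` (induced edge table).
#' @export
crosstalk_subnetwork <- function(matrix, diseaseA, diseaseB, term_genes,
                                 network) {
  for (d in c(diseaseA, diseaseB)) {
    if (!(d %in% colnames(matrix))) {
      stopf("unknown disease '%s'; valid names: %s", d,
            paste(colnames(matrix), collapse = ", "))
    }
  }
  sets <- disease_gene_sets(matrix)
  a <- sets[[diseaseA]]
  b <- sets[[diseaseB]]
  term_genes <- unique(as.character(term_genes))
  all_nodes <- sort(unique(c(a, b, term_genes)))
  category <- ifelse(all_nodes %in% intersect(a, b), "overlap",
              ifelse(all_nodes %in% a, "diseaseA_only",
              ifelse(all_nodes %in% b, "diseaseB_only", "term_only")))
  present <- intersect(all_nodes, network_nodes(network))
  sub <- igraph::induced_subgraph(network$graph, present)
  edges <- network_edges(structure(list(graph = sub),
                                   class = "functional_network"))
  structure(list(nodes = data.frame(gene = all_nodes, category = category,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "crosstalk_subnetwork")
}

#' @export
print.crosstalk_subnetwork <- function(x, ...) {
  cat(sprintf("crosstalk_subnetwork: %d nodes (%d overlap), %d edges\n",
              nrow(x$nodes), sum(x$nodes$category == "overlap"),
              nrow(x$edges)))
  invisible(x)
}

#' Run the whole study end to end
#'
#' Either generates the synthetic benchmark bundle or loads real inputs,
#' encodes every gene once, runs per-disease feature selection, enumerates
#' all disease-set intersections, reports features shared between diseases,
#' and extracts a cross-talk subnetwork for the most widely shared feature
#' (or an explicitly requested disease pair and term). All outputs are
#' plain TSV/JSON/YAML and byte-reproducible from the seed.
#'
#' @param config list (or path to a YAML file with the same structure):
#'   \describe{
#'     \item{inputs}{optional list with paths `matrix`, `network`, `gmt`
#'       (one or more); when absent the synthetic bundle is generated.}
#'     \item{synthetic}{optional list of [synthetic_config()] overrides.}
#'     \item{score_threshold}{edge-confidence cutoff for the network
#'       (default 0).}
#'     \item{universe_size}{optional explicit universe `N` for encoding and
#'       intersections.}
#'     \item{mcfs}{list of [mcfs_params()] overrides.}
#'     \item{top_n}{`"significant"` or integer, for the shared-feature
#'       report.}
#'     \item{crosstalk}{optional list `diseaseA`, `diseaseB`, `term_id`.}
#'     \item{seed}{mandatory master seed.}
#'   }
#' @param out_dir output directory.
#' @return invisibly, a list with every in-memory result (`matrix`,
#'   `network`, `catalog`, `encoding`, `rankings`, `intersections`,
#'   `shared`, `crosstalk`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stopf("config$seed is mandatory")
  config$seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed: %d", config$seed))

  if (is.null(config$inputs)) {
    syn <- do.call(synthetic_config,
                   c(config$synthetic %||% list(),
                     list(seed = derive_seed(config$seed, "synthetic"))))
    bundle_dir <- file.path(out_dir, "bundle")
    generate_benchmark_bundle(syn, bundle_dir)
    matrix <- read_disease_gene_matrix(
      file.path(bundle_dir, "disease_gene_matrix.tsv"))
    network <- read_network_edges(file.path(bundle_dir, "network.txt"),
                                  config$score_threshold %||% 0L)
    catalog <- read_gmt(file.path(bundle_dir, "annotations.gmt"))
    log_lines <- c(log_lines, "inputs: synthetic bundle",
                   sprintf("synthetic seed: %d", syn$seed))
  } else {
    matrix <- read_disease_gene_matrix(config$inputs$matrix)
    network <- read_network_edges(config$inputs$network,
                                  config$score_threshold %||% 0L)
    gmts <- lapply(config$inputs$gmt, read_gmt)
    catalog <- if (length(gmts) == 1) gmts[[1]] else {
      annotation_catalog(
        unlist(lapply(gmts, `[[`, "term_ids")),
        unlist(lapply(gmts, `[[`, "descriptions")),
        do.call(c, lapply(gmts, `[[`, "gene_sets")))
    }
    log_lines <- c(log_lines,
                   sprintf("inputs: %s", paste(unlist(config$inputs),
                                               collapse = ", ")))
  }

  encoding <- encode_profiles(network, catalog, rownames(matrix),
                              universe_size = config$universe_size)
  log_lines <- c(log_lines,
                 sprintf("encoding: %d genes x %d features (digest %s)",
                         nrow(encoding), ncol(encoding),
                         substr(paste(
                           format(sum(encoding), digits = 15),
                           collapse = ""), 1, 20)))

  mcfs_over <- config$mcfs %||% list()
  mcfs_over$seed <- config$seed
  params <- do.call(mcfs_params, mcfs_over)
  rankings <- list()
  for (disease in colnames(matrix)) {
    rk <- run_disease_feature_selection(encoding, matrix, disease, params)
    rankings[[disease]] <- rk
    write_report(as.data.frame(rk),
                 file.path(out_dir, paste0("ranking_", disease, ".tsv")))
    log_lines <- c(log_lines,
                   sprintf("disease %s: seed %d, cutoff %.6g, %d significant",
                           disease, derive_seed(config$seed, "disease",
                                                disease),
                           attr(rk, "cutoff"), sum(rk$significant)))
  }

  intersections <- enumerate_intersections(matrix, config$universe_size)
  write_report(intersections, file.path(out_dir, "intersections.tsv"))

  shared <- shared_feature_report(rankings,
                                  config$top_n %||% "significant")
  write_report(shared, file.path(out_dir, "shared_features.tsv"))

  crosstalk <- NULL
  ct_cfg <- config$crosstalk
  if (is.null(ct_cfg) && nrow(shared) > 0) {
    ds <- strsplit(shared$diseases[1], ";", fixed = TRUE)[[1]]
    ct_cfg <- list(diseaseA = ds[1], diseaseB = ds[2],
                   term_id = shared$feature_id[1])
  }
  if (!is.null(ct_cfg)) {
    term_genes <- catalog$gene_sets[[ct_cfg$term_id]]
    if (is.null(term_genes)) stopf("unknown term '%s'", ct_cfg$term_id)
    crosstalk <- crosstalk_subnetwork(matrix, ct_cfg$diseaseA,
                                      ct_cfg$diseaseB, term_genes, network)
    write_report(crosstalk$nodes,
                 file.path(out_dir, "crosstalk_nodes.tsv"))
    write_report(crosstalk$edges,
                 file.path(out_dir, "crosstalk_edges.tsv"))
    log_lines <- c(log_lines,
                   sprintf("crosstalk: %s vs %s via %s", ct_cfg$diseaseA,
                           ct_cfg$diseaseB, ct_cfg$term_id))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(matrix = matrix, network = network, catalog = catalog,
                 encoding = encoding, rankings = rankings,
                 intersections = intersections, shared = shared,
                 crosstalk = crosstalk))
}
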