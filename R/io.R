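#' @useDynLib fibrotalk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dhyper phyper quantile rbinom runif setNames
#' @importFrom utils combn head read.delim write.table
NULL

# ---- disease-gene membership matrix ----------------------------------------

#' Construct a disease-gene membership matrix
#'
#' A genes x diseases 0/1 matrix recording which genes have been associated
#' with which disease. Row and column order is meaningful and preserved by all
#' operations.
#'
#' @param membership integer matrix of 0/1 values with row names (gene
#'   symbols) and column names (disease names).
#' @return an object of class `disease_gene_matrix`: the validated integer
#'   matrix.
#' @export
disease_gene_matrix <- function(membership) {
  if (!is.matrix(membership) || is.null(rownames(membership)) ||
      is.null(colnames(membership))) {
    stopf("membership must be a matrix with gene row names and disease column names")
  }
  if (!all(membership %in% c(0L, 1L))) {
    stopf("membership values must be exactly 0 or 1")
  }
  if (anyDuplicated(rownames(membership))) {
    stopf("duplicate gene symbol: %s",
          rownames(membership)[duplicated(rownames(membership))][1])
  }
  if (anyDuplicated(colnames(membership))) {
    stopf("duplicate disease name: %s",
          colnames(membership)[duplicated(colnames(membership))][1])
  }
  storage.mode(membership) <- "integer"
  structure(membership, class = c("disease_gene_matrix", "matrix", "array"))
}

#' Read a disease-gene membership matrix from TSV
#'
#' Expects a header line `gene<TAB>disease1<TAB>...` followed by one row per
#' gene with 0/1 entries. Duplicate gene rows and non-binary cells are errors.
#'
#' @param path path to the TSV file.
#' @return a [disease_gene_matrix()].
#' @export
read_disease_gene_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (nrow(df) == 0 || ncol(df) < 2) {
    stopf("empty or malformed disease-gene matrix: %s", path)
  }
  genes <- df[[1]]
  diseases <- colnames(df)[-1]
  if (anyDuplicated(genes)) {
    stopf("duplicate gene symbol in %s: %s", path, genes[duplicated(genes)][1])
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(body %in% c("0", "1")))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(body)) + 1
    j <- ((bad[1] - 1) %/% nrow(body)) + 1
    stopf("non-{0,1} cell '%s' at gene '%s', disease '%s' in %s",
          body[bad[1]], genes[i], diseases[j], path)
  }
  m <- matrix(as.integer(body), nrow = nrow(body),
              dimnames = list(genes, diseases))
  disease_gene_matrix(m)
}

#' Write a disease-gene membership matrix as TSV
#'
#' Inverse of [read_disease_gene_matrix()].
#'
#' @param matrix a [disease_gene_matrix()].
#' @param path output path.
#' @export
write_disease_gene_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), unclass(matrix),
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-disease gene sets of a membership matrix
#'
#' @param matrix a [disease_gene_matrix()].
#' @return named list of character vectors, one gene set per disease, in
#'   column order.
#' @export
disease_gene_sets <- function(matrix) {
  lapply(setNames(colnames(matrix), colnames(matrix)),
         function(d) rownames(matrix)[matrix[, d] == 1L])
}

# ---- functional-association network ----------------------------------------

#' Construct a functional-association network
#'
#' An undirected gene network with integer confidence scores in `[0, 999]`
#' following the STRING `protein.links` convention. Self-loops are rejected
#' and reciprocal duplicates collapse to a single edge keeping the maximum
#' score.
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param nodes optional character vector of node names; nodes appearing in
#'   `edges` are always included.
#' @return an object of class `functional_network` wrapping an
#'   [igraph::graph] with a `score` edge attribute.
#' @export
functional_network <- function(edges, nodes = NULL) {
  if (nrow(edges)) {
    if (any(edges$combined_score < 0 | edges$combined_score > 999)) {
      stopf("combined_score outside [0, 999]")
    }
    self <- edges$protein1 == edges$protein2
    if (any(self)) {
      warnf("skipping %d self-loop line(s)", sum(self))
      edges <- edges[!self, , drop = FALSE]
    }
    a <- pmin(edges$protein1, edges$protein2)
    b <- pmax(edges$protein1, edges$protein2)
    key <- paste(a, b, sep = "\r")
    agg <- tapply(edges$combined_score, key, max)
    pairs <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    edges <- data.frame(protein1 = pairs[, 1], protein2 = pairs[, 2],
                        combined_score = as.integer(agg),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
    rownames(edges) <- NULL
  }
  vnames <- sort(unique(c(nodes, edges$protein1, edges$protein2)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(vnames), name = vnames)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$protein1, edges$protein2),
                           score = edges$combined_score)
  }
  structure(list(graph = g), class = "functional_network")
}

#' Read a STRING-style edge list
#'
#' Whitespace-delimited file with a header and columns `protein1`,
#' `protein2`, `combined_score`. Edges scoring below `score_threshold` are
#' dropped; reciprocal duplicates keep the maximum score; self-loops are
#' skipped with a warning.
#'
#' @param path path to the edge-list file.
#' @param score_threshold integer in `[0, 999]`; edges with
#'   `combined_score < score_threshold` are discarded.
#' @return a [functional_network()].
#' @export
read_network_edges <- function(path, score_threshold = 0L) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  stopifnot(score_threshold >= 0, score_threshold <= 999)
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines <= 1) {
    return(functional_network(data.frame(protein1 = character(),
                                         protein2 = character(),
                                         combined_score = integer())))
  }
  df <- read.table(path, header = TRUE, colClasses = "character",
                   stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% colnames(df))) {
    stopf("network file must have columns %s", paste(need, collapse = ", "))
  }
  score <- suppressWarnings(as.integer(df$combined_score))
  if (anyNA(score) || any(score < 0 | score > 999)) {
    stopf("combined_score outside [0, 999] in %s", path)
  }
  keep <- score >= score_threshold
  functional_network(data.frame(protein1 = df$protein1[keep],
                                protein2 = df$protein2[keep],
                                combined_score = score[keep],
                                stringsAsFactors = FALSE))
}

#' Write a network as a STRING-style edge list
#'
#' @param network a [functional_network()].
#' @param path output path.
#' @export
write_network_edges <- function(network, path) {
  write.table(network_edges(network), path, sep = " ", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Node names of a functional network
#' @param network a [functional_network()].
#' @return character vector of gene names.
#' @export
network_nodes <- function(network) {
  igraph::V(network$graph)$name %||% character()
}

#' Edge table of a functional network
#' @param network a [functional_network()].
#' @return data.frame with columns `protein1`, `protein2`, `combined_score`,
#'   one row per unordered edge, sorted.
#' @export
network_edges <- function(network) {
  g <- network$graph
  if (igraph::ecount(g) == 0) {
    return(data.frame(protein1 = character(), protein2 = character(),
                      combined_score = integer()))
  }
  el <- igraph::as_edgelist(g)
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  df <- data.frame(protein1 = a, protein2 = b,
                   combined_score = as.integer(igraph::E(g)$score),
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein1, df$protein2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("functional_network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

# ---- annotation catalogs (GMT) ---------------------------------------------

#' Construct an annotation catalog
#'
#' An ordered collection of functional terms (GO terms, KEGG pathways, ...),
#' each with an id, a free-text description, and a non-empty gene set. GO and
#' KEGG terms are treated identically as features.
#'
#' @param term_ids character vector of unique term identifiers.
#' @param descriptions character vector, same length.
#' @param gene_sets list of character vectors, same length; duplicates within
#'   a set are removed.
#' @return an object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(term_ids, descriptions, gene_sets) {
  stopifnot(length(term_ids) == length(descriptions),
            length(term_ids) == length(gene_sets))
  if (anyDuplicated(term_ids)) {
    stopf("duplicate term_id: %s", term_ids[duplicated(term_ids)][1])
  }
  gene_sets <- lapply(gene_sets, function(g) unique(as.character(g)))
  if (any(lengths(gene_sets) == 0) && length(gene_sets)) {
    stopf("term with empty gene set: %s",
          term_ids[which(lengths(gene_sets) == 0)[1]])
  }
  names(gene_sets) <- term_ids
  structure(list(term_ids = as.character(term_ids),
                 descriptions = as.character(descriptions),
                 gene_sets = gene_sets),
            class = "annotation_catalog")
}

#' @export
length.annotation_catalog <- function(x) length(x$term_ids)

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation_catalog: %d terms, median set size %g\n",
              length(x), stats::median(lengths(x$gene_sets))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: one term per line,
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Genes are deduplicated
#' within a term; file order is preserved.
#'
#' @param path path to the GMT file.
#' @return an [annotation_catalog()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stopf("GMT line %d has fewer than 3 fields in %s", short[1], path)
  }
  annotation_catalog(
    term_ids = vapply(fields, `[[`, "", 1),
    descriptions = vapply(fields, `[[`, "", 2),
    gene_sets = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write an annotation catalog as GMT
#'
#' @param catalog an [annotation_catalog()].
#' @param path output path.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(seq_along(catalog$term_ids), function(i) {
    paste(c(catalog$term_ids[i], catalog$descriptions[i],
            catalog$gene_sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- tabular reports -------------------------------------------------------

#' Write a tabular report
#'
#' Deterministic serialization of a record table: column order as given, row
#' order as given, doubles rendered with 6 significant digits. TSV output
#' round-trips through [read_report()].
#'
#' @param records data.frame of records sharing one schema.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  if (format == "tsv") {
    txt <- out
    for (j in seq_along(txt)) {
      if (is.double(txt[[j]])) {
        txt[[j]] <- ifelse(is.na(txt[[j]]), "NA",
                           formatC(txt[[j]], digits = 6, format = "g"))
      }
    }
    write.table(txt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read a tabular report written by [write_report()]
#'
#' @param path path to the report.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame of records.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
               quote = "", stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
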