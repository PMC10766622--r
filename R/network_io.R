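#' Load an interactome as a simple undirected gene network
#'
#' Reads a protein-interaction network from a two-column edge list (TSV or
#' whitespace-separated; extra columns ignored) or a GraphML file. Gene
#' symbols are trimmed and upper-cased, self-edges are dropped and duplicate
#' edges collapsed, yielding a simple undirected [igraph::igraph] graph.
#'
#' @param path path to the network file.
#' @param format `"auto"` (by file extension), `"edgelist"` or `"graphml"`.
#' @param provenance free-text source tag stored as a graph attribute.
#' @return an undirected simple `igraph` graph with vertex names.
#' @export
load_interactome <- function(path, format = c("auto", "edgelist", "graphml"),
                             provenance = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::V(g)$name)) stop("GraphML file has no vertex names")
    igraph::V(g)$name <- toupper(trimws(igraph::V(g)$name))
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
    if (!any(keep)) stop("empty network file: ", path)
    idx <- which(keep)
    fields <- strsplit(trimws(lines[idx]), "[\t ]+")
    nf <- lengths(fields)
    if (any(nf < 2L))
      stop("unparseable edge list row (fewer than 2 fields) at line ",
           idx[which(nf < 2L)[1L]])
    el <- cbind(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
    el <- toupper(trimws(el))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
  }
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_graph_attr(g, "provenance", provenance)
  validate_gene_network(g, require_connected = FALSE)
  g
}

# Invariants every gene network must satisfy. Connectivity is only required
# after LCC extraction, so it is opt-in.
validate_gene_network <- function(net, require_connected = TRUE) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::is_directed(net)) stop("gene network must be undirected")
  if (any(igraph::which_loop(net))) stop("gene network must have no self-edges")
  if (any(igraph::which_multiple(net))) stop("gene network must be simple")
  if (is.null(igraph::V(net)$name)) stop("gene network nodes must be named")
  if (require_connected && igraph::count_components(net) != 1L)
    stop("gene network must be connected")
  invisible(net)
}

#' Restrict a network to a gene set and extract the largest connected component
#'
#' Takes the subgraph induced on the intersection of `genes` with the network
#' nodes, then keeps the largest connected component. Ties on component size
#' are broken deterministically by the component containing the
#' lexicographically smallest node name.
#'
#' @param net an undirected simple `igraph` gene network.
#' @param genes character vector of gene symbols, or `"all"` to keep every
#'   node.
#' @return the connected induced subgraph (`igraph`).
#' @export
restrict_and_lcc <- function(net, genes = "all") {
  validate_gene_network(net, require_connected = FALSE)
  if (!(length(genes) == 1L && identical(genes, "all"))) {
    if (length(genes) == 0L) stop("gene restriction set is empty")
    genes <- toupper(trimws(genes))
    keep <- intersect(igraph::V(net)$name, genes)
    if (length(keep) == 0L)
      stop("no overlap between the restriction set and the network nodes")
    net <- igraph::induced_subgraph(net, keep)
  }
  comp <- igraph::components(net)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    # deterministic tie-break: component holding the smallest node name
    first_member <- vapply(big, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, "")
    big <- big[order(first_member)][1L]
  }
  out <- igraph::induced_subgraph(net, which(comp$membership == big))
  validate_gene_network(out, require_connected = TRUE)
  out
}

#' Filter genes by minimum read-count support
#'
#' Keeps genes observed with at least `min_count` reads in at least
#' `min_samples` samples. The filter is monotone: raising either threshold
#' never adds genes.
#'
#' @param counts nonnegative integer matrix of raw counts, genes in rows,
#'   samples in columns.
#' @param min_samples,min_count inclusion thresholds (defaults 10 and 10).
#' @return the row-subset count matrix (possibly with zero rows).
#' @export
gene_inclusion_filter <- function(counts, min_samples = 10L, min_count = 10L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  keep <- rowSums(counts >= min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Load an expression matrix
#'
#' Reads a delimited table with a header row of sample identifiers and gene
#' symbols in the first column. Gene symbols are trimmed and upper-cased;
#' duplicated symbols or missing values are errors.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param sep field separator; `NULL` picks `","` for `.csv`, tab otherwise.
#' @param transpose set when the file stores samples in rows.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
load_expression <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- toupper(trimws(as.character(tab[[1L]])))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (transpose) mat <- t(mat)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene symbols in expression matrix: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyNA(mat)) stop("expression matrix contains missing values")
  mat
}

#' Load a sample-to-subtype label table
#'
#' Two-column TSV (sample, label), no header required.
#'
#' @param path path to the label file.
#' @return named character vector of labels, names are sample identifiers.
#' @export
load_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label file must have two columns: sample, label")
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Write a gene network as a canonical two-column edge list
#'
#' Edges are written with endpoints sorted within each row and rows sorted
#' lexicographically, so output is deterministic and round-trips through
#' [load_interactome()].
#'
#' @param net an `igraph` gene network.
#' @param path output path (TSV).
#' @export
write_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(net)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# TSV writers for result matrices/tables (genes or samples in rows).
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records every effective parameter of a run together with seed and package
#' version, so a run is reproducible from its manifest alone.
#'
#' @param params named list of parameters.
#' @param path output JSON path.
#' @export
write_manifest <- function(params, path) {
  params$package <- "curvnet"
  params$version <- as.character(utils::packageVersion("curvnet"))
  params$r_version <- as.character(getRversion())
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# Match expression genes onto network nodes; genes absent from the network
# are dropped from network analyses but reported.
match_genes <- function(expr, net, quiet = FALSE) {
  nodes <- igraph::V(net)$name
  dropped <- setdiff(rownames(expr), nodes)
  if (length(dropped) > 0L && !quiet)
    message(length(dropped),
            " expression gene(s) absent from the network were dropped: ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  missing <- setdiff(nodes, rownames(expr))
  if (length(missing) > 0L)
    stop("network nodes missing from the expression matrix: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "")
  expr[nodes, , drop = FALSE]
}
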