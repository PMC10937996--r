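#' Load a protein-interaction network from disk
#'
#' Reads an undirected network from a whitespace/tab edge list (two identifier
#' columns, an optional third column is ignored), GraphML, or SIF. The result
#' is simplified to an undirected simple graph: duplicate edges are collapsed
#' and self-loops dropped, with a message reporting how many of each were
#' removed.
#'
#' @param path path to the network file.
#' @param format one of `"auto"` (guess from the file extension),
#'   `"edgelist"`, `"graphml"`, `"sif"`.
#' @return an undirected simple `igraph` graph with named vertices.
#' @export
load_network <- function(path, format = c("auto", "edgelist", "graphml",
                                          "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     graphml = "graphml", xml = "graphml", sif = "sif",
                     "edgelist")
  }
  g <- switch(format,
    edgelist = {
      tab <- tryCatch(
        utils::read.table(path, header = FALSE, colClasses = "character",
                          comment.char = "#"),
        error = function(e) stop("failed to parse edge list: ",
                                 conditionMessage(e)))
      if (ncol(tab) < 2) stop("edge list needs at least two columns")
      igraph::graph_from_data_frame(tab[, 1:2], directed = FALSE)
    },
    graphml = {
      g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                    error = function(e) stop("failed to parse GraphML: ",
                                             conditionMessage(e)))
      if (is.null(igraph::V(g)$name))
        igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
      igraph::as_undirected(g, mode = "collapse")
    },
    sif = read_sif(path))
  if (igraph::vcount(g) == 0) stop("network is empty")
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loops > 0) message("dropped ", n_loops, " self-loop(s)")
  if (n_multi > 0) message("collapsed ", n_multi, " duplicate edge(s)")
  g
}

# SIF: "node relation target1 [target2 ...]"; a line with a single token
# declares an isolated node
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("SIF file is empty")
  edges <- character(0)
  singletons <- character(0)
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(tok) == 1) {
      singletons <- c(singletons, tok)
    } else if (length(tok) >= 3) {
      edges <- c(edges, rbind(tok[1], tok[-(1:2)]))
    } else {
      stop("malformed SIF line (expected 1 or >=3 tokens): ", ln)
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  verts <- unique(c(edges, singletons))
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (length(edges))
    g <- igraph::add_edges(g, match(edges, verts))
  g
}

#' Read a gene-expression table
#'
#' Accepts delimited text (TSV/CSV, genes as rows, samples as columns, header
#' row required, first column gene identifiers) or Matrix Market (`.mtx`) with
#' companion row- and column-name files.
#'
#' @param path path to the expression table.
#' @param row_names,col_names for MTX input: paths to one-identifier-per-line
#'   files naming the genes (rows) and samples (columns).
#' @return numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path, row_names = NULL, col_names = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(row_names) || is.null(col_names))
      stop("MTX input requires row_names and col_names files")
    rownames(m) <- readLines(row_names, warn = FALSE)
    colnames(m) <- readLines(col_names, warn = FALSE)
    return(m)
  }
  sep <- if (ext == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, comment.char = "")
  as.matrix(tab)
}

#' Read a gene-to-protein mapping table
#'
#' @param path two-column TSV (`gene_id`, `protein_id`), header optional (a
#'   header row named `gene_id` is detected and skipped).
#' @return data.frame with columns `gene_id`, `protein_id`.
#' @export
read_mapping <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2) stop("mapping table needs two columns")
  tab <- tab[, 1:2]
  names(tab) <- c("gene_id", "protein_id")
  if (nrow(tab) && identical(tolower(tab$gene_id[1]), "gene_id"))
    tab <- tab[-1, , drop = FALSE]
  tab
}

#' Write an edge field as a three-column TSV
#'
#' @param field an `edge_field`
#' @param path output path
#' @param value_name column name for the value column.
#' @return `path`, invisibly.
#' @export
write_edge_field <- function(field, path, value_name = "weight") {
  df <- as.data.frame(field)
  names(df)[3] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a matched network as an edge list plus expression table
#'
#' Produces `<stem>.edges.tsv` (two columns) and `<stem>.expr.tsv` (gene,
#' value), the formats [load_network()] and [read_expression()] read back.
#'
#' @param net a `matched_network`
#' @param stem output path stem
#' @return character vector of the two paths written, invisibly.
#' @export
write_matched_network <- function(net, stem) {
  edges_path <- paste0(stem, ".edges.tsv")
  expr_path <- paste0(stem, ".expr.tsv")
  utils::write.table(
    data.frame(a = net$node_ids[net$edge_i], b = net$node_ids[net$edge_j]),
    edges_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(gene = net$node_ids, sample1 = net$expression),
    expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges_path, expr_path))
}
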