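# Protein-protein interaction graph and hub ranking --------------------------

#' Read a PPI edge list
#'
#' Accepts STRING-export-like delimited text with two node columns and an
#' optional numeric score column (`protein1<TAB>protein2[<TAB>combined_score]`).
#' A header line naming the columns is detected and skipped. Edges are
#' undirected: self-loops are removed and symmetric duplicates collapse to
#' one edge (the maximum score is kept when scores are present).
#'
#' @param path Path to the edge-list file.
#' @param allowed_genes Optional gene set; edges with an endpoint outside it
#'   are dropped.
#' @param min_score Optional score cutoff; edges scoring below it are
#'   dropped (requires a score column).
#' @param sep Field separator.
#' @return Object of class `PPIGraph`: list with `nodes` and `edges` (data
#'   frame `a`, `b`, `score`; `score` is `NA` when absent).
#' @export
read_ppi <- function(path, allowed_genes = NULL, min_score = NULL, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, sep, fixed = TRUE)
  start <- 1
  if (length(fields) > 0) {
    f1 <- tolower(fields[[1]])
    if (any(f1 %in% c("protein1", "node_a", "gene1", "source"))) start <- 2
  }
  a <- character(0); b <- character(0); s <- numeric(0)
  for (i in seq_along(fields)[seq_along(fields) >= start]) {
    f <- trimws(fields[[i]])
    if (length(f) < 2 || any(f[1:2] == "")) {
      stop("malformed PPI line ", i, " in ", path, ": '", lines[i], "'")
    }
    sc <- NA_real_
    if (length(f) >= 3 && f[3] != "") {
      sc <- suppressWarnings(as.numeric(f[3]))
      if (is.na(sc)) {
        stop("malformed PPI line ", i, " in ", path,
             ": non-numeric score '", f[3], "'")
      }
    }
    a <- c(a, f[1]); b <- c(b, f[2]); s <- c(s, sc)
  }
  edges <- data.frame(a = a, b = b, score = s, stringsAsFactors = FALSE)
  ppi_graph(edges, allowed_genes = allowed_genes, min_score = min_score)
}

#' Construct a PPI graph from an edge data frame
#'
#' @param edges Data frame with columns `a`, `b` and optionally `score`.
#' @param allowed_genes,min_score As in [read_ppi()].
#' @param isolated_nodes Optional extra nodes with no edges.
#' @return A `PPIGraph`.
#' @export
ppi_graph <- function(edges, allowed_genes = NULL, min_score = NULL,
                      isolated_nodes = character(0)) {
  if (is.null(edges$score)) edges$score <- rep(NA_real_, nrow(edges))
  if (!is.null(min_score)) {
    edges <- edges[!is.na(edges$score) & edges$score >= min_score, ,
                   drop = FALSE]
  }
  if (!is.null(allowed_genes)) {
    edges <- edges[edges$a %in% allowed_genes & edges$b %in% allowed_genes, ,
                   drop = FALSE]
    isolated_nodes <- intersect(isolated_nodes, allowed_genes)
  }
  edges <- edges[edges$a != edges$b, , drop = FALSE]   # no self-loops
  if (nrow(edges) > 0) {
    lo <- pmin(edges$a, edges$b)
    hi <- pmax(edges$a, edges$b)
    key <- paste(lo, hi, sep = "\r")
    score <- tapply(edges$score, key, function(x) {
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    })
    uk <- sort(unique(key))
    parts <- strsplit(uk, "\r", fixed = TRUE)
    edges <- data.frame(a = vapply(parts, `[`, "", 1),
                        b = vapply(parts, `[`, "", 2),
                        score = as.numeric(score[uk]),
                        stringsAsFactors = FALSE)
  }
  if (nrow(edges) == 0 && length(isolated_nodes) == 0) {
    warning("PPI graph is empty")
  }
  nodes <- sort(unique(c(edges$a, edges$b, isolated_nodes)))
  structure(list(nodes = nodes, edges = edges), class = "PPIGraph")
}

#' @export
print.PPIGraph <- function(x, ...) {
  cat(sprintf("PPIGraph: %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a PPI graph
#'
#' @param g A `PPIGraph`.
#' @return Named integer vector over all nodes (isolated nodes get 0).
#' @export
ppi_degree <- function(g) {
  deg <- stats::setNames(integer(length(g$nodes)), g$nodes)
  if (nrow(g$edges) > 0) {
    tab <- table(c(g$edges$a, g$edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Top-k hub genes by degree
#'
#' Ranks nodes by decreasing degree, ties broken lexicographically by gene
#' id, and returns the first `k`. If the graph has fewer than `k` nodes,
#' all are returned with a warning.
#'
#' @param g A `PPIGraph` with at least one node.
#' @param k Number of hubs (default 20).
#' @return Object of class `HubSet`: data frame with `rank`, `gene`,
#'   `degree`.
#' @export
top_hubs <- function(g, k = 20) {
  if (length(g$nodes) == 0) stop("empty PPI graph")
  if (k < 1) stop("`k` must be >= 1")
  deg <- ppi_degree(g)
  ord <- order(-deg, names(deg))
  if (length(ord) < k) {
    warning("graph has only ", length(ord), " nodes; returning all")
    k <- length(ord)
  }
  sel <- ord[seq_len(k)]
  structure(data.frame(rank = seq_len(k), gene = names(deg)[sel],
                       degree = unname(deg[sel]), stringsAsFactors = FALSE),
            class = c("HubSet", "data.frame"))
}

#' Induced subgraph on a node subset
#'
#' @param g A `PPIGraph`.
#' @param nodes Nodes to keep.
#' @return A `PPIGraph` on `intersect(nodes, g$nodes)`.
#' @export
ppi_subgraph <- function(g, nodes) {
  keep <- intersect(g$nodes, nodes)
  suppressWarnings(
    ppi_graph(g$edges, allowed_genes = keep, isolated_nodes = keep))
}

#' Write a PPI edge list as TSV
#'
#' @param g A `PPIGraph`.
#' @param path Output path.
#' @param header Write a `protein1/protein2/combined_score` header row?
#' @return `path`, invisibly.
#' @export
write_ppi <- function(g, path, header = TRUE) {
  df <- g$edges
  colnames(df) <- c("protein1", "protein2", "combined_score")
  if (all(is.na(df$combined_score))) df$combined_score <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}
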