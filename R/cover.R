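# Bipartite miRNA-target network and minimum set cover ----------------------

#' Build a bipartite miRNA-target network restricted to a gene set
#'
#' Parses (or accepts) a two-column `mirna<TAB>gene` edge list, restricts it
#' to the genes of interest, and records genes with no incident regulator as
#' `uncoverable` rather than silently dropping them. Duplicate edges
#' collapse to one.
#'
#' @param edges Path to a delimited edge file (a `mirna`/`gene` header line
#'   is detected and skipped), or a data frame with columns `mirna`, `gene`.
#' @param gene_set Target genes of interest (the set the cover must hit).
#' @param sep Field separator for file input.
#' @return Object of class `BipartiteRegNet`: list with `genes` (the
#'   requested gene set), `mirnas`, `edges` (deduplicated data frame),
#'   `target_sets` (named list, miRNA -> covered genes, sorted), and
#'   `uncoverable` (genes with zero incident edges).
#' @export
build_bipartite <- function(edges, gene_set, sep = "\t") {
  if (is.character(edges) && length(edges) == 1) {
    path <- edges
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, sep, fixed = TRUE)
    start <- 1
    if (length(fields) > 0 &&
        any(tolower(fields[[1]]) %in% c("mirna", "regulator"))) {
      start <- 2
    }
    mir <- character(0); gene <- character(0)
    for (i in seq_along(fields)[seq_along(fields) >= start]) {
      f <- trimws(fields[[i]])
      if (length(f) < 2 || any(f[1:2] == "")) {
        stop("malformed bipartite line ", i, " in ", path, ": '",
             lines[i], "'")
      }
      mir <- c(mir, f[1]); gene <- c(gene, f[2])
    }
    edges <- data.frame(mirna = mir, gene = gene, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("mirna", "gene") %in% names(edges)))
  gene_set <- unique(as.character(gene_set))
  edges <- edges[edges$gene %in% gene_set, c("mirna", "gene"), drop = FALSE]
  edges <- unique(edges)
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  target_sets <- lapply(split(edges$gene, edges$mirna), sort)
  target_sets <- target_sets[order(names(target_sets))]
  uncoverable <- sort(setdiff(gene_set, unique(edges$gene)))
  structure(list(genes = gene_set, mirnas = names(target_sets), edges = edges,
                 target_sets = target_sets, uncoverable = uncoverable),
            class = "BipartiteRegNet")
}

#' @export
print.BipartiteRegNet <- function(x, ...) {
  cat(sprintf("BipartiteRegNet: %d miRNAs, %d genes (%d uncoverable), %d edges\n",
              length(x$mirnas), length(x$genes), length(x$uncoverable),
              nrow(x$edges)))
  invisible(x)
}

#' miRNA degrees (target-set sizes) in a bipartite network
#'
#' @param net A `BipartiteRegNet`.
#' @return Named integer vector, miRNA -> number of targeted genes.
#' @export
mirna_degree <- function(net) {
  vapply(net$target_sets, length, integer(1))
}

.cover_solution <- function(net, selected, newly_covered, method) {
  covered <- sort(unique(as.character(
    unlist(net$target_sets[selected], use.names = FALSE))))
  # validity certificate, asserted on every run
  want <- sort(setdiff(net$genes, net$uncoverable))
  if (!identical(covered, want)) {
    stop("internal error: ", method, " cover is not a valid cover")
  }
  structure(list(selected = selected, newly_covered = newly_covered,
                 covered = covered, dropped = net$uncoverable,
                 method = method),
            class = "CoverSolution")
}

#' @export
print.CoverSolution <- function(x, ...) {
  cat(sprintf("CoverSolution (%s): %d miRNAs cover %d genes (%d dropped as uncoverable)\n",
              x$method, length(x$selected), length(x$covered),
              length(x$dropped)))
  for (i in seq_along(x$selected)) {
    cat(sprintf("  %d. %s (+%d genes)\n", i, x$selected[i],
                length(x$newly_covered[[i]])))
  }
  invisible(x)
}

#' Greedy minimum set cover over a bipartite regulator network
#'
#' Genes without any regulator are excluded up front and reported in
#' `dropped`. Then, repeatedly, the miRNA covering the most still-uncovered
#' genes is selected (ties broken lexicographically by miRNA id) until every
#' coverable gene is covered. The selection order and per-step newly covered
#' genes are recorded.
#'
#' @param net A `BipartiteRegNet`.
#' @return Object of class `CoverSolution`: list with `selected` (ordered
#'   miRNAs), `newly_covered` (named list of gene sets, one per step),
#'   `covered`, `dropped` (uncoverable genes), `method = "greedy"`.
#' @export
greedy_cover <- function(net) {
  stopifnot(inherits(net, "BipartiteRegNet"))
  uncovered <- setdiff(net$genes, net$uncoverable)
  selected <- character(0)
  newly <- list()
  sets <- net$target_sets   # name-sorted, so which.max ties go lexicographic
  while (length(uncovered) > 0) {
    gain <- vapply(sets, function(s) length(intersect(s, uncovered)),
                   integer(1))
    best <- names(sets)[which.max(gain)]
    new_genes <- sort(intersect(sets[[best]], uncovered))
    selected <- c(selected, best)
    newly[[best]] <- new_genes
    uncovered <- setdiff(uncovered, new_genes)
    sets[[best]] <- NULL
  }
  .cover_solution(net, selected, newly, "greedy")
}

#' Exact minimum set cover by branch-and-bound
#'
#' Finds a minimum-cardinality miRNA cover of the coverable genes by
#' iterative-deepening depth-first search over miRNAs in lexicographic
#' order, so the returned solution is the lexicographically smallest among
#' all minimum covers. Intended as the optimality certificate for
#' [greedy_cover()]; the search is exponential in the number of miRNAs and
#' refuses instances larger than `max_mirnas`.
#'
#' @param net A `BipartiteRegNet`.
#' @param max_mirnas Size guard (default 25).
#' @return A `CoverSolution` with `method = "exact"`; `selected` is in
#'   lexicographic order.
#' @export
exact_cover <- function(net, max_mirnas = 25) {
  stopifnot(inherits(net, "BipartiteRegNet"))
  l <- length(net$mirnas)
  if (l > max_mirnas) {
    stop("instance has ", l, " miRNAs (> max_mirnas = ", max_mirnas,
         "); use greedy_cover()")
  }
  genes <- sort(setdiff(net$genes, net$uncoverable))
  if (length(genes) == 0) {
    return(.cover_solution(net, character(0), list(), "exact"))
  }
  ng <- length(genes)
  sets <- lapply(net$target_sets, function(s) match(s, genes))
  sizes <- vapply(sets, length, integer(1))
  # suffix reachability: genes coverable using sets i..l only
  reach <- vector("list", l + 1)
  reach[[l + 1]] <- logical(ng)
  for (i in rev(seq_len(l))) {
    r <- reach[[i + 1]]
    r[sets[[i]]] <- TRUE
    reach[[i]] <- r
  }
  if (!all(reach[[1]])) {
    stop("internal error: coverable gene unreachable from target sets")
  }

  found <- NULL
  dfs <- function(start, chosen, covered, remaining) {
    if (!any(!covered)) {
      found <<- chosen
      return(TRUE)
    }
    if (remaining == 0 || start > l) return(FALSE)
    n_unc <- sum(!covered)
    for (i in start:l) {
      if (l - i + 1 < remaining) break
      if (any(!covered & !reach[[i]])) return(FALSE)  # a gene is now unreachable
      if (max(sizes[i:l]) * remaining < n_unc) return(FALSE)
      gain <- sum(!covered[sets[[i]]])
      if (gain == 0) next
      cov2 <- covered
      cov2[sets[[i]]] <- TRUE
      if (dfs(i + 1, c(chosen, i), cov2, remaining - 1)) return(TRUE)
    }
    FALSE
  }
  max_size <- max(sizes)
  for (k in seq(from = max(1, ceiling(ng / max_size)), to = l)) {
    found <- NULL
    if (dfs(1, integer(0), logical(ng), k)) break
  }
  if (is.null(found)) stop("internal error: no cover found")
  selected <- net$mirnas[found]
  # per-step newly covered genes, replayed in selection (lex) order
  newly <- list()
  covered <- character(0)
  for (m in selected) {
    newly[[m]] <- sort(setdiff(net$target_sets[[m]], covered))
    covered <- union(covered, net$target_sets[[m]])
  }
  .cover_solution(net, selected, newly, "exact")
}

#' Write a cover solution report (TSV steps + JSON summary)
#'
#' @param sol A `CoverSolution`.
#' @param path Output path for the TSV (one row per selection step); a
#'   `.json` sibling with the full solution is written alongside.
#' @return `path`, invisibly.
#' @export
write_cover <- function(sol, path) {
  steps <- data.frame(
    step = seq_along(sol$selected),
    mirna = sol$selected,
    newly_covered = vapply(sol$newly_covered, function(g)
      paste(g, collapse = ","), character(1)),
    n_new = vapply(sol$newly_covered, length, integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json_path <- paste0(sub("\\.[^.]*$", "", path), ".json")
  jsonlite::write_json(
    list(method = sol$method, selected = sol$selected,
         newly_covered = sol$newly_covered, covered = sol$covered,
         dropped = sol$dropped),
    json_path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' The published worked cover instance bundled with the package
#'
#' Returns the path to the bundled miRNA-target edge list (35 edges over 5
#' miRNAs and 17 genes) and the 20-gene hub list it regulates.
#'
#' @param which `"edges"` or `"hub_genes"`.
#' @return A file path.
#' @export
example_cover_instance <- function(which = c("edges", "hub_genes")) {
  which <- match.arg(which)
  fname <- switch(which,
                  edges = "asd_mirna_targets.tsv",
                  hub_genes = "asd_hub_genes.tsv")
  system.file("extdata", fname, package = "netbiomark", mustWork = TRUE)
}
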