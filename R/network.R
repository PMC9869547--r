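# Signed-hybrid co-expression network, TOM, modules, eigengenes -------------

#' Module color palette
#'
#' Fixed color order used to name modules by descending size; the first
#' (largest) module is always "turquoise" and unassigned genes are "grey".
#' Versioned here so partitions are reproducible across runs.
#'
#' @return Character vector of color names.
#' @export
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}

#' Signed-hybrid weighted adjacency from expression
#'
#' Computes pairwise gene-gene correlations (biweight midcorrelation by
#' default) and converts them to a soft-thresholded signed-hybrid adjacency:
#' positive correlations are raised to the power `beta`, non-positive
#' correlations become 0. The diagonal is stored as 0 so connectivity sums
#' never include self-edges.
#'
#' @param em An `ExpressionMatrix` (>= 2 genes, >= 3 samples), or a plain
#'   genes x samples numeric matrix with rownames.
#' @param beta Positive integer soft-thresholding power (default 8).
#' @param correlation_kind `"bicor"` (default) or `"pearson"`.
#' @return An object of class `CoexpressionNetwork`: list with `gene_ids`,
#'   `adjacency` (symmetric, entries in \[0,1\], zero diagonal), `beta`,
#'   `correlation_kind`.
#' @export
signed_hybrid_adjacency <- function(em, beta = 8,
                                    correlation_kind = c("bicor", "pearson")) {
  correlation_kind <- match.arg(correlation_kind)
  x <- if (inherits(em, "ExpressionMatrix")) em$values else em
  if (!is.matrix(x) || nrow(x) < 2) stop("need at least 2 genes")
  if (ncol(x) < 3) stop("need at least 3 samples")
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be positive")
  r <- if (correlation_kind == "bicor") {
    bicor_matrix(x)
  } else {
    cv <- .row_vars(x)
    if (any(cv == 0)) {
      stop("undefined correlation: '", rownames(x)[which(cv == 0)[1]],
           "' is constant")
    }
    stats::cor(t(x))
  }
  a <- ifelse(r > 0, r^beta, 0)
  diag(a) <- 0
  structure(list(gene_ids = rownames(x), adjacency = a, beta = beta,
                 correlation_kind = correlation_kind),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork: %d genes, %s^%g signed-hybrid adjacency\n",
              length(x$gene_ids), x$correlation_kind, x$beta))
  invisible(x)
}

#' Topological overlap matrix
#'
#' For adjacency `a` with zero diagonal, the topological overlap of genes i
#' and j is `(L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_u a_iu * a_uj` counts shared-neighbour strength and `k_i` is
#' the connectivity of gene i. The diagonal is 1 by convention and the
#' clustering dissimilarity is `1 - TOM`.
#'
#' @param net A `CoexpressionNetwork`.
#' @return Object of class `TOMatrix`: list with `gene_ids`, `tom`
#'   (symmetric, in \[0,1\], unit diagonal) and `dissimilarity` (`1 - tom`).
#' @export
topological_overlap <- function(net) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  a <- net$adjacency
  k <- rowSums(a)
  l <- a %*% a                       # zero diagonal excludes u = i, j terms
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom[tom > 1] <- 1
  structure(list(gene_ids = net$gene_ids, tom = tom,
                 dissimilarity = 1 - tom),
            class = "TOMatrix")
}

#' Detect modules by hierarchical clustering of the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a height
#' that is a fixed fraction of the maximum merge height. `deep_split` in
#' 0..3 maps to cut fractions 0.998, 0.995, 0.99, 0.985: larger values cut
#' lower and produce more, smaller clusters. (TOM dissimilarities crowd
#' close to 1, so usable cuts sit just below the top of the tree.)
#' Clusters smaller than
#' `min_module_size` are collapsed into the unassigned group (label 0,
#' "grey"); surviving modules are relabelled 1, 2, ... by descending size
#' and named from [module_palette()], so the largest module is always
#' "turquoise".
#'
#' @param tomd A `TOMatrix`.
#' @param min_module_size Minimum genes per module (default 30).
#' @param deep_split Integer in 0..3 (default 2).
#' @return Object of class `ModulePartition`: list with `gene_ids`,
#'   `label_of` (named integer, 0 = unassigned), `color_of` (named by
#'   label), `min_module_size`, `deep_split`.
#' @export
cluster_modules <- function(tomd, min_module_size = 30, deep_split = 2) {
  stopifnot(inherits(tomd, "TOMatrix"))
  if (!deep_split %in% 0:3) stop("`deep_split` must be in 0..3")
  genes <- tomd$gene_ids
  n <- length(genes)
  labels <- integer(n)
  names(labels) <- genes
  if (min_module_size <= n) {
    d <- stats::as.dist(tomd$dissimilarity)
    tree <- stats::hclust(d, method = "average")
    h0 <- c(0.998, 0.995, 0.99, 0.985)[deep_split + 1] * max(tree$height)
    raw <- stats::cutree(tree, h = h0)
    sizes <- table(raw)
    big <- names(sizes)[sizes >= min_module_size]
    # descending size; ties by first cutree label for determinism
    big <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(big)) {
      labels[raw == as.integer(big[i])] <- i
    }
  }
  new_module_partition(genes, labels, min_module_size, deep_split)
}

#' Build a module partition from explicit labels
#'
#' @param gene_ids Character vector of gene ids.
#' @param labels Integer labels aligned with `gene_ids` (0 = unassigned).
#' @param min_module_size,deep_split Recorded parameters.
#' @return A `ModulePartition`.
#' @export
new_module_partition <- function(gene_ids, labels, min_module_size = 30,
                                 deep_split = 2) {
  labels <- as.integer(labels)
  names(labels) <- gene_ids
  k <- max(labels, 0L)
  pal <- module_palette()
  cols <- if (k > 0) {
    c(pal, sprintf("module%d", seq_len(max(0, k - length(pal)))))[seq_len(k)]
  } else {
    character(0)
  }
  color_of <- stats::setNames(c("grey", cols), as.character(0:k))
  structure(list(gene_ids = gene_ids, label_of = labels, color_of = color_of,
                 min_module_size = min_module_size, deep_split = deep_split),
            class = "ModulePartition")
}

#' @export
print.ModulePartition <- function(x, ...) {
  sizes <- table(x$label_of)
  nz <- setdiff(names(sizes), "0")
  cat(sprintf("ModulePartition: %d modules over %d genes (%d unassigned)\n",
              length(nz), length(x$gene_ids),
              sum(x$label_of == 0L)))
  if (length(nz) > 0) {
    for (l in nz) {
      cat(sprintf("  %s: %d genes\n", x$color_of[[l]], sizes[[l]]))
    }
  }
  invisible(x)
}

#' Genes of one module
#'
#' @param part A `ModulePartition`.
#' @param module Module label (integer) or color name.
#' @return Character vector of gene ids.
#' @export
module_genes <- function(part, module) {
  if (is.character(module) && !module %in% names(part$color_of)) {
    lab <- names(part$color_of)[part$color_of == module]
    if (length(lab) == 0) stop("no module named '", module, "'")
    module <- as.integer(lab)
  }
  names(part$label_of)[part$label_of == as.integer(module)]
}

#' Per-gene module colors
#'
#' @param part A `ModulePartition`.
#' @return Named character vector, gene id -> color.
#' @export
module_colors <- function(part) {
  stats::setNames(part$color_of[as.character(part$label_of)],
                  names(part$label_of))
}

#' Write a module partition as TSV (gene_id, label, color)
#'
#' @param part A `ModulePartition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  utils::write.table(
    data.frame(gene_id = part$gene_ids,
               label = unname(part$label_of),
               color = unname(module_colors(part)),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' gene-standardized module submatrix: a unit-norm vector over samples,
#' sign-oriented so its mean correlation with member gene profiles is
#' positive. It summarizes the module's expression across samples.
#'
#' @param em An `ExpressionMatrix` covering the partition's genes.
#' @param part A `ModulePartition`; every nonzero-label module needs >= 2
#'   genes.
#' @return Object of class `EigengeneSet`: list with `eigengenes` (samples
#'   x modules matrix, columns named `ME<color>`) and `sample_ids`.
#' @export
module_eigengenes <- function(em, part) {
  labs <- sort(unique(part$label_of[part$label_of > 0L]))
  if (length(labs) == 0) stop("no modules in partition")
  out <- matrix(NA_real_, nrow = ncol(em$values), ncol = length(labs))
  colnames(out) <- paste0("ME", part$color_of[as.character(labs)])
  rownames(out) <- sample_ids(em)
  for (j in seq_along(labs)) {
    color <- part$color_of[[as.character(labs[j])]]
    members <- intersect(module_genes(part, labs[j]), gene_ids(em))
    if (length(members) < 2) {
      stop("module '", color, "' has fewer than 2 genes in the matrix")
    }
    x <- em$values[members, , drop = FALSE]
    v <- .row_vars(x)
    if (all(v == 0)) stop("module '", color, "' contains only constant genes")
    if (any(v == 0)) {
      warning("dropping ", sum(v == 0), " constant gene(s) from module '",
              color, "' for eigengene computation")
      x <- x[v > 0, , drop = FALSE]
    }
    xs <- t(scale(t(x)))               # standardize each gene across samples
    sv <- svd(t(xs), nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (mean(stats::cor(e, t(xs))) < 0) e <- -e
    out[, j] <- e
  }
  structure(list(eigengenes = out, sample_ids = sample_ids(em)),
            class = "EigengeneSet")
}
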