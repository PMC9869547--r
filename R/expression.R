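# Expression matrices and differential expression ---------------------------

#' Construct an expression matrix object
#'
#' Container for a genes x samples matrix of log2-scale expression values
#' together with a control/case group label per sample. Values are assumed
#' already normalized (e.g. RMA) and on the log2 scale; no renormalization
#' is performed anywhere in the package.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique non-missing rownames (gene ids) and colnames (sample ids).
#' @param groups Named character vector mapping every sample id to
#'   `"control"` or `"case"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `group_of` (named character vector aligned
#'   with `colnames(values)`).
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || anyNA(gene_ids) || any(gene_ids == "")) {
    stop("gene ids (rownames) must be present and non-missing")
  }
  if (is.null(sample_ids) || anyNA(sample_ids) || any(sample_ids == "")) {
    stop("sample ids (colnames) must be present and non-missing")
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing) > 0) {
    stop("sample(s) missing from group map: ", paste(missing, collapse = ", "))
  }
  group_of <- as.character(groups[sample_ids])
  names(group_of) <- sample_ids
  bad <- !group_of %in% c("control", "case")
  if (any(bad)) {
    stop("group labels must be 'control' or 'case'; offending sample(s): ",
         paste(sample_ids[bad], collapse = ", "))
  }
  structure(list(values = values, group_of = group_of),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  tab <- table(factor(x$group_of, levels = c("control", "case")))
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d control, %d case)\n",
              nrow(x$values), ncol(x$values), tab[["control"]], tab[["case"]]))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample accessors
#'
#' @param em An `ExpressionMatrix`.
#' @return Character vectors of gene or sample identifiers.
#' @export
gene_ids <- function(em) rownames(em$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(em) colnames(em$values)

#' Subset an expression matrix to one sample group
#'
#' @param em An `ExpressionMatrix`.
#' @param group `"control"` or `"case"`.
#' @return An `ExpressionMatrix` with only the requested samples.
#' @export
subset_group <- function(em, group = c("control", "case")) {
  group <- match.arg(group)
  keep <- names(em$group_of)[em$group_of == group]
  if (length(keep) == 0) stop("no samples in group '", group, "'")
  expression_matrix(em$values[, keep, drop = FALSE], em$group_of[keep])
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids,
#' with a numeric body (tab-separated by default).
#'
#' @param path Path to the delimited file.
#' @param group_map Either a named character vector (sample id -> group), a
#'   data frame with columns `sample_id` and `group`, or a path to a
#'   two-column headerless TSV with those fields. Groups must be
#'   `"control"`/`"case"`.
#' @param sep Field separator.
#' @return An `ExpressionMatrix`; row and column order are preserved from
#'   the file.
#' @export
read_expression <- function(path, group_map, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("expression file needs a gene id column plus samples")
  gid <- df[[1]]
  dup <- gid[duplicated(gid)]
  if (length(dup) > 0) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  sample_names <- colnames(df)[-1]
  dup <- sample_names[duplicated(sample_names)]
  if (length(dup) > 0) {
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    idx <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
    if (nrow(idx) > 0) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                   body[idx[1, 1], idx[1, 2]], gid[idx[1, 1]],
                   sample_names[idx[1, 2]], path))
    }
    stop("missing values in expression body of ", path)
  }
  dimnames(num) <- list(gid, sample_names)
  expression_matrix(num, .resolve_group_map(group_map))
}

.resolve_group_map <- function(group_map) {
  if (is.character(group_map) && length(group_map) == 1 && is.null(names(group_map)) &&
      file.exists(group_map)) {
    df <- utils::read.table(group_map, header = FALSE, sep = "\t",
                            col.names = c("sample_id", "group"),
                            colClasses = "character", quote = "")
    group_map <- df
  }
  if (is.data.frame(group_map)) {
    stats::setNames(as.character(group_map$group), group_map$sample_id)
  } else {
    group_map
  }
}

#' Write an expression matrix (and optionally its group map) to TSV
#'
#' @param em An `ExpressionMatrix`.
#' @param path Output path for the expression TSV (first column `gene_id`).
#' @param groups_path Optional output path for a headerless two-column
#'   `sample_id<TAB>group` TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, groups_path = NULL) {
  df <- data.frame(gene_id = gene_ids(em), em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(
      data.frame(sample_id = sample_ids(em), group = unname(em$group_of)),
      groups_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Keep the most variable genes
#'
#' Ranks genes by sample variance pooled over all samples (both groups) and
#' retains the top `ceiling(keep_fraction * m)`. Ties at the cutoff are
#' broken lexicographically by gene id so the result is deterministic; the
#' original gene order is preserved among survivors.
#'
#' @param em An `ExpressionMatrix` with at least 2 samples.
#' @param keep_fraction Fraction of genes to keep, in (0, 1].
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_diverse_genes <- function(em, keep_fraction = 0.25) {
  if (nrow(em$values) == 0) stop("empty expression matrix")
  if (ncol(em$values) < 2) stop("need at least 2 samples to compute variance")
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("`keep_fraction` must be in (0, 1]")
  }
  m <- nrow(em$values)
  n_keep <- ceiling(keep_fraction * m)
  v <- .row_vars(em$values)
  ord <- order(-v, gene_ids(em))
  keep <- sort(ord[seq_len(n_keep)])  # restore original row order
  expression_matrix(em$values[keep, , drop = FALSE], em$group_of)
}

.row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Per-gene differential expression between case and control
#'
#' Welch two-sample t-tests on log2 expression, Benjamini-Hochberg
#' adjustment across all tested genes. `log_fc` is mean(case) -
#' mean(control), so positive values mean higher expression in cases. A gene
#' is flagged as differentially expressed when `|log_fc| > lfc_threshold`
#' AND `adj_p < alpha` (both inequalities strict). Genes with zero variance
#' in both groups get `p_value = 1` (the fold change is still reported).
#'
#' @param em An `ExpressionMatrix` with at least 2 samples per group.
#' @param lfc_threshold Positive log2 fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A data frame with columns `gene_id`, `log_fc`, `p_value`,
#'   `adj_p`, `is_deg`.
#' @export
differential_expression <- function(em, lfc_threshold = 1, alpha = 0.05) {
  stopifnot(lfc_threshold > 0, alpha > 0, alpha < 1)
  ctrl <- em$values[, em$group_of == "control", drop = FALSE]
  case <- em$values[, em$group_of == "case", drop = FALSE]
  n_c <- ncol(ctrl)
  n_a <- ncol(case)
  if (n_c < 2 || n_a < 2) stop("both groups need at least 2 samples")
  m_c <- rowMeans(ctrl)
  m_a <- rowMeans(case)
  v_c <- .row_vars(ctrl)
  v_a <- .row_vars(case)
  log_fc <- m_a - m_c
  se2 <- v_a / n_a + v_c / n_c
  tstat <- log_fc / sqrt(se2)
  # Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_c / n_c)^2 / (n_c - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- 1
  adj_p <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene_id = gene_ids(em),
    log_fc = unname(log_fc),
    p_value = unname(p),
    adj_p = unname(adj_p),
    is_deg = unname(abs(log_fc) > lfc_threshold & adj_p < alpha),
    stringsAsFactors = FALSE
  )
}

#' Write a differential-expression table as TSV
#'
#' @param deg Data frame from [differential_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
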