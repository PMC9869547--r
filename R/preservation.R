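# Permutation-based module preservation -------------------------------------

#' Module preservation Z statistics between a reference and a test network
#'
#' Quantifies, per module, whether the co-expression structure seen in the
#' reference network reproduces in the test network. Two observed statistics
#' are computed for each module M:
#'
#' * density `D(M)`: mean test-network adjacency over unordered gene pairs
#'   in M — are M's genes as densely connected in the test network?
#' * connectivity `C(M)`: Pearson correlation between the intramodular
#'   connectivity vectors of M's genes in the reference and test networks —
#'   is the within-module connectivity pattern similar?
#'
#' The permutation null redraws, `n_permutations` times, a uniform random
#' gene set of the same size from the full analyzed gene universe and
#' recomputes both statistics. Each observed statistic is standardized
#' against its null (`Z = (obs - mean) / sd`), and
#' `z_summary = (z_density + z_connectivity) / 2`. Modules with
#' `z_summary < threshold` (default 2) are flagged non-preserved. The
#' unassigned (grey, label 0) group is never tested, though its genes stay
#' in the sampling universe.
#'
#' @param ref,test `CoexpressionNetwork` objects sharing gene ids (the
#'   intersection is used, with a warning if they differ).
#' @param part A `ModulePartition` over (a superset of) the shared genes.
#' @param n_permutations Number of permutation draws (>= 20, default 200).
#' @param seed Optional integer seed fixing the permutation draws.
#' @param threshold Non-preservation cutoff on `z_summary` (default 2).
#' @return Object of class `PreservationReport`: a data frame with columns
#'   `module_label`, `module_color`, `module_size`, `z_density`,
#'   `z_connectivity`, `z_summary`, `non_preserved`, and attributes
#'   `n_permutations`, `seed`, `threshold`. Modules with fewer than 3
#'   shared genes are skipped with a warning.
#' @export
preservation_statistics <- function(ref, test, part, n_permutations = 200,
                                    seed = NULL, threshold = 2) {
  stopifnot(inherits(ref, "CoexpressionNetwork"),
            inherits(test, "CoexpressionNetwork"),
            inherits(part, "ModulePartition"))
  if (n_permutations < 20) stop("`n_permutations` must be >= 20")
  universe <- intersect(ref$gene_ids, test$gene_ids)
  if (length(universe) < length(ref$gene_ids) ||
      length(universe) < length(test$gene_ids)) {
    warning("reference and test networks differ; using the ",
            length(universe), "-gene intersection")
  }
  a_ref <- ref$adjacency[universe, universe, drop = FALSE]
  a_test <- test$adjacency[universe, universe, drop = FALSE]
  labs <- part$label_of[universe]

  mod_stats <- function(idx) {
    s <- length(idx)
    at <- a_test[idx, idx, drop = FALSE]
    dens <- sum(at) / (s * (s - 1))
    kim_ref <- rowSums(a_ref[idx, idx, drop = FALSE])
    kim_test <- rowSums(at)
    conn <- if (stats::sd(kim_ref) == 0 || stats::sd(kim_test) == 0) {
      0
    } else {
      stats::cor(kim_ref, kim_test)
    }
    c(dens, conn)
  }

  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }

  tested <- sort(unique(labs[labs > 0L]))
  rows <- list()
  for (lab in tested) {
    idx <- which(labs == lab)
    color <- part$color_of[[as.character(lab)]]
    if (length(idx) < 3) {
      warning("module '", color, "' has fewer than 3 genes; skipped")
      next
    }
    obs <- mod_stats(idx)
    perm <- matrix(NA_real_, n_permutations, 2)
    for (p in seq_len(n_permutations)) {
      perm[p, ] <- mod_stats(sample.int(length(universe), length(idx)))
    }
    mu <- colMeans(perm)
    sdv <- apply(perm, 2, stats::sd)
    z <- (obs - mu) / sdv
    if (any(sdv == 0)) {
      warning("degenerate permutation null for module '", color,
              "'; Z set to +/-Inf")
      z[sdv == 0] <- ifelse(obs[sdv == 0] >= mu[sdv == 0], Inf, -Inf)
    }
    rows[[length(rows) + 1]] <- data.frame(
      module_label = lab, module_color = color, module_size = length(idx),
      z_density = z[1], z_connectivity = z[2],
      z_summary = (z[1] + z[2]) / 2,
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  if (is.null(rep)) {
    rep <- data.frame(module_label = integer(0), module_color = character(0),
                      module_size = integer(0), z_density = numeric(0),
                      z_connectivity = numeric(0), z_summary = numeric(0))
  }
  rep$non_preserved <- rep$z_summary < threshold
  attr(rep, "n_permutations") <- n_permutations
  attr(rep, "seed") <- seed
  attr(rep, "threshold") <- threshold
  class(rep) <- c("PreservationReport", "data.frame")
  rep
}

#' Write a preservation report as TSV
#'
#' @param report A `PreservationReport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preservation <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
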