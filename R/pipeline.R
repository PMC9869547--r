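# Pipeline orchestration ----------------------------------------------------

#' Pipeline configuration with study defaults
#'
#' Collects every stage parameter with its default: soft power 8, biweight
#' midcorrelation, minimum module size 30, deep split 2, 200 permutations,
#' Z_summary threshold 2, top 20 hubs, variance-filter fraction 0.25, DEG
#' thresholds |logFC| > 1 and adjusted p < 0.05. The configuration is
#' serialized into the run manifest so every output directory records how
#' it was produced.
#'
#' @param keep_fraction,power,correlation_kind,min_module_size,deep_split
#'   Network-construction parameters (see the stage functions).
#' @param n_permutations,z_threshold Preservation-test parameters.
#' @param k_hubs Hub-set size.
#' @param lfc_threshold,alpha DEG thresholds.
#' @param min_ppi_score Optional PPI score cutoff (default none).
#' @param seed Integer seed for the permutation test.
#' @return A named list of class `RunConfig`.
#' @export
run_config <- function(keep_fraction = 0.25, power = 8,
                       correlation_kind = "bicor", min_module_size = 30,
                       deep_split = 2, n_permutations = 200, z_threshold = 2,
                       k_hubs = 20, lfc_threshold = 1, alpha = 0.05,
                       min_ppi_score = NULL, seed = 1) {
  structure(list(keep_fraction = keep_fraction, power = power,
                 correlation_kind = correlation_kind,
                 min_module_size = min_module_size, deep_split = deep_split,
                 n_permutations = n_permutations, z_threshold = z_threshold,
                 k_hubs = k_hubs, lfc_threshold = lfc_threshold,
                 alpha = alpha, min_ppi_score = min_ppi_score, seed = seed),
            class = "RunConfig")
}

#' Stage one: modules, preservation, hubs
#'
#' Runs the gene-discovery stage: variance-filter the pooled expression
#' matrix, build the control-group network as the reference and the
#' case-group network as the test, detect modules on the reference TOM,
#' test each module's preservation in the case network, and rank hub genes
#' (by PPI degree) for every non-preserved module. If several modules are
#' non-preserved each gets its own hub set; if none is, `hubs` is an empty
#' list and `status` says so.
#'
#' @param em An `ExpressionMatrix` with both groups, or a path to an
#'   expression TSV (then `groups` must be given).
#' @param ppi A `PPIGraph` or a path to a PPI edge list.
#' @param config A [run_config()].
#' @param groups Group map (only when `em` is a path).
#' @return List with `expression` (filtered), `ref_network`, `test_network`,
#'   `partition`, `eigengenes`, `preservation`, `hubs` (named list of
#'   `HubSet` by module color, largest non-preserved module first),
#'   `status`, `manifest`.
#' @export
run_fa_gene <- function(em, ppi, config = run_config(), groups = NULL) {
  inputs <- list()
  if (is.character(em)) {
    inputs$expression <- em
    em <- read_expression(em, groups)
  }
  if (is.character(ppi)) {
    inputs$ppi <- ppi
    ppi <- read_ppi(ppi, min_score = config$min_ppi_score)
  }
  fem <- filter_diverse_genes(em, config$keep_fraction)
  ref <- signed_hybrid_adjacency(subset_group(fem, "control"),
                                 beta = config$power,
                                 correlation_kind = config$correlation_kind)
  test <- signed_hybrid_adjacency(subset_group(fem, "case"),
                                  beta = config$power,
                                  correlation_kind = config$correlation_kind)
  tomd <- topological_overlap(ref)
  part <- cluster_modules(tomd, min_module_size = config$min_module_size,
                          deep_split = config$deep_split)
  eig <- if (any(part$label_of > 0L)) {
    module_eigengenes(subset_group(fem, "control"), part)
  } else {
    NULL
  }
  pres <- preservation_statistics(ref, test, part,
                                  n_permutations = config$n_permutations,
                                  seed = config$seed,
                                  threshold = config$z_threshold)
  np <- pres[pres$non_preserved, , drop = FALSE]
  np <- np[order(-np$module_size), , drop = FALSE]
  hubs <- list()
  for (i in seq_len(nrow(np))) {
    genes <- module_genes(part, np$module_label[i])
    sub <- ppi_subgraph(ppi, genes)
    if (length(sub$nodes) == 0) {
      warning("no PPI nodes for non-preserved module '",
              np$module_color[i], "'")
      next
    }
    hubs[[np$module_color[i]]] <- top_hubs(sub, config$k_hubs)
  }
  status <- if (nrow(np) == 0) {
    "all modules preserved"
  } else {
    paste0(nrow(np), " non-preserved module(s): ",
           paste(np$module_color, collapse = ", "))
  }
  manifest <- list(
    config = unclass(config),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    n_genes_in = nrow(em$values), n_genes_analyzed = nrow(fem$values),
    n_modules = sum(part$color_of != "grey"),
    status = status)
  list(expression = fem, ref_network = ref, test_network = test,
       partition = part, eigengenes = eig, preservation = pres, hubs = hubs,
       status = status, manifest = manifest)
}

#' Stage two: minimum miRNA cover of a hub-gene set
#'
#' Builds the bipartite miRNA-target network restricted to the hub genes,
#' reports the genes that have no regulator at all (these are excluded, not
#' covered), and solves the minimum set cover with the requested method.
#'
#' @param hubs A `HubSet`, or a character vector of hub genes.
#' @param edges Bipartite edge list: path or data frame (see
#'   [build_bipartite()]).
#' @param method `"greedy"` (default) or `"exact"`.
#' @param max_mirnas Instance-size guard passed to [exact_cover()].
#' @return List with `network` (the `BipartiteRegNet`) and `solution` (a
#'   `CoverSolution`).
#' @export
run_dmn_mirna <- function(hubs, edges, method = c("greedy", "exact"),
                          max_mirnas = 25) {
  method <- match.arg(method)
  genes <- if (inherits(hubs, "HubSet")) hubs$gene else as.character(hubs)
  if (length(genes) == 0) stop("hub gene set is empty")
  net <- build_bipartite(edges, genes)
  if (length(net$uncoverable) == length(net$genes)) {
    stop("no hub gene has any miRNA regulator in the edge list; ",
         "nothing to cover")
  }
  sol <- if (method == "greedy") {
    greedy_cover(net)
  } else {
    exact_cover(net, max_mirnas = max_mirnas)
  }
  list(network = net, solution = sol)
}

#' Write a run manifest as JSON
#'
#' @param manifest Manifest list (from [run_fa_gene()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
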