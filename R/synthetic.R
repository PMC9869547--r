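# Seeded synthetic data with planted ground truth ---------------------------
#
# Emulates the study design end-to-end without any downloads: two balanced
# sample groups, latent-factor co-expression modules of which exactly one is
# decorrelated in the case group, a PPI graph whose hubs sit in that module,
# and a bipartite regulator network with a certified minimum cover.

#' Generate a case-control expression matrix with planted modules
#'
#' Latent-factor model: each module has one latent sample vector; a member
#' gene is `mu + lambda_g * latent + noise`. Per-gene loadings are drawn as
#' `s_g ~ Uniform(sqrt(within_cor) - loading_spread, sqrt(within_cor) +
#' loading_spread)` with `lambda_g = noise_sd * s_g / sqrt(1 - s_g^2)`, so
#' the correlation between two module genes is `s_i * s_j` and its
#' expectation is exactly `within_cor`, while modules get a realistic
#' core-periphery structure: strongly loaded genes have both higher
#' marginal variance (`noise_sd^2 / (1 - s_g^2)` versus `noise_sd^2` for
#' background genes) and tighter co-expression — which is what lets a
#' variance filter retain coherent module cores. In the case group only,
#' the genes of one planted module draw gene-specific latents, destroying
#' their co-expression while leaving each gene's marginal mean and variance
#' unchanged; the destroyed module is therefore invisible to differential
#' expression. Background genes are independent noise in both groups.
#'
#' @param n_genes Total genes, including background (default 1600).
#' @param n_modules Planted modules (default 8).
#' @param module_size Genes per module (default 100, minimum 3).
#' @param n_control,n_case Samples per group (defaults 21 and 21).
#' @param within_cor Target within-module correlation in (0,1) (default 0.6).
#' @param loading_spread Half-width of the per-gene loading distribution on
#'   the `sqrt(correlation)` scale (default 0.18; clipped to keep loadings
#'   in (0,1)).
#' @param noise_sd Residual standard deviation on the log2 scale (default 1).
#' @param n_hubs Planted hub genes inside the destroyed module (default 20).
#' @param destroyed_module Index of the module decorrelated in cases
#'   (default 1).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List with `expression` (an `ExpressionMatrix`) and `truth` (list
#'   with `module_of`, `destroyed_module`, `hub_genes`, and the generator
#'   parameters; cover fields are filled in by [generate_bipartite()]).
#' @export
generate_expression <- function(n_genes = 1600, n_modules = 8,
                                module_size = 100, n_control = 21,
                                n_case = 21, within_cor = 0.6,
                                loading_spread = 0.18, noise_sd = 1,
                                n_hubs = 20, destroyed_module = 1,
                                seed = 1) {
  if (module_size < 3) stop("`module_size` must be >= 3")
  stopifnot(n_modules >= 1, n_genes >= n_modules * module_size,
            within_cor > 0, within_cor < 1, noise_sd > 0,
            destroyed_module %in% seq_len(n_modules),
            n_hubs <= module_size)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)

  n <- n_control + n_case
  gid <- sprintf("gene_%04d", seq_len(n_genes))
  sid <- c(sprintf("ctrl_%02d", seq_len(n_control)),
           sprintf("case_%02d", seq_len(n_case)))
  groups <- stats::setNames(rep(c("control", "case"), c(n_control, n_case)),
                            sid)
  is_case <- groups == "case"

  mu <- stats::runif(n_genes, 4, 12)          # baseline log2 abundance
  module_of <- integer(n_genes)               # 0 = background
  values <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n,
                   dimnames = list(gid, sid))
  s0 <- sqrt(within_cor)
  for (m in seq_len(n_modules)) {
    rows <- ((m - 1) * module_size + 1):(m * module_size)
    module_of[rows] <- m
    s <- stats::runif(length(rows),
                      max(0.05, s0 - loading_spread),
                      min(0.99, s0 + loading_spread))
    lambda <- noise_sd * s / sqrt(1 - s^2)
    latent <- stats::rnorm(n)
    values[rows, ] <- values[rows, ] + lambda %o% latent
    if (m == destroyed_module) {
      # case group: replace the shared latent by gene-specific latents,
      # leaving each gene's marginal mean and variance untouched
      nc <- sum(is_case)
      own <- matrix(stats::rnorm(length(rows) * nc), length(rows), nc)
      values[rows, is_case] <- values[rows, is_case] +
        lambda * (own - matrix(latent[is_case], length(rows), nc,
                               byrow = TRUE))
    }
  }
  values <- values + mu
  names(module_of) <- gid
  hub_genes <- sort(sample(gid[module_of == destroyed_module], n_hubs))
  truth <- list(module_of = module_of, destroyed_module = destroyed_module,
                hub_genes = hub_genes,
                params = list(n_genes = n_genes, n_modules = n_modules,
                              module_size = module_size,
                              n_control = n_control, n_case = n_case,
                              within_cor = within_cor,
                              loading_spread = loading_spread,
                              noise_sd = noise_sd, seed = seed))
  list(expression = expression_matrix(values, groups), truth = truth)
}

#' Generate a PPI graph whose hubs are the planted hub genes
#'
#' Builds a random graph over the destroyed module's genes by stub pairing:
#' every gene gets `base_degree` stubs, planted hubs get
#' `base_degree + hub_degree_boost`, stubs are shuffled and paired, and
#' self-loops/duplicate pairs are discarded. Hubs therefore end up with
#' stochastically much higher degree than the rest of the module.
#'
#' @param truth Truth list from [generate_expression()].
#' @param hub_degree_boost Extra stubs per hub (default 20).
#' @param base_degree Stubs per ordinary gene (default 4).
#' @param seed Integer seed.
#' @return A `PPIGraph` over the destroyed module's genes.
#' @export
generate_ppi <- function(truth, hub_degree_boost = 20, base_degree = 4,
                         seed = 1) {
  nodes <- names(truth$module_of)[truth$module_of == truth$destroyed_module]
  if (length(nodes) == 0) stop("destroyed module has no genes")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  stubs_per <- stats::setNames(rep(base_degree, length(nodes)), nodes)
  stubs_per[truth$hub_genes] <- base_degree + hub_degree_boost
  stubs <- sample(rep(names(stubs_per), stubs_per))
  if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
  half <- length(stubs) / 2
  edges <- data.frame(a = stubs[seq_len(half)],
                      b = stubs[half + seq_len(half)],
                      stringsAsFactors = FALSE)
  suppressWarnings(
    ppi_graph(edges, isolated_nodes = nodes))
}

#' Generate a bipartite regulator network with a certified minimum cover
#'
#' Targets the planted hub genes. `n_uncoverable` of them receive no
#' regulator at all (they must be excluded, not covered). The remaining
#' genes are covered by `cover_size` designated miRNAs, each of which owns
#' at least one private gene targeted by no other miRNA — so every cover
#' must contain all designated miRNAs and the minimum cover size is exactly
#' `cover_size`. Decoy miRNAs target strict subsets of a designated miRNA's
#' genes (never a private gene), so the greedy heuristic also recovers the
#' designated set. The construction is verified with [exact_cover()] before
#' returning.
#'
#' @param truth Truth list from [generate_expression()].
#' @param n_mirnas Total miRNAs, designated + decoys (default 35).
#' @param cover_size Planted minimum cover size (default 5).
#' @param n_uncoverable Hub genes left without any regulator (default 3).
#' @param seed Integer seed.
#' @return List with `net` (a `BipartiteRegNet` over the hub genes) and
#'   `truth` (the input truth extended with `min_cover_size`,
#'   `min_cover_set`, `uncoverable_genes`).
#' @export
generate_bipartite <- function(truth, n_mirnas = 35, cover_size = 5,
                               n_uncoverable = 3, seed = 1) {
  hubs <- truth$hub_genes
  stopifnot(cover_size >= 1, n_uncoverable >= 0,
            length(hubs) - n_uncoverable >= cover_size,
            n_mirnas >= cover_size)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  uncoverable <- sort(sample(hubs, n_uncoverable))
  coverable <- setdiff(hubs, uncoverable)
  designated <- sprintf("hsa-mir-sim-%02d-5p", seq_len(cover_size))
  decoys <- if (n_mirnas > cover_size) {
    sprintf("hsa-mir-x%03d-3p", seq_len(n_mirnas - cover_size))
  } else {
    character(0)
  }
  # one private gene per designated miRNA, rest of the genes spread randomly
  private <- sample(coverable, cover_size)
  rest <- setdiff(coverable, private)
  owner <- sample(cover_size, length(rest), replace = TRUE)
  sets <- lapply(seq_len(cover_size), function(i) {
    c(private[i], rest[owner == i])
  })
  # overlap between designated sets (on non-private genes), as in real
  # regulator networks where strong miRNAs share targets
  for (i in seq_len(cover_size)) {
    extra <- setdiff(rest, sets[[i]])
    if (length(extra) > 0) {
      n_extra <- stats::rbinom(1, length(extra), 0.3)
      if (n_extra > 0) sets[[i]] <- c(sets[[i]], sample(extra, n_extra))
    }
  }
  names(sets) <- designated
  # decoys: strict subsets of one designated set, private genes excluded,
  # so no decoy ever beats a designated miRNA during greedy selection
  hosts <- which(vapply(seq_len(cover_size),
                        function(i) length(setdiff(sets[[i]], private)) > 0,
                        logical(1)))
  if (length(decoys) > 0 && length(hosts) == 0) {
    stop("cannot place decoy miRNAs: every designated target set is a ",
         "single private gene (increase the gene pool or cut n_mirnas)")
  }
  for (d in decoys) {
    pool <- setdiff(sets[[hosts[sample.int(length(hosts), 1)]]], private)
    n_t <- sample(seq_len(min(3, length(pool))), 1)
    sets[[d]] <- sample(pool, n_t)
  }
  edges <- data.frame(
    mirna = rep(names(sets), vapply(sets, length, integer(1))),
    gene = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  net <- build_bipartite(edges, hubs)
  # generation-time self-check: the planted cover is minimum and greedy
  # agrees with it
  ex <- exact_cover(net, max_mirnas = max(25, n_mirnas))
  if (length(ex$selected) != cover_size ||
      !setequal(ex$selected, designated)) {
    stop("internal error: planted cover is not the exact minimum cover")
  }
  truth$min_cover_size <- cover_size
  truth$min_cover_set <- designated
  truth$uncoverable_genes <- uncoverable
  list(net = net, truth = truth)
}

#' Write a full synthetic dataset to a directory
#'
#' Emits the expression TSV, group map TSV, PPI edge TSV, bipartite edge
#' TSV and a JSON ground-truth file, all plain text, so every pipeline
#' stage can be exercised from files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all three generators.
#' @param ... Passed to [generate_expression()].
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects (`expression`, `ppi`, `bipartite`, `truth`).
#' @export
write_synthetic_dataset <- function(dir, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_expression(seed = seed, ...)
  ppi <- generate_ppi(gen$truth, seed = seed + 1)
  bip <- generate_bipartite(gen$truth, seed = seed + 2)
  truth <- bip$truth
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    bipartite = file.path(dir, "mirna_targets.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression(gen$expression, paths$expression, paths$groups)
  write_ppi(ppi, paths$ppi)
  utils::write.table(bip$net$edges, paths$bipartite, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(module_of = as.list(truth$module_of),
         destroyed_module = truth$destroyed_module,
         hub_genes = truth$hub_genes,
         min_cover_size = truth$min_cover_size,
         min_cover_set = truth$min_cover_set,
         uncoverable_genes = truth$uncoverable_genes,
         params = truth$params),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(expression_obj = gen$expression, ppi_graph = ppi,
                          bipartite_net = bip$net, truth_list = truth)))
}
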