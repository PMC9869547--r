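# Shared fixture builders; everything is generated in code at test time.

tiny_em <- function(values, groups = NULL) {
  if (is.null(groups)) {
    n <- ncol(values)
    groups <- stats::setNames(rep(c("control", "case"), length.out = n),
                              colnames(values))
  }
  expression_matrix(values, groups)
}

random_em <- function(n_genes, n_control, n_case, seed, sd = 1) {
  set.seed(seed)
  n <- n_control + n_case
  v <- matrix(rnorm(n_genes * n, mean = 8, sd = sd), n_genes, n,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  tiny_em(v, stats::setNames(rep(c("control", "case"), c(n_control, n_case)),
                             colnames(v)))
}

# random adjacency with zero diagonal, entries in [0, 1)
random_adjacency <- function(n, seed, density = 0.5) {
  set.seed(seed)
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  vals <- runif(sum(up)) * (runif(sum(up)) < density)
  a[up] <- vals
  a <- a + t(a)
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

as_network <- function(a, beta = 8, kind = "bicor") {
  structure(list(gene_ids = rownames(a), adjacency = a, beta = beta,
                 correlation_kind = kind), class = "CoexpressionNetwork")
}

# independent TOM oracle: direct triple loop over the formula
tom_bruteforce <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# random bipartite cover instance; gene_set = union of all targets plus
# optional regulator-free genes
random_cover_instance <- function(seed, max_mirnas = 12, max_genes = 15,
                                  n_uncoverable = 0) {
  set.seed(seed)
  l <- sample(2:max_mirnas, 1)
  ng <- sample(3:max_genes, 1)
  genes <- sprintf("G%02d", seq_len(ng))
  mirnas <- sprintf("mir-%02d", seq_len(l))
  edges <- do.call(rbind, lapply(mirnas, function(m) {
    k <- sample(seq_len(ng), 1)
    data.frame(mirna = m, gene = sample(genes, k), stringsAsFactors = FALSE)
  }))
  gene_set <- unique(edges$gene)
  if (n_uncoverable > 0) {
    gene_set <- c(gene_set, sprintf("U%02d", seq_len(n_uncoverable)))
  }
  build_bipartite(edges, gene_set)
}

# exhaustive minimum-cover oracle over all 2^l miRNA subsets (bitmask DP)
exhaustive_min_cover <- function(net) {
  genes <- sort(setdiff(net$genes, net$uncoverable))
  l <- length(net$mirnas)
  stopifnot(l <= 20, length(genes) <= 30)
  masks <- vapply(net$target_sets, function(s)
    sum(2^(match(s, genes) - 1)), numeric(1))
  full <- sum(2^(seq_along(genes) - 1))
  if (length(genes) == 0) return(0L)
  union_of <- numeric(2^l)
  best <- Inf
  for (s in seq_len(2^l - 1)) {
    low <- bitwAnd(s, -s)
    union_of[s + 1] <- bitwOr(union_of[s - low + 1],
                              masks[log2(low) + 1])
    if (union_of[s + 1] == full) {
      sz <- sum(bitwAnd(s, 2^(0:(l - 1))) > 0)
      if (sz < best) best <- sz
    }
  }
  as.integer(best)
}

table3_net <- function() {
  hubs <- utils::read.delim(example_cover_instance("hub_genes"))$gene
  build_bipartite(example_cover_instance("edges"), hubs)
}
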