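test_that("signed-hybrid adjacency follows the elementwise formula", {
  # three genes with known pairwise structure
  set.seed(21)
  x <- matrix(rnorm(3 * 40), 3, 40, dimnames = list(c("a", "b", "c"), NULL))
  x[2, ] <- 0.8 * x[1, ] + 0.6 * rnorm(40)       # positively correlated
  x[3, ] <- -x[1, ] + 0.3 * rnorm(40)            # negatively correlated
  net <- signed_hybrid_adjacency(x, beta = 8)
  r <- bicor_matrix(x)
  for (i in 1:3) for (j in 1:3) {
    want <- if (i == j) 0 else if (r[i, j] > 0) r[i, j]^8 else 0
    expect_equal(net$adjacency[i, j], want, tolerance = 1e-12)
  }
  expect_equal(net$adjacency["a", "c"], 0)        # negative cor zeroed
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
  expect_equal(net$adjacency, t(net$adjacency))
  # cor = 0.5 at beta 8 gives 0.5^8 (formula spot check)
  expect_equal(0.5^8, 0.00390625)
  # adjacency is monotone in correlation on the positive side
  rs <- c(0.3, 0.5, 0.7, 0.9)
  expect_true(all(diff(rs^8) > 0))
})

test_that("TOM matches hand evaluation and a triple-loop oracle", {
  a <- matrix(0, 3, 3, dimnames = list(c("g1", "g2", "g3"),
                                       c("g1", "g2", "g3")))
  a["g1", "g2"] <- a["g2", "g1"] <- 0.5
  a["g1", "g3"] <- a["g3", "g1"] <- 0.5
  tomd <- topological_overlap(as_network(a))
  expect_equal(tomd$tom["g1", "g2"], 0.5)   # (0 + 0.5)/(min(1,.5) + 1 - .5)
  expect_equal(tomd$tom["g2", "g3"],
               (0.5 * 0.5) / (min(0.5, 0.5) + 1 - 0))
  expect_equal(diag(tomd$tom), stats::setNames(rep(1, 3), rownames(a)))

  # edgeless network: TOM off-diagonal 0, dissimilarity 1
  z <- topological_overlap(as_network(matrix(0, 4, 4,
    dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))))
  expect_true(all(z$tom[upper.tri(z$tom)] == 0))
  expect_true(all(z$dissimilarity[upper.tri(z$tom)] == 1))

  # brute-force agreement on random 20-gene networks
  for (seed in 1:20) {
    a <- random_adjacency(20, seed = seed)
    tom <- topological_overlap(as_network(a))$tom
    expect_lt(max(abs(tom - tom_bruteforce(a))), 1e-10)
  }
})

test_that("TOM is equivariant under gene permutation and equals adjacency without two-paths", {
  a <- random_adjacency(12, seed = 4)
  tom <- topological_overlap(as_network(a))$tom
  set.seed(5)
  p <- sample(12)
  tom_p <- topological_overlap(as_network(a[p, p]))$tom
  expect_equal(tom_p, tom[p, p])

  # single edge: no shared neighbours anywhere, TOM = adjacency off-diagonal
  b <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  b[1, 2] <- b[2, 1] <- 0.4
  tb <- topological_overlap(as_network(b))$tom
  expect_equal(tb[1, 2], 0.4 / (0.4 + 1 - 0.4))
  expect_equal(tb[3, 4], 0)
})

test_that("cluster_modules recovers two planted blocks and is deterministic", {
  set.seed(31)
  n <- 100
  d <- matrix(runif(n * n, 0.9, 1), n, n)    # background: far apart
  d <- (d + t(d)) / 2
  blocks <- list(1:50, 51:100)
  for (b in blocks) d[b, b] <- d[b, b] * 0.1  # planted tight blocks
  diag(d) <- 0
  ids <- sprintf("g%03d", 1:n)
  dimnames(d) <- list(ids, ids)
  tomd <- structure(list(gene_ids = ids, tom = 1 - d, dissimilarity = d),
                    class = "TOMatrix")
  part <- cluster_modules(tomd, min_module_size = 30, deep_split = 2)
  expect_equal(sum(part$color_of != "grey"), 2)
  for (b in blocks) {
    labs <- part$label_of[ids[b]]
    expect_equal(length(unique(labs)), 1)  # pure
    expect_true(all(labs > 0))
  }
  # largest module gets the first palette color
  sizes <- table(part$label_of[part$label_of > 0])
  expect_equal(part$color_of[[names(which.max(sizes))]], "turquoise")
  # determinism
  part2 <- cluster_modules(tomd, min_module_size = 30, deep_split = 2)
  expect_identical(part$label_of, part2$label_of)
})

test_that("clusters below min_module_size become grey", {
  a <- random_adjacency(10, seed = 9)
  tomd <- topological_overlap(as_network(a))
  part <- cluster_modules(tomd, min_module_size = 50)
  expect_true(all(part$label_of == 0))
  expect_identical(unname(module_colors(part)), rep("grey", 10))
})

test_that("module partitions round-trip through their TSV writer", {
  part <- new_module_partition(paste0("g", 1:5), c(1L, 1L, 2L, 0L, 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, path)
  back <- read.delim(path)
  expect_equal(back$label, c(1, 1, 2, 0, 2))
  expect_equal(back$color, c("turquoise", "turquoise", "blue", "grey", "blue"))
})

test_that("module eigengenes are unit-norm, sign-oriented, and optimal", {
  # rank-1 module: all genes share one profile (plus tiny jitter)
  set.seed(41)
  v <- rnorm(12)
  x <- matrix(rep(v, each = 6), 6, 12) + matrix(rnorm(72, sd = 1e-3), 6, 12)
  dimnames(x) <- list(paste0("g", 1:6), paste0("s", 1:12))
  em <- tiny_em(x)
  part <- new_module_partition(paste0("g", 1:6), rep(1L, 6))
  eig <- module_eigengenes(em, part)
  e <- eig$eigengenes[, "MEturquoise"]
  expect_equal(sum(e^2), 1)
  cors <- cor(e, scale(t(x)))
  expect_true(all(cors > 0.99))
  # flipping the sign would violate the orientation rule
  expect_lt(mean(cor(-e, scale(t(x)))), 0)

  # optimality: eigengene explains >= variance of any single member profile
  em2 <- random_em(8, 5, 5, seed = 6)
  part2 <- new_module_partition(gene_ids(em2), rep(1L, 8))
  e2 <- module_eigengenes(em2, part2)$eigengenes[, 1]
  xs <- t(scale(t(em2$values)))
  explained <- function(u) sum((xs %*% u)^2)
  for (i in 1:8) {
    u <- xs[i, ] / sqrt(sum(xs[i, ]^2))
    expect_gte(explained(e2) + 1e-8, explained(u))
  }

  # all-constant module errors with the module named
  flat <- tiny_em(matrix(5, 3, 6, dimnames = list(paste0("g", 1:3),
                                                  paste0("s", 1:6))))
  expect_error(
    module_eigengenes(flat, new_module_partition(paste0("g", 1:3),
                                                 rep(1L, 3))),
    "turquoise")
})
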