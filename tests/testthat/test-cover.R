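test_that("the bundled worked instance parses to the published network", {
  net <- table3_net()
  expect_equal(length(net$mirnas), 5)
  expect_equal(nrow(net$edges), 35)
  deg <- mirna_degree(net)
  expect_equal(deg[["hsa-mir-155-5p"]], 10)
  expect_equal(deg[["hsa-mir-17-5p"]], 8)
  expect_equal(deg[["hsa-mir-181a-5p"]], 7)
  expect_equal(deg[["hsa-mir-18a-5p"]], 6)
  expect_equal(deg[["hsa-mir-92a-1-5p"]], 4)
  expect_setequal(net$uncoverable, c("LCK", "CD19", "ZAP70"))
  expect_equal(length(setdiff(net$genes, net$uncoverable)), 17)
})

test_that("build_bipartite records uncoverable genes and dedupes edges", {
  edges <- data.frame(mirna = c("m1", "m1", "m1"),
                      gene = c("A", "B", "A"))
  net <- build_bipartite(edges, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$uncoverable, "C")
  expect_equal(net$target_sets$m1, c("A", "B"))

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tgene", "m1\tA", "badline"), path)
  expect_error(build_bipartite(path, "A"), "malformed bipartite line 3")
})

test_that("greedy cover on the worked instance follows the published order", {
  net <- table3_net()
  sol <- greedy_cover(net)
  expect_equal(sol$selected[1], "hsa-mir-155-5p")
  expect_equal(length(sol$newly_covered[[1]]), 10)
  expect_setequal(sol$selected, net$mirnas)       # all five needed
  expect_equal(length(sol$covered), 17)
  expect_setequal(sol$dropped, c("LCK", "CD19", "ZAP70"))
  # no selected miRNA is redundant under the greedy order
  expect_true(all(vapply(sol$newly_covered, length, integer(1)) >= 1))
})

test_that("exact cover certifies the worked instance minimum of five", {
  net <- table3_net()
  sol <- exact_cover(net)
  expect_equal(length(sol$selected), 5)
  expect_setequal(sol$selected, net$mirnas)
  # each miRNA covers a gene no other miRNA covers (the minimality witness)
  for (m in net$mirnas) {
    others <- unique(unlist(net$target_sets[setdiff(net$mirnas, m)]))
    expect_gt(length(setdiff(net$target_sets[[m]], others)), 0)
  }
  # removing any single miRNA from the exact solution uncovers a gene
  for (m in sol$selected) {
    rest <- unique(unlist(net$target_sets[setdiff(sol$selected, m)]))
    expect_false(setequal(rest, sol$covered))
  }
})

test_that("degenerate cover instances behave as forced", {
  one <- build_bipartite(data.frame(mirna = "m1", gene = c("A", "B", "C")),
                         c("A", "B", "C"))
  expect_equal(greedy_cover(one)$selected, "m1")
  expect_equal(exact_cover(one)$selected, "m1")

  singletons <- build_bipartite(
    data.frame(mirna = paste0("m", 1:4), gene = paste0("G", 1:4)),
    paste0("G", 1:4))
  expect_equal(length(exact_cover(singletons)$selected), 4)

  empty <- build_bipartite(data.frame(mirna = character(0),
                                      gene = character(0)), character(0))
  expect_equal(length(greedy_cover(empty)$selected), 0)
  expect_equal(length(exact_cover(empty)$selected), 0)

  big <- build_bipartite(
    data.frame(mirna = paste0("m", 1:30), gene = paste0("G", 1:30)),
    paste0("G", 1:30))
  expect_error(exact_cover(big), "max_mirnas")
})

test_that("greedy ties break lexicographically and runs are deterministic", {
  edges <- data.frame(mirna = c("mB", "mB", "mA", "mA"),
                      gene = c("G1", "G2", "G3", "G4"))
  net <- build_bipartite(edges, paste0("G", 1:4))
  sol <- greedy_cover(net)
  expect_equal(sol$selected, c("mA", "mB"))   # tie at 2 genes: mA first
  sol2 <- greedy_cover(build_bipartite(edges[sample(4), ], paste0("G", 1:4)))
  expect_identical(sol$selected, sol2$selected)
  expect_identical(sol$newly_covered, sol2$newly_covered)
})

test_that("greedy and exact agree with exhaustive enumeration on 200 instances", {
  h <- function(n) sum(1 / seq_len(n))
  for (seed in 1:200) {
    net <- random_cover_instance(seed, n_uncoverable = seed %% 3)
    g <- greedy_cover(net)
    e <- exact_cover(net)
    oracle <- exhaustive_min_cover(net)
    expect_equal(length(e$selected), oracle)
    expect_lte(oracle, length(g$selected))
    # classical greedy guarantee: within H(largest target set) of optimum
    dmax <- max(mirna_degree(net))
    expect_lte(length(g$selected), h(dmax) * oracle)
    # both are valid covers of the coverable genes
    want <- sort(setdiff(net$genes, net$uncoverable))
    expect_identical(g$covered, want)
    expect_identical(e$covered, want)
  }
})

test_that("cover reports round-trip through the TSV/JSON writer", {
  sol <- greedy_cover(table3_net())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cover(sol, path)
  steps <- read.delim(path)
  expect_equal(steps$mirna, sol$selected)
  expect_equal(steps$n_new, c(10, 3, 2, 1, 1))
  js <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                            simplifyVector = TRUE)
  expect_equal(js$method, "greedy")
  expect_equal(js$selected, sol$selected)
})
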