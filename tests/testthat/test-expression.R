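test_that("read_expression round-trips a small TSV and validates input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t3\t4", "gC\t5\t6"), path)
  groups <- c(s1 = "control", s2 = "case")
  em <- read_expression(path, groups)
  expect_identical(gene_ids(em), c("gA", "gB", "gC"))
  expect_identical(sample_ids(em), c("s1", "s2"))
  expect_equal(unname(em$values), matrix(c(1, 3, 5, 2, 4, 6), 3, 2))

  writeLines(c("gene_id\ts1\ts1", "gA\t1\t2"), path)
  expect_error(read_expression(path, groups), "duplicate sample")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_expression(path, groups), "duplicate gene id.*gA")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\toops"), path)
  expect_error(read_expression(path, groups), "non-numeric.*gA.*s2")
  writeLines(c("gene_id\ts1\ts3", "gA\t1\t2"), path)
  expect_error(read_expression(path, groups), "missing from group map.*s3")
})

test_that("write_expression / read_expression round-trip random matrices", {
  for (seed in 1:3) {
    em <- random_em(25, 4, 4, seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    gpath <- withr::local_tempfile(fileext = ".tsv")
    write_expression(em, path, gpath)
    back <- read_expression(path, gpath)
    expect_equal(back$values, em$values, tolerance = 1e-12)
    expect_identical(back$group_of, em$group_of)
  }
})

test_that("filter_diverse_genes keeps the highest-variance genes", {
  v <- rbind(g1 = c(5, 5, 5, 5), g2 = c(4, 5, 6, 7),
             g3 = c(2, 4, 6, 8), g4 = c(0, 3, 6, 9))
  colnames(v) <- paste0("s", 1:4)
  em <- tiny_em(v)
  out <- filter_diverse_genes(em, 0.5)
  expect_identical(gene_ids(out), c("g3", "g4"))
  expect_identical(gene_ids(filter_diverse_genes(em, 1)), gene_ids(em))
  expect_error(filter_diverse_genes(em, 0), "keep_fraction")
})

test_that("variance filter matches a brute-force sort and is idempotent", {
  em <- random_em(1000, 5, 5, seed = 7, sd = runif(1, 0.5, 2))
  # heterogeneous variances
  set.seed(8)
  em$values <- em$values * rexp(1000)
  out <- filter_diverse_genes(em, 0.3)
  v <- apply(em$values, 1, var)
  kept <- gene_ids(out)
  expect_equal(length(kept), ceiling(0.3 * 1000))
  expect_gte(min(v[kept]), max(v[setdiff(names(v), kept)]))
  # survivors keep original order; re-filtering at same fraction is identity
  expect_identical(kept, intersect(gene_ids(em), kept))
  again <- filter_diverse_genes(out, 1)
  expect_identical(gene_ids(again), kept)
})

test_that("ties at the variance cutoff break lexicographically by gene id", {
  v <- rbind(gB = c(1, 2, 3), gA = c(3, 2, 1), gC = c(0, 0, 0))
  colnames(v) <- paste0("s", 1:3)
  out <- filter_diverse_genes(tiny_em(v), 2 / 3)  # gA and gB tie at var 1
  expect_identical(sort(gene_ids(out)), c("gA", "gB"))
})

test_that("differential_expression matches stats::t.test and thresholds strictly", {
  em <- random_em(40, 6, 6, seed = 3)
  deg <- differential_expression(em)
  ctrl <- em$values[, em$group_of == "control"]
  case <- em$values[, em$group_of == "case"]
  for (i in c(1, 13, 40)) {
    tt <- t.test(case[i, ], ctrl[i, ])
    expect_equal(deg$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(deg$log_fc[i], mean(case[i, ]) - mean(ctrl[i, ]),
                 tolerance = 1e-12)
  }
  expect_equal(deg$adj_p, p.adjust(deg$p_value, "BH"))
  expect_true(all(deg$adj_p >= deg$p_value))
  # BH preserves p-value ordering
  expect_true(all(diff(deg$adj_p[order(deg$p_value)]) >= -1e-15))

  # copied columns: case identical to control -> no signal at all
  v <- em$values[, 1:6]
  both <- cbind(v, v)
  colnames(both) <- paste0("s", 1:12)
  em2 <- tiny_em(both, stats::setNames(rep(c("control", "case"), each = 6),
                                       colnames(both)))
  deg2 <- differential_expression(em2)
  expect_true(all(deg2$log_fc == 0))
  expect_false(any(deg2$is_deg))
})

test_that("a planted strong fold change is called, |logFC| = 1 exactly is not", {
  set.seed(42)
  n <- 21
  v <- matrix(rnorm(50 * 2 * n, sd = 0.05), 50, 2 * n,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("s%02d", 1:(2 * n))))
  groups <- stats::setNames(rep(c("control", "case"), each = n),
                            colnames(v))
  v["g01", groups == "case"] <- v["g01", groups == "case"] + 2.5
  em <- tiny_em(v, groups)
  deg <- differential_expression(em)
  expect_true(deg$is_deg[deg$gene_id == "g01"])
  expect_equal(deg$log_fc[deg$gene_id == "g01"], 2.5, tolerance = 0.05)

  # boundary: a gene whose log_fc is exactly 1 with tiny p is NOT a DEG
  v2 <- rbind(gX = c(rep(0, 4), rep(1, 4)),
              gY = rnorm(8, sd = 0.1))
  v2["gX", ] <- v2["gX", ] + rep(c(0, 0), each = 4)
  colnames(v2) <- paste0("s", 1:8)
  g2 <- stats::setNames(rep(c("control", "case"), each = 4), colnames(v2))
  v2["gX", 1:4] <- c(-0.01, 0.01, -0.01, 0.01)       # mean 0
  v2["gX", 5:8] <- 1 + c(-0.01, 0.01, -0.01, 0.01)   # mean exactly 1
  deg2 <- differential_expression(tiny_em(v2, g2))
  row <- deg2[deg2$gene_id == "gX", ]
  expect_equal(row$log_fc, 1)
  expect_false(row$is_deg)
})

test_that("zero-variance genes get p = 1 without crashing", {
  v <- rbind(flat = rep(3, 8), ok = rnorm(8))
  colnames(v) <- paste0("s", 1:8)
  em <- tiny_em(v, stats::setNames(rep(c("control", "case"), each = 4),
                                   colnames(v)))
  deg <- differential_expression(em)
  expect_equal(deg$p_value[deg$gene_id == "flat"], 1)
  expect_equal(deg$log_fc[deg$gene_id == "flat"], 0)
})
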