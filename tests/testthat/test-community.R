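test_that("modularity-based algorithms split two joined cliques into the cliques", {
  net <- fixture_two_cliques(5)
  truth <- stats::setNames(rep(1:2, each = 5),
                           c(sprintf("A%02d", 1:5), sprintf("B%02d", 1:5)))
  for (algo in c("walktrap", "spinglass", "infomap")) {
    part <- detect_communities(net, algo, seed = 42)
    expect_equal(n_communities(part), 2L, info = algo)
    expect_equal(ari(truth, part), 1, info = algo)
  }
})

test_that("a complete graph is one community and bad specs error", {
  idx <- t(utils::combn(6, 2))
  k6 <- build_induced_network(LETTERS[1:6],
    data.frame(gene_a = LETTERS[idx[, 1]], gene_b = LETTERS[idx[, 2]]))
  expect_equal(n_communities(detect_communities(k6, "walktrap", seed = 1)), 1L)
  expect_equal(n_communities(detect_communities(k6, "infomap", seed = 1)), 1L)

  expect_error(detect_communities(k6, "leiden"), "arg")
  expect_error(detect_communities(k6, "sbm"), "not.*available")
  disc <- build_induced_network(c("A", "B", "C"),
                                data.frame(gene_a = "A", gene_b = "B"))
  expect_error(detect_communities(disc, "walktrap"), "connected")
})

test_that("planted 3-block structure is recovered by all algorithms", {
  pg <- planted_partition_graph(60, 3, 0.5, 0.01, seed = 1)
  for (algo in c("walktrap", "infomap")) {
    part <- detect_communities(pg$network, algo, seed = 9)
    expect_gte(ari(pg$truth$partition, part), 0.9)
  }
})

test_that("align_partitions recovers permuted labels and matches by overlap", {
  ref <- stats::setNames(c(1L, 1L, 2L, 2L, 3L), LETTERS[1:5])
  perm <- stats::setNames(c(3L, 3L, 1L, 1L, 2L), LETTERS[1:5])
  expect_equal(unname(align_partitions(ref, perm)[LETTERS[1:5]]),
               unname(ref[LETTERS[1:5]]))

  ref2 <- stats::setNames(c(1L, 1L, 2L, 2L), LETTERS[1:4])
  oth2 <- stats::setNames(c(1L, 1L, 1L, 2L), LETTERS[1:4])
  aligned <- align_partitions(ref2, oth2)
  expect_equal(unname(aligned[c("A", "B", "C")]), c(1L, 1L, 1L))
  expect_equal(unname(aligned["D"]), 2L)

  expect_equal(unname(align_partitions(ref, ref)[names(ref)]), unname(ref))
  expect_error(align_partitions(ref, ref2), "different node sets")
})

test_that("alignment never changes which nodes are grouped together", {
  set.seed(4)
  for (i in 1:25) {
    nodes <- sprintf("N%02d", 1:12)
    ref <- stats::setNames(sample(1:3, 12, replace = TRUE), nodes)
    ref <- stats::setNames(match(ref, unique(ref)), nodes)
    oth <- stats::setNames(sample(1:4, 12, replace = TRUE), nodes)
    oth <- stats::setNames(match(oth, unique(oth)), nodes)
    aligned <- align_partitions(ref, oth)
    co <- function(p) outer(p[nodes], p[nodes], "==")
    expect_identical(co(aligned), co(oth))
  }
})

test_that("bootstrap memberships without resampling reproduce the reference one-hot", {
  net <- fixture_two_cliques(5)
  m <- bootstrap_memberships(net, "walktrap", n_boot = 1, seed = 3,
                             resample = FALSE)
  ref <- attr(m, "reference")
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  for (g in rownames(m)) {
    expect_equal(unname(m[g, ref[g]]), 1)
  }
})

test_that("bootstrap rows are probability vectors and interior nodes are stable", {
  net <- fixture_two_cliques(8)
  stable <- 0L
  for (seed in 1:10) {
    m <- bootstrap_memberships(net, "infomap", n_boot = 100, seed = seed)
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))
    expect_true(all(m >= 0 & m <= 1))
    # interior nodes: everyone but the two clique-joining nodes A01, B01
    interior <- setdiff(rownames(m), c("A01", "B01"))
    if (all(apply(m[interior, , drop = FALSE], 1, max) >= 0.95)) {
      stable <- stable + 1L
    }
  }
  expect_gte(stable, 9L)
})

test_that("consensus partition follows the majority of inputs", {
  p <- stats::setNames(c(1L, 1L, 2L, 2L), LETTERS[1:4])
  expect_equal(unname(consensus_partition(list(p, p, p))[LETTERS[1:4]]),
               unname(p))

  # D sides with {A,B} in 2 of 3 partitions
  p1 <- stats::setNames(c(1L, 1L, 2L, 1L), LETTERS[1:4])
  p2 <- stats::setNames(c(1L, 1L, 2L, 1L), LETTERS[1:4])
  p3 <- stats::setNames(c(1L, 1L, 2L, 2L), LETTERS[1:4])
  cons <- consensus_partition(list(p1, p2, p3))
  expect_equal(cons[["D"]], cons[["A"]])
  expect_true(cons[["C"]] != cons[["A"]])

  expect_error(consensus_partition(list(p1, p1[1:3])), "inconsistent")
})

test_that("consensus of several algorithms recovers the planted blocks", {
  pg <- planted_partition_graph(60, 3, 0.5, 0.01, seed = 2)
  parts <- lapply(c("walktrap", "spectral", "infomap"), function(a)
    detect_communities(pg$network, a, seed = 5))
  cons <- consensus_partition(parts)
  expect_gte(ari(pg$truth$partition, cons), 0.9)
})

test_that("partitions and membership matrices round-trip through TSV", {
  pg <- planted_partition_graph(30, 2, 0.5, 0.02, seed = 5)
  part <- detect_communities(pg$network, "walktrap", seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, f)
  expect_equal(read_partition(f), stats::setNames(as.integer(part),
                                                  names(part)))

  m <- bootstrap_memberships(pg$network, "walktrap", n_boot = 5, seed = 2)
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_memberships(m, fm)
  m2 <- read_memberships(fm)
  expect_equal(m2, matrix(signif(unclass(m), 6), nrow(m),
                          dimnames = dimnames(m)),
               ignore_attr = TRUE, tolerance = 1e-6)
})
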