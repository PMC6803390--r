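test_that("read_edge_table filters types, drops self-loops, collapses duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tinteraction_type\tsource",
               "A\tB\tdirect\tdb1",
               "B\tA\tdirect\tdb2",
               "C\tC\tdirect\tdb1",
               "A\tC\tcolocalization\tdb1"), f)
  got <- suppressMessages(read_edge_table(f, allowed_types = "direct"))
  expect_equal(nrow(got), 1L)
  expect_equal(got$gene_a, "A")
  expect_equal(got$gene_b, "B")
  expect_equal(got$source, "db1")  # first source retained

  all_types <- suppressMessages(read_edge_table(f, allowed_types = NULL))
  expect_equal(nrow(all_types), 2L)
  expect_setequal(paste(all_types$gene_a, all_types$gene_b),
                  c("A B", "A C"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "A\tB"), bad)
  expect_error(read_edge_table(bad), "missing required column")
})

test_that("edge tables round-trip through write and read", {
  edges <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "D"),
                      interaction_type = "MI:0407", source = "synthetic",
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(edges, f)
  expect_equal(read_edge_table(f, allowed_types = "MI:0407"), edges)
})

test_that("PSI-MI TAB input maps id and type columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  row <- function(a, b, type) {
    paste(c(paste0("uniprotkb:", a), paste0("uniprotkb:", b),
            rep("-", 9), type, 'psi-mi:"MI:0463"(biogrid)', "-"),
          collapse = "\t")
  }
  writeLines(c(row("p1", "p2", 'psi-mi:"MI:0407"(direct interaction)'),
               row("p1", "p3", 'psi-mi:"MI:0914"(association)')), f)
  got <- read_edge_table(f, format = "psimitab")
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$gene_a, got$gene_b), c("P1", "P2"))
  expect_equal(got$interaction_type, "MI:0407")
})

test_that("build_induced_network keeps listed proteins and internal edges only", {
  net <- build_induced_network(
    c("A", "B", "C"),
    data.frame(gene_a = c("A", "A"), gene_b = c("B", "D")))
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(net), 1L)
  expect_equal(unname(igraph::degree(net)["C"]), 0)

  solo <- build_induced_network("A", data.frame(gene_a = character(0),
                                                gene_b = character(0)))
  expect_equal(igraph::vcount(solo), 1L)
  expect_equal(igraph::ecount(solo), 0L)
})

test_that("building a network from its own edge dump reproduces it", {
  pg <- planted_partition_graph(40, 2, 0.4, 0.05, seed = 7)
  el <- igraph::as_edgelist(pg$network)
  rebuilt <- build_induced_network(
    igraph::V(pg$network)$name,
    data.frame(gene_a = el[, 1], gene_b = el[, 2]))
  edge_keys <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_setequal(igraph::V(rebuilt)$name, igraph::V(pg$network)$name)
  expect_equal(edge_keys(rebuilt), edge_keys(pg$network))
})

test_that("largest_connected_component picks the maximal component deterministically", {
  edges <- data.frame(
    gene_a = c("A", "B", "C", "D", "X", "Y"),
    gene_b = c("B", "C", "D", "E", "Y", "Z"))
  net <- build_induced_network(c(LETTERS[1:5], "X", "Y", "Z"), edges)
  lcc <- largest_connected_component(net)
  expect_setequal(igraph::V(lcc)$name, LETTERS[1:5])

  # connected graph -> identity
  conn <- fixture_path(4)
  expect_setequal(igraph::V(largest_connected_component(conn))$name,
                  igraph::V(conn)$name)

  # tie in size -> component containing the smallest symbol
  tie <- build_induced_network(c("A", "B", "Y", "Z"),
    data.frame(gene_a = c("A", "Y"), gene_b = c("B", "Z")))
  expect_setequal(igraph::V(largest_connected_component(tie))$name,
                  c("A", "B"))
})

test_that("LCC agrees with a union-find oracle on random sparse graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    g <- igraph::sample_gnp(50, 0.03)
    igraph::V(g)$name <- sprintf("N%02d", 1:50)
    comp <- oracle_components(g)
    biggest <- names(which.max(table(comp)))
    expected <- names(comp)[comp == as.integer(biggest)]
    got <- igraph::V(largest_connected_component(g))$name
    expect_equal(length(got), length(expected))
    # maximality: no other component is larger
    expect_true(all(table(comp) <= length(got)))
  }
})

test_that("semi-local centrality matches hand-derived fixtures", {
  p4 <- fixture_path(4)
  sl <- semilocal_centrality(p4)
  expect_equal(stats::setNames(sl$raw, sl$gene),
               c(A = 5, B = 8, C = 8, D = 5))
  expect_equal(stats::setNames(sl$norm, sl$gene),
               c(A = 0, B = 1, C = 1, D = 0))

  tri <- build_induced_network(c("A", "B", "C", "D"),
    data.frame(gene_a = c("A", "A", "B", "A"),
               gene_b = c("B", "C", "C", "D")))
  sl <- semilocal_centrality(tri)
  expect_equal(stats::setNames(sl$raw, sl$gene),
               c(A = 15, B = 15, C = 15, D = 9))
  expect_equal(stats::setNames(sl$norm, sl$gene),
               c(A = 1, B = 1, C = 1, D = 0))

  # symmetric star: all raw equal -> degenerate normalization to 0.5
  star <- build_induced_network(c("A", "B", "C", "D", "E"),
    data.frame(gene_a = rep("A", 4), gene_b = c("B", "C", "D", "E")))
  sl <- semilocal_centrality(star)
  expect_true(all(sl$raw == 16))
  expect_true(all(sl$norm == 0.5))

  solo <- build_induced_network("A", NULL)
  expect_error(semilocal_centrality(solo), "at least 2 nodes")
})

test_that("semi-local centrality equals the brute-force two-hop oracle", {
  for (seed in 1:100) {
    g <- random_connected_graph(sample(5:30, 1), seed = seed)
    if (igraph::vcount(g) < 2) next
    sl <- semilocal_centrality(g)
    expect_equal(stats::setNames(sl$raw, sl$gene), oracle_semilocal(g))
    expect_true(all(sl$norm >= 0 & sl$norm <= 1))
  }
})

test_that("centrality_table populates all eight measures correctly", {
  p3 <- fixture_path(3)
  ct <- centrality_table(p3)
  expect_equal(stats::setNames(ct$degree, ct$gene), c(A = 1, B = 2, C = 1))
  expect_equal(stats::setNames(ct$betweenness, ct$gene),
               c(A = 0, B = 1, C = 0))
  expect_equal(stats::setNames(ct$mean_shortest_path, ct$gene),
               c(A = 1.5, B = 1, C = 1.5))

  k4 <- build_induced_network(LETTERS[1:4], {
    idx <- t(utils::combn(4, 2))
    data.frame(gene_a = LETTERS[idx[, 1]], gene_b = LETTERS[idx[, 2]])
  })
  ct <- centrality_table(k4)
  expect_true(all(ct$clustering_coefficient == 1))
  expect_equal(sum(ct$pagerank), 1, tolerance = 1e-9)
  expect_true(all(ct$closeness > 0 & ct$closeness <= 1))

  disc <- build_induced_network(c("A", "B", "C"),
                                data.frame(gene_a = "A", gene_b = "B"))
  expect_error(centrality_table(disc), "largest_connected_component")
})
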