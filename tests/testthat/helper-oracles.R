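# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (loops, enumeration) so they cannot share
# code paths with the implementation they check.

# Brute-force semi-local centrality: N(w) by explicit BFS-to-depth-2 counts,
# then two nested neighbour sums.
oracle_semilocal <- function(g) {
  d <- igraph::distances(g)
  n <- igraph::vcount(g)
  nw <- sapply(seq_len(n), function(w) sum(d[w, ] >= 1 & d[w, ] <= 2))
  adj <- lapply(seq_len(n), function(v) which(d[v, ] == 1))
  q <- sapply(seq_len(n), function(u) sum(nw[adj[[u]]]))
  cl <- sapply(seq_len(n), function(v) sum(q[adj[[v]]]))
  stats::setNames(cl, igraph::V(g)$name)
}

# Exhaustive hypergeometric upper tail from binomial coefficients.
oracle_hypergeom <- function(k, n, M, N) {
  if (k == 0) return(1)
  i <- k:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# Union-find component labelling, independent of igraph's components().
oracle_components <- function(g) {
  n <- igraph::vcount(g)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  for (i in seq_len(nrow(el))) {
    ra <- find(el[i, 1]); rb <- find(el[i, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), igraph::V(g)$name)
}

# A random connected graph with <= n nodes (LCC of an Erdos-Renyi draw).
random_connected_graph <- function(n, p = 2.5 / n, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
}

# Adjusted Rand index between two labelings over the same (named) nodes.
ari <- function(a, b) {
  b <- b[names(a)]
  igraph::compare(as.integer(a), as.integer(b), method = "adjusted.rand")
}

# Rank-based AUC: probability that a positive scores above a negative.
auc_score <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Tiny labelled graphs used by several files.
fixture_path <- function(k) {
  build_induced_network(LETTERS[1:k],
    data.frame(gene_a = LETTERS[1:(k - 1)], gene_b = LETTERS[2:k]))
}

fixture_two_cliques <- function(size = 5) {
  idx <- t(utils::combn(size, 2))
  c1 <- sprintf("A%02d", seq_len(size))
  c2 <- sprintf("B%02d", seq_len(size))
  edges <- rbind(
    data.frame(gene_a = c1[idx[, 1]], gene_b = c1[idx[, 2]]),
    data.frame(gene_a = c2[idx[, 1]], gene_b = c2[idx[, 2]]),
    data.frame(gene_a = c1[1], gene_b = c2[1]))
  build_induced_network(c(c1, c2), edges)
}
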