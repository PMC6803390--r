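#' Community-detection algorithms available for partitioning the LCC
#'
#' `walktrap`, `spinglass`, `spectral` (leading-eigenvector with fine
#' tuning) and `infomap` are delegated to igraph. `sbm` (the mixed-membership
#' stochastic blockmodel) has no installed R backend and is reported as
#' unavailable; downstream averaging simply runs on the remaining set.
#'
#' @return Character vector of recognized algorithm names.
#' @export
community_algorithms <- function() {
  c("walktrap", "spinglass", "spectral", "infomap", "sbm")
}

.as_partition <- function(membership, nodes, algorithm = NULL) {
  ids <- match(membership, sort(unique(membership)))
  p <- stats::setNames(as.integer(ids), nodes)
  attr(p, "algorithm") <- algorithm
  p
}

#' Number of communities in a partition
#'
#' @param partition Named integer vector (gene -> community id).
#' @return Integer count of communities.
#' @export
n_communities <- function(partition) length(unique(partition))

#' Detect communities on a connected network
#'
#' Hard-partitions the network with one of the published algorithms the
#' interactome analysis relies on. Stochastic algorithms (spinglass,
#' infomap, walktrap tie-breaking) are made reproducible via `seed`.
#'
#' @param net A connected igraph network.
#' @param algorithm One of [community_algorithms()].
#' @param seed Integer seed recorded for reproducibility (`NULL` leaves the
#'   RNG state untouched).
#' @param ... Passed to the underlying igraph routine.
#' @return Named integer vector mapping each gene to a community id
#'   `1..c` (contiguous), with attribute `algorithm`.
#' @export
detect_communities <- function(net, algorithm = "spinglass", seed = NULL, ...) {
  algorithm <- match.arg(algorithm, community_algorithms())
  if (algorithm == "sbm") {
    stop("the 'sbm' (mixed-membership stochastic blockmodel) backend is not ",
         "available in this installation; use one of walktrap, spinglass, ",
         "spectral, infomap")
  }
  if (!igraph::is_connected(net)) {
    stop("detect_communities() requires a connected network (the LCC)")
  }
  if (!is.null(seed)) set.seed(seed)
  comm <- switch(algorithm,
    walktrap = igraph::cluster_walktrap(net, ...),
    spinglass = igraph::cluster_spinglass(net, ...),
    spectral = igraph::cluster_leading_eigen(net, ...),
    infomap = igraph::cluster_infomap(net, ...)
  )
  .as_partition(igraph::membership(comm), igraph::V(net)$name, algorithm)
}

# Greedy maximum-overlap label matching between two hard partitions that may
# live on different node sets (overlap computed on the shared nodes). Returns
# an integer vector mapping each community id of `other` to a label in the
# reference id space; unmatched communities receive fresh ids.
.match_labels <- function(reference, other) {
  shared <- intersect(names(reference), names(other))
  c_ref <- max(reference)
  c_oth <- max(other)
  ov <- matrix(0L, nrow = c_ref, ncol = c_oth)
  if (length(shared)) {
    tab <- table(factor(reference[shared], levels = seq_len(c_ref)),
                 factor(other[shared], levels = seq_len(c_oth)))
    ov[] <- as.integer(tab)
  }
  map <- integer(c_oth)
  used_ref <- logical(c_ref)
  repeat {
    if (all(map != 0L) || !any(ov > 0L)) break
    best <- max(ov)
    cand <- which(ov == best, arr.ind = TRUE)
    # ties: smaller reference id, then smaller other id
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    map[j] <- i
    used_ref[i] <- TRUE
    ov[i, ] <- -1L
    ov[, j] <- -1L
  }
  nxt <- c_ref
  for (j in which(map == 0L)) {
    nxt <- nxt + 1L
    map[j] <- nxt
  }
  map
}

#' Relabel a partition to match a reference
#'
#' Communities of `other` are renamed by greedy maximum-overlap matching
#' against `reference` (largest intersection first; ties broken toward the
#' smaller reference id); communities with no remaining match get fresh ids.
#' Which nodes are grouped together never changes, only the labels.
#'
#' @param reference,other Named integer partitions over the same node set.
#' @return `other` relabeled into the reference id space.
#' @export
align_partitions <- function(reference, other) {
  if (!setequal(names(reference), names(other))) {
    stop("partitions are defined on different node sets")
  }
  map <- .match_labels(reference, other)
  out <- stats::setNames(map[other[names(other)]], names(other))
  attr(out, "algorithm") <- attr(other, "algorithm")
  out
}

#' Bootstrap soft community memberships
#'
#' Estimates, for every node, the probability of belonging to each community
#' of a reference partition. The reference is `detect_communities(net,
#' algorithm, seed)`. Each replicate perturbs the network by resampling its
#' edge multiset with replacement (duplicates collapsed), restricts to the
#' largest connected component, re-detects communities, aligns the labels to
#' the reference by maximum overlap, and increments per-node counts. Rows
#' are normalized by the number of replicates in which the node survived;
#' nodes absent from every replicate fall back to their one-hot reference
#' row. With `resample = FALSE` the graph is left intact and only the
#' algorithm's own stochasticity (a fresh seed per replicate) perturbs the
#' partition.
#'
#' @param net A connected igraph network.
#' @param algorithm Algorithm name (see [community_algorithms()]).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; replicate `b` uses `seed + b`.
#' @param resample Resample edges (default) or reseed only.
#' @param ... Passed to [detect_communities()].
#' @return A numeric matrix (nodes x communities, rows summing to 1) with
#'   attributes `algorithm`, `n_boot` and `reference` (the reference
#'   partition).
#' @export
bootstrap_memberships <- function(net, algorithm = "spinglass", n_boot = 100,
                                  seed = 1, resample = TRUE, ...) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  reference <- detect_communities(net, algorithm, seed = seed, ...)
  nodes <- names(reference)
  c_ref <- max(reference)
  counts <- matrix(0, nrow = length(nodes), ncol = c_ref,
                   dimnames = list(nodes, NULL))
  appear <- stats::setNames(numeric(length(nodes)), nodes)
  m <- igraph::ecount(net)
  for (b in seq_len(n_boot)) {
    set.seed(seed + b)
    if (resample) {
      idx <- sample.int(m, m, replace = TRUE)
      sub <- igraph::subgraph_from_edges(net, unique(idx),
                                         delete.vertices = TRUE)
      sub <- largest_connected_component(sub)
      if (igraph::vcount(sub) < 2L) next
    } else {
      sub <- net
    }
    part <- tryCatch(detect_communities(sub, algorithm, seed = seed + b, ...),
                     error = function(e) NULL)
    if (is.null(part)) next
    map <- .match_labels(reference, part)
    lab <- map[part]
    if (max(lab) > ncol(counts)) {
      counts <- cbind(counts,
                      matrix(0, nrow = nrow(counts),
                             ncol = max(lab) - ncol(counts)))
    }
    ri <- match(names(part), nodes)
    counts[cbind(ri, lab)] <- counts[cbind(ri, lab)] + 1
    appear[ri] <- appear[ri] + 1
  }
  never <- which(appear == 0)
  if (length(never)) {
    counts[cbind(never, reference[nodes[never]])] <- 1
    appear[never] <- 1
  }
  u <- counts / appear
  colnames(u) <- paste0("C", seq_len(ncol(u)))
  attr(u, "algorithm") <- algorithm
  attr(u, "n_boot") <- n_boot
  attr(u, "reference") <- reference
  u
}

#' Consensus partition across algorithms
#'
#' Builds the node-by-node co-classification frequency matrix over the input
#' partitions, links every pair grouped together in a strict majority
#' (frequency > 0.5) of them, and returns the connected components of that
#' majority graph as the consensus communities.
#'
#' @param partitions List of named integer partitions over a common node set.
#' @return Named integer consensus partition.
#' @export
consensus_partition <- function(partitions) {
  if (length(partitions) < 1L) stop("need at least one partition")
  nodes <- sort(names(partitions[[1]]))
  for (p in partitions) {
    if (!setequal(names(p), nodes)) stop("partitions have inconsistent node sets")
  }
  n <- length(nodes)
  co <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (p in partitions) {
    lab <- p[nodes]
    co <- co + outer(lab, lab, "==")
  }
  co <- co / length(partitions)
  adj <- (co > 0.5)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  .as_partition(comp$membership, nodes, algorithm = "consensus")
}

#' Read / write partition TSV
#'
#' Two tab-separated columns, `gene` and `community`.
#'
#' @param partition Named integer partition.
#' @param path File path.
#' @return `write_partition` returns `path` invisibly; `read_partition`
#'   returns a named integer partition.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(gene = names(partition), community = as.integer(partition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$community), toupper(df$gene))
}

#' Read / write a soft membership matrix TSV
#'
#' A `gene` column followed by one probability column per community.
#'
#' @param memberships Numeric matrix from [bootstrap_memberships()].
#' @param path File path.
#' @return `write_memberships` returns `path` invisibly; `read_memberships`
#'   a numeric matrix with gene rownames.
#' @export
write_memberships <- function(memberships, path) {
  df <- data.frame(gene = rownames(memberships),
                   signif(unclass(memberships), 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_memberships
#' @export
read_memberships <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- toupper(df$gene)
  m
}
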