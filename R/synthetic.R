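#' Planted-partition benchmark graph
#'
#' A stochastic block model with near-equal block sizes: each within-block
#' pair is an edge with probability `p_in`, each between-block pair with
#' `p_out`. The graph is reduced to its largest connected component, with
#' the planted ground truth restricted accordingly; the pre-reduction graph
#' is also returned for tests of the raw construction. Synthetic gene
#' symbols are `G000001, G000002, ...`. Deterministic given `seed`.
#'
#' @param n_nodes Total number of nodes.
#' @param n_comms Number of planted communities.
#' @param p_in Within-block edge probability.
#' @param p_out Between-block edge probability (`0 <= p_out < p_in <= 1`).
#' @param seed RNG seed.
#' @return List with `network` (the LCC), `network_full` (before LCC
#'   reduction) and `truth` (a `planted_truth` list holding `partition`,
#'   `bridges`, `enriched_pairs`, `disease_pairs`).
#' @export
planted_partition_graph <- function(n_nodes, n_comms, p_in, p_out, seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  sizes <- rep(n_nodes %/% n_comms, n_comms)
  extra <- n_nodes - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  pref <- matrix(p_out, n_comms, n_comms)
  diag(pref) <- p_in
  set.seed(seed)
  g <- igraph::sample_sbm(n_nodes, pref.matrix = pref, block.sizes = sizes)
  igraph::V(g)$name <- sprintf("G%06d", seq_len(n_nodes))
  planted <- stats::setNames(rep(seq_len(n_comms), sizes),
                             igraph::V(g)$name)
  lcc <- largest_connected_component(g)
  truth <- structure(list(
    partition = planted[igraph::V(lcc)$name],
    bridges = character(0),
    enriched_pairs = list(),
    disease_pairs = list()), class = "planted_truth")
  list(network = lcc, network_full = g, truth = truth)
}

#' Plant bridge nodes between communities
#'
#' Adds nodes wired evenly into several planted communities — ground truth
#' for bridging-protein recovery. Each new node (`B000001, ...`) connects to
#' `degree_per_comm` uniformly chosen members of each of `span` randomly
#' chosen communities. Bridges are recorded in `truth$bridges` and excluded
#' from `truth$partition` (they belong to no single planted block).
#'
#' @param net The LCC from [planted_partition_graph()].
#' @param truth Its `planted_truth`.
#' @param n_bridges Number of bridge nodes (>= 1).
#' @param degree_per_comm Edges into each spanned community (>= 1).
#' @param span Number of communities each bridge spans (default 2).
#' @param seed RNG seed.
#' @return List with updated `network` and `truth`.
#' @export
add_bridge_nodes <- function(net, truth, n_bridges, degree_per_comm,
                             span = 2, seed = 1) {
  if (n_bridges < 1L || degree_per_comm < 1L) {
    stop("n_bridges and degree_per_comm must be >= 1")
  }
  comm_ids <- sort(unique(truth$partition))
  if (span > length(comm_ids)) stop("span exceeds the number of communities")
  sizes <- table(truth$partition)
  if (degree_per_comm > min(sizes)) {
    stop("degree_per_comm exceeds the smallest community size")
  }
  set.seed(seed)
  bridge_names <- sprintf("B%06d", seq_len(n_bridges))
  g <- igraph::add_vertices(net, n_bridges, name = bridge_names)
  for (bn in bridge_names) {
    target_comms <- sample(comm_ids, span)
    for (cid in target_comms) {
      members <- names(truth$partition)[truth$partition == cid]
      anchors <- sample(members, degree_per_comm)
      g <- igraph::add_edges(g, as.vector(rbind(bn, anchors)))
    }
  }
  truth$bridges <- c(truth$bridges, bridge_names)
  list(network = igraph::simplify(g), truth = truth)
}

#' Plant community-enriched annotation terms
#'
#' Builds an annotation set over a background of `background_size` genes
#' (the network genes plus filler symbols `X000001, ...`). Each enriched
#' term `TERM_ENRICH_k` annotates a fraction `frac_in` of its target
#' community (targets cycle through the planted communities) plus a
#' fraction `frac_out` of the rest of the background; each decoy term
#' annotates a `frac_out` fraction of the background uniformly at random.
#'
#' @param truth A `planted_truth` with a `partition`.
#' @param background_size Background universe size (>= number of network
#'   genes).
#' @param n_terms Number of enriched terms.
#' @param frac_in Annotated fraction within the target community.
#' @param frac_out Annotated fraction elsewhere (`0 <= frac_out < frac_in`).
#' @param n_decoys Number of decoy terms (default `n_terms`).
#' @param seed RNG seed.
#' @return List with `annotations` (an [annotation_set()]) and updated
#'   `truth` (`enriched_pairs` = list of `(community, term)`).
#' @export
planted_annotations <- function(truth, background_size, n_terms,
                                frac_in, frac_out, n_decoys = n_terms,
                                seed = 1) {
  if (!(frac_out >= 0 && frac_out < frac_in && frac_in <= 1)) {
    stop("need 0 <= frac_out < frac_in <= 1")
  }
  part <- truth$partition
  comm_ids <- sort(unique(part))
  net_genes <- names(part)
  if (background_size < length(net_genes)) {
    stop("background_size smaller than the number of network genes")
  }
  filler <- if (background_size > length(net_genes)) {
    sprintf("X%06d", seq_len(background_size - length(net_genes)))
  } else character(0)
  background <- c(net_genes, filler)
  set.seed(seed)
  terms <- list()
  pairs <- list()
  for (t in seq_len(n_terms)) {
    cid <- comm_ids[(t - 1L) %% length(comm_ids) + 1L]
    members <- net_genes[part == cid]
    rest <- setdiff(background, members)
    genes <- c(sample(members, max(1L, round(frac_in * length(members)))),
               if (frac_out > 0)
                 sample(rest, round(frac_out * length(rest))))
    id <- sprintf("TERM_ENRICH_%02d", t)
    terms[[id]] <- genes
    pairs[[length(pairs) + 1L]] <- list(community = cid, term = id)
  }
  for (t in seq_len(n_decoys)) {
    terms[[sprintf("TERM_DECOY_%02d", t)]] <-
      sample(background, max(2L, round(frac_out * background_size)))
  }
  truth$enriched_pairs <- pairs
  list(annotations = annotation_set(terms, background), truth = truth)
}

#' Plant a disease gene-set pair with known topology
#'
#' `separated` mode samples the two disease gene sets from two different
#' planted communities (expected `S_AB > 0`); `overlapping` mode samples
#' both from one community with a configured Jaccard overlap (expected
#' `S_AB < 0`).
#'
#' @param net The planted network (only used for feasibility checks).
#' @param truth A `planted_truth` with a `partition`.
#' @param mode `"separated"` or `"overlapping"`.
#' @param size_a,size_b Disease gene-set sizes (>= 2).
#' @param jaccard Target Jaccard index of the two sets in overlapping mode.
#' @param seed RNG seed.
#' @return List with `a`, `b` (gene sets), `expected_sign` (+1 or -1) and
#'   updated `truth`.
#' @export
planted_disease_pair <- function(net, truth, mode = c("separated", "overlapping"),
                                 size_a, size_b, jaccard = 0.5, seed = 1) {
  mode <- match.arg(mode)
  if (size_a < 2L || size_b < 2L) stop("disease set sizes must be >= 2")
  part <- truth$partition
  comm_ids <- names(sort(table(part), decreasing = TRUE))
  set.seed(seed)
  if (mode == "separated") {
    if (length(comm_ids) < 2L) stop("separated mode needs >= 2 communities")
    ca <- names(part)[part == as.integer(comm_ids[1])]
    cb <- names(part)[part == as.integer(comm_ids[2])]
    if (size_a > length(ca) || size_b > length(cb)) {
      stop("disease set sizes exceed community sizes")
    }
    a <- sample(ca, size_a)
    b <- sample(cb, size_b)
    sign <- 1
  } else {
    cc <- names(part)[part == as.integer(comm_ids[1])]
    n_shared <- round(jaccard * (size_a + size_b) / (1 + jaccard))
    n_shared <- min(n_shared, size_a, size_b)
    need <- size_a + size_b - n_shared
    if (need > length(cc)) {
      stop("overlapping mode needs a community of at least ", need, " genes")
    }
    pool <- sample(cc, need)
    shared <- pool[seq_len(n_shared)]
    rest <- pool[seq_len(need - n_shared) + n_shared]
    a <- c(shared, rest[seq_len(size_a - n_shared)])
    b <- c(shared, rest[seq_len(size_b - n_shared) + (size_a - n_shared)])
    sign <- -1
  }
  truth$disease_pairs <- c(truth$disease_pairs,
                           list(list(mode = mode, expected_sign = sign)))
  list(a = a, b = b, expected_sign = sign, truth = truth)
}

#' Synthetic interactome-list pair with an exact planted overlap
#'
#' Two gene lists drawn from a genome of `genome_size` synthetic symbols
#' with exactly `n_shared` genes in common — the fixture mirroring a
#' cross-context bait-interactome comparison.
#'
#' @param genome_size Genome (background) size.
#' @param n_a,n_b List sizes.
#' @param n_shared Planted overlap (`<= min(n_a, n_b)`; the union must fit
#'   in the genome).
#' @param seed RNG seed.
#' @return List with `a`, `b` and `genome`.
#' @export
synthetic_interactome_pair <- function(genome_size, n_a, n_b, n_shared,
                                       seed = 1) {
  if (n_shared > min(n_a, n_b)) stop("n_shared exceeds a list size")
  if (n_a + n_b - n_shared > genome_size) {
    stop("union of the lists exceeds genome_size")
  }
  genome <- sprintf("G%06d", seq_len(genome_size))
  set.seed(seed)
  pool <- sample(genome, n_a + n_b - n_shared)
  shared <- pool[seq_len(n_shared)]
  only <- pool[seq_len(length(pool) - n_shared) + n_shared]
  a <- c(shared, only[seq_len(n_a - n_shared)])
  b <- c(shared, only[seq_len(n_b - n_shared) + (n_a - n_shared)])
  list(a = a, b = b, genome = genome)
}
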