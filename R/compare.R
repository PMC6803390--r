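#' Hypergeometric overlap test between two interactor lists
#'
#' How surprising is the observed intersection of two bait-interactor lists
#' drawn from a genome of `genome_size` genes? The p-value is the
#' hypergeometric upper tail `P(X >= overlap)` with `M = |A|`, `n = |B|`,
#' `N = genome_size`; it is exactly symmetric in A and B.
#'
#' @param list_a,list_b Character gene lists (normalized and deduplicated on
#'   ingest).
#' @param genome_size Background genome size `N` (>= the size of the union).
#' @return List of class `overlap_result` with `n_a`, `n_b`, `overlap`,
#'   `genome_size`, `p` and `shared_genes`.
#' @export
list_overlap_test <- function(list_a, list_b, genome_size) {
  a <- unique(toupper(list_a))
  b <- unique(toupper(list_b))
  if (genome_size < length(union(a, b))) {
    stop("genome_size is smaller than the union of the two lists")
  }
  shared <- intersect(a, b)
  structure(list(
    n_a = length(a), n_b = length(b), overlap = length(shared),
    genome_size = genome_size,
    p = hypergeom_tail(length(shared), length(b), length(a), genome_size),
    shared_genes = sort(shared)), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap of %d genes between lists of %d and %d (genome %d): P = %.3g\n",
    x$overlap, x$n_a, x$n_b, x$genome_size, x$p))
  invisible(x)
}

#' Community-pair overlap significance between two partitions
#'
#' For every community `i` of partition A and community `j` of partition B,
#' tests the size of their gene intersection by the hypergeometric upper
#' tail against a shared background (default: the union of the two
#' partitions' node sets — a conservative, self-contained choice; pass an
#' explicit universe to change it). Pairs with an empty intersection get
#' p = 1.
#'
#' @param part_a,part_b Named integer partitions of two networks.
#' @param background Optional background gene universe.
#' @return Numeric matrix of p-values (rows: communities of A, columns:
#'   communities of B), with dimnames `A1..` / `B1..`.
#' @export
cluster_pair_overlap <- function(part_a, part_b, background = NULL) {
  if (is.null(background)) {
    background <- union(names(part_a), names(part_b))
  }
  background <- unique(toupper(background))
  miss <- setdiff(union(names(part_a), names(part_b)), background)
  if (length(miss)) {
    stop("background must contain all partition genes; missing: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  N <- length(background)
  ids_a <- sort(unique(part_a))
  ids_b <- sort(unique(part_b))
  p <- matrix(1, length(ids_a), length(ids_b),
              dimnames = list(paste0("A", ids_a), paste0("B", ids_b)))
  for (i in seq_along(ids_a)) {
    ca <- names(part_a)[part_a == ids_a[i]]
    for (j in seq_along(ids_b)) {
      cb <- names(part_b)[part_b == ids_b[j]]
      k <- length(intersect(ca, cb))
      p[i, j] <- hypergeom_tail(k, length(cb), length(ca), N)
    }
  }
  p
}
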