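#' Mean intra-module distance of a gene set
#'
#' For every member gene, the unweighted shortest-path (hop) distance to its
#' nearest *other* member; `d_AA` is the mean of those nearest-neighbour
#' distances. Genes not on the network are ignored; at least two mapped
#' genes are required.
#'
#' @param net A connected igraph network.
#' @param genes Character gene set.
#' @return Mean nearest-neighbour distance (>= 1 on a simple graph).
#' @export
intra_module_distance <- function(net, genes) {
  nodes <- intersect(unique(toupper(genes)), igraph::V(net)$name)
  if (length(nodes) < 2L) {
    stop("need at least 2 genes mapped onto the network")
  }
  d <- igraph::distances(net, v = nodes, to = nodes)
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Mean cross-module distance between two gene sets
#'
#' For each gene of A the distance to its nearest gene of B, and vice
#' versa; `d_AB` is the mean of all `|A| + |B|` values. A gene present in
#' both sets contributes 0 from each side.
#'
#' @param net A connected igraph network.
#' @param genes_a,genes_b Character gene sets (>= 1 mapped gene each).
#' @return Mean nearest-neighbour cross distance (>= 0).
#' @export
cross_module_distance <- function(net, genes_a, genes_b) {
  a <- intersect(unique(toupper(genes_a)), igraph::V(net)$name)
  b <- intersect(unique(toupper(genes_b)), igraph::V(net)$name)
  if (length(a) < 1L || length(b) < 1L) {
    stop("both gene sets need at least 1 gene mapped onto the network")
  }
  d <- igraph::distances(net, v = a, to = b)
  mean(c(apply(d, 1, min), apply(d, 2, min)))
}

#' Disease-module separation score S_AB
#'
#' `S_AB = d_AB - (d_AA + d_BB) / 2`. Negative values indicate two disease
#' modules occupying overlapping network neighbourhoods (identical sets give
#' `S_AB = -d_AA < 0`); positive values indicate topological separation.
#' `|S_AB|` is bounded by the network diameter.
#'
#' @param net A connected igraph network.
#' @param genes_a,genes_b Character gene sets (>= 2 mapped genes each).
#' @return The separation score (a single number).
#' @export
separation_score <- function(net, genes_a, genes_b) {
  d_aa <- intra_module_distance(net, genes_a)
  d_bb <- intra_module_distance(net, genes_b)
  d_ab <- cross_module_distance(net, genes_a, genes_b)
  d_ab - (d_aa + d_bb) / 2
}

#' Randomized null model for S_AB
#'
#' Draws `size_a` and `size_b` genes uniformly without replacement from the
#' network nodes (independently per disease per iteration), computes the
#' separation of each random pair, and summarizes the null sample.
#'
#' @param net A connected igraph network.
#' @param size_a,size_b Sizes of the random gene sets (>= 2).
#' @param n_iter Number of iterations (default 1000).
#' @param seed RNG seed.
#' @return List with `null_mean`, `null_sd`, and the full `sample`.
#' @export
separation_null <- function(net, size_a, size_b, n_iter = 1000, seed = 1) {
  nodes <- igraph::V(net)$name
  if (size_a < 2L || size_b < 2L) stop("set sizes must be >= 2")
  if (n_iter < 2L) stop("n_iter must be >= 2")
  if (max(size_a, size_b) > length(nodes)) {
    stop("set size exceeds the number of network nodes")
  }
  set.seed(seed)
  s <- vapply(seq_len(n_iter), function(i) {
    separation_score(net, sample(nodes, size_a), sample(nodes, size_b))
  }, numeric(1))
  list(null_mean = mean(s), null_sd = stats::sd(s), sample = s)
}

#' Pairwise disease-module separation analysis
#'
#' For every pair of disease gene sets: the intra- and cross-module
#' distances, `S_AB`, the randomized-null mean and standard deviation, the
#' z-score `(S_AB - null_mean) / null_sd`, a two-sided normal p-value,
#' Bonferroni correction over all pairs tested in the call, significance
#' stars at 0.05/0.01/0.001, and the "of interest" flag
#' (`S_AB < -3` or `S_AB > 0.1`). Diseases with fewer than two genes mapped
#' onto the network are skipped with a warning; genes off the network are
#' dropped with a message.
#'
#' @param net A connected igraph network (the LCC).
#' @param gda Named list of disease gene sets, or an [annotation_set()].
#' @param n_iter Null-model iterations per pair (default 1000).
#' @param seed RNG seed (incremented per pair).
#' @return Data.frame, one row per disease pair, with an attribute
#'   `diameter` (the `d_max` bound on `|S_AB|`).
#' @export
disease_separation <- function(net, gda, n_iter = 1000, seed = 1) {
  if (inherits(gda, "annotation_set")) gda <- gda$terms
  nodes <- igraph::V(net)$name
  mapped <- lapply(gda, function(g) intersect(unique(toupper(g)), nodes))
  dropped <- sum(lengths(gda) - lengths(mapped))
  if (dropped > 0) {
    message(dropped, " disease gene(s) not on the network were dropped")
  }
  ok <- lengths(mapped) >= 2L
  if (any(!ok)) {
    warning("skipping disease(s) with < 2 mapped genes: ",
            paste(names(mapped)[!ok], collapse = ", "))
  }
  mapped <- mapped[ok]
  if (length(mapped) < 2L) stop("need at least two usable disease sets")
  d_max <- igraph::diameter(net)
  prs <- utils::combn(names(mapped), 2)
  rows <- vector("list", ncol(prs))
  for (i in seq_len(ncol(prs))) {
    a <- prs[1, i]; b <- prs[2, i]
    d_aa <- intra_module_distance(net, mapped[[a]])
    d_bb <- intra_module_distance(net, mapped[[b]])
    d_ab <- cross_module_distance(net, mapped[[a]], mapped[[b]])
    s_ab <- d_ab - (d_aa + d_bb) / 2
    stopifnot(abs(s_ab) <= d_max + 1e-9)
    nul <- separation_null(net, length(mapped[[a]]), length(mapped[[b]]),
                           n_iter = n_iter, seed = seed + i)
    z <- (s_ab - nul$null_mean) / nul$null_sd
    rows[[i]] <- data.frame(
      disease_a = a, disease_b = b,
      n_a = length(mapped[[a]]), n_b = length(mapped[[b]]),
      d_aa = d_aa, d_bb = d_bb, d_ab = d_ab, s_ab = s_ab,
      null_mean = nul$null_mean, null_sd = nul$null_sd,
      z = z, p = 2 * stats::pnorm(-abs(z)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- adjust_pvalues(out$p, "bonferroni")
  out$stars <- ifelse(out$p_bonferroni <= 0.001, "***",
               ifelse(out$p_bonferroni <= 0.01, "**",
               ifelse(out$p_bonferroni <= 0.05, "*", "")))
  out$of_interest <- out$s_ab < -3 | out$s_ab > 0.1
  attr(out, "diameter") <- d_max
  rownames(out) <- NULL
  out
}

#' Read a gene-disease annotation (GDA) file
#'
#' Accepts either GMT (`parse_gmt`) or a two-column TSV with header
#' `disease_id` and `gene`.
#'
#' @param path File path.
#' @return Named list of disease gene sets.
#' @export
read_gda <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  f <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(f) >= 2 && identical(tolower(f[1:2]), c("disease_id", "gene"))) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(lapply(split(toupper(df$gene), df$disease_id), unique))
  }
  parse_gmt(path)$terms
}
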