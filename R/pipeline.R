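#' Serialize / read a network as diff-stable JSON
#'
#' The network is written as a sorted node list plus a lexicographically
#' sorted list of `[a, b]` edge pairs (`a < b`), so that byte-identical
#' output is a meaningful reproducibility check.
#'
#' @param net An igraph network with vertex names.
#' @param path Output path.
#' @return `write_network_json` returns `path` invisibly;
#'   `read_network_json` an igraph network.
#' @export
write_network_json <- function(net, path) {
  nodes <- sort(igraph::V(net)$name)
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    lo <- pmin(el[, 1], el[, 2])
    hi <- pmax(el[, 1], el[, 2])
    o <- order(lo, hi)
    edges <- Map(c, lo[o], hi[o])
  } else {
    edges <- list()
  }
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       pretty = TRUE, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(x$nodes), name = unlist(x$nodes))
  if (length(x$edges)) {
    em <- if (is.matrix(x$edges)) x$edges else do.call(rbind, x$edges)
    g <- igraph::add_edges(g, as.vector(t(em)))
  }
  igraph::simplify(g)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full interactome-topology pipeline
#'
#' Chains network construction, community detection (with bootstrap
#' memberships per algorithm and a consensus partition), influence
#' classification, per-community annotation enrichment, disease-module
#' separation, and (optionally) a cross-interactome overlap test, writing
#' every stage's table into `out_dir` together with a log of seeds and
#' versions. Deterministic given `seed`.
#'
#' @param proteins Character vector of interactor gene symbols, or a path
#'   to a protein-list file.
#' @param edges Interaction data.frame (from [read_edge_table()]) or a path
#'   to an edge TSV.
#' @param out_dir Output directory (created if needed).
#' @param annotations Optional [annotation_set()] or GMT path for
#'   enrichment.
#' @param background Background gene universe (vector or protein-list path)
#'   used when `annotations` is a GMT path; GMT files do not carry one.
#' @param gda Optional named list of disease gene sets or GDA/GMT path.
#' @param compare_list Optional second interactor list (vector or path) for
#'   the overlap test.
#' @param genome_size Background genome size for the overlap test.
#' @param algorithms Community-detection algorithms to run (first one is the
#'   headline partition used for enrichment).
#' @param allowed_types Interaction-type filter for `edges` paths (see
#'   [read_edge_table()]).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param n_boot Bootstrap replicates per algorithm.
#' @param n_perm Permutations for the enrichment strength test.
#' @param n_iter Null-model iterations for disease separation.
#' @param take_lcc Reduce to the largest connected component (default TRUE;
#'   required by all topology stages).
#' @return `out_dir`, invisibly. Side effects: `network.json`,
#'   `centrality.tsv`, `partition_<algorithm>.tsv`,
#'   `membership_<algorithm>.tsv`, `partition_consensus.tsv`,
#'   `influence.tsv`, and where inputs allow `enrichment.tsv`,
#'   `separation.tsv`, `overlap.txt`, plus `run_log.txt`.
#' @export
run_pipeline <- function(proteins, edges, out_dir,
                         annotations = NULL, background = NULL, gda = NULL,
                         compare_list = NULL, genome_size = NULL,
                         algorithms = c("spinglass", "spectral", "infomap"),
                         allowed_types = direct_physical_types(),
                         seed, n_boot = 100, n_perm = 1000, n_iter = 1000,
                         take_lcc = TRUE) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed)) {
    stop("an explicit integer seed is required")
  }
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    proteins <- read_protein_list(proteins)
  }
  if (is.character(edges)) edges <- read_edge_table(edges, allowed_types)
  if (is.character(background) && length(background) == 1L &&
      file.exists(background)) {
    background <- read_protein_list(background)
  }
  if (is.character(annotations)) {
    annotations <- parse_gmt(annotations, background = background)
  }
  if (is.character(gda)) gda <- read_gda(gda)
  if (is.character(compare_list) && length(compare_list) == 1L &&
      file.exists(compare_list)) {
    compare_list <- read_protein_list(compare_list)
  }

  net <- build_induced_network(proteins, edges)
  if (take_lcc) net <- largest_connected_component(net)
  write_network_json(net, file.path(out_dir, "network.json"))
  .write_tsv(centrality_table(net), file.path(out_dir, "centrality.tsv"))

  memberships <- list()
  partitions <- list()
  for (i in seq_along(algorithms)) {
    a <- algorithms[i]
    m <- bootstrap_memberships(net, a, n_boot = n_boot,
                               seed = seed + i * 1000L)
    memberships[[a]] <- m
    partitions[[a]] <- attr(m, "reference")
    write_partition(attr(m, "reference"),
                    file.path(out_dir, paste0("partition_", a, ".tsv")))
    write_memberships(m, file.path(out_dir, paste0("membership_", a, ".tsv")))
  }
  cons <- consensus_partition(partitions)
  write_partition(cons, file.path(out_dir, "partition_consensus.tsv"))

  infl <- influence_table(net, memberships)
  .write_tsv(infl, file.path(out_dir, "influence.tsv"))

  headline <- partitions[[algorithms[1]]]
  if (!is.null(annotations)) {
    extra <- setdiff(names(headline), annotations$background)
    if (length(extra)) {
      message(length(extra), " network gene(s) absent from the annotation ",
              "background were added to it")
      annotations$background <- c(annotations$background, extra)
    }
    enr <- cluster_term_enrichment(headline, annotations, n_perm = n_perm,
                                   seed = seed + 77L)
    .write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(gda)) {
    sep <- disease_separation(net, gda, n_iter = n_iter, seed = seed + 99L)
    .write_tsv(sep, file.path(out_dir, "separation.tsv"))
  }
  if (!is.null(compare_list)) {
    if (is.null(genome_size)) stop("genome_size is required with compare_list")
    ov <- list_overlap_test(proteins, compare_list, genome_size)
    writeLines(c(
      sprintf("n_a\t%d", ov$n_a), sprintf("n_b\t%d", ov$n_b),
      sprintf("overlap\t%d", ov$overlap),
      sprintf("genome_size\t%d", ov$genome_size),
      sprintf("p\t%.6g", ov$p),
      paste0("shared\t", paste(ov$shared_genes, collapse = ","))),
      file.path(out_dir, "overlap.txt"))
  }
  writeLines(c(
    paste("bridgenet", as.character(utils::packageVersion("bridgenet"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("igraph", as.character(utils::packageVersion("igraph"))),
    paste("seed", seed),
    paste("algorithms", paste(algorithms, collapse = ",")),
    paste("n_boot", n_boot), paste("n_perm", n_perm),
    paste("n_iter", n_iter)),
    file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
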