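#' Default "direct and physical" interaction-type allow-list
#'
#' PSI-MI controlled-vocabulary terms conventionally taken to denote direct
#' and physical interactions: `MI:0407` (direct interaction) and `MI:0915`
#' (physical association). `MI:0914` (association) is deliberately excluded
#' because it also covers co-complex inferences. The exact term set is a
#' curation choice, not a community standard; override it freely.
#'
#' @return Character vector of accepted interaction-type tokens (MI ids and
#'   their canonical names).
#' @export
direct_physical_types <- function() {
  c("MI:0407", "direct interaction",
    "MI:0915", "physical association")
}

#' Read a protein (gene-symbol) list
#'
#' One symbol per line; blank lines and `#` comments are ignored; symbols are
#' uppercased and deduplicated.
#'
#' @param path Path to the list file.
#' @return Character vector of unique uppercase gene symbols.
#' @export
read_protein_list <- function(path) {
  if (!file.exists(path)) stop("protein list not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  unique(toupper(x))
}

#' Write a protein list
#'
#' @param proteins Character vector of gene symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_list <- function(proteins, path) {
  writeLines(toupper(proteins), path)
  invisible(path)
}

# Reduce a PSI-MI TAB field to its MI id when one is present,
# e.g. 'psi-mi:"MI:0407"(direct interaction)' -> "MI:0407".
.psimitab_token <- function(x) {
  has_mi <- grepl("MI:[0-9]{4}", x)
  x[has_mi] <- regmatches(x[has_mi], regexpr("MI:[0-9]{4}", x[has_mi]))
  x
}

.psimitab_id <- function(x) {
  x <- sub("^[^:]*:", "", x)
  sub("\\|.*$", "", x)
}

#' Read an interaction edge table
#'
#' Reads either a plain TSV with header columns `gene_a`, `gene_b`,
#' `interaction_type`, `source`, or a PSI-MI TAB 2.5 file (no header;
#' columns 1 and 2 are interactor ids, 12 the interaction type, 13 the
#' source database). Symbols are uppercased, self-loops dropped, and
#' duplicate unordered pairs collapsed (first source retained; the number
#' collapsed is reported via `message()`).
#'
#' @param path Path to the edge table.
#' @param allowed_types Character vector of accepted `interaction_type`
#'   tokens (compared against both the raw token and, for PSI-MI TAB input,
#'   the extracted `MI:nnnn` id), or `NULL` to accept all types. Defaults to
#'   [direct_physical_types()].
#' @param format `"tsv"` or `"psimitab"`.
#' @return A data.frame with columns `gene_a`, `gene_b`, `interaction_type`,
#'   `source`; one row per retained unordered pair, `gene_a < gene_b`.
#' @export
read_edge_table <- function(path, allowed_types = direct_physical_types(),
                            format = c("tsv", "psimitab")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("edge table not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("gene_a", "gene_b", "interaction_type", "source")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("edge table is missing required column(s): ",
           paste(miss, collapse = ", "))
    }
    df <- df[need]
  } else {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 13) stop("PSI-MI TAB input needs at least 13 columns")
    df <- data.frame(gene_a = .psimitab_id(raw[[1]]),
                     gene_b = .psimitab_id(raw[[2]]),
                     interaction_type = .psimitab_token(raw[[12]]),
                     source = .psimitab_token(raw[[13]]),
                     stringsAsFactors = FALSE)
  }
  df$gene_a <- toupper(trimws(df$gene_a))
  df$gene_b <- toupper(trimws(df$gene_b))
  if (!is.null(allowed_types)) {
    df <- df[df$interaction_type %in% allowed_types, , drop = FALSE]
  }
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no interactions retained after filtering")
    return(df)
  }
  lo <- pmin(df$gene_a, df$gene_b)
  hi <- pmax(df$gene_a, df$gene_b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate unordered pair(s) collapsed")
  }
  out <- df[!dup, , drop = FALSE]
  out$gene_a <- lo[!dup]
  out$gene_b <- hi[!dup]
  rownames(out) <- NULL
  out
}

#' Write an interaction edge table
#'
#' @param edges Data.frame as returned by [read_edge_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the induced bait-interactome network
#'
#' Keeps every interaction whose two endpoints are both on the protein list
#' and returns the simple undirected graph on the full list: listed proteins
#' with no retained interaction stay as isolated (degree-0) vertices.
#'
#' @param proteins Character vector of gene symbols (the interactor list).
#' @param interactions Data.frame with columns `gene_a`, `gene_b` (other
#'   columns ignored), e.g. from [read_edge_table()].
#' @return An undirected simple [igraph::graph] with vertex names.
#' @export
build_induced_network <- function(proteins, interactions) {
  proteins <- unique(toupper(proteins))
  if (length(proteins) == 0L) stop("protein list is empty")
  if (is.null(interactions) || nrow(interactions) == 0L) {
    ed <- character(0)
  } else {
    a <- toupper(interactions$gene_a)
    b <- toupper(interactions$gene_b)
    keep <- a %in% proteins & b %in% proteins & a != b
    ed <- rbind(a[keep], b[keep])
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(proteins), name = proteins)
  if (length(ed)) g <- igraph::add_edges(g, as.vector(ed))
  igraph::simplify(g)
}

#' Extract the largest connected component
#'
#' Ties in component size are broken by the lexicographically smallest member
#' symbol, so the result is deterministic.
#'
#' @param net An igraph network.
#' @return The induced subgraph on the largest component.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) < 1L) stop("network has no nodes")
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    nm <- igraph::V(net)$name
    first_member <- vapply(best, function(ci) min(nm[comp$membership == ci]), "")
    best <- best[order(first_member)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Semi-local centrality
#'
#' A degree-based influence measure using the two-hop neighbourhood:
#' `N(w)` is the number of nodes within distance 2 of `w` (excluding `w`),
#' `Q(u) = sum of N(w)` over the neighbours `w` of `u`, and
#' `Cl(v) = sum of Q(u)` over the neighbours `u` of `v`. Values are
#' unity-normalized to `[0, 1]`; when all raw values coincide (a fully
#' symmetric graph) every node is assigned 0.5 so that no node is forced
#' into an extreme influence quadrant.
#'
#' @param net A connected igraph network with at least 2 nodes (run on the
#'   LCC).
#' @return Data.frame with columns `gene`, `raw`, `norm`.
#' @export
semilocal_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("semi-local centrality needs at least 2 nodes")
  if (!igraph::is_connected(net)) {
    stop("network must be connected; take largest_connected_component() first")
  }
  nw <- igraph::ego_size(net, order = 2, mindist = 1)
  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  q <- as.numeric(adj %*% nw)
  cl <- as.numeric(adj %*% q)
  rng <- range(cl)
  norm <- if (rng[1] == rng[2]) rep(0.5, n) else (cl - rng[1]) / diff(rng)
  data.frame(gene = igraph::V(net)$name, raw = cl, norm = norm,
             stringsAsFactors = FALSE)
}

#' Node centrality table
#'
#' Computes the centrality panel used to profile interactome nodes: degree,
#' betweenness (unnormalized shortest-path pair counts), closeness
#' (normalized to `(0, 1]`), local clustering coefficient, PageRank (damping
#' 0.85), semi-local centrality (raw and unity-normalized), and the mean
#' shortest-path distance to all other nodes. All distances are unweighted
#' hop counts.
#'
#' @param net A connected igraph network (the LCC).
#' @return Data.frame with one row per node.
#' @export
centrality_table <- function(net) {
  if (!igraph::is_connected(net)) {
    stop("network is disconnected; take largest_connected_component() first")
  }
  sl <- semilocal_centrality(net)
  n <- igraph::vcount(net)
  d <- igraph::distances(net)
  data.frame(
    gene = igraph::V(net)$name,
    degree = igraph::degree(net),
    betweenness = igraph::betweenness(net, directed = FALSE),
    closeness = igraph::closeness(net, normalized = TRUE),
    clustering_coefficient = igraph::transitivity(net, type = "local",
                                                  isolates = "zero"),
    pagerank = igraph::page_rank(net, damping = 0.85)$vector,
    semilocal_raw = sl$raw,
    semilocal_norm = sl$norm,
    mean_shortest_path = rowSums(d) / (n - 1),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
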