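#' Construct an annotation set
#'
#' Bundles term -> gene-set mappings with the background gene universe that
#' enrichment is tested against. Annotated genes must be drawn from the
#' background; term gene sets must be non-empty.
#'
#' @param terms Named list of character gene vectors (one entry per term).
#' @param background Character vector: the background gene universe (size
#'   `N` of the hypergeometric test).
#' @param descriptions Optional named character vector of term descriptions.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(terms, background, descriptions = NULL) {
  if (length(terms) && is.null(names(terms))) stop("terms must be named")
  background <- unique(toupper(background))
  terms <- lapply(terms, function(g) unique(toupper(g)))
  if (any(lengths(terms) == 0L)) {
    stop("empty term gene set(s): ",
         paste(names(terms)[lengths(terms) == 0L], collapse = ", "))
  }
  stray <- setdiff(unique(unlist(terms)), background)
  if (length(stray)) {
    stop("annotated genes missing from the background: ",
         paste(utils::head(stray, 10), collapse = ", "),
         if (length(stray) > 10) " ...")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(terms)), names(terms))
  }
  structure(list(terms = terms, background = background,
                 descriptions = descriptions[names(terms)]),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$terms), "terms over a background of",
      length(x$background), "genes\n")
  invisible(x)
}

#' Parse a GMT gene-set file
#'
#' Tab-separated lines: term id, description, then member genes. Duplicate
#' genes within a term are collapsed; a line with no genes is an error.
#'
#' @param path Path to the GMT file.
#' @param background Background universe; defaults to the union of all
#'   annotated genes (with a message, since the choice of `N` matters).
#' @return An [annotation_set()].
#' @export
parse_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(annotation_set(stats::setNames(list(), character(0)),
                          background %||% character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], " in ", path,
         ": need term, description and at least one gene")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(genes) <- ids
  if (is.null(background)) {
    message("parse_gmt: no background given; using the union of annotated genes")
    background <- unique(unlist(genes))
  }
  annotation_set(genes, background, stats::setNames(desc, ids))
}

#' Write an annotation set to GMT
#'
#' @param annotations An [annotation_set()] (or named list of gene vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  if (inherits(annotations, "annotation_set")) {
    terms <- annotations$terms
    desc <- annotations$descriptions
  } else {
    terms <- annotations
    desc <- stats::setNames(rep("", length(terms)), names(terms))
  }
  lines <- vapply(names(terms), function(id) {
    paste(c(id, if (nzchar(desc[[id]])) desc[[id]] else "na", terms[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Upper-tail hypergeometric probability
#'
#' The over-representation p-value `P(X >= k)` for drawing `k` annotated
#' genes in a list of size `n`, when `M` of the `N` background genes carry
#' the annotation:
#'
#'   `p = 1 - sum_{i=0}^{k-1} C(M,i) C(N-M, n-i) / C(N,n)`
#'
#' Evaluated in log space (via the stable tail of [stats::phyper()]), so
#' p-values far below machine-epsilon-from-1 magnitudes (e.g. 1e-22) are
#' exact. `k = 0` returns exactly 1. All arguments are vectorized.
#'
#' @param k Number of annotated genes in the list.
#' @param n List size.
#' @param M Number of annotated genes in the background.
#' @param N Background size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeom_tail <- function(k, n, M, N) {
  if (any(k < 0 | n < 0 | M < 0 | N < 0)) stop("negative arguments")
  if (any(n > N) || any(M > N)) stop("n and M must not exceed N")
  if (any(k > pmin(n, M))) stop("k must not exceed min(n, M)")
  ifelse(k == 0, 1,
         stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE))
}

#' Per-community annotation enrichment
#'
#' Tests every (community, term) pair with at least one annotated member
#' for over-representation by the hypergeometric upper tail, against the
#' annotation set's background. The Bonferroni family is the set of pairs
#' tested in this call; Benjamini-Yekutieli FDR values are reported
#' alongside. Significance stars follow the Bonferroni-adjusted p at 0.05
#' (`*`), 0.01 (`**`) and 0.001 (`***`).
#'
#' @param partition Named integer partition of network genes (all of which
#'   must be in the background).
#' @param annotations An [annotation_set()].
#' @param clusters Optional integer vector restricting which communities are
#'   tested.
#' @param n_perm If > 0, the permutation strength-of-significance test is
#'   run (with `n_perm` label permutations) for every pair with
#'   `p <= strength_alpha`.
#' @param strength_alpha Raw-p threshold gating the permutation test
#'   (default 0.01, the conventional follow-up cutoff).
#' @param seed Seed for the permutation test.
#' @return Data.frame with columns `cluster`, `term`, `description`, `k`,
#'   `n`, `M`, `N`, `p`, `p_bonferroni`, `p_by`, `stars`, and (when
#'   `n_perm > 0`) `strength_pct`.
#' @export
cluster_term_enrichment <- function(partition, annotations, clusters = NULL,
                                    n_perm = 0, strength_alpha = 0.01,
                                    seed = 1) {
  genes <- toupper(names(partition))
  stray <- setdiff(genes, annotations$background)
  if (length(stray)) {
    stop("partition genes missing from the background: ",
         paste(utils::head(stray, 10), collapse = ", "),
         if (length(stray) > 10) " ...")
  }
  N <- length(annotations$background)
  cl_ids <- sort(unique(partition))
  if (!is.null(clusters)) cl_ids <- intersect(cl_ids, clusters)
  rows <- list()
  for (cl in cl_ids) {
    members <- genes[partition == cl]
    n <- length(members)
    for (term in names(annotations$terms)) {
      tg <- annotations$terms[[term]]
      k <- length(intersect(members, tg))
      if (k < 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, term = term,
        description = unname(annotations$descriptions[term]),
        k = k, n = n, M = length(tg), N = N,
        p = hypergeom_tail(k, n, length(tg), N),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(cluster = integer(0), term = character(0),
                      description = character(0), k = integer(0),
                      n = integer(0), M = integer(0), N = integer(0),
                      p = numeric(0), p_bonferroni = numeric(0),
                      p_by = numeric(0), stars = character(0)))
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- adjust_pvalues(out$p, "bonferroni")
  out$p_by <- adjust_pvalues(out$p, "benjamini_yekutieli")
  out$stars <- ifelse(out$p_bonferroni <= 0.001, "***",
               ifelse(out$p_bonferroni <= 0.01, "**",
               ifelse(out$p_bonferroni <= 0.05, "*", "")))
  if (n_perm > 0) {
    out$strength_pct <- NA_real_
    todo <- which(out$p <= strength_alpha)
    for (idx in seq_along(todo)) {
      i <- todo[idx]
      out$strength_pct[i] <- permutation_strength(
        out$p[i], genes[partition == out$cluster[i]], out$term[i],
        annotations, n_perm = n_perm, seed = seed + idx)
    }
  }
  rownames(out) <- NULL
  out
}

#' Permutation strength-of-significance test
#'
#' Shuffles the annotation labels of one term across the background (each
#' permutation re-draws the term's `M` labels uniformly over the `N`
#' background genes, which is exactly a label permutation restricted to
#' this term), recomputes the enrichment p-value for the community, and
#' returns the percentage of permuted p-values lower than or equal to the
#' observed one (ties inclusive). A strength below 1 (percent) is the
#' conventional significance call.
#'
#' @param observed_p Observed hypergeometric p for the (community, term)
#'   pair.
#' @param cluster_genes Genes of the community.
#' @param term Term id in `annotations`.
#' @param annotations An [annotation_set()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param within Optional gene universe to permute over instead of the full
#'   background (e.g. network nodes only).
#' @return Strength as a percentage in `[0, 100]`.
#' @export
permutation_strength <- function(observed_p, cluster_genes, term, annotations,
                                 n_perm = 1000, seed = 1, within = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  universe <- if (is.null(within)) annotations$background else
    unique(toupper(within))
  tg <- annotations$terms[[term]]
  if (is.null(tg)) stop("unknown term: ", term)
  M <- length(intersect(tg, universe))
  N <- length(universe)
  cluster_genes <- intersect(toupper(cluster_genes), universe)
  n <- length(cluster_genes)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(universe, M)
    k <- length(intersect(perm, cluster_genes))
    if (hypergeom_tail(k, n, M, N) <= observed_p * (1 + 1e-12)) {
      hits <- hits + 1L
    }
  }
  100 * hits / n_perm
}

#' Multiple-testing adjustment
#'
#' Standard Bonferroni, Benjamini-Hochberg (step-up FDR) and
#' Benjamini-Yekutieli (FDR under dependence) corrections, returned in the
#' input order and capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"`, `"benjamini_hochberg"` or
#'   `"benjamini_yekutieli"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "benjamini_hochberg",
                                         "benjamini_yekutieli")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method,
    bonferroni = "bonferroni",
    benjamini_hochberg = "BH",
    benjamini_yekutieli = "BY"))
}
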