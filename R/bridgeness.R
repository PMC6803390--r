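#' Bridgeness of a single membership row
#'
#' Bridgeness measures how evenly a node's community-membership probability
#' vector `u` is spread across the `c` communities found by one algorithm:
#'
#'   `Ba(v) = 1 - sqrt( c/(c-1) * sum_j (u_jv - 1/c)^2 )`
#'
#' It is 0 for a one-hot row (the node sits squarely in one community) and 1
#' for the uniform row (a "global bridge" shared equally by all
#' communities). The square root is required for the uniform row to reach
#' exactly 1 with this normalizing constant; `sqrt = FALSE` is provided only
#' as a compatibility switch and no longer spans `[0, 1]` linearly.
#'
#' @param u Probability vector of length `c`, summing to 1.
#' @param c Number of communities (>= 2); defaults to `length(u)`.
#' @param sqrt Apply the square root (default `TRUE`).
#' @return Bridgeness in `[0, 1]`.
#' @export
bridgeness_single <- function(u, c = length(u), sqrt = TRUE) {
  if (c < 2L) stop("bridgeness is undefined for a single community (c < 2)")
  if (length(u) != c) stop("membership row length must equal c")
  if (any(u < -1e-9) || abs(sum(u) - 1) > 1e-6) {
    stop("membership row must be a probability vector summing to 1")
  }
  d2 <- c / (c - 1) * sum((u - 1 / c)^2)
  ba <- if (sqrt) 1 - base::sqrt(d2) else 1 - d2
  min(max(ba, 0), 1)
}

#' Per-node bridgeness from a membership matrix
#'
#' @param memberships Nodes-by-communities probability matrix (rows sum
#'   to 1), e.g. from [bootstrap_memberships()].
#' @param sqrt Passed to [bridgeness_single()].
#' @return Named numeric vector of Ba values.
#' @export
bridgeness <- function(memberships, sqrt = TRUE) {
  if (ncol(memberships) < 2L) {
    stop("bridgeness is undefined for a single community (c < 2)")
  }
  stats::setNames(
    apply(memberships, 1, bridgeness_single, c = ncol(memberships),
          sqrt = sqrt),
    rownames(memberships))
}

#' Mean bridgeness across algorithms
#'
#' The consensus bridging score `Br(v)` is the arithmetic mean of `Ba(v)`
#' over the configured algorithm set; algorithms missing for a node are
#' excluded from its mean.
#'
#' @param ba_per_algorithm Named list (algorithm -> named Ba vector) or, for
#'   a single node, a named numeric vector of per-algorithm values.
#' @return Named numeric vector of Br values (or a single number).
#' @export
mean_bridgeness <- function(ba_per_algorithm) {
  if (is.numeric(ba_per_algorithm)) {
    if (length(ba_per_algorithm) == 0L) stop("no algorithms present")
    return(mean(ba_per_algorithm, na.rm = TRUE))
  }
  if (length(ba_per_algorithm) == 0L) stop("no algorithms present")
  nodes <- unique(unlist(lapply(ba_per_algorithm, names)))
  mat <- vapply(ba_per_algorithm,
                function(v) unname(v[nodes]), numeric(length(nodes)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(nodes))
  stats::setNames(rowMeans(mat, na.rm = TRUE), nodes)
}

#' Influence-region levels
#' @return Character vector of the four region labels.
#' @export
influence_regions <- function() {
  c("R1_global_bridge", "R2_mixed_bridge", "R3_local_hub", "R4_local_only")
}

#' Classify nodes into influence regions
#'
#' Partitions the (semi-local centrality, mean bridgeness) plane into the
#' four quadrants used to read the influence scatter:
#' \itemize{
#'   \item Region 1 (global bridges): `Cl < 0.5`, `Br >= 0.5`
#'   \item Region 2 (mixed global/local bridges): `Cl >= 0.5`, `Br >= 0.5`
#'   \item Region 3 (local hubs): `Cl < 0.5`, `0.1 <= Br < 0.5`
#'   \item Region 4 (local influence only): everything else, i.e.
#'     `Cl >= 0.5` with `Br < 0.5`, or `Br < 0.1`
#' }
#' Boundaries are resolved half-open (a point exactly on 0.5 goes to the
#' high side) because the published closed intervals overlap. "Bridging
#' proteins" are those in Regions 1 and 2.
#'
#' @param cl_norm Normalized semi-local centrality in `[0, 1]` (vectorized).
#' @param br Mean bridgeness in `[0, 1]` (vectorized).
#' @return Factor with levels [influence_regions()].
#' @export
classify_region <- function(cl_norm, br) {
  if (any(cl_norm < 0 | cl_norm > 1 | br < 0 | br > 1, na.rm = TRUE)) {
    stop("cl_norm and br must lie in [0, 1]")
  }
  out <- ifelse(br >= 0.5,
                ifelse(cl_norm < 0.5, "R1_global_bridge", "R2_mixed_bridge"),
                ifelse(cl_norm >= 0.5, "R4_local_only",
                       ifelse(br >= 0.1, "R3_local_hub", "R4_local_only")))
  factor(out, levels = influence_regions())
}

#' Per-node influence table
#'
#' Combines normalized semi-local centrality with per-algorithm bridgeness,
#' the cross-algorithm mean `Br`, and the influence-region label into one
#' table (the quadrant-plot input).
#'
#' @param net The connected network (LCC) the memberships were computed on.
#' @param membership_list Named list (algorithm -> membership matrix from
#'   [bootstrap_memberships()]).
#' @param sqrt Passed to [bridgeness()].
#' @return Data.frame with columns `gene`, `cl_norm`, one `ba_<algorithm>`
#'   column per entry of `membership_list`, `br`, `region`, and
#'   `is_bridging` (Region 1 or 2).
#' @export
influence_table <- function(net, membership_list, sqrt = TRUE) {
  if (length(membership_list) == 0L) stop("no membership matrices supplied")
  sl <- semilocal_centrality(net)
  ba <- lapply(membership_list, bridgeness, sqrt = sqrt)
  br <- mean_bridgeness(ba)
  out <- data.frame(gene = sl$gene, cl_norm = sl$norm,
                    stringsAsFactors = FALSE)
  for (a in names(ba)) out[[paste0("ba_", a)]] <- unname(ba[[a]][sl$gene])
  out$br <- unname(br[sl$gene])
  out$region <- classify_region(out$cl_norm, out$br)
  out$is_bridging <- out$region %in% c("R1_global_bridge", "R2_mixed_bridge")
  out
}
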