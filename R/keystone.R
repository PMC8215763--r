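# Putative keystone identification: recompute the five network measures after
# removing each node in turn, rank the deltas per measure in the direction a
# structurally load-bearing node would move them (transitivity and density
# down; modularity, average path length and eigenvector centralisation up),
# and aggregate the five ranks per cluster with a Borda count (sum of ranks,
# lowest wins).

.measure_names <- c("transitivity", "density", "modularity",
                    "avg_path_length", "eigen_centralization")
.decrease_measures <- c("transitivity", "density")

#' Five-measure deltas for removing one node
#'
#' Measures are computed on the full graph and on the graph minus the node,
#' with the cluster partition held fixed (restricted to the remaining nodes,
#' no re-clustering). Delta = removed - full.
#'
#' @param net A clustered `family_network` (after [detect_clusters()]).
#' @param node Node (family) name.
#' @param scope `"full"` computes measures on the whole network; `"subgraph"`
#'   restricts to the node's cluster subgraph first.
#' @return Named numeric vector of the five deltas.
#' @export
removal_deltas <- function(net, node, scope = c("full", "subgraph")) {
  scope <- match.arg(scope)
  stopifnot(inherits(net, "family_network"))
  g <- net$graph
  membership <- net$membership
  if (is.null(membership)) stop("removal_deltas: run detect_clusters() first")
  if (!node %in% igraph::V(g)$name) {
    stop("removal_deltas: unknown node ", node)
  }
  if (scope == "subgraph") {
    cl <- membership[[node]]
    keep <- names(membership)[!is.na(membership) & membership == cl]
    g <- igraph::induced_subgraph(g, keep)
    membership <- membership[keep]
  }
  if (igraph::vcount(g) < 2) {
    stop("removal_deltas: cannot remove the last node of the graph")
  }
  full <- network_measures(g, membership[igraph::V(g)$name])
  g2 <- igraph::delete_vertices(g, node)
  removed <- network_measures(g2, membership[igraph::V(g2)$name])
  d <- removed - full
  # removing a node from an edgeless remainder: modularity undefined both ways
  d[is.na(d)] <- 0
  # deltas that agree to 1e-10 are genuine ties; rounding keeps the ranks
  # stable against eigendecomposition round-off
  round(d, 10)
}

#' Directional ranks of removal deltas
#'
#' Rank 1 marks the strongest keystone signal: the most negative delta for
#' transitivity and density, the most positive delta for modularity, average
#' path length and eigenvector centralisation. Ties receive average ranks.
#'
#' @param deltas Numeric vector of deltas for one measure across candidates.
#' @param measure Measure name (one of the five).
#' @return Numeric ranks (average-rank ties).
#' @export
rank_candidates <- function(deltas, measure) {
  measure <- match.arg(measure, .measure_names)
  if (measure %in% .decrease_measures) {
    rank(deltas, ties.method = "average")
  } else {
    rank(-deltas, ties.method = "average")
  }
}

#' Keystone analysis of a clustered network
#'
#' For every labelled node, computes the five removal deltas, ranks them per
#' measure *within the node's cluster*, sums the five ranks into a Borda
#' score, and flags the `top_k` lowest scores per cluster as putative
#' keystones. Equal Borda scores are reported as ties (`tied` column);
#' deterministic id order is used only for output ordering.
#'
#' @param net A clustered `family_network`.
#' @param top_k Keystone candidates flagged per cluster (default 2).
#' @param scope Passed to [removal_deltas()].
#' @return A `keystone_report` data frame: node, cluster, five `delta_*`
#'   columns, five `rank_*` columns, `borda`, `overall_rank` (1 = strongest,
#'   per cluster), `keystone` flag and `tied` flag.
#' @export
keystone_analysis <- function(net, top_k = 2, scope = "full") {
  stopifnot(inherits(net, "family_network"))
  if (is.null(net$membership)) {
    stop("keystone_analysis: run detect_clusters() first")
  }
  membership <- net$membership
  nodes <- sort(names(membership)[!is.na(membership)])
  if (length(nodes) == 0) {
    out <- data.frame(node = character(0), cluster = character(0))
    class(out) <- c("keystone_report", "data.frame")
    return(out)
  }
  deltas <- t(vapply(nodes, function(v) removal_deltas(net, v, scope),
                     numeric(length(.measure_names))))
  out <- data.frame(node = nodes, cluster = unname(membership[nodes]),
                    stringsAsFactors = FALSE)
  colnames(deltas) <- paste0("delta_", .measure_names)
  out <- cbind(out, deltas)
  for (m in .measure_names) out[[paste0("rank_", m)]] <- NA_real_
  out$borda <- NA_real_
  out$overall_rank <- NA_integer_
  out$keystone <- FALSE
  out$tied <- FALSE
  for (cl in unique(out$cluster)) {
    rows <- which(out$cluster == cl)
    for (m in .measure_names) {
      out[rows, paste0("rank_", m)] <-
        rank_candidates(out[rows, paste0("delta_", m)], m)
    }
    borda <- rowSums(out[rows, paste0("rank_", .measure_names), drop = FALSE])
    out$borda[rows] <- borda
    ord <- order(borda, out$node[rows])
    out$overall_rank[rows[ord]] <- seq_along(rows)
    out$keystone[rows[ord[seq_len(min(top_k, length(rows)))]]] <- TRUE
    out$tied[rows] <- duplicated(borda) | duplicated(borda, fromLast = TRUE)
  }
  out <- out[order(out$cluster, out$overall_rank), ]
  rownames(out) <- NULL
  class(out) <- c("keystone_report", "data.frame")
  out
}
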