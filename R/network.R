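# Signed co-occurrence network over taxonomic families: Spearman correlations
# with BH-corrected p-values, the |rho| > 0.7 & adjusted p < 0.1 edge rule,
# greedy modularity clusters, and the five network-level measures consumed by
# the keystone stage.

#' Spearman correlation matrix with BH-adjusted p-values
#'
#' Correlations use average ranks (ties mid-ranked). P-values come from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom, or from exact permutation when `exact = TRUE` (only for
#' `n <= 8` samples). BH adjustment runs over the strict upper triangle.
#' Constant families yield `NA` correlations and can never form edges.
#'
#' @param fm A `family_matrix` (any stage; correlations are rank-based) or a
#'   plain family x sample matrix.
#' @param exact Use the exact permutation null instead of the t approximation.
#' @return A `correlation_matrix`: list with symmetric matrices `rho`, `p`,
#'   `padj` and the sample count `n`.
#' @export
spearman_correlations <- function(fm, exact = FALSE) {
  mat <- unclass(fm)
  n <- ncol(mat)
  if (n < 4) stop("spearman_correlations: need at least 4 samples")
  rho <- suppressWarnings(stats::cor(t(mat), method = "spearman"))
  diag(rho) <- 1
  if (exact) {
    if (n > 8) stop("spearman_correlations: exact permutation only for n <= 8")
    null_rho <- .spearman_permutation_null(n)
    p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
    ok <- !is.na(rho)
    p[ok] <- vapply(rho[ok],
                    function(r) mean(abs(null_rho) >= abs(r) - 1e-12),
                    numeric(1))
  } else {
    r2 <- pmin(rho^2, 1)
    tstat <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
    p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
    p[r2 >= 1] <- 0
  }
  diag(p) <- NA_real_
  padj <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  up <- upper.tri(p)
  padj[up] <- stats::p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(list(rho = rho, p = p, padj = padj, n = n),
            class = "correlation_matrix")
}

# Exact permutation distribution of Spearman's rho for untied data of size n.
.spearman_permutation_null <- function(n) {
  perms <- .permutations(n)
  ref <- seq_len(n)
  apply(perms, 1, function(pm) stats::cor(ref, pm, method = "spearman"))
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, ] <- cbind(sub + (sub >= i), i)[, c(n, seq_len(n - 1))]
  }
  out
}

#' Build the signed co-occurrence network
#'
#' An edge joins two families iff `|rho| > rho_min` and the BH-adjusted
#' p-value is below `alpha`; the edge sign is the sign of rho. All families
#' are kept as nodes (isolated nodes carry no cluster label downstream); node
#' weight is the family's total expression.
#'
#' @param cm A `correlation_matrix` from [spearman_correlations()].
#' @param node_weights Named vector of total expression per family (typically
#'   `rowSums()` of the scaled matrix). Defaults to zero weights.
#' @param rho_min Correlation magnitude threshold (default 0.7).
#' @param alpha Adjusted-p threshold (default 0.1).
#' @param signed If `FALSE`, threshold the raw rho instead of `|rho|`, so
#'   negative correlations can never form edges.
#' @return A `family_network`: list with `graph` (igraph, undirected), an
#'   `edges` data frame (`from`, `to`, `rho`, `p`, `padj`, `sign`), thresholds
#'   and (after [detect_clusters()]) the membership and modularity.
#' @export
build_network <- function(cm, node_weights = NULL, rho_min = 0.7, alpha = 0.1,
                          signed = TRUE) {
  stopifnot(inherits(cm, "correlation_matrix"))
  fams <- rownames(cm$rho)
  if (is.null(node_weights)) {
    node_weights <- stats::setNames(rep(0, length(fams)), fams)
  }
  stopifnot(all(fams %in% names(node_weights)))
  idx <- which(upper.tri(cm$rho), arr.ind = TRUE)
  rho <- cm$rho[idx]
  padj <- cm$padj[idx]
  mag <- if (signed) abs(rho) else rho
  keep <- !is.na(rho) & !is.na(padj) & mag > rho_min & padj < alpha
  edges <- data.frame(
    from = fams[idx[keep, 1]],
    to = fams[idx[keep, 2]],
    rho = rho[keep],
    p = cm$p[idx][keep],
    padj = padj[keep],
    sign = ifelse(rho[keep] >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = fams,
                          total_expression = unname(node_weights[fams]),
                          stringsAsFactors = FALSE)
  )
  igraph::V(g)$cluster <- NA_character_
  structure(list(graph = g, edges = edges, rho_min = rho_min, alpha = alpha,
                 signed = signed, membership = NULL, modularity = NA_real_),
            class = "family_network")
}

#' Detect modularity clusters
#'
#' Communities are found by greedy modularity agglomeration on the unweighted
#' skeleton of the *positive* edges: negative edges encode antagonism between
#' sub-communities and would otherwise merge the anticorrelated blocks they
#' separate. Nodes whose only edges are negative become singleton clusters;
#' isolated nodes get no label. The procedure is deterministic for a given
#' graph; `seed` is accepted for interface stability.
#'
#' @param net A `family_network`.
#' @param seed Unused by the deterministic greedy algorithm; kept so callers
#'   can treat all stages uniformly.
#' @return The network with `membership` (named cluster labels, `NA` for
#'   isolated nodes) and `modularity` (Q of the partition on the positive
#'   skeleton) filled in.
#' @export
detect_clusters <- function(net, seed = 1L) {
  stopifnot(inherits(net, "family_network"))
  g <- net$graph
  labels <- stats::setNames(rep(NA_character_, igraph::vcount(g)),
                            igraph::V(g)$name)
  pos <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$sign == "+"], delete.vertices = FALSE
  )
  connected <- igraph::V(g)$name[igraph::degree(g) > 0]
  pos_deg <- igraph::degree(pos)
  core <- igraph::induced_subgraph(pos, igraph::V(pos)[pos_deg > 0])
  q <- NA_real_
  if (igraph::vcount(core) > 0) {
    comm <- igraph::cluster_fast_greedy(core)
    # cut the dendrogram at the modularity maximum ourselves: ties (within
    # 1e-12) go to the coarsest partition, which keeps the result stable
    # against floating-point drift in the greedy merge scores
    ks <- seq_len(igraph::vcount(core))
    best_q <- -Inf
    best_m <- rep(1L, igraph::vcount(core))
    for (k in ks) {
      # cut_at warns when k is below the number of components; the returned
      # partition is still the finest achievable one
      mk <- tryCatch(suppressWarnings(igraph::cut_at(comm, no = k)),
                     error = function(e) NULL)
      if (is.null(mk)) next
      qk <- igraph::modularity(core, mk)
      if (qk > best_q + 1e-12) {
        best_q <- qk
        best_m <- mk
      }
    }
    labels[igraph::V(core)$name] <- sprintf("C%02d", best_m)
    q <- best_q
  }
  # nodes with only negative edges: their own singletons
  neg_only <- setdiff(connected, names(labels)[!is.na(labels)])
  if (length(neg_only) > 0) {
    labels[neg_only] <- sprintf("N%02d", seq_along(neg_only))
  }
  igraph::V(g)$cluster <- unname(labels[igraph::V(g)$name])
  net$graph <- g
  net$membership <- labels
  net$modularity <- q
  net
}

.check_graph <- function(g, op) {
  if (igraph::vcount(g) == 0) stop(op, ": empty graph")
  invisible(g)
}

#' Global transitivity (clustering coefficient)
#'
#' `3 * triangles / connected triples`; 0 when the graph has no connected
#' triple.
#'
#' @param g An undirected igraph graph.
#' @return A single number in `[0, 1]`.
#' @export
net_transitivity <- function(g) {
  .check_graph(g, "net_transitivity")
  x <- igraph::transitivity(g, type = "global")
  if (is.nan(x) || is.na(x)) 0 else x
}

#' Edge density
#'
#' `2E / (N (N - 1))`; 0 for fewer than two nodes.
#'
#' @param g An undirected igraph graph.
#' @return A single number in `[0, 1]`.
#' @export
net_density <- function(g) {
  .check_graph(g, "net_density")
  if (igraph::vcount(g) < 2) return(0)
  igraph::edge_density(g)
}

#' Modularity of a fixed partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` on the unweighted skeleton.
#'
#' @param g An undirected igraph graph.
#' @param membership Cluster labels, one per vertex (any atomic type).
#' @return Q; `NA` when the graph has no edges.
#' @export
net_modularity <- function(g, membership) {
  .check_graph(g, "net_modularity")
  if (igraph::ecount(g) == 0) return(NA_real_)
  membership <- as.character(membership)
  na <- is.na(membership)
  # unlabelled (isolated) nodes sit in their own singleton communities
  membership[na] <- sprintf(".iso%d", seq_len(sum(na)))
  igraph::modularity(g, as.integer(factor(membership)))
}

#' Average shortest-path length over reachable pairs
#'
#' Mean geodesic distance over ordered pairs that are connected; 0 when no
#' pair is reachable. Setting `unreachable_as_n = TRUE` instead counts each
#' unreachable pair as a path of length N.
#'
#' @param g An undirected igraph graph.
#' @param unreachable_as_n Alternative convention for disconnected graphs.
#' @return A single non-negative number.
#' @export
net_avg_path_length <- function(g, unreachable_as_n = FALSE) {
  .check_graph(g, "net_avg_path_length")
  d <- igraph::distances(g)
  d <- d[upper.tri(d)]
  if (unreachable_as_n) d[is.infinite(d)] <- igraph::vcount(g)
  d <- d[is.finite(d)]
  if (length(d) == 0) return(0)
  mean(d)
}

# Eigenvector centrality scores under the pinned convention: Perron vector of
# the connected component with the largest spectral radius (ties broken by
# component size, then by smallest vertex id), scaled to max 1; vertices
# outside that component score 0. A dense symmetric eigendecomposition keeps
# the result deterministic even when components tie.
.eigen_scores <- function(g) {
  n <- igraph::vcount(g)
  scores <- stats::setNames(rep(0, n), igraph::V(g)$name)
  if (igraph::ecount(g) == 0) return(scores)
  comp <- igraph::components(g)
  best <- NULL
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    if (length(members) < 2) next
    adj <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, members), sparse = FALSE
    )
    ev <- eigen(adj, symmetric = TRUE)
    lambda <- ev$values[1]
    cand <- list(lambda = lambda, members = members,
                 vec = abs(ev$vectors[, 1]))
    if (is.null(best) ||
        lambda > best$lambda + 1e-9 ||
        (abs(lambda - best$lambda) <= 1e-9 &&
         (length(members) > length(best$members) ||
          (length(members) == length(best$members) &&
           min(members) < min(best$members))))) {
      best <- cand
    }
  }
  if (is.null(best) || max(best$vec) == 0) return(scores)
  scores[best$members] <- best$vec / max(best$vec)
  scores
}

#' Eigenvector centralisation
#'
#' Graph-level dispersion of eigenvector centralities:
#' `sum_i (c_max - c_i) / (N - 1)` with scores scaled so the most central node
#' has score 1 (see the package vignette for the convention on disconnected
#' graphs).
#'
#' @param g An undirected igraph graph.
#' @return A single number in `[0, 1]`.
#' @export
net_eigen_centralization <- function(g) {
  .check_graph(g, "net_eigen_centralization")
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  s <- .eigen_scores(g)
  sum(max(s) - s) / (n - 1)
}

#' All five network-level measures at once
#'
#' @param g An undirected igraph graph.
#' @param membership Cluster labels for the modularity term.
#' @return Named numeric vector: `transitivity`, `density`, `modularity`,
#'   `avg_path_length`, `eigen_centralization`.
#' @export
network_measures <- function(g, membership) {
  c(
    transitivity = net_transitivity(g),
    density = net_density(g),
    modularity = net_modularity(g, membership),
    avg_path_length = net_avg_path_length(g),
    eigen_centralization = net_eigen_centralization(g)
  )
}
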