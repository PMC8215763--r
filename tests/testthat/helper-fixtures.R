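# Shared in-code fixtures for the test suite.

# small default-like generator config that runs fast
small_config <- function(seed = 42, ...) {
  generator_config(
    n_primary_families = 5, n_secondary_families = 5,
    n_independent_families = 6, n_keystone_per_block = 1,
    genes_per_family_range = c(10, 15), seed = seed, ...
  )
}

# a tiny hand-made expression table: 2 families, 5 genes, 4 samples
toy_table <- function() {
  counts <- matrix(
    c(2, 3, 0, 1, 4,
      5, 1, 2, 0, 0,
      1, 0, 3, 2, 1,
      0, 2, 1, 1, 3),
    nrow = 5, dimnames = list(sprintf("g%d", 1:5),
                              sprintf("A%d_T%d", c(1, 1, 2, 2), c(1, 2, 1, 2)))
  )
  meta <- data.frame(
    gene_id = sprintf("g%d", 1:5),
    family = c("FamA", "FamA", "FamB", "FamB", "FamB"),
    genus = "g",
    functional_cluster = c("FC1", "FC2", "FC1", "FC1", "FC2"),
    enzyme_tag = c("GH5", NA, "GH5", "M24b", NA),
    length_bp = c(500L, 1000L, 750L, 1500L, 300L),
    stringsAsFactors = FALSE
  )
  expression_table(counts, meta)
}

toy_design <- function() {
  sample_design(data.frame(
    sample_id = sprintf("A%d_T%d", c(1, 1, 2, 2), c(1, 2, 1, 2)),
    animal_id = sprintf("A%d", c(1, 1, 2, 2)),
    timepoint_h = c(1, 2, 1, 2)
  ))
}

# balanced 3-animal x 5-timepoint design without baseline
balanced_design <- function(n_animals = 3, timepoints = c(1, 2, 4, 6, 8)) {
  g <- expand.grid(animal_id = sprintf("A%d", seq_len(n_animals)),
                   timepoint_h = timepoints, stringsAsFactors = FALSE)
  sample_design(data.frame(
    sample_id = sprintf("%s_T%g", g$animal_id, g$timepoint_h),
    animal_id = g$animal_id, timepoint_h = g$timepoint_h
  ))
}

# family_network from an explicit edge list (all correlations set by hand)
net_from_edges <- function(edges, nodes, rho = 0.9, padj = 0.01) {
  rho_m <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  diag(rho_m) <- 1
  p_m <- matrix(1, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      r <- if (!is.null(edges$rho)) edges$rho[i] else rho
      rho_m[edges$from[i], edges$to[i]] <- r
      rho_m[edges$to[i], edges$from[i]] <- r
      p_m[edges$from[i], edges$to[i]] <- padj
      p_m[edges$to[i], edges$from[i]] <- padj
    }
  }
  cm <- structure(list(rho = rho_m, p = p_m, padj = p_m, n = 15),
                  class = "correlation_matrix")
  build_network(cm, stats::setNames(rep(1, length(nodes)), nodes))
}

# random undirected graph as a clustered family_network plus its adjacency
random_labelled_net <- function(n, p = 0.35) {
  nodes <- sprintf("v%02d", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      stringsAsFactors = FALSE)
  net <- net_from_edges(edges, nodes)
  net <- detect_clusters(net)
  list(net = net, adj = adj, membership = net$membership)
}
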