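# Independent brute-force implementations of the five network measures and the
# node-removal keystone procedure, used only as oracles. They work on a plain
# adjacency matrix and share no code with the package implementations
# (triangle enumeration, all-pairs BFS, direct modularity sum, power
# iteration).

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0
  triples <- 0
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      e <- adj[i, j] + adj[i, k] + adj[j, k]
      if (e == 3) triangles <- triangles + 1
    }
  }
  # connected triples: sum over centre nodes of choose(degree, 2)
  deg <- rowSums(adj)
  triples <- sum(choose(deg, 2))
  if (triples == 0) return(0)
  3 * triangles / triples
}

oracle_density <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  sum(adj) / (n * (n - 1))
}

oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  membership <- as.character(membership)
  na <- is.na(membership)
  membership[na] <- paste0(".solo", seq_len(sum(na)))
  q <- 0
  for (cl in unique(membership)) {
    idx <- membership == cl
    e_c <- sum(adj[idx, idx, drop = FALSE]) / 2
    d_c <- sum(adj[idx, , drop = FALSE])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

oracle_apl <- function(adj) {
  n <- nrow(adj)
  total <- 0
  count <- 0
  for (s in seq_len(n)) {
    # BFS from s
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    reach <- dist[-s][is.finite(dist[-s])]
    total <- total + sum(reach)
    count <- count + length(reach)
  }
  if (count == 0) return(0)
  total / count
}

oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in which(adj[v, ] == 1)) {
        if (comp[w] == 0) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

oracle_eigen_centralization <- function(adj) {
  n <- nrow(adj)
  if (n < 2 || sum(adj) == 0) return(0)
  comp <- oracle_components(adj)
  best <- NULL
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (length(idx) < 2) next
    sub <- adj[idx, idx, drop = FALSE]
    # power iteration on A + I (same Perron vector, strictly dominant
    # eigenvalue even for bipartite components)
    shifted <- sub + diag(length(idx))
    v <- rep(1, length(idx))
    lambda <- 0
    for (it in 1:10000) {
      v2 <- as.numeric(shifted %*% v)
      lambda2 <- sqrt(sum(v2^2))
      if (lambda2 == 0) break
      v2 <- v2 / lambda2
      if (max(abs(v2 - v)) < 1e-13) {
        v <- v2
        lambda <- lambda2
        break
      }
      v <- v2
      lambda <- lambda2
    }
    lambda <- lambda - 1   # undo the shift to compare spectral radii
    cand <- list(lambda = lambda, idx = idx, vec = abs(v))
    if (is.null(best) ||
        lambda > best$lambda + 1e-9 ||
        (abs(lambda - best$lambda) <= 1e-9 &&
         (length(idx) > length(best$idx) ||
          (length(idx) == length(best$idx) && min(idx) < min(best$idx))))) {
      best <- cand
    }
  }
  if (is.null(best) || max(best$vec) == 0) return(0)
  scores <- rep(0, n)
  scores[best$idx] <- best$vec / max(best$vec)
  sum(max(scores) - scores) / (n - 1)
}

oracle_measures <- function(adj, membership) {
  c(transitivity = oracle_transitivity(adj),
    density = oracle_density(adj),
    modularity = oracle_modularity(adj, membership),
    avg_path_length = oracle_apl(adj),
    eigen_centralization = oracle_eigen_centralization(adj))
}

# full keystone report recomputed from scratch for a labelled graph
oracle_keystone <- function(adj, membership, top_k = 2) {
  nodes <- sort(names(membership)[!is.na(membership)])
  full <- oracle_measures(adj, membership)
  deltas <- t(vapply(nodes, function(v) {
    keep <- setdiff(rownames(adj), v)
    d <- oracle_measures(adj[keep, keep, drop = FALSE], membership[keep]) - full
    d[is.na(d)] <- 0
    round(d, 10)   # same numeric tie policy as the implementation
  }, numeric(5)))
  down <- c("transitivity", "density")
  out <- data.frame(node = nodes, cluster = unname(membership[nodes]),
                    borda = NA_real_, stringsAsFactors = FALSE)
  for (cl in unique(out$cluster)) {
    rows <- which(out$cluster == cl)
    ranks <- sapply(colnames(deltas), function(m) {
      if (m %in% down) rank(deltas[rows, m]) else rank(-deltas[rows, m])
    })
    if (length(rows) == 1) ranks <- matrix(ranks, nrow = 1)
    out$borda[rows] <- rowSums(ranks)
  }
  list(deltas = deltas, borda = stats::setNames(out$borda, out$node))
}

# hand implementation of the Benjamini-Hochberg step-up adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
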