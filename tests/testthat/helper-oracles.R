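# Independent oracles used across the suite. Everything here is written
# from first principles (plain-R arithmetic, hand BFS, exhaustive
# enumeration) and never calls the package code paths it checks.

# Build an igraph from a character vector of "A-B" edge specs.
graph_from_pairs <- function(pairs) {
  el <- do.call(rbind, strsplit(pairs, "-", fixed = TRUE))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Hand-rolled BFS connectivity check on an edge list (n x 2 character
# matrix); independent of igraph.
oracle_connected <- function(nodes, edges) {
  nodes <- unique(nodes)
  if (length(nodes) <= 1) return(TRUE)
  if (is.null(dim(edges)) || nrow(edges) == 0) return(FALSE)
  keep <- edges[, 1] %in% nodes & edges[, 2] %in% nodes
  edges <- edges[keep, , drop = FALSE]
  seen <- nodes[1]
  repeat {
    nxt <- unique(c(edges[edges[, 1] %in% seen, 2],
                    edges[edges[, 2] %in% seen, 1]))
    nxt <- setdiff(intersect(nxt, nodes), seen)
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
  }
  length(seen) == length(nodes)
}

# Brute-force connected components by BFS from every node.
oracle_components <- function(nodes, edges) {
  comps <- list()
  remaining <- nodes
  while (length(remaining) > 0) {
    start <- remaining[1]
    seen <- start
    repeat {
      nxt <- unique(c(edges[edges[, 1] %in% seen, 2],
                      edges[edges[, 2] %in% seen, 1]))
      nxt <- setdiff(intersect(nxt, remaining), seen)
      if (length(nxt) == 0) break
      seen <- c(seen, nxt)
    }
    comps[[length(comps) + 1]] <- sort(seen)
    remaining <- setdiff(remaining, seen)
  }
  comps
}

# Direct arithmetic for the neighborhood statistic; xi is the node's own
# state, nb a vector of neighbor states.
oracle_mu <- function(xi, k, nb, w, mode = "discordance") {
  x1k_self <- if (k == 1) 1 - xi else xi      # X_i^{1-k}
  x1k_nb <- if (k == 1) 1 - nb else nb
  denom <- w + length(nb)
  if (denom == 0) return(0)
  if (mode == "discordance") {
    (w * x1k_self + sum(x1k_nb)) / denom
  } else {
    (w * (1 - x1k_self) + sum(1 - x1k_nb)) / denom
  }
}

oracle_p1 <- function(xi, nb, gamma0, gamma1, beta, w,
                      mode = "discordance") {
  e1 <- exp(gamma1 - beta * oracle_mu(xi, 1, nb, w, mode))
  e0 <- exp(gamma0 - beta * oracle_mu(xi, 0, nb, w, mode))
  e1 / (e0 + e1)
}

# Exact distribution over all 2^n state vectors after `n_sweeps`
# deterministic-scan sweeps of the single-site kernel, starting from a
# point mass on `init`. `adj` is a list of neighbor index vectors in the
# (sorted) node order the sampler uses.
oracle_sweep_distribution <- function(adj, init, gamma0, gamma1, beta, w,
                                      n_sweeps, mode = "discordance") {
  n <- length(adj)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  # row index of a state vector: binary with node 1 as the high bit
  idx_of <- function(x) sum(x * 2^((n - 1):0)) + 1
  dist <- numeric(2^n)
  dist[idx_of(init)] <- 1
  for (sweep in seq_len(n_sweeps)) {
    for (i in seq_len(n)) {
      new_dist <- numeric(2^n)
      for (s in seq_len(2^n)) {
        if (dist[s] == 0) next
        x <- states[s, ]
        p1 <- oracle_p1(x[i], x[adj[[i]]], gamma0, gamma1, beta, w, mode)
        x1 <- x; x1[i] <- 1
        x0 <- x; x0[i] <- 0
        new_dist[idx_of(x1)] <- new_dist[idx_of(x1)] + dist[s] * p1
        new_dist[idx_of(x0)] <- new_dist[idx_of(x0)] + dist[s] * (1 - p1)
      }
      dist <- new_dist
    }
  }
  list(states = states, prob = dist, index = idx_of)
}

# All nonempty node subsets of a small graph whose induced subgraph is
# connected, with their aggregate z-scores; returns the optimum.
oracle_best_connected_score <- function(net, z) {
  nms <- sort(igraph::V(net)$name)
  n <- length(nms)
  el <- igraph::as_edgelist(net, names = TRUE)
  best <- -Inf
  best_set <- NULL
  for (mask in 1:(2^n - 1)) {
    sel <- nms[bitwAnd(mask, 2^(0:(n - 1))) > 0]
    if (!oracle_connected(sel, el)) next
    s <- sum(z[sel]) / sqrt(length(sel))
    if (s > best) {
      best <- s
      best_set <- sel
    }
  }
  list(score = best, nodes = sort(best_set))
}

# Welch two-sample t from first principles.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}
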