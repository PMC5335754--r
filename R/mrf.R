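#' Parameters of the Markov random field state sampler
#'
#' The sampler assigns each gene a binary state (1 = differentially
#' expressed, DE; 0 = equally expressed, EE) by single-site Gibbs updates
#' on the PPI network. The conditional for gene i taking state k is
#' \deqn{p_i(k | \cdot) \propto \exp(\gamma_k - \beta \mu_i(1-k))}
#' where \eqn{\mu_i(1-k)} is a normalized count of disagreement with state
#' k in the gene's neighborhood, augmented by a self-retention weight w
#' that anchors each gene to its current state. Large w makes initial
#' states sticky (few false positives/negatives relative to the planted
#' subnetwork); large beta smooths states along network edges.
#'
#' @param gamma0 external field for state 0 (EE). Default 0.
#' @param gamma1 external field for state 1 (DE). Default 0.
#' @param beta nonnegative coupling strength. Default 1.
#' @param w nonnegative self-retention weight. Default 50.
#' @param n_sweeps number of full Gibbs sweeps over all nodes. Default 1.
#' @param mu_mode `"discordance"` (default): the neighborhood statistic
#'   counts disagreement with the candidate state, so large w retains the
#'   initialization. `"literal"`: the algebraically mirrored form in which
#'   the numerator counts agreement (provided for sensitivity analysis;
#'   under it large w flips states).
#' @param scan `"sorted"` (default; deterministic sweep over nodes in
#'   lexicographic order) or `"random"` (random permutation each sweep).
#' @param seed integer RNG seed.
#' @return object of class `mrf_params`.
#' @export
mrf_params <- function(gamma0 = 0, gamma1 = 0, beta = 1, w = 50,
                       n_sweeps = 1, mu_mode = c("discordance", "literal"),
                       scan = c("sorted", "random"), seed = 1) {
  mu_mode <- match.arg(mu_mode)
  scan <- match.arg(scan)
  if (!is.finite(gamma0) || !is.finite(gamma1) || !is.finite(beta)) {
    stop("MRF parameters must be finite")
  }
  stopifnot(beta >= 0, w >= 0, n_sweeps >= 1)
  structure(list(gamma0 = gamma0, gamma1 = gamma1, beta = beta, w = w,
                 n_sweeps = as.integer(n_sweeps), mu_mode = mu_mode,
                 scan = scan, seed = as.integer(seed)),
            class = "mrf_params")
}

# Core neighborhood statistic. xi: state of the node itself; s: number of
# neighbors in state 1; deg: number of neighbors. Returns mu_i(1-k).
mu_core <- function(xi, k, s, deg, w, mode) {
  denom <- w + deg
  if (denom == 0) return(0) # isolated node, w = 0: no information
  if (mode == "discordance") {
    # X^{1-k} in the numerator: counts disagreement with candidate state k
    if (k == 1) (w * (1 - xi) + (deg - s)) / denom
    else        (w * xi       + s)         / denom
  } else {
    # literal: numerator terms are (1 - X^{1-k}) = X^k (counts agreement)
    if (k == 1) (w * xi       + s)         / denom
    else        (w * (1 - xi) + (deg - s)) / denom
  }
}

# P(X_i = 1 | rest), numerically stable.
p1_core <- function(xi, s, deg, params) {
  e1 <- params$gamma1 - params$beta * mu_core(xi, 1, s, deg, params$w, params$mu_mode)
  e0 <- params$gamma0 - params$beta * mu_core(xi, 0, s, deg, params$w, params$mu_mode)
  m <- max(e0, e1)
  exp(e1 - m) / (exp(e0 - m) + exp(e1 - m))
}

#' Neighborhood discordance statistic \eqn{\mu_i(1-k)}
#'
#' Normalized, w-weighted count of the neighborhood's disagreement with
#' candidate state k for one gene. In `"discordance"` mode
#' \deqn{\mu_i(1-k) = \frac{w X_i^{1-k} + \sum_{j \in N_i} X_j^{1-k}}{w + |N_i|}}
#' with \eqn{X^1 = X}, \eqn{X^0 = 1 - X}. In `"literal"` mode each
#' \eqn{X^{1-k}} term in the numerator is replaced by its complement
#' \eqn{1 - X^{1-k} = X^k}; the denominator is unchanged since
#' \eqn{\sum_j (X_j^{1-k} + X_j^k) = |N_i|} identically.
#'
#' @param node gene identifier.
#' @param k candidate state (0 or 1).
#' @param X named binary state vector covering the network's nodes.
#' @param net `igraph` PPI network.
#' @param w nonnegative self-retention weight.
#' @param mode `"discordance"` or `"literal"`.
#' @return value in `[0, 1]`.
#' @export
mu_stat <- function(node, k, X, net, w = 50,
                    mode = c("discordance", "literal")) {
  mode <- match.arg(mode)
  stopifnot(k %in% c(0, 1), w >= 0)
  if (!node %in% igraph::V(net)$name) stop(sprintf("unknown node '%s'", node))
  nb <- igraph::V(net)$name[as.integer(
    igraph::neighbors(net, node))]
  mu_core(X[[node]], k, sum(X[nb]), length(nb), w, mode)
}

#' Conditional probability that a gene is differentially expressed
#'
#' \eqn{P(X_i = 1 | X_{-i}) = e^{\gamma_1 - \beta\mu_i(0)} /
#' (e^{\gamma_0 - \beta\mu_i(1)} + e^{\gamma_1 - \beta\mu_i(0)})},
#' computed with the largest exponent subtracted for stability.
#'
#' @inheritParams mu_stat
#' @param params an [mrf_params()] object.
#' @return probability in (0, 1).
#' @export
conditional_p1 <- function(node, X, net, params = mrf_params()) {
  if (!node %in% igraph::V(net)$name) stop(sprintf("unknown node '%s'", node))
  nb <- igraph::V(net)$name[as.integer(igraph::neighbors(net, node))]
  p1_core(X[[node]], sum(X[nb]), length(nb), params)
}

#' Sample gene DE/EE states by Gibbs sweeps on the network
#'
#' Initializes the planted subnetwork's genes to state 1 (DE) and all other
#' genes to 0 (EE), then performs `params$n_sweeps` full sweeps of
#' single-site Gibbs updates, each site drawn from [conditional_p1()]. The
#' self-retention term sees the gene's current state, so with very large w
#' the output equals the initialization exactly; moderate w introduces
#' false positives and false negatives around the planted truth.
#'
#' @param net `igraph` PPI network.
#' @param g0 a `ground_truth` object (or character vector of node names).
#' @param params an [mrf_params()] object.
#' @param quiet suppress per-sweep DE-count logging.
#' @return named integer vector of 0/1 states, one per network node,
#'   in sorted name order.
#' @export
gibbs_sample_states <- function(net, g0, params = mrf_params(),
                                quiet = FALSE) {
  g0_nodes <- if (inherits(g0, "ground_truth")) g0$nodes else as.character(g0)
  nms <- sort(igraph::V(net)$name)
  if (!all(g0_nodes %in% nms)) {
    stop("ground-truth nodes not all present in the network")
  }
  adj <- lapply(adjacency_list(net)[nms], function(v) match(v, nms))
  in_g0 <- nms %in% g0_nodes
  n <- length(nms)
  x <- with_seed(params$seed, {
    x <- as.integer(in_g0)
    for (sweep in seq_len(params$n_sweeps)) {
      ord <- if (params$scan == "random") sample.int(n) else seq_len(n)
      for (i in ord) {
        nb <- adj[[i]]
        p1 <- p1_core(x[i], sum(x[nb]), length(nb), params)
        x[i] <- as.integer(stats::runif(1) < p1)
      }
      if (!quiet) {
        message(sprintf(
          "sweep %d: %d DE genes (%d retained in G0, %d outside G0)",
          sweep, sum(x), sum(x[in_g0]), sum(x[!in_g0])))
      }
    }
    x
  })
  stats::setNames(x, nms)
}

#' Write / read a state vector as two-column TSV (gene, state)
#' @param x named binary state vector.
#' @param path file path.
#' @export
write_states <- function(x, path) {
  utils::write.table(
    data.frame(gene = names(x), state = as.integer(x)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_states
#' @export
read_states <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  stats::setNames(df$state, df$gene)
}
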