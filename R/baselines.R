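#' Search parameters for the reference subnetwork searchers
#'
#' @param max_depth hop radius for greedy candidate neighbors (1-3 by
#'   default validation; widen with `allow_deep = TRUE`).
#' @param seeds optional character vector of start nodes for the greedy
#'   search; by default the highest-z gene is used.
#' @param max_modules number of modules the greedy search returns
#'   (default 1; further modules restart from the best remaining seed
#'   after removing already-selected nodes).
#' @param t0 initial annealing temperature.
#' @param cooling geometric cooling factor per iteration, in (0, 1).
#' @param iterations number of annealing iterations.
#' @param rng_seed integer seed for the annealing RNG.
#' @param allow_deep allow `max_depth` outside 1-3.
#' @return object of class `search_params`.
#' @export
search_params <- function(max_depth = 1, seeds = NULL, max_modules = 1,
                          t0 = 1, cooling = 0.995, iterations = 2000,
                          rng_seed = 1, allow_deep = FALSE) {
  if (!allow_deep && !max_depth %in% 1:3) {
    stop("max_depth must be 1, 2 or 3 (set allow_deep = TRUE to widen)")
  }
  stopifnot(max_modules >= 1, t0 > 0, cooling > 0, cooling < 1,
            iterations >= 0)
  structure(list(max_depth = as.integer(max_depth), seeds = seeds,
                 max_modules = as.integer(max_modules), t0 = t0,
                 cooling = cooling, iterations = as.integer(iterations),
                 rng_seed = as.integer(rng_seed)),
            class = "search_params")
}

#' Aggregate z-score of a subnetwork
#'
#' \deqn{z_A = \frac{\sum_{i \in A} z_i}{\sqrt{|A|}}}
#' The classic aggregate score for an active module: the standardized sum
#' of member z-scores, which for independent standard-normal z is itself
#' standard normal for any module size. No background calibration is
#' applied (see the package vignette for this stated limitation).
#'
#' @param nodes nonempty character vector of member genes.
#' @param z named numeric vector of per-gene z-scores covering `nodes`.
#' @return the aggregate score.
#' @export
subnetwork_score <- function(nodes, z) {
  if (length(nodes) == 0) stop("cannot score an empty subnetwork")
  if (!all(nodes %in% names(z))) stop("z-scores missing for some nodes")
  sum(z[nodes]) / sqrt(length(nodes))
}

# Candidate expansions of `current` within `max_depth` hops: for each node
# v at distance 1..max_depth from the set, the expansion is v together
# with the interior of one shortest path from the set to v (ties broken
# lexicographically), so the result stays connected.
candidate_expansions <- function(net, current, max_depth, adj) {
  if (max_depth == 1L) {
    frontier <- sort(setdiff(unique(unlist(adj[current])), current))
    return(lapply(frontier, function(v) v))
  }
  # BFS out to max_depth hops recording one lexicographically-least parent
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  parent <- stats::setNames(rep(NA_character_, length(adj)), names(adj))
  dist[current] <- 0
  layer <- sort(current)
  d <- 0
  while (length(layer) > 0 && d < max_depth) {
    d <- d + 1
    nxt <- character(0)
    for (u in layer) { # layer is sorted, so parents are lexicographic
      for (v in adj[[u]]) {
        if (is.infinite(dist[[v]])) {
          dist[[v]] <- d
          parent[[v]] <- u
          nxt <- c(nxt, v)
        }
      }
    }
    layer <- sort(unique(nxt))
  }
  reached <- names(dist)[is.finite(dist) & dist > 0]
  lapply(sort(reached), function(v) {
    path <- v
    p <- parent[[v]]
    while (!p %in% current) {
      path <- c(path, p)
      p <- parent[[p]]
    }
    path
  })
}

#' Greedy subnetwork search by aggregate z-score
#'
#' Starts from the highest-z gene (or from each node in `params$seeds`,
#' keeping the best-scoring result) and repeatedly applies the expansion
#' within `max_depth` hops that maximally increases the aggregate z-score,
#' stopping when no expansion improves it. An expansion at depth d > 1
#' adds the target node together with a shortest connecting path, so the
#' returned node set is always connected. Deterministic: all ties are
#' broken by lexicographic node identifier.
#'
#' @param net `igraph` PPI network.
#' @param z named numeric vector of per-gene z-scores covering the network.
#' @param params a [search_params()] object.
#' @return a `subnetwork_result` with `method_name = "greedy"`; its
#'   `score` attribute holds the final aggregate z-score.
#' @export
greedy_search <- function(net, z, params = search_params()) {
  nms <- igraph::V(net)$name
  if (!all(nms %in% names(z))) stop("z-scores missing for some network genes")
  adj <- adjacency_list(net)
  run_from <- function(seed_node) {
    current <- seed_node
    total <- z[[seed_node]]
    score <- total
    frontier <- sort(setdiff(adj[[seed_node]], current))
    repeat {
      if (params$max_depth == 1L) {
        if (length(frontier) == 0) break
        # vectorized one-step gains over the frontier (kept sorted, so
        # which.max realizes the lexicographic tie-break)
        s_new <- (total + z[frontier]) / sqrt(length(current) + 1)
        best <- which.max(s_new)
        if (s_new[best] <= score + 1e-12) break
        v <- frontier[best]
        current <- c(current, v)
        total <- total + z[[v]]
        score <- s_new[[best]]
        frontier <- sort(union(setdiff(frontier, v),
                               setdiff(adj[[v]], current)))
      } else {
        cands <- candidate_expansions(net, current, params$max_depth, adj)
        if (length(cands) == 0) break
        gains <- vapply(cands, function(ext) {
          (total + sum(z[ext])) / sqrt(length(current) + length(ext))
        }, numeric(1))
        best <- which.max(gains)
        if (gains[best] <= score + 1e-12) break
        ext <- cands[[best]]
        current <- c(current, ext)
        total <- total + sum(z[ext])
        score <- gains[[best]]
      }
    }
    list(nodes = current, score = score)
  }
  seeds <- params$seeds
  if (is.null(seeds)) {
    zn <- z[nms]
    seeds <- sort(nms[zn == max(zn)])[1]
  }
  modules <- list()
  remaining <- net
  for (mod in seq_len(params$max_modules)) {
    rem_nms <- igraph::V(remaining)$name
    use_seeds <- intersect(seeds, rem_nms)
    if (mod > 1 || length(use_seeds) == 0) {
      if (length(rem_nms) == 0) break
      zr <- z[rem_nms]
      use_seeds <- sort(rem_nms[zr == max(zr)])[1]
    }
    runs <- lapply(sort(use_seeds), run_from)
    scores <- vapply(runs, `[[`, numeric(1), "score")
    best <- runs[[which.max(scores)]]
    modules[[mod]] <- best
    remaining <- igraph::delete_vertices(remaining, intersect(best$nodes, igraph::V(remaining)$name))
    adj <- adjacency_list(remaining)
    net <- remaining
  }
  nodes <- unlist(lapply(modules, `[[`, "nodes"))
  res <- subnetwork_result("greedy", nodes)
  attr(res, "score") <- modules[[1]]$score
  res
}

# Largest connected component of the induced subgraph on the included
# nodes; size ties broken by smallest member name. Returns sorted member
# names, or character(0) when nothing is included.
best_component <- function(net, inc) {
  if (length(inc) == 0) return(character(0))
  sub <- igraph::induced_subgraph(net, inc)
  comp <- igraph::components(sub)
  big <- which(comp$csize == max(comp$csize))
  snms <- igraph::V(sub)$name
  if (length(big) > 1) {
    mins <- vapply(big, function(ci) min(snms[comp$membership == ci]),
                   character(1))
    big <- big[order(mins)][1]
  }
  sort(snms[comp$membership == big])
}

#' Simulated-annealing subnetwork search
#'
#' Maintains a binary inclusion state per node (initialized by fair coin
#' flips). Each iteration toggles a uniformly random node; the move is
#' accepted if the aggregate z-score of the largest included connected
#' component improves, and otherwise with probability exp(delta / T).
#' The temperature follows a geometric schedule T <- cooling * T. The
#' best-seen component (by score) is tracked and returned, so the result
#' never degrades with more iterations.
#'
#' @inheritParams greedy_search
#' @return a `subnetwork_result` with `method_name = "annealing"`; its
#'   `score` attribute holds the best-seen aggregate z-score.
#' @export
simulated_annealing_search <- function(net, z, params = search_params()) {
  nms <- sort(igraph::V(net)$name)
  if (!all(nms %in% names(z))) stop("z-scores missing for some network genes")
  n <- length(nms)
  with_seed(params$rng_seed, {
    included <- stats::runif(n) < 0.5
    comp <- best_component(net, nms[included])
    score <- if (length(comp) == 0) -Inf else subnetwork_score(comp, z)
    best_nodes <- comp
    best_score <- score
    temp <- params$t0
    for (it in seq_len(params$iterations)) {
      i <- sample.int(n, 1)
      included[i] <- !included[i]
      new_comp <- best_component(net, nms[included])
      new_score <- if (length(new_comp) == 0) -Inf
                   else subnetwork_score(new_comp, z)
      delta <- new_score - score
      if (is.nan(delta)) delta <- 0 # both components empty
      if (delta > 0 || stats::runif(1) < exp(delta / temp)) {
        score <- new_score
        if (new_score > best_score) {
          best_score <- new_score
          best_nodes <- new_comp
        }
      } else {
        included[i] <- !included[i] # reject: revert
      }
      temp <- temp * params$cooling
    }
    if (length(best_nodes) == 0) {
      # degenerate start with nothing included and zero iterations:
      # fall back to the single best gene
      best_nodes <- sort(nms[z[nms] == max(z[nms])])[1]
      best_score <- subnetwork_score(best_nodes, z)
    }
    res <- subnetwork_result("annealing", best_nodes)
    attr(res, "score") <- best_score
    res
  })
}

#' Write a subnetwork result: node list + induced-edge TSV
#'
#' `<path>` gets one node per line; `<path>.edges.tsv` gets the induced
#' edges (two tab-separated columns) when the result carries them.
#'
#' @param result a `subnetwork_result`.
#' @param path output file path.
#' @export
write_subnetwork <- function(result, path) {
  writeLines(result$nodes, path)
  if (!is.null(result$edges) && nrow(result$edges) > 0) {
    utils::write.table(result$edges, paste0(path, ".edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = c("from", "to"))
  }
  invisible(path)
}
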