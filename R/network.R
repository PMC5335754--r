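#' Read a PPI network from an edge list or SIF stream
#'
#' Parses a tab- or whitespace-delimited two-column edge list (gene symbol
#' pairs, HPRD-style) or a SIF file (`node relation node [node ...]`) into a
#' simple undirected \pkg{igraph} graph. Lines starting with `#` are
#' comments. Duplicate edges (in either orientation) collapse to one edge;
#' self-interactions are dropped by default, mirroring the usual cleaning of
#' interaction databases before network analysis.
#'
#' Node identifiers are opaque, case-sensitive strings; no symbol
#' normalization is attempted.
#'
#' @param source path to a file, or a character vector of lines.
#' @param format `"edgelist"` (two columns; extra columns ignored) or
#'   `"sif"` (column 2 is a relation type; columns 3+ are partner nodes).
#' @param drop_self_loops drop edges whose endpoints are identical
#'   (default `TRUE`).
#' @param quiet suppress the node/edge count message.
#' @return an undirected simple `igraph` graph with a `name` vertex
#'   attribute.
#' @examples
#' g <- load_ppi(c("A\tB", "B\tA", "A\tA", "B\tC"), quiet = TRUE)
#' igraph::vcount(g) # 3
#' @export
load_ppi <- function(source, format = c("edgelist", "sif"),
                     drop_self_loops = TRUE, quiet = FALSE) {
  format <- match.arg(format)
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) {
    stop("empty network input: no edge lines found")
  }
  from <- character(0)
  to <- character(0)
  for (ln in keep) {
    tok <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (format == "edgelist") {
      if (length(tok) < 2L) {
        stop(sprintf("malformed edge line %d: fewer than 2 tokens", ln))
      }
      from <- c(from, tok[1])
      to <- c(to, tok[2])
    } else {
      if (length(tok) == 1L) next # isolated node entry; no edge
      if (length(tok) < 3L) {
        stop(sprintf("malformed SIF line %d: need node, relation, node", ln))
      }
      from <- c(from, rep(tok[1], length(tok) - 2L))
      to <- c(to, tok[-(1:2)])
    }
  }
  if (length(from) == 0L) stop("empty network input: no edges parsed")
  if (drop_self_loops) {
    ok <- from != to
    from <- from[ok]
    to <- to[ok]
  }
  if (length(from) == 0L) stop("network input contains only self-loops")
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE,
                        remove.loops = drop_self_loops)
  if (!quiet) {
    message(sprintf("loaded PPI network: %d nodes, %d edges",
                    igraph::vcount(g), igraph::ecount(g)))
  }
  g
}

#' Write a network as a two-column edge list
#'
#' Endpoints within each edge, and edges overall, are written in sorted
#' order so that the output is canonical: load -> write -> load round-trips
#' to an identical edge set.
#'
#' @param net an `igraph` graph.
#' @param path output file path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) > 0) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, 2:1]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' @param path file path; blank lines and `#` comments are skipped.
#' @return character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest component; ties between
#' equally-sized components are broken by the lexicographically smallest
#' member node, so the result is deterministic.
#'
#' @param net an `igraph` graph.
#' @return the induced `igraph` subgraph.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component containing the smallest node name
    min_name <- vapply(best, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(min_name)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Sample a planted ground-truth subnetwork
#'
#' Selects `m` genes to serve as the planted differential subnetwork G0.
#' In `"connected"` mode (default) the set is grown by seeded random-walk
#' expansion: starting from a uniformly chosen node of the largest
#' connected component, at each step a uniformly random node adjacent to
#' the current set is added, so the induced subgraph is always connected.
#' `"uniform"` mode draws `m` nodes uniformly without the connectivity
#' constraint, for sensitivity analysis.
#'
#' @param net an `igraph` PPI network.
#' @param m number of ground-truth genes (default 274).
#' @param seed integer RNG seed; the same seed yields the same subset.
#' @param mode `"connected"` (default) or `"uniform"`.
#' @return object of class `ground_truth`: list with `nodes` (character
#'   vector, sorted), `m`, `seed`, `mode`.
#' @export
sample_ground_truth <- function(net, m = 274, seed = 1,
                                mode = c("connected", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(m >= 1)
  if (mode == "uniform") {
    if (m > igraph::vcount(net)) {
      stop(sprintf("m = %d exceeds network size %d", m, igraph::vcount(net)))
    }
    nodes <- with_seed(seed, sample(igraph::V(net)$name, m))
  } else {
    lcc <- largest_connected_component(net)
    if (m > igraph::vcount(lcc)) {
      stop(sprintf("m = %d exceeds largest component size %d",
                   m, igraph::vcount(lcc)))
    }
    adj <- adjacency_list(lcc)
    nodes <- with_seed(seed, {
      all_nodes <- sort(names(adj))
      current <- sample(all_nodes, 1)
      in_set <- stats::setNames(logical(length(all_nodes)), all_nodes)
      in_set[current] <- TRUE
      frontier <- setdiff(adj[[current]], current)
      while (sum(in_set) < m) {
        nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1)
        in_set[nxt] <- TRUE
        frontier <- union(frontier, adj[[nxt]])
        frontier <- frontier[!in_set[frontier]]
      }
      names(in_set)[in_set]
    })
  }
  structure(list(nodes = sort(nodes), m = m, seed = seed, mode = mode),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth subnetwork: %d genes (mode = %s, seed = %d)\n",
              length(x$nodes), x$mode, x$seed))
  invisible(x)
}

# Named list: node name -> character vector of neighbor names.
adjacency_list <- function(net) {
  nms <- igraph::V(net)$name
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  out <- lapply(adj, function(v) nms[as.integer(v)])
  names(out) <- nms
  out
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
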