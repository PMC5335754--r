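#' Confusion counts for a recovered gene set against ground truth
#'
#' @param recovered character vector of recovered gene identifiers.
#' @param ground character vector of ground-truth gene identifiers.
#' @return named integer vector `c(tp, fp, fn)`: tp = correctly recovered,
#'   fp = recovered but not planted, fn = planted but missed.
#' @export
confusion_counts <- function(recovered, ground) {
  recovered <- unique(as.character(recovered))
  ground <- unique(as.character(ground))
  tp <- length(intersect(recovered, ground))
  c(tp = tp, fp = length(recovered) - tp, fn = length(ground) - tp)
}

#' Precision and recall from confusion counts
#'
#' precision = tp/(tp+fp), recall = tp/(tp+fn). An empty recovered set
#' (tp + fp = 0) yields precision 0 with a warning rather than NaN, so
#' comparison tables always tabulate.
#'
#' @param tp,fp,fn nonnegative counts.
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0) {
    warning("empty recovered set: precision defined as 0")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = precision, recall = recall)
}

#' F-measure (harmonic mean of precision and recall)
#'
#' \eqn{F_1 = 2PR/(P+R)}; returns 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return value in `[0, 1]`.
#' @export
f_measure <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Fold enrichment of a selection against a reference gene list
#'
#' \deqn{\mathrm{FE} = \frac{recovered \cdot n_{network}}
#'   {n_{reference} \cdot selected}}
#' the ratio of the reference-gene fraction inside the selected subnetwork
#' to the reference-gene fraction in the whole network.
#'
#' @param recovered_in_ref number of selected genes found in the reference
#'   list.
#' @param selected number of genes selected by the method (> 0).
#' @param n_network number of genes in the whole network.
#' @param n_reference number of reference genes present in the network
#'   (> 0).
#' @return nonnegative real.
#' @examples
#' fold_enrichment(46, 246, 5335, 400) # 2.494
#' @export
fold_enrichment <- function(recovered_in_ref, selected, n_network,
                            n_reference) {
  if (selected <= 0) stop("fold enrichment undefined for an empty selection")
  if (n_reference <= 0) stop("n_reference must be positive")
  recovered_in_ref * n_network / (n_reference * selected)
}

#' Build a subnetwork result object
#'
#' @param method_name label for the method that produced the selection.
#' @param nodes character vector of selected gene identifiers.
#' @param net optional `igraph` network; when given, the induced edges
#'   within the selection are recorded and nodes absent from the network
#'   are rejected.
#' @return object of class `subnetwork_result` with fields `method_name`,
#'   `nodes` (sorted, unique), and `edges` (two-column matrix or NULL).
#' @export
subnetwork_result <- function(method_name, nodes, net = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- NULL
  if (!is.null(net)) {
    missing <- setdiff(nodes, igraph::V(net)$name)
    if (length(missing) > 0) {
      stop(sprintf("%d selected node(s) not in the network (e.g. '%s')",
                   length(missing), missing[1]))
    }
    sub <- igraph::induced_subgraph(net, nodes)
    edges <- igraph::as_edgelist(sub, names = TRUE)
  }
  structure(list(method_name = method_name, nodes = nodes, edges = edges),
            class = "subnetwork_result")
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat(sprintf("subnetwork [%s]: %d nodes, %s edges\n", x$method_name,
              length(x$nodes),
              if (is.null(x$edges)) "?" else nrow(x$edges)))
  invisible(x)
}

#' Score one recovered subnetwork against ground truth and/or a reference
#'
#' Computes confusion counts, precision, recall and F-measure against the
#' planted ground truth (when `ground` is given), and fold enrichment
#' against a reference gene list (when `reference` is given). Metrics are
#' computed on nodes only; induced edges are reported but never scored.
#'
#' @param result a `subnetwork_result`, or a character vector of nodes.
#' @param ground ground-truth genes (`ground_truth` object or character
#'   vector), or NULL.
#' @param reference reference gene list (character vector), or NULL.
#' @param n_network number of genes in the network universe (required for
#'   fold enrichment).
#' @return one-row data frame (class `eval_report`) with columns: method,
#'   selected, edges, tp, fp, fn, precision, recall, f_measure,
#'   recovered_in_reference, n_network, n_reference, fold_enrichment.
#'   Fields whose inputs were not supplied are NA.
#' @export
evaluate <- function(result, ground = NULL, reference = NULL,
                     n_network = NA_integer_) {
  if (!inherits(result, "subnetwork_result")) {
    result <- subnetwork_result("unnamed", result)
  }
  sel <- result$nodes
  row <- data.frame(
    method = result$method_name,
    selected = length(sel),
    edges = if (is.null(result$edges)) NA_integer_ else nrow(result$edges),
    tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
    precision = NA_real_, recall = NA_real_, f_measure = NA_real_,
    recovered_in_reference = NA_integer_,
    n_network = as.integer(n_network),
    n_reference = NA_integer_, fold_enrichment = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(ground)) {
    gnodes <- if (inherits(ground, "ground_truth")) ground$nodes
              else as.character(ground)
    cc <- confusion_counts(sel, gnodes)
    pr <- if (cc["tp"] + cc["fp"] == 0) {
      warning(sprintf("method '%s': empty selection, precision set to 0",
                      result$method_name))
      c(precision = 0, recall = 0)
    } else {
      precision_recall(cc[["tp"]], cc[["fp"]], cc[["fn"]])
    }
    row$tp <- cc[["tp"]]; row$fp <- cc[["fp"]]; row$fn <- cc[["fn"]]
    row$precision <- pr[["precision"]]
    row$recall <- pr[["recall"]]
    row$f_measure <- f_measure(pr[["precision"]], pr[["recall"]])
  }
  if (!is.null(reference)) {
    reference <- unique(as.character(reference))
    row$n_reference <- length(reference)
    row$recovered_in_reference <- length(intersect(sel, reference))
    row$fold_enrichment <- if (length(sel) == 0 || is.na(n_network)) {
      NA_real_
    } else {
      fold_enrichment(row$recovered_in_reference, length(sel),
                      n_network, length(reference))
    }
  }
  class(row) <- c("eval_report", class(row))
  row
}

#' Write an evaluation table as TSV
#'
#' One row per method, columns as in [evaluate()]. Real-valued metrics are
#' rounded half-even to 3 decimals for display; pass `digits = NA` to keep
#' full precision.
#'
#' @param report data frame of stacked [evaluate()] rows.
#' @param path output file path.
#' @param digits decimals for real-valued columns (default 3; NA = none).
#' @export
write_eval_table <- function(report, path, digits = 3) {
  out <- as.data.frame(report)
  if (!is.na(digits)) {
    for (col in c("precision", "recall", "f_measure", "fold_enrichment")) {
      if (col %in% names(out)) out[[col]] <- round(out[[col]], digits)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score external result files against ground truth / reference
#'
#' Reads each node-list file (one gene per line) and evaluates it,
#' producing one table row per file. Genes not present in the network are
#' excluded with a warning so partial overlaps still score.
#'
#' @param result_files named character vector of paths; names become
#'   method labels (file basenames when unnamed).
#' @param net `igraph` network defining the gene universe.
#' @param ground,reference as in [evaluate()].
#' @return stacked `eval_report` data frame.
#' @export
evaluate_external <- function(result_files, net, ground = NULL,
                              reference = NULL) {
  labels <- names(result_files)
  if (is.null(labels)) labels <- basename(result_files)
  universe <- igraph::V(net)$name
  rows <- lapply(seq_along(result_files), function(i) {
    genes <- read_gene_list(result_files[[i]])
    unknown <- setdiff(genes, universe)
    if (length(unknown) > 0) {
      warning(sprintf("%s: %d gene(s) not in the network excluded",
                      labels[i], length(unknown)))
      genes <- intersect(genes, universe)
    }
    res <- subnetwork_result(labels[i], genes, net)
    evaluate(res, ground = ground, reference = reference,
             n_network = igraph::vcount(net))
  })
  do.call(rbind, rows)
}
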