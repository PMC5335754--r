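#' Parameters of the Gamma-Gamma expression model
#'
#' Hierarchical model for nonnegative expression values: a latent per-gene
#' scale \eqn{\beta_g \sim \mathrm{Gamma}(\alpha_0, \nu)} (shape
#' \eqn{\alpha_0}, scale \eqn{\nu}), then observed expression
#' \eqn{y \sim \mathrm{Gamma}(\alpha, \beta_g)} with mean
#' \eqn{\mu_g = \alpha \beta_g}. Equally-expressed (EE) genes share one
#' latent scale across both phenotypes; differentially-expressed (DE)
#' genes draw independent scales for case and control, so their group
#' means differ whenever the two draws do.
#'
#' Defaults follow the standard Gamma-Gamma calibration for two-channel
#' microarray intensity data: alpha = 10, alpha0 = 0.9, nu = 0.5, giving a
#' marginal mean of alpha * alpha0 * nu = 4.5.
#'
#' @param alpha observation shape (> 0). Default 10.
#' @param alpha0 scale-prior shape (> 0). Default 0.9.
#' @param nu scale-prior scale (> 0) under the default shape/scale reading;
#'   set `nu_is_rate = TRUE` to interpret it as a rate instead.
#' @param n_case,n_control samples per phenotype. Defaults 50 and 50.
#' @param nu_is_rate interpret `nu` as a Gamma rate rather than a scale.
#' @param seed integer RNG seed.
#' @return object of class `gg_params`.
#' @export
gg_params <- function(alpha = 10, alpha0 = 0.9, nu = 0.5,
                      n_case = 50, n_control = 50,
                      nu_is_rate = FALSE, seed = 1) {
  stopifnot(alpha > 0, alpha0 > 0, nu > 0, n_case >= 1, n_control >= 1)
  structure(list(alpha = alpha, alpha0 = alpha0, nu = nu,
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 nu_is_rate = isTRUE(nu_is_rate), seed = as.integer(seed)),
            class = "gg_params")
}

#' Gamma-Gamma observation density
#'
#' \deqn{p(y | \alpha, \beta_g) = \frac{y^{\alpha-1} e^{-y/\beta_g}}
#'   {\beta_g^\alpha \Gamma(\alpha)}}
#' i.e. the Gamma density with shape `alpha` and scale `beta_g`, with
#' mean \eqn{\alpha \beta_g}.
#'
#' @param y positive expression value(s).
#' @param alpha shape (> 0).
#' @param beta_g scale (> 0).
#' @return density value(s).
#' @export
gg_density <- function(y, alpha = 10, beta_g = 1) {
  if (any(y <= 0)) stop("expression value y must be > 0")
  stats::dgamma(y, shape = alpha, scale = beta_g)
}

#' Generate a case/control expression matrix from gene states
#'
#' For each EE gene (state 0) one latent scale is drawn and shared by both
#' phenotypes; for each DE gene (state 1) case and control get independent
#' latent scales from the same prior, so differential expression arises
#' from the difference between the two draws.
#'
#' @param net_genes ordered character vector of gene identifiers.
#' @param X named binary state vector covering `net_genes`.
#' @param params a [gg_params()] object.
#' @return object of class `gg_expression`: list with `values` (genes x
#'   samples matrix, rownames = genes), `labels` (per-column `"case"` /
#'   `"control"`), and `scales` (per-gene data frame of the latent scales
#'   actually drawn, for diagnostics).
#' @export
generate_expression <- function(net_genes, X, params = gg_params()) {
  net_genes <- as.character(net_genes)
  if (!all(net_genes %in% names(X))) {
    stop("state vector is missing genes present in the network")
  }
  x <- X[net_genes]
  nG <- length(net_genes)
  nc <- params$n_case
  nn <- params$n_control
  prior_scale <- if (params$nu_is_rate) 1 / params$nu else params$nu
  with_seed(params$seed, {
    vals <- matrix(0, nrow = nG, ncol = nc + nn,
                   dimnames = list(net_genes,
                                   c(paste0("case_", seq_len(nc)),
                                     paste0("control_", seq_len(nn)))))
    b_case <- b_ctrl <- numeric(nG)
    for (g in seq_len(nG)) {
      if (x[g] == 1) {
        b_case[g] <- stats::rgamma(1, shape = params$alpha0, scale = prior_scale)
        b_ctrl[g] <- stats::rgamma(1, shape = params$alpha0, scale = prior_scale)
      } else {
        b_case[g] <- b_ctrl[g] <-
          stats::rgamma(1, shape = params$alpha0, scale = prior_scale)
      }
      vals[g, seq_len(nc)] <-
        stats::rgamma(nc, shape = params$alpha, scale = b_case[g])
      vals[g, nc + seq_len(nn)] <-
        stats::rgamma(nn, shape = params$alpha, scale = b_ctrl[g])
    }
    structure(list(
      values = vals,
      labels = c(rep("case", nc), rep("control", nn)),
      scales = data.frame(gene = net_genes, state = as.integer(x),
                          beta_case = b_case, beta_control = b_ctrl)),
      class = "gg_expression")
  })
}

#' @export
print.gg_expression <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Per-gene differential-expression test
#'
#' Welch two-sample t-test of case vs control per gene (default), or the
#' pooled-variance t-test or Wilcoxon rank-sum test. Reports the two-sided
#' p-value, the test statistic, and a signed z-score
#' \eqn{z = \Phi^{-1}(1 - p/2) \cdot \mathrm{sign}(t)} used by the
#' searchers; p-values are clamped to at least 1e-300 before the quantile
#' transformation. A gene with zero variance in both groups (no evidence
#' either way) is assigned p = 1, z = 0 with a warning.
#'
#' @param expr a `gg_expression` object.
#' @param method `"welch"` (default), `"pooled"`, or `"wilcoxon"`.
#' @return data frame with columns `gene`, `statistic`, `p_value`, `z`.
#' @export
differential_test <- function(expr, method = c("welch", "pooled", "wilcoxon")) {
  method <- match.arg(method)
  case <- expr$values[, expr$labels == "case", drop = FALSE]
  ctrl <- expr$values[, expr$labels == "control", drop = FALSE]
  if (ncol(case) < 2 || ncol(ctrl) < 2) {
    stop("each phenotype group needs at least 2 samples")
  }
  nG <- nrow(expr$values)
  stat <- p <- numeric(nG)
  degenerate <- 0L
  for (g in seq_len(nG)) {
    a <- case[g, ]
    b <- ctrl[g, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      stat[g] <- 0
      p[g] <- 1
      degenerate <- degenerate + 1L
      next
    }
    res <- switch(method,
      welch = stats::t.test(a, b, var.equal = FALSE),
      pooled = stats::t.test(a, b, var.equal = TRUE),
      wilcoxon = stats::wilcox.test(a, b, exact = FALSE))
    stat[g] <- unname(res$statistic)
    p[g] <- res$p.value
  }
  if (degenerate > 0) {
    warning(sprintf("%d gene(s) had zero variance in both groups; p set to 1",
                    degenerate))
  }
  p_clamped <- pmax(p, 1e-300)
  sgn <- ifelse(stat > 0, 1, ifelse(stat < 0, -1, 0))
  # Wilcoxon's W is not signed around 0; center it for the z sign
  if (method == "wilcoxon") {
    w0 <- ncol(case) * ncol(ctrl) / 2
    sgn <- ifelse(stat > w0, 1, ifelse(stat < w0, -1, 0))
  }
  # upper-tail form stays finite for tiny p (1 - p/2 would round to 1)
  z <- stats::qnorm(p_clamped / 2, lower.tail = FALSE) * sgn
  data.frame(gene = rownames(expr$values), statistic = stat,
             p_value = p, z = z, row.names = NULL)
}

#' Write / read an expression matrix as TSV plus a sidecar label file
#'
#' `<path>` holds the genes x samples matrix with a header row of sample
#' IDs; `<path>.labels.tsv` holds two columns (sample, phenotype).
#'
#' @param expr a `gg_expression` object.
#' @param path output file path.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(
    data.frame(sample = colnames(expr$values), phenotype = expr$labels),
    paste0(path, ".labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  vals <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                      row.names = 1, check.names = FALSE))
  lab <- utils::read.table(paste0(path, ".labels.tsv"), header = TRUE,
                           sep = "\t", colClasses = "character")
  structure(list(values = vals,
                 labels = lab$phenotype[match(colnames(vals), lab$sample)],
                 scales = NULL),
            class = "gg_expression")
}
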