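#' Fit the regression model of one interaction
#'
#' For an interaction (X, Y) — X the lexicographically smaller gene, used as
#' regressor by convention — fits `Y = beta0 + beta1 * X` by ordinary least
#' squares over control samples, then summarizes the perpendicular
#' (orthogonal) distances of the controls from the fitted line,
#' `d_i = |beta1 x_i - y_i + beta0| / sqrt(beta1^2 + 1)`, by their median and
#' median absolute deviation.
#'
#' @param expr Numeric genes x samples control matrix.
#' @param edge Character vector of two gene ids.
#' @return An object of class `"edge_model"`: list with `gene_a`, `gene_b`,
#'   `beta0`, `beta1`, `d_median`, `d_mad`.
#' @export
fit_edge_model <- function(expr, edge) {
  stopifnot(length(edge) == 2L, all(edge %in% rownames(expr)),
            ncol(expr) >= 3L)
  edge <- sort(edge)
  x <- expr[edge[1L], ]
  y <- expr[edge[2L], ]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate edge: regressor gene has zero variance")
  beta1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  beta0 <- mean(y) - beta1 * mean(x)
  d <- perp_distance(beta0, beta1, x, y)
  dm <- median(d)
  structure(list(gene_a = edge[1L], gene_b = edge[2L],
                 beta0 = beta0, beta1 = beta1,
                 d_median = dm, d_mad = median(abs(d - dm))),
            class = "edge_model")
}

# perpendicular distance of points (x, y) from the line y = beta0 + beta1 x
perp_distance <- function(beta0, beta1, x, y) {
  abs(beta1 * x - y + beta0) / sqrt(beta1^2 + 1)
}

#' Fit regression models for every network interaction
#'
#' Vectorized OLS fit (plus distance median/MAD over controls) for each edge
#' of the reference network. Edges whose regressor has zero variance are
#' degenerate: they are removed from the returned network copy so that the
#' reference and any individualized network share one edge universe. More
#' than 10% degenerate edges aborts, as that signals malformed input.
#'
#' @param expr Numeric genes x samples control matrix.
#' @param network A [tissue_network].
#' @return List with `models` (an `edge_models` data frame: gene_a, gene_b,
#'   weight, beta0, beta1, d_median, d_mad) and `network` (the possibly
#'   pruned [tissue_network]).
#' @export
fit_all_edges <- function(expr, network) {
  stopifnot(all(network$nodes %in% rownames(expr)))
  ed <- network$edges
  if (nrow(ed) == 0L) {
    m <- data.frame(gene_a = character(), gene_b = character(),
                    weight = numeric(), beta0 = numeric(), beta1 = numeric(),
                    d_median = numeric(), d_mad = numeric())
    class(m) <- c("edge_models", "data.frame")
    return(list(models = m, network = network))
  }
  X <- expr[ed$gene_a, , drop = FALSE]
  Y <- expr[ed$gene_b, , drop = FALSE]
  mx <- rowMeans(X); my <- rowMeans(Y)
  cx <- X - mx; cy <- Y - my
  sxx <- rowSums(cx^2)
  degenerate <- sxx == 0
  if (mean(degenerate) > 0.1)
    stop("more than 10% of edges are degenerate (zero-variance regressor)")
  if (any(degenerate)) {
    message(sum(degenerate), " degenerate edge(s) removed from the network")
    ed <- ed[!degenerate, , drop = FALSE]
    X <- X[!degenerate, , drop = FALSE]; Y <- Y[!degenerate, , drop = FALSE]
    cx <- cx[!degenerate, , drop = FALSE]; cy <- cy[!degenerate, , drop = FALSE]
    mx <- mx[!degenerate]; my <- my[!degenerate]; sxx <- sxx[!degenerate]
    network <- tissue_network(ed, network$community_of,
                              soft_power = network$soft_power)
  }
  beta1 <- rowSums(cx * cy) / sxx
  beta0 <- my - beta1 * mx
  D <- abs(beta1 * X - Y + beta0) / sqrt(beta1^2 + 1)
  d_median <- apply(D, 1L, median)
  d_mad <- apply(abs(D - d_median), 1L, median)
  m <- data.frame(gene_a = ed$gene_a, gene_b = ed$gene_b, weight = ed$weight,
                  beta0 = beta0, beta1 = beta1,
                  d_median = d_median, d_mad = d_mad,
                  stringsAsFactors = FALSE, row.names = NULL)
  class(m) <- c("edge_models", "data.frame")
  list(models = m, network = network)
}

#' Write / read an edge-model table
#'
#' Persists the per-interaction regression parameters and control-distance
#' summaries so that case samples can be scored without refitting.
#'
#' @param models An `edge_models` data frame from [fit_all_edges()].
#' @param path TSV file path.
#' @export
write_edge_models <- function(models, path) {
  write.table(models, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_models
#' @export
read_edge_models <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  class(m) <- c("edge_models", "data.frame")
  m
}
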