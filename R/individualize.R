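#' Perpendicular distance of a case sample from an interaction model
#'
#' `d_j = |beta1 x_j - y_j + beta0| / sqrt(beta1^2 + 1)`: the orthogonal
#' distance of the case expression point from the control-fitted line.
#'
#' @param model An `edge_model` (or anything with `beta0`, `beta1`).
#' @param x_case,y_case Case expression of the regressor / response gene.
#' @return Non-negative distance.
#' @export
case_distance <- function(model, x_case, y_case) {
  perp_distance(model$beta0, model$beta1, x_case, y_case)
}

#' Modified z-score of a case distance
#'
#' Robust standardization of the case distance against the control distance
#' distribution: `z = (d - median) / (1.486 * MAD)`. With `d_mad = 0` the
#' scale is degenerate: z is `Inf` if the case distance exceeds the median,
#' else 0 (logged).
#'
#' @param model An `edge_model` with `d_median`, `d_mad`.
#' @param d_case Case distance from [case_distance()].
#' @param mad_constant Scale constant (default 1.486; 1.4826 available for
#'   the exact normal-consistency value).
#' @return Modified z-score.
#' @export
modified_zscore <- function(model, d_case, mad_constant = 1.486) {
  if (model$d_mad == 0) {
    message("degenerate-scale edge (MAD = 0)")
    return(ifelse(d_case > model$d_median, Inf, 0))
  }
  (d_case - model$d_median) / (mad_constant * model$d_mad)
}

#' Flag individualized perturbed interactions of one case sample
#'
#' For every modelled interaction, the case perpendicular distance is
#' standardized by the modified z-score and converted to a one-tailed
#' (upper-tail, standard normal) p-value; interactions with `p < alpha`
#' (default 0.001, i.e. z > 3.0902) are the sample's individualized
#' perturbed interactions. Only unusually large distances are flagged.
#'
#' @param models `edge_models` data frame from [fit_all_edges()].
#' @param case_expr Named numeric vector of case expression (or a 1-column
#'   matrix with gene row names).
#' @param alpha Per-interaction significance level in `(0, 1)`.
#' @param sample_id Identifier stored on the result.
#' @param mad_constant See [modified_zscore()].
#' @return A `perturbation_set`: list with `sample_id`, `alpha`, `n_edges`
#'   (edges evaluated), `skipped` (edges dropped for missing case values)
#'   and `flagged` — a data frame (gene_a, gene_b, d_case, mod_z, p_value).
#' @export
flag_perturbed <- function(models, case_expr, alpha = 0.001,
                           sample_id = "case", mad_constant = 1.486) {
  stopifnot(alpha > 0, alpha <= 1)
  if (is.matrix(case_expr)) case_expr <- setNames(case_expr[, 1L], rownames(case_expr))
  x <- case_expr[models$gene_a]
  y <- case_expr[models$gene_b]
  have <- !is.na(x) & !is.na(y)
  if (!all(have))
    message(sum(!have), " edge(s) skipped: missing case expression")
  d <- perp_distance(models$beta0, models$beta1, x, y)
  z <- ifelse(models$d_mad > 0,
              (d - models$d_median) / (mad_constant * models$d_mad),
              ifelse(d > models$d_median, Inf, 0))
  if (any(models$d_mad == 0)) message(sum(models$d_mad == 0),
                                      " degenerate-scale edge(s) (MAD = 0)")
  p <- pnorm(z, lower.tail = FALSE)
  hit <- have & p < alpha
  structure(list(sample_id = sample_id, alpha = alpha,
                 n_edges = sum(have), skipped = sum(!have),
                 flagged = data.frame(gene_a = models$gene_a[hit],
                                      gene_b = models$gene_b[hit],
                                      d_case = unname(d[hit]),
                                      mod_z = unname(z[hit]),
                                      p_value = unname(p[hit]),
                                      stringsAsFactors = FALSE)),
            class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  cat("Perturbation set for sample", x$sample_id, "\n")
  cat("  ", nrow(x$flagged), "of", x$n_edges,
      "interactions flagged at alpha =", x$alpha, "\n")
  if (x$skipped) cat("  ", x$skipped, "edges skipped (missing values)\n")
  invisible(x)
}

#' Individualized gene network of a case sample
#'
#' Removes a sample's individualized perturbed interactions from the
#' reference network. The node set and community assignments are preserved
#' exactly; genes left without edges remain as isolated nodes.
#'
#' @param reference The normal-tissue [tissue_network].
#' @param perturbed A `perturbation_set` from [flag_perturbed()].
#' @return A [tissue_network] with the flagged edges removed.
#' @export
individualize_network <- function(reference, perturbed) {
  fl <- perturbed$flagged
  key_ref <- paste(reference$edges$gene_a, reference$edges$gene_b)
  key_fl <- paste(pmin(fl$gene_a, fl$gene_b), pmax(fl$gene_a, fl$gene_b))
  if (!all(key_fl %in% key_ref))
    stop("flagged edges are not a subset of the reference edges")
  out <- reference
  out$edges <- reference$edges[!key_ref %in% key_fl, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}
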