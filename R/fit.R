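#' Fit the normal-tissue cohesion model
#'
#' End-to-end construction of the reference needed to score individual case
#' samples: (1) a seeded 80/20 split of the control columns; (2) soft
#' power selection by scale-free topology fit on the training set;
#' (3) unsigned adjacency and topological overlap; (4) average-linkage
#' hierarchical communities (modularity-maximizing cut, `min_community_size`
#' filter); (5) a permutation preservation filter against the held-out
#' controls (`Zsummary > z_cutoff`); (6) retention of the top-weight
#' `top_fraction` of intra-community pairs as edges; (7) a per-edge simple
#' linear regression over all controls, summarizing each edge's
#' perpendicular-distance distribution by median and MAD.
#'
#' @param x Controls: numeric genes x samples matrix, or a file path
#'   readable by [read_expression()].
#' @param power Soft-threshold power, or `"auto"` to select via
#'   [pick_soft_power()].
#' @param candidate_powers,r2_cutoff Passed to [pick_soft_power()].
#' @param top_fraction Fraction of intra-community pairs kept as edges
#'   (default 0.1).
#' @param min_community_size Minimum community size (default 30).
#' @param n_permutations,z_cutoff Preservation-filter settings (defaults
#'   200 permutations, Zsummary > 10).
#' @param train_fraction Fraction of control samples in the training split
#'   (default 0.8).
#' @param split_seed Seed for the control split and permutations
#'   (default 17).
#' @param mad_constant Modified z-score scale constant used downstream
#'   (default 1.486).
#' @return An object of class `"cohesion_fit"`: list with the reference
#'   `network` ([tissue_network]), `models` (edge-model table),
#'   `preservation` report, `soft_power`, the community `tree`, control
#'   ids per split, and the call. Use [predict.cohesion_fit()] to score
#'   case samples.
#' @examples
#' cfg <- simulation_config(n_genes = 120, n_controls = 120, n_cases = 5,
#'                          communities = data.frame(size = c(40, 40),
#'                                                   cor = 0.9),
#'                          seed = 7)
#' fit <- cohesion_fit(generate_controls(cfg), power = 6,
#'                     min_community_size = 20, n_permutations = 50)
#' fit
#' prof <- predict(fit, generate_cases(cfg)$expr)
#' summary(prof)
#' @export
cohesion_fit <- function(x, power = "auto", candidate_powers = 1:20,
                         r2_cutoff = 0.8, top_fraction = 0.1,
                         min_community_size = 30L, n_permutations = 200L,
                         z_cutoff = 10, train_fraction = 0.8,
                         split_seed = 17L, mad_constant = 1.486) {
  expr <- if (is.character(x)) read_expression(x) else validate_expression(x)
  n <- ncol(expr)
  set.seed(split_seed)
  train_ids <- sort(sample(n, max(3L, round(train_fraction * n))))
  test_ids <- setdiff(seq_len(n), train_ids)
  if (length(test_ids) < 3L) stop("too few controls for an 80/20 split")
  train <- expr[, train_ids, drop = FALSE]
  test <- expr[, test_ids, drop = FALSE]

  if (identical(power, "auto"))
    power <- as.integer(pick_soft_power(train, candidate_powers, r2_cutoff))
  adj_train <- compute_adjacency(train, power)
  tom_train <- compute_tom(adj_train)
  communities <- detect_communities(tom_train, min_size = min_community_size)
  tom_test <- compute_tom(compute_adjacency(test, power))
  preservation <- preservation_filter(tom_train, tom_test, communities,
                                      n_permutations = n_permutations,
                                      z_cutoff = z_cutoff, seed = split_seed)
  kept <- preservation$community[preservation$kept]
  if (!length(kept)) stop("no community passed the preservation filter")
  network <- retain_top_edges(tom_train, communities, fraction = top_fraction,
                              kept = kept, soft_power = power)
  fitted <- fit_all_edges(expr, network)

  structure(list(network = fitted$network,
                 models = fitted$models,
                 preservation = preservation,
                 communities_all = communities,
                 tree = attr(communities, "tree"),
                 soft_power = power,
                 top_fraction = top_fraction,
                 mad_constant = mad_constant,
                 train_samples = colnames(train),
                 test_samples = colnames(test),
                 n_controls = n,
                 call = match.call()),
            class = "cohesion_fit")
}

#' @export
print.cohesion_fit <- function(x, ...) {
  cat("Normal-tissue cohesion model\n")
  cat("  controls:", x$n_controls,
      " (train", length(x$train_samples),
      "/ test", length(x$test_samples), ")\n")
  cat("  soft power:", x$soft_power,
      " top edge fraction:", x$top_fraction, "\n")
  cat("  communities kept:", sum(x$preservation$kept), "of",
      nrow(x$preservation), " | edges modelled:", nrow(x$models), "\n")
  invisible(x)
}

#' @export
summary.cohesion_fit <- function(object, ...) {
  sz <- vapply(object$network$communities, length, integer(1L))
  ne <- table(factor(object$network$community_of[object$network$edges$gene_a],
                     levels = names(sz)))
  out <- list(fit = object,
              communities = data.frame(
                community = names(sz), n_genes = as.integer(sz),
                n_edges = as.integer(ne[names(sz)]),
                z_summary = object$preservation$z_summary[
                  match(names(sz), object$preservation$community)],
                row.names = NULL))
  class(out) <- "summary.cohesion_fit"
  out
}

#' @export
print.summary.cohesion_fit <- function(x, ...) {
  print(x$fit)
  cat("\nRetained communities:\n")
  print(x$communities, row.names = FALSE)
  dropped <- x$fit$preservation$community[!x$fit$preservation$kept]
  if (length(dropped))
    cat("Dropped by preservation filter:", paste(dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Edge-model coefficients
#'
#' @param object A `cohesion_fit`.
#' @param ... Unused.
#' @return The edge-model table: one row per reference interaction with the
#'   regression coefficients and control-distance summaries.
#' @export
coef.cohesion_fit <- function(object, ...) object$models

#' Dendrogram of the control co-expression clustering
#'
#' @param x A `cohesion_fit`.
#' @param ... Passed to `plot.hclust`.
#' @export
plot.cohesion_fit <- function(x, ...) {
  plot(x$tree, labels = FALSE, hang = -1,
       main = "Control co-expression communities",
       xlab = "", sub = paste(sum(x$preservation$kept), "preserved communities"),
       ...)
  invisible(x)
}

#' Score case samples against a fitted cohesion model
#'
#' For each case sample: flags individualized perturbed interactions
#' (modified z-score, one-tailed p < `alpha`), removes them to obtain the
#' individualized network, and computes the community cohesion score (the
#' efficiency ratio) for every retained community plus per-gene
#' connectivity-loss scores.
#'
#' @param object A `cohesion_fit`.
#' @param newdata Case expression: genes x samples matrix (or named vector
#'   for one sample, or a file path).
#' @param alpha Per-interaction significance level (default 0.001).
#' @param ... Unused.
#' @return An object of class `"cohesion_profile"`: list with `scores`
#'   (samples x communities matrix), `loss` (samples x genes matrix),
#'   `eff_normal` (per-community reference efficiencies), `eff_individual`
#'   (samples x communities), `perturbations` (list of `perturbation_set`),
#'   and `alpha`.
#' @export
predict.cohesion_fit <- function(object, newdata, alpha = 0.001, ...) {
  if (is.character(newdata) && length(newdata) == 1L)
    newdata <- read_expression(newdata)
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, ncol = 1L,
                      dimnames = list(names(newdata), "case"))
  net <- object$network
  labs <- names(net$communities)
  eff_normal <- vapply(labs, function(lb) network_efficiency(net, lb),
                       numeric(1L))
  genes <- sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
  ns <- ncol(newdata)
  scores <- eff_ind <- matrix(NA_real_, ns, length(labs),
                              dimnames = list(colnames(newdata), labs))
  loss <- matrix(NA_real_, ns, length(genes),
                 dimnames = list(colnames(newdata), genes))
  perturbations <- vector("list", ns)
  names(perturbations) <- colnames(newdata)
  for (j in seq_len(ns)) {
    ps <- flag_perturbed(object$models,
                         setNames(newdata[, j], rownames(newdata)),
                         alpha = alpha, sample_id = colnames(newdata)[j],
                         mad_constant = object$mad_constant)
    ind <- individualize_network(net, ps)
    for (lb in labs) {
      eff_ind[j, lb] <- network_efficiency(ind, lb)
      scores[j, lb] <- eff_ind[j, lb] / eff_normal[[lb]]
    }
    prof <- connectivity_loss_profile(net, ps)
    loss[j, rownames(prof)] <- prof$loss
    perturbations[[j]] <- ps
  }
  structure(list(scores = scores, loss = loss,
                 eff_normal = eff_normal, eff_individual = eff_ind,
                 perturbations = perturbations, alpha = alpha),
            class = "cohesion_profile")
}

#' @export
print.cohesion_profile <- function(x, ...) {
  cat("Cohesion profile:", nrow(x$scores), "case sample(s),",
      ncol(x$scores), "communities (alpha =", x$alpha, ")\n")
  cat("Cohesion scores (head):\n")
  print(round(head(x$scores), 3))
  invisible(x)
}

#' @export
summary.cohesion_profile <- function(object, ...) {
  s <- object$scores
  out <- data.frame(community = colnames(s),
                    mean_score = colMeans(s),
                    min_score = apply(s, 2L, min),
                    row.names = NULL)
  # how often each community attains the sample-wise minimum score
  out$n_min <- vapply(seq_len(ncol(s)), function(k)
    sum(apply(s, 1L, which.min) == k), integer(1L))
  class(out) <- c("summary.cohesion_profile", "data.frame")
  out
}

#' @export
print.summary.cohesion_profile <- function(x, ...) {
  cat("Per-community cohesion score summary\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Boxplot of cohesion scores by community
#'
#' @param x A `cohesion_profile`.
#' @param ... Passed to [boxplot()].
#' @export
plot.cohesion_profile <- function(x, ...) {
  boxplot(as.data.frame(x$scores), ylab = "community cohesion score",
          xlab = "community", ylim = c(0, 1), ...)
  invisible(x)
}
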