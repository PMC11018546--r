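#' Weighted network efficiency of a community
#'
#' Global efficiency of the community subgraph:
#' `E_k = 1/(N(N-1)) * sum_{X != Y in G_k} 1 / d(X, Y)`, where `d(X, Y)` is
#' the weighted shortest-path length under edge lengths `1/w` (strong
#' interactions are short) and disconnected pairs contribute 0. Only
#' intra-community edges enter the computation; 1 means every pair is
#' directly connected at full weight, 0 means the community is edgeless.
#'
#' @param network A [tissue_network].
#' @param community Community label.
#' @return Non-negative efficiency value.
#' @export
network_efficiency <- function(network, community) {
  members <- network$communities[[community]]
  if (is.null(members)) stop("unknown community: ", community)
  if (length(members) < 2L) stop("community too small to score")
  ed <- network$edges
  ed <- ed[network$community_of[ed$gene_a] == community, , drop = FALSE]
  efficiency_from_edges(ed, members)
}

# efficiency of an explicit node set given its (intra-set) edge list
efficiency_from_edges <- function(edges, nodes) {
  n <- length(nodes)
  if (nrow(edges) == 0L) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$gene_a, to = edges$gene_b),
    directed = FALSE, vertices = nodes)
  D <- igraph::distances(g, weights = 1 / edges$weight, algorithm = "dijkstra")
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0   # disconnected pairs and the diagonal
  sum(inv) / (n * (n - 1))
}

#' Community cohesion score
#'
#' Ratio of a community's network efficiency in the individualized network
#' to its efficiency in the normal-tissue reference: 1 = fully intact,
#' 0 = fully disconnected. Since individualization only removes edges, the
#' score always lies in `[0, 1]`.
#'
#' @param reference Normal-tissue [tissue_network].
#' @param individualized Individualized [tissue_network] (same nodes and
#'   communities, edge subset).
#' @param community Community label.
#' @return Cohesion score in `[0, 1]`.
#' @export
cohesion_score <- function(reference, individualized, community) {
  e_ref <- network_efficiency(reference, community)
  if (e_ref == 0) stop("unscored community: reference efficiency is zero")
  network_efficiency(individualized, community) / e_ref
}

#' Connectivity loss score of a gene
#'
#' Weight sum of a gene's flagged (perturbed) incident interactions divided
#' by the weight sum of all its incident interactions in the reference
#' network: 0 when untouched, 1 when the gene loses all its connectivity.
#'
#' @param reference Normal-tissue [tissue_network].
#' @param perturbed A `perturbation_set` from [flag_perturbed()].
#' @param gene Gene identifier with at least one incident reference edge.
#' @return Loss score in `[0, 1]`.
#' @export
connectivity_loss <- function(reference, perturbed, gene) {
  prof <- connectivity_loss_profile(reference, perturbed)
  if (!gene %in% rownames(prof))
    stop("gene has no incident reference edges: ", gene)
  prof[gene, "loss"]
}

# per-gene loss / strength / degree table for one perturbation set
connectivity_loss_profile <- function(reference, perturbed) {
  ed <- reference$edges
  key <- paste(ed$gene_a, ed$gene_b)
  fl <- perturbed$flagged
  flagged <- key %in% paste(pmin(fl$gene_a, fl$gene_b),
                            pmax(fl$gene_a, fl$gene_b))
  genes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  z <- numeric(length(genes)); names(z) <- genes
  add <- function(acc, id, val) { s <- tapply(val, id, sum)
    acc[names(s)] <- acc[names(s)] + s; acc }
  strength <- add(add(z, ed$gene_a, ed$weight), ed$gene_b, ed$weight)
  degree <- add(add(z, ed$gene_a, rep(1, nrow(ed))), ed$gene_b, rep(1, nrow(ed)))
  lost <- add(add(z, ed$gene_a, ed$weight * flagged), ed$gene_b, ed$weight * flagged)
  data.frame(loss = lost / strength, strength = strength, degree = degree,
             row.names = genes)
}

#' Prioritize individualized druggable targets
#'
#' Ranks the druggable genes of the selected community (by default the
#' community with the sample's minimum cohesion score — the one losing the
#' most cohesion) by connectivity-loss score, descending. Ties are broken
#' by normal-network connectivity, i.e. incident weight sum (strength),
#' descending, then lexicographically.
#'
#' @param reference Normal-tissue [tissue_network].
#' @param scores Named numeric vector of the sample's cohesion scores per
#'   community.
#' @param perturbed The sample's `perturbation_set`.
#' @param druggable Character vector of druggable gene symbols.
#' @param community Optional explicit community label; default
#'   `names(which.min(scores))`.
#' @return Data frame (rank, gene, community, loss, strength, degree); zero
#'   rows (with a message) when the community holds no druggable gene.
#' @export
prioritize_targets <- function(reference, scores, perturbed, druggable,
                               community = NULL) {
  if (!length(intersect(druggable, reference$nodes)))
    stop("no druggable gene present in the network")
  if (is.null(community)) community <- names(scores)[which.min(scores)]
  members <- reference$communities[[community]]
  cand <- intersect(sort(members), druggable)
  if (!length(cand)) {
    message("no druggable gene in community ", community)
    return(data.frame(rank = integer(), gene = character(),
                      community = character(), loss = numeric(),
                      strength = numeric(), degree = numeric()))
  }
  prof <- connectivity_loss_profile(reference, perturbed)
  cand <- cand[cand %in% rownames(prof)]
  p <- prof[cand, , drop = FALSE]
  ord <- order(-p$loss, -p$strength, rownames(p))
  data.frame(rank = seq_along(ord), gene = rownames(p)[ord],
             community = community,
             loss = p$loss[ord], strength = p$strength[ord],
             degree = p$degree[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}
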