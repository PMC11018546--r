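#' Unsigned soft-threshold adjacency
#'
#' Computes `a_ij = |cor(gene_i, gene_j)|^power` over samples, with a zero
#' diagonal. Genes with zero variance get correlation 0 against every other
#' gene (with a warning) rather than NA.
#'
#' @param expr Numeric genes x samples matrix.
#' @param power Soft-threshold exponent, a positive integer (see
#'   [pick_soft_power()]).
#' @return Symmetric genes x genes matrix with entries in `[0, 1]` and zero
#'   diagonal.
#' @export
compute_adjacency <- function(expr, power) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2L, power >= 1)
  r <- suppressWarnings(cor(t(expr)))
  if (anyNA(r)) {
    warning("zero-variance gene(s): correlations set to 0")
    r[is.na(r)] <- 0
  }
  a <- abs(r)^power
  diag(a) <- 0
  a
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the connectivity distribution of the resulting
#' adjacency is binned, and the signed R-squared of the regression of
#' `log10(frequency)` on `log10(connectivity)` is computed (sign flipped so a
#' decaying, power-law-like distribution scores positively). The smallest
#' power reaching `r2_cutoff` is returned; if none qualifies, the power with
#' the maximal fit is returned with a warning.
#'
#' @param expr Numeric genes x samples matrix.
#' @param candidate_powers Ascending integer vector of powers to try.
#' @param r2_cutoff Required scale-free fit (default 0.8).
#' @param n_bins Number of connectivity bins (default 10).
#' @return The selected power, with the per-power fit table attached as
#'   attribute `"fit"` (columns `power`, `r_squared`).
#' @export
pick_soft_power <- function(expr, candidate_powers = 1:20, r2_cutoff = 0.8,
                            n_bins = 10L) {
  stopifnot(length(candidate_powers) >= 1L, !is.unsorted(candidate_powers))
  r <- suppressWarnings(cor(t(expr)))
  r[is.na(r)] <- 0
  absr <- abs(r); diag(absr) <- 0
  fits <- vapply(candidate_powers, function(p) {
    scale_free_fit(rowSums(absr^p), n_bins = n_bins)
  }, numeric(1L))
  tab <- data.frame(power = candidate_powers, r_squared = fits)
  ok <- which(fits >= r2_cutoff)
  if (length(ok)) {
    sel <- candidate_powers[ok[1L]]
  } else {
    sel <- candidate_powers[which.max(fits)]
    warning("no candidate power reached the scale-free fit cutoff; ",
            "using best fit (power = ", sel, ")")
  }
  structure(sel, fit = tab)
}

# Signed scale-free topology fit of a connectivity vector: bin k, regress
# log10(freq) on log10(mean k per bin), return -sign(slope) * R^2.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 2L) stop("degenerate connectivity distribution")
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mid <- tapply(k, bin, mean)
  occ <- freq > 0 & !is.na(mid) & mid > 0
  if (sum(occ) < 2L) stop("degenerate connectivity distribution")
  x <- log10(mid[occ]); y <- log10(freq[occ] / sum(freq))
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[[2L]]) * r2
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` and a unit diagonal: two genes are similar when they
#' share network neighbours in addition to their direct connection.
#'
#' @param adjacency Symmetric matrix with entries in `[0, 1]` and zero
#'   diagonal, e.g. from [compute_adjacency()].
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
compute_tom <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (any(abs(adjacency - t(adjacency)) > 1e-12)) stop("adjacency not symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (min(adjacency) < 0 || max(adjacency) > 1) stop("adjacency entries outside [0,1]")
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  den <- outer(k, k, pmin) + 1 - adjacency
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  # guard against rounding drift just above 1
  pmin(pmax((tom + t(tom)) / 2, 0), 1)
}

#' Detect co-expression communities from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at the partition (over `k = 1..max_k` clusters) maximizing weighted
#' modularity of the TOM graph. Clusters smaller than `min_size` are
#' relabelled `"unassigned"` and excluded from all downstream scoring.
#' Retained communities are labelled `"C1"`, `"C2"`, ... in decreasing size
#' order.
#'
#' @param tom Symmetric similarity matrix from [compute_tom()].
#' @param min_size Minimum community size (default 30).
#' @param max_k Largest number of clusters considered for the cut.
#' @return Named character vector mapping gene to community label, with the
#'   `hclust` tree attached as attribute `"tree"`.
#' @export
detect_communities <- function(tom, min_size = 30L, max_k = 30L) {
  stopifnot(min_size >= 2L)
  genes <- rownames(tom)
  n <- nrow(tom)
  hc <- hclust(as.dist(1 - tom), method = "average")
  g <- igraph::graph_from_adjacency_matrix(tom - diag(n), mode = "undirected",
                                           weighted = TRUE)
  ks <- seq_len(min(max_k, n - 1L))
  qs <- vapply(ks, function(k) {
    memb <- if (k == 1L) rep(1L, n) else cutree(hc, k = k)
    igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  }, numeric(1L))
  best_k <- ks[which.max(qs)]
  if (best_k == 1L) {
    warning("no modular structure found; all genes form a single community")
    memb <- rep(1L, n)
  } else {
    memb <- cutree(hc, k = best_k)
  }
  sizes <- table(memb)
  keep <- names(sizes)[sizes >= min_size]
  if (!length(keep))
    warning("no cluster reaches min_size; all genes unassigned")
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  lab <- setNames(rep("unassigned", n), genes)
  for (i in seq_along(ord)) lab[memb == as.integer(ord[i])] <- paste0("C", i)
  structure(lab, tree = hc)
}

#' Permutation preservation filter for communities
#'
#' Tests, for each community detected in the training controls, whether its
#' structure is preserved in held-out test controls. Two statistics are
#' used: mean intra-community TOM density in the test set, and the
#' correlation of intra-community connectivity between train and test.
#' Each is standardized against its permutation null (random gene sets of
#' the same size); `Zsummary` is the mean of the two z-statistics, and a
#' community is kept when `Zsummary > z_cutoff`.
#'
#' @param tom_train,tom_test TOM matrices over the same gene universe.
#' @param communities Named gene -> label map (label `"unassigned"` ignored).
#' @param n_permutations Number of label permutations (>= 50; default 200).
#' @param z_cutoff Preservation threshold (default 10).
#' @param seed Integer seed for the permutation draws.
#' @return A `preservation_report` data frame with one row per community:
#'   observed statistics, permutation means/sds, per-statistic z, `z_summary`
#'   and the keep decision.
#' @export
preservation_filter <- function(tom_train, tom_test, communities,
                                n_permutations = 200L, z_cutoff = 10,
                                seed = 1L) {
  stopifnot(identical(rownames(tom_train), rownames(tom_test)),
            n_permutations >= 50L)
  genes <- rownames(tom_train)
  labs <- sort(setdiff(unique(communities[genes]), "unassigned"))
  # train_set and test_set are paired gene vectors: under the null the
  # community's labels are permuted in the test data, so its train members
  # are paired with a random test gene set (breaking both the density and
  # the connectivity correspondence); observed = identity pairing
  stats_of <- function(train_set, test_set) {
    idx_tr <- match(train_set, genes)
    idx_te <- match(test_set, genes)
    sub_te <- tom_test[idx_te, idx_te, drop = FALSE]
    sub_tr <- tom_train[idx_tr, idx_tr, drop = FALSE]
    off <- row(sub_te) != col(sub_te)
    dens <- mean(sub_te[off])
    k_tr <- rowSums(sub_tr) - 1
    k_te <- rowSums(sub_te) - 1
    cc <- suppressWarnings(cor(k_tr, k_te))
    if (is.na(cc)) cc <- 0
    c(density = dens, conn_cor = cc)
  }
  rows <- lapply(seq_along(labs), function(li) {
    lb <- labs[li]
    members <- genes[communities[genes] == lb]
    obs <- stats_of(members, members)
    set.seed(seed + li)
    perm <- vapply(seq_len(n_permutations), function(i) {
      stats_of(members, sample(genes, length(members)))
    }, numeric(2L))
    pm <- rowMeans(perm); ps <- apply(perm, 1L, stats::sd)
    z <- ifelse(ps > 0, (obs - pm) / ps,
                ifelse(obs > pm, Inf, -Inf))
    if (any(ps == 0)) message("community ", lb, ": zero permutation sd")
    data.frame(community = lb, size = length(members),
               density_obs = obs[["density"]],
               density_perm_mean = pm[["density"]],
               density_perm_sd = ps[["density"]],
               z_density = z[["density"]],
               conn_cor_obs = obs[["conn_cor"]],
               conn_cor_perm_mean = pm[["conn_cor"]],
               conn_cor_perm_sd = ps[["conn_cor"]],
               z_connectivity = z[["conn_cor"]],
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$z_summary <- (rep$z_density + rep$z_connectivity) / 2
  rep$kept <- rep$z_summary > z_cutoff
  class(rep) <- c("preservation_report", "data.frame")
  rep
}

#' Retain the top-weight fraction of intra-community interactions
#'
#' Within each kept community independently, all gene pairs are ranked by
#' TOM weight (ties broken by lexicographic gene-pair order, for
#' deterministic builds) and the top `ceiling(fraction * n_pairs)` become
#' network edges. Inter-community pairs are never retained.
#'
#' @param tom TOM matrix.
#' @param communities Named gene -> label map.
#' @param fraction Fraction of pairs to keep per community, in `(0, 1]`.
#' @param kept Optional character vector of community labels to retain
#'   (e.g. those passing [preservation_filter()]); default all labels except
#'   `"unassigned"`.
#' @param soft_power Soft-threshold power recorded on the network object.
#' @return A [tissue_network] object.
#' @export
retain_top_edges <- function(tom, communities, fraction = 0.1, kept = NULL,
                             soft_power = NA_integer_) {
  stopifnot(fraction > 0, fraction <= 1)
  genes <- rownames(tom)
  communities <- communities[names(communities) %in% genes]
  labs <- setdiff(unique(communities), "unassigned")
  if (!is.null(kept)) labs <- intersect(labs, kept)
  edge_list <- lapply(labs, function(lb) {
    members <- sort(names(communities)[communities == lb])
    if (length(members) < 2L) {
      warning("community ", lb, " has fewer than 2 genes; no edges")
      return(NULL)
    }
    prs <- utils::combn(members, 2L)
    w <- tom[cbind(prs[1L, ], prs[2L, ])]
    n_keep <- ceiling(fraction * ncol(prs))
    # order: weight desc, then lexicographic pair order for ties
    ord <- order(-w, prs[1L, ], prs[2L, ])
    sel <- ord[seq_len(n_keep)]
    data.frame(gene_a = prs[1L, sel], gene_b = prs[2L, sel], weight = w[sel],
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges))
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  comm_of <- communities[communities %in% labs]
  tissue_network(edges, comm_of, soft_power = soft_power)
}

#' Construct a tissue network object
#'
#' The weighted, undirected normal-tissue reference network: every edge is
#' intra-community with a strictly positive weight, and each gene belongs to
#' exactly one community.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight`
#'   (`gene_a < gene_b` lexicographically; enforced).
#' @param community_of Named character vector gene -> community label; its
#'   names define the node set (isolated genes allowed).
#' @param soft_power Soft-threshold power used for the adjacency (metadata).
#' @return An object of class `"tissue_network"` with fields `nodes`,
#'   `edges`, `community_of`, `communities`, `soft_power`.
#' @export
tissue_network <- function(edges, community_of, soft_power = NA_integer_) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
  }
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  key <- paste(edges$gene_a, edges$gene_b)
  if (anyDuplicated(key)) stop("duplicate edges")
  if (any(edges$weight <= 0)) stop("edge weights must be strictly positive")
  nodes <- names(community_of)
  if (!all(c(edges$gene_a, edges$gene_b) %in% nodes))
    stop("edge endpoint missing from the community map")
  same <- community_of[edges$gene_a] == community_of[edges$gene_b]
  if (!all(same)) stop("inter-community edges are not allowed")
  rownames(edges) <- NULL
  structure(list(nodes = nodes,
                 edges = edges,
                 community_of = community_of,
                 communities = split(nodes, community_of[nodes]),
                 soft_power = soft_power),
            class = "tissue_network")
}

#' @export
print.tissue_network <- function(x, ...) {
  cat("Tissue co-expression network\n")
  cat("  nodes:", length(x$nodes),
      " edges:", nrow(x$edges),
      " communities:", length(x$communities), "\n")
  sz <- vapply(x$communities, length, integer(1L))
  cat("  community sizes:", paste(names(sz), sz, sep = "=", collapse = " "), "\n")
  if (!is.na(x$soft_power)) cat("  soft power:", x$soft_power, "\n")
  invisible(x)
}

#' Write / read a tissue network as plain text
#'
#' `write_network()` writes `edges.tsv` (gene_a, gene_b, weight) and
#' `communities.tsv` (gene, community) into `dir`; `read_network()` loads
#' them back.
#'
#' @param network A [tissue_network] object.
#' @param dir Output directory (created if missing).
#' @return `write_network()` returns `dir` invisibly; `read_network()`
#'   returns a [tissue_network].
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(network$edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cm <- data.frame(gene = names(network$community_of),
                   community = unname(network$community_of))
  write.table(cm, file.path(dir, "communities.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  edges <- read.delim(file.path(dir, "edges.tsv"), stringsAsFactors = FALSE)
  cm <- read.delim(file.path(dir, "communities.tsv"), stringsAsFactors = FALSE)
  tissue_network(edges, setNames(cm$community, cm$gene))
}
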