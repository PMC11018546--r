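# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive (loops, closed forms) so it cannot
# share a bug with the vectorized implementations it checks.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force TOM by triple loop
tom_loops <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# random symmetric adjacency in [0,1] with zero diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# all-pairs shortest paths by Floyd-Warshall over 1/w edge lengths,
# then global efficiency of the node set
efficiency_fw <- function(edges, nodes) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    len <- 1 / edges$weight[r]
    a <- edges$gene_a[r]; b <- edges$gene_b[r]
    D[a, b] <- D[b, a] <- min(D[a, b], len)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# point-to-line distance by orthogonal projection (geometry, not Eq. form)
dist_by_projection <- function(beta0, beta1, px, py) {
  p0 <- c(0, beta0)
  u <- c(1, beta1) / sqrt(1 + beta1^2)
  v <- c(px, py) - p0
  sqrt(sum((v - sum(v * u) * u)^2))
}

# random connected-ish weighted community network on n nodes
random_community <- function(n, n_edges, seed, label = "C1") {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  prs <- t(combn(nodes, 2))
  sel <- sample(nrow(prs), n_edges)
  edges <- data.frame(gene_a = prs[sel, 1], gene_b = prs[sel, 2],
                      weight = runif(n_edges, 0.05, 1),
                      stringsAsFactors = FALSE)
  tissue_network(edges, setNames(rep(label, n), nodes))
}

# two-group log-rank chi-square from the classic risk-table formula
logrank_table <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1L); n2 <- sum(at_risk & group == 2L)
    d1 <- sum(time == t & event == 1 & group == 1L)
    d2 <- sum(time == t & event == 1 & group == 2L)
    d <- d1 + d2; n <- n1 + n2
    if (n < 2) next
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# small planted two-block expression fixture
two_block_expr <- function(n_per_block = 20, n_samples = 100, rho = 0.9,
                           seed = 42) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(2 * n_per_block))
  m <- matrix(rnorm(2 * n_per_block * n_samples), ncol = n_samples,
              dimnames = list(genes, paste0("s", seq_len(n_samples))))
  for (b in 0:1) {
    idx <- b * n_per_block + seq_len(n_per_block)
    z <- rnorm(n_samples)
    m[idx, ] <- sqrt(rho) * matrix(z, n_per_block, n_samples, byrow = TRUE) +
      sqrt(1 - rho) * m[idx, ]
  }
  m
}
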