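test_that("adjacency is |cor|^power with zero diagonal", {
  set.seed(1)
  x <- rnorm(50)
  expr <- rbind(a = x, b = 2 * x + 1, c = rnorm(50))
  colnames(expr) <- paste0("s", 1:50)
  a6 <- compute_adjacency(expr, 6)
  expect_equal(a6["a", "b"], 1)                      # |r| = 1 fixed point
  expect_equal(diag(a6), c(a = 0, b = 0, c = 0))
  expect_equal(a6, t(a6))
  # exponentiation matches direct oracle at every power
  r_ac <- abs(cor(x, expr["c", ]))
  for (p in c(1, 4, 6)) {
    expect_equal(compute_adjacency(expr, p)["a", "c"], r_ac^p, tolerance = 1e-12)
  }
  # r = 0.8, power 6 -> 0.262144 on an exactly-correlated pair
  y <- 0.8 * scale(x)[, 1] + sqrt(1 - 0.64) * scale(resid(lm(rnorm(50) ~ x)))[, 1]
  expr2 <- rbind(a = scale(x)[, 1], b = y)
  colnames(expr2) <- paste0("s", 1:50)
  expect_equal(compute_adjacency(expr2, 6)["a", "b"],
               abs(cor(expr2["a", ], expr2["b", ]))^6, tolerance = 1e-12)
})

test_that("constant genes yield zero correlation with a warning", {
  expr <- rbind(a = rnorm(20), b = rep(1, 20), c = rnorm(20))
  colnames(expr) <- paste0("s", 1:20)
  expect_warning(a <- compute_adjacency(expr, 2), "zero-variance")
  expect_equal(a["b", "a"], 0)
  expect_equal(a["b", "c"], 0)
})

test_that("TOM matches the brute-force formula and its bounds", {
  # fully connected triangle: TOM_12 = (1 + 1)/(2 + 1 - 1) = 1
  a <- matrix(1, 3, 3) - diag(3)
  expect_equal(compute_tom(a)[1, 2], 1)
  # all-zero adjacency -> off-diagonal zero, unit diagonal
  z <- compute_tom(matrix(0, 4, 4))
  expect_equal(z, diag(4))
  # random matrices: symmetry, [0,1], unit diagonal, loop-oracle agreement
  for (seed in 1:5) {
    adj <- random_adjacency(6, seed)
    tom <- compute_tom(adj)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(unname(diag(tom)), rep(1, 6))
    expect_equal(tom, tom_loops(adj), tolerance = 1e-12)
  }
})

test_that("aligned (identical) neighbourhoods maximize TOM for a fixed profile", {
  # permuting one gene's neighbourhood weights keeps its connectivity and
  # the direct weight fixed but can only lower the shared-neighbour overlap
  set.seed(3)
  for (rep in 1:5) {
    adj <- random_adjacency(6, 100 + rep)
    shared <- runif(4)
    adj[1, 3:6] <- adj[3:6, 1] <- shared
    adj[2, 3:6] <- adj[3:6, 2] <- shared
    tom_aligned <- compute_tom(adj)
    for (k in 1:5) {
      adj2 <- adj
      perm <- sample(4)
      adj2[2, 3:6] <- adj2[3:6, 2] <- shared[perm]
      tom_perm <- compute_tom(adj2)
      expect_gte(tom_aligned[1, 2], tom_perm[1, 2] - 1e-12)
    }
  }
})

test_that("planted two-block structure is recovered exactly", {
  expr <- two_block_expr(n_per_block = 20, n_samples = 150, rho = 0.9)
  tom <- compute_tom(compute_adjacency(expr, 6))
  comm <- detect_communities(tom, min_size = 5)
  planted <- rep(c("b1", "b2"), each = 20)
  expect_equal(ari(comm, planted), 1)
  expect_length(unique(comm), 2L)
})

test_that("community detection handles degenerate cuts", {
  expr <- two_block_expr(n_per_block = 10, n_samples = 80, rho = 0.9)
  tom <- compute_tom(compute_adjacency(expr, 6))
  # min_size larger than any cluster -> everything unassigned, with warning
  expect_warning(comm <- detect_communities(tom, min_size = 15),
                 "unassigned")
  expect_true(all(comm == "unassigned"))
  # identical TOM rows merge first: duplicate a gene
  expr2 <- rbind(expr, dup = expr[1, ] + 1e-9 * rnorm(80))
  tom2 <- compute_tom(compute_adjacency(expr2, 6))
  comm2 <- detect_communities(tom2, min_size = 3)
  expect_equal(unname(comm2["dup"]), unname(comm2[rownames(expr)[1]]))
})

test_that("top-edge retention keeps exact per-community counts with ties broken lexicographically", {
  genes <- paste0("g", 1:5)
  tom <- matrix(0.5, 5, 5, dimnames = list(genes, genes))
  diag(tom) <- 1
  tom["g1", "g2"] <- tom["g2", "g1"] <- 0.9
  comm <- setNames(rep("C1", 5), genes)
  # 10 pairs, fraction .1 -> exactly the single max-weight pair
  net <- retain_top_edges(tom, comm, fraction = 0.1)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$gene_a, "g1")
  expect_equal(net$edges$gene_b, "g2")
  # tie at the boundary: all remaining weights equal; lexicographic order wins
  net2 <- retain_top_edges(tom, comm, fraction = 0.2)
  expect_equal(nrow(net2$edges), 2L)
  expect_equal(net2$edges$gene_a[2], "g1")
  expect_equal(net2$edges$gene_b[2], "g3")
  # fraction 1 keeps every pair
  expect_equal(nrow(retain_top_edges(tom, comm, fraction = 1)$edges), 10L)
})

test_that("retention is intra-community with exact ceil counts", {
  set.seed(9)
  n <- 12
  genes <- sprintf("g%02d", 1:n)
  tom <- random_adjacency(n, 77); diag(tom) <- 1
  dimnames(tom) <- list(genes, genes)
  comm <- setNames(rep(c("C1", "C2"), each = 6), genes)
  for (f in c(0.1, 0.37, 0.8)) {
    net <- retain_top_edges(tom, comm, fraction = f)
    same <- comm[net$edges$gene_a] == comm[net$edges$gene_b]
    expect_true(all(same))
    per <- table(comm[net$edges$gene_a])
    expect_equal(unname(per[["C1"]]), ceiling(f * choose(6, 2)))
    expect_equal(unname(per[["C2"]]), ceiling(f * choose(6, 2)))
  }
})

test_that("preservation keeps planted communities and drops a noise block", {
  set.seed(5)
  n_samp <- 300
  n_g <- 80
  genes <- sprintf("g%03d", seq_len(n_g))
  m <- matrix(rnorm(n_g * n_samp), n_g, dimnames = list(genes, paste0("s", 1:n_samp)))
  blockify <- function(m, rows, cols) {
    z <- rnorm(length(cols))
    m[rows, cols] <- sqrt(0.9) * matrix(z, length(rows), length(cols), byrow = TRUE) +
      sqrt(0.1) * m[rows, cols]
    m
  }
  # genes 1..40 (two blocks): correlated in both halves;
  # genes 41..60: correlated only in the training half; 61..80 background
  m <- blockify(m, 1:20, 1:n_samp)
  m <- blockify(m, 21:40, 1:n_samp)
  m <- blockify(m, 41:60, 1:150)
  tr <- m[, 1:150]; te <- m[, 151:300]
  tom_tr <- compute_tom(compute_adjacency(tr, 6))
  tom_te <- compute_tom(compute_adjacency(te, 6))
  comm <- setNames(c(rep(c("C1", "C2", "C3"), each = 20),
                     rep("unassigned", 20)), genes)
  rep1 <- preservation_filter(tom_tr, tom_te, comm, n_permutations = 100,
                              z_cutoff = 5, seed = 7)
  expect_true(rep1$kept[rep1$community == "C1"])
  expect_true(rep1$kept[rep1$community == "C2"])
  expect_false(rep1$kept[rep1$community == "C3"])
  expect_lt(rep1$z_summary[rep1$community == "C3"], 0)
  # vacuous cutoff keeps everything
  rep2 <- preservation_filter(tom_tr, tom_te, comm, n_permutations = 100,
                              z_cutoff = -Inf, seed = 7)
  expect_true(all(rep2$kept))
})

test_that("preservation z is equivariant under gene relabeling", {
  expr <- two_block_expr(n_per_block = 15, n_samples = 160, rho = 0.85, seed = 8)
  tr <- expr[, 1:80]; te <- expr[, 81:160]
  tom_tr <- compute_tom(compute_adjacency(tr, 6))
  tom_te <- compute_tom(compute_adjacency(te, 6))
  comm <- setNames(rep(c("C1", "C2"), each = 15), rownames(expr))
  r1 <- preservation_filter(tom_tr, tom_te, comm, n_permutations = 60, seed = 3)
  # relabel genes (permute the universe consistently everywhere)
  set.seed(10)
  perm <- sample(rownames(expr))
  relab <- setNames(rownames(expr), perm)  # new name -> old name
  tom_tr2 <- tom_tr; tom_te2 <- tom_te
  rownames(tom_tr2) <- colnames(tom_tr2) <- names(relab)[match(rownames(tom_tr), relab)]
  rownames(tom_te2) <- colnames(tom_te2) <- rownames(tom_tr2)
  comm2 <- setNames(comm, rownames(tom_tr2)[match(names(comm), rownames(tom_tr))])
  r2 <- preservation_filter(tom_tr2, tom_te2, comm2, n_permutations = 60, seed = 3)
  expect_equal(r1$density_obs, r2$density_obs, tolerance = 1e-12)
  expect_equal(r1$conn_cor_obs, r2$conn_cor_obs, tolerance = 1e-12)
})

test_that("soft power selection honors the smallest-qualifying and fallback contracts", {
  expr <- two_block_expr(n_per_block = 25, n_samples = 150, rho = 0.9, seed = 12)
  # single candidate: returned as-is
  expect_equal(as.integer(suppressWarnings(pick_soft_power(expr, 6L))), 6L)
  # independent oracle for the fit values: rebin + regress here
  fit_oracle <- function(k, n_bins = 10) {
    k <- k[k > 0]
    br <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    fr <- tabulate(bin, n_bins); mid <- tapply(k, bin, mean)
    occ <- fr > 0 & !is.na(mid)
    f <- lm(log10(fr[occ] / sum(fr)) ~ log10(mid[occ]))
    -sign(coef(f)[[2]]) * summary(f)$r.squared
  }
  r <- abs(cor(t(expr)))
  diag(r) <- 0
  cand <- c(2L, 6L, 10L)
  fits <- sapply(cand, function(p) fit_oracle(rowSums(r^p)))
  cutoff <- 0.3
  got <- withCallingHandlers(
    pick_soft_power(expr, cand, r2_cutoff = cutoff),
    warning = function(w) invokeRestart("muffleWarning"))
  if (any(fits >= cutoff)) {
    expect_equal(as.integer(got), cand[which(fits >= cutoff)[1]])
  } else {
    expect_equal(as.integer(got), cand[which.max(fits)])
  }
  # impossible cutoff: argmax fallback with warning
  expect_warning(fb <- pick_soft_power(expr, cand, r2_cutoff = 2),
                 "cutoff")
  expect_equal(as.integer(fb), cand[which.max(attr(fb, "fit")$r_squared)])
})

test_that("network objects reject malformed input and round-trip to disk", {
  comm <- setNames(rep("C1", 3), c("a", "b", "c"))
  e <- data.frame(gene_a = "b", gene_b = "a", weight = 0.5)
  net <- tissue_network(e, comm)            # orientation normalized
  expect_equal(net$edges$gene_a, "a")
  expect_error(tissue_network(data.frame(gene_a = "a", gene_b = "a", weight = 1), comm),
               "self-loops")
  expect_error(tissue_network(data.frame(gene_a = "a", gene_b = "b", weight = 0), comm),
               "positive")
  comm2 <- setNames(c("C1", "C1", "C2"), c("a", "b", "c"))
  expect_error(tissue_network(data.frame(gene_a = "a", gene_b = "c", weight = 1), comm2),
               "inter-community")
  dir <- withr::local_tempdir()
  write_network(net, dir)
  back <- read_network(dir)
  expect_equal(back$edges, net$edges)
  expect_equal(back$community_of, net$community_of)
})
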