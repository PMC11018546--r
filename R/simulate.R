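#' Configuration for the synthetic cohesion study
#'
#' Describes the generative regime the method assumes: block-correlated
#' (equicorrelated Gaussian) control expression, case samples in which the
#' co-expression of one target community is destroyed by re-drawing genes
#' independently, and exponential survival outcomes whose hazard depends on
#' a low/high cohesion label.
#'
#' @param n_genes Total genes (background genes fill up beyond the blocks).
#' @param n_controls,n_cases Sample counts.
#' @param communities Data frame with columns `size` and `cor` (within-block
#'   correlation in (0, 1)); default five blocks of 80/60/60/40/40 genes at
#'   correlation 0.9.
#' @param target_community Index of the perturbed block.
#' @param fraction_broken Fraction of the target block's gene pairs whose
#'   co-expression is destroyed in each case sample, in `[0, 1]`.
#' @param hub_gene_mode If `TRUE`, instead of a random pair fraction, all
#'   pairs incident to one designated hub gene are broken — the "gene loses
#'   all its connectivity" pattern. The hub is the target community's
#'   highest-degree gene when a reference network is supplied to
#'   [generate_cases()], else the block's first gene.
#' @param noise_sd_multiplier Dysregulation magnitude (>= 1, default 3):
#'   re-drawn values are `sign * (multiplier + |N(0,1)|)` with a random
#'   sign, i.e. gross dysregulation bounded away from the normal dynamic
#'   range. A re-drawn value that happens to land where co-expression
#'   predicts is geometrically indistinguishable from an intact
#'   interaction, so a centered within-range re-draw would leave the
#'   "broken" pairs of a sample intact whenever the draw is small — the
#'   perturbation is meant to break them in (essentially) every sample.
#' @param perturbation_mode `"redraw"` (destroy co-expression) or
#'   `"mean_shift"` (negative control: shift the target block's mean by 2
#'   while preserving its correlation structure).
#' @param baseline_hazard,hazard_ratio Exponential hazards: baseline for
#'   high-cohesion samples, baseline x ratio for low-cohesion samples.
#' @param true_threshold Cohesion-score cutpoint separating the risk groups.
#' @param censor_max Upper bound of the uniform censoring time.
#' @param seed Integer seed; every generator is a pure function of the
#'   config (including this seed).
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 300L, n_controls = 500L,
                              n_cases = 200L,
                              communities = data.frame(
                                size = c(80L, 60L, 60L, 40L, 40L),
                                cor = rep(0.9, 5L)),
                              target_community = 1L,
                              fraction_broken = 1,
                              hub_gene_mode = FALSE,
                              noise_sd_multiplier = 3,
                              perturbation_mode = c("redraw", "mean_shift"),
                              baseline_hazard = 0.3,
                              hazard_ratio = 3,
                              true_threshold = 0.5,
                              censor_max = 10,
                              seed = 1L) {
  stopifnot(sum(communities$size) <= n_genes,
            all(communities$cor > 0 & communities$cor < 1),
            fraction_broken >= 0, fraction_broken <= 1,
            noise_sd_multiplier >= 1,
            target_community >= 1L,
            target_community <= nrow(communities))
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases),
                 communities = communities,
                 target_community = as.integer(target_community),
                 fraction_broken = fraction_broken,
                 hub_gene_mode = isTRUE(hub_gene_mode),
                 noise_sd_multiplier = noise_sd_multiplier,
                 perturbation_mode = match.arg(perturbation_mode),
                 baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio,
                 true_threshold = true_threshold,
                 censor_max = censor_max,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# hub = target-block gene with highest degree (strength on ties) in the
# reference network; falls back to the block's first gene
designate_hub <- function(target, reference) {
  if (is.null(reference)) return(target[1L])
  if (inherits(reference, "cohesion_fit")) reference <- reference$network
  ed <- reference$edges
  inc <- c(ed$gene_a, ed$gene_b)
  w <- c(ed$weight, ed$weight)
  keep <- inc %in% target
  if (!any(keep)) return(target[1L])
  deg <- tapply(rep(1, sum(keep)), inc[keep], sum)
  str <- tapply(w[keep], inc[keep], sum)
  cand <- names(deg)[deg == max(deg)]
  cand[which.max(str[cand])]
}

# gene ids per planted block (and background), fixed by the config
sim_block_genes <- function(config) {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  sizes <- config$communities$size
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  blocks <- lapply(seq_along(sizes), function(b) genes[starts[b]:ends[b]])
  names(blocks) <- paste0("B", seq_along(sizes))
  list(genes = genes, blocks = blocks,
       background = if (ends[length(ends)] < config$n_genes)
         genes[(ends[length(ends)] + 1L):config$n_genes] else character())
}

# one genes x n matrix draw from the block-equicorrelated control model:
# within a block with correlation rho, x_g = sqrt(rho) z + sqrt(1-rho) e_g
sim_draw <- function(config, n, prefix) {
  bl <- sim_block_genes(config)
  m <- matrix(rnorm(config$n_genes * n), nrow = config$n_genes,
              dimnames = list(bl$genes, sprintf("%s%03d", prefix, seq_len(n))))
  for (b in seq_len(nrow(config$communities))) {
    rho <- config$communities$cor[b]
    idx <- match(bl$blocks[[b]], bl$genes)
    shared <- rnorm(n)
    m[idx, ] <- sqrt(rho) * matrix(shared, nrow = length(idx), ncol = n,
                                   byrow = TRUE) +
      sqrt(1 - rho) * m[idx, ]
  }
  m
}

#' Generate control expression
#'
#' Multivariate-normal controls with block-diagonal equicorrelation: genes
#' inside each planted community share correlation `cor`, genes in
#' different blocks (and background genes) are independent. Deterministic
#' under the config seed.
#'
#' @param config A [simulation_config()].
#' @return Genes x samples numeric matrix.
#' @export
generate_controls <- function(config) {
  set.seed(config$seed)
  sim_draw(config, config$n_controls, "Ctl")
}

#' Generate case expression with planted perturbation
#'
#' Cases are drawn from the control distribution, then the target
#' community is perturbed per sample. In `"redraw"` mode a fixed-size
#' random subset of its genes is re-drawn as independent noise, sized so
#' the expected fraction of broken gene pairs (pairs with at least one
#' re-drawn member) equals `fraction_broken`; in `hub_gene_mode` only the
#' designated hub gene is re-drawn, breaking every pair incident to it. In
#' `"mean_shift"` mode (negative control) the whole target block is shifted
#' by +2 with its correlation structure intact.
#'
#' @param config A [simulation_config()].
#' @param reference Optional fitted [tissue_network] (or a `cohesion_fit`):
#'   in `hub_gene_mode` the hub is designated as the target community
#'   member with the highest degree (strength on ties) in this network.
#' @return List with `expr` (genes x cases matrix) and `truth`: the target
#'   block label, its gene set, the hub gene (or `NA`), and `broken_genes`
#'   (per-sample list of re-drawn genes).
#' @export
generate_cases <- function(config, reference = NULL) {
  set.seed(config$seed + 1L)
  m <- sim_draw(config, config$n_cases, "Case")
  bl <- sim_block_genes(config)
  target <- bl$blocks[[config$target_community]]
  n_k <- length(target)
  hub <- if (config$hub_gene_mode) designate_hub(target, reference)
         else NA_character_
  if (config$perturbation_mode == "mean_shift") {
    m[target, ] <- m[target, ] + 2
    broken <- rep(list(character()), config$n_cases)
    names(broken) <- colnames(m)
    return(list(expr = m,
                truth = list(target_block = names(bl$blocks)[config$target_community],
                             target_genes = target, hub_gene = hub,
                             broken_genes = broken)))
  }
  n_redraw <- if (config$hub_gene_mode) 1L else
    round(n_k * (1 - sqrt(1 - config$fraction_broken)))
  broken <- vector("list", config$n_cases)
  for (j in seq_len(config$n_cases)) {
    redraw <- if (config$hub_gene_mode) hub else
      if (n_redraw > 0L) sample(target, n_redraw) else character()
    if (length(redraw)) {
      nr <- length(redraw)
      m[redraw, j] <- sample(c(-1, 1), nr, replace = TRUE) *
        (config$noise_sd_multiplier + abs(rnorm(nr)))
    }
    broken[[j]] <- redraw
  }
  names(broken) <- colnames(m)
  list(expr = m,
       truth = list(target_block = names(bl$blocks)[config$target_community],
                    target_genes = target, hub_gene = hub,
                    broken_genes = broken))
}

#' Generate survival outcomes tied to cohesion loss
#'
#' Exponential event times with hazard `baseline_hazard` for high-cohesion
#' samples and `baseline_hazard * hazard_ratio` for low-cohesion samples,
#' with uniform censoring on `(0, censor_max)`. Deterministic under the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @param low Logical (or 0/1) vector, `TRUE` for low-cohesion samples;
#'   names become sample ids (or `S001...` if unnamed).
#' @return Data frame (sample_id, time, event).
#' @export
generate_survival <- function(config, low) {
  if (config$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  set.seed(config$seed + 2L)
  n <- length(low)
  hz <- ifelse(as.logical(low), config$baseline_hazard * config$hazard_ratio,
               config$baseline_hazard)
  t_event <- rexp(n, rate = hz)
  t_cens <- runif(n, 0, config$censor_max)
  ids <- if (!is.null(names(low))) names(low) else sprintf("S%03d", seq_len(n))
  data.frame(sample_id = ids,
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}
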