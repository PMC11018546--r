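#' Two-group log-rank test
#'
#' Standard log-rank chi-square comparison of two survival experiences.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping vector.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("need exactly two nonempty groups")
  if (sum(event) == 0) stop("no events to compare")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = sd$chisq,
       p_value = pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Cohesion-score threshold sweep for prognostic stratification
#'
#' Slides a threshold t over `{0, step, 2 step, ..., 1}`, splitting the
#' cohort into low (`score < t`) and high (`score >= t`) cohesion groups,
#' and evaluates each admissible split (both groups at least `min_group`)
#' by the log-rank test after truncating follow-up at `horizon` (events
#' beyond the horizon become censored at the horizon). Returns the grid and
#' the threshold attaining the minimum p (ties resolved toward the smaller
#' threshold). The optimized p-value is reported as-is — it is a
#' threshold-optimized quantity and inherits the usual selection inflation.
#'
#' @param scores Named numeric vector: one community's cohesion score per
#'   sample.
#' @param survival_data Data frame with columns `sample_id`, `time`, `event`.
#' @param step Grid increment in `(0, 1)` (default 0.001).
#' @param min_group Minimum group size for an admissible split (default 10).
#' @param horizon Follow-up truncation (default 5, i.e. 5-year outcome);
#'   `Inf` disables truncation.
#' @param community Label recorded on the result.
#' @return An object of class `"sweep_result"`: list with `community`,
#'   `best_threshold`, `p_value`, `statistic`, `group_sizes` and the full
#'   admissible `grid` data frame (threshold, p_value, n_low, n_high).
#' @export
threshold_sweep <- function(scores, survival_data, step = 0.001,
                            min_group = 10L, horizon = 5,
                            community = NA_character_) {
  stopifnot(step > 0, step < 1, min_group >= 1L)
  ids <- intersect(names(scores), survival_data$sample_id)
  if (length(ids) < 2L * min_group) stop("no valid threshold: cohort too small")
  sv <- survival_data[match(ids, survival_data$sample_id), ]
  if (anyDuplicated(sv$sample_id)) stop("duplicate sample ids in survival table")
  if (any(!is.finite(sv$time) | sv$time <= 0)) stop("times must be finite and positive")
  s <- scores[ids]
  time <- pmin(sv$time, horizon)
  event <- ifelse(sv$time > horizon, 0L, as.integer(sv$event))
  grid_t <- seq(0, 1, by = step)
  n_low <- vapply(grid_t, function(t) sum(s < t), integer(1L))
  admissible <- n_low >= min_group & (length(s) - n_low) >= min_group
  if (!any(admissible)) stop("no valid threshold: every split is degenerate")
  # thresholds inducing the same partition share one log-rank test
  res <- data.frame(threshold = grid_t[admissible],
                    n_low = n_low[admissible],
                    n_high = length(s) - n_low[admissible],
                    p_value = NA_real_, statistic = NA_real_)
  for (nl in unique(res$n_low)) {
    i <- which(res$n_low == nl)
    t0 <- res$threshold[i[1L]]
    lr <- tryCatch(logrank(time, event, s < t0), error = function(e) NULL)
    if (!is.null(lr)) {
      res$p_value[i] <- lr$p_value
      res$statistic[i] <- lr$statistic
    }
  }
  res <- res[!is.na(res$p_value), , drop = FALSE]
  if (!nrow(res)) stop("no valid threshold: no events in any admissible split")
  best <- which.min(res$p_value)   # first index: smallest threshold on ties
  structure(list(community = community,
                 best_threshold = res$threshold[best],
                 p_value = res$p_value[best],
                 statistic = res$statistic[best],
                 group_sizes = c(n_low = res$n_low[best],
                                 n_high = res$n_high[best]),
                 horizon = horizon, step = step, min_group = min_group,
                 grid = res[, c("threshold", "p_value", "n_low", "n_high")]),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Cohesion threshold sweep",
      if (!is.na(x$community)) paste0("(community ", x$community, ")"), "\n")
  cat("  best threshold:", x$best_threshold,
      " log-rank p:", format(x$p_value, digits = 4),
      " (threshold-optimized, not adjusted)\n")
  cat("  groups: low =", x$group_sizes[["n_low"]],
      " high =", x$group_sizes[["n_high"]],
      " horizon =", x$horizon, "\n")
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  plot(x$grid$threshold, -log10(x$grid$p_value), type = "l",
       xlab = "cohesion-score threshold", ylab = "-log10 log-rank p", ...)
  abline(v = x$best_threshold, lty = 2)
  invisible(x)
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time`, `event` (1 = event, 0 = censored).
#'
#' @param path File path.
#' @return Data frame with validated columns.
#' @export
read_survival <- function(path) {
  sv <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time", "event") %in% names(sv)))
  if (anyDuplicated(sv$sample_id)) stop("duplicate sample ids")
  if (any(!is.finite(sv$time) | sv$time <= 0)) stop("times must be finite and positive")
  if (!all(sv$event %in% c(0, 1))) stop("event must be 0/1")
  sv
}
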