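# Bootstrap accuracy / stability suite. Per-replicate seeds are derived from
# the master seed by replicate index, so results are identical however the
# replicates are scheduled.

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

refit_network <- function(values, communities, gamma, n_lambdas,
                          lambda_min_ratio) {
  x <- item_matrix(values, communities = communities)
  estimate_network(spearman_matrix(x), gamma = gamma, n_lambdas = n_lambdas,
                   lambda_min_ratio = lambda_min_ratio)
}

#' Nonparametric bootstrap of the whole network pipeline
#'
#' Resamples subjects with replacement, reruns Spearman correlation, PSD
#' repair, the graphical lasso path and EBIC selection on every resample,
#' and stores per-replicate edge weights, expected influences and bridge
#' expected influences. This replicate store feeds [edge_ci()] and
#' [difference_tests()]. Replicates whose resample is degenerate (e.g. a
#' constant item) are dropped and counted; more than `max_fail_prop` failures
#' abort.
#'
#' @param responses An `item_matrix`.
#' @param nboots Number of bootstrap resamples (default 2000).
#' @param seed Master seed; every replicate's seed derives from it.
#' @param gamma,n_lambdas,lambda_min_ratio Estimation settings passed through
#'   to [estimate_network()].
#' @param max_fail_prop Maximum tolerated proportion of failed resamples.
#' @return A `network_boot`: point-estimate network, matrices of replicate
#'   edge weights (`edges`, resamples x pairs), `ei` and `bei`
#'   (resamples x nodes), pair labels, failure count.
#' @export
bootstrap_network <- function(responses, nboots = 2000L, seed = 1L,
                              gamma = 0.5, n_lambdas = 100L,
                              lambda_min_ratio = 0.01,
                              max_fail_prop = 0.1) {
  stopifnot(inherits(responses, "item_matrix"), nboots >= 100L)
  point <- refit_network(responses$values, responses$communities, gamma,
                         n_lambdas, lambda_min_ratio)
  n <- nrow(responses$values)
  p <- length(point$labels)
  ut <- upper.tri(point$W)
  pair_idx <- which(ut, arr.ind = TRUE)
  pairs <- paste(point$labels[pair_idx[, 1]], point$labels[pair_idx[, 2]],
                 sep = "--")
  seeds <- derive_seeds(seed, nboots)
  edges <- matrix(NA_real_, nboots, length(pairs),
                  dimnames = list(NULL, pairs))
  ei <- bei <- matrix(NA_real_, nboots, p, dimnames = list(NULL, point$labels))
  failures <- 0L
  for (b in seq_len(nboots)) {
    set.seed(seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    net_b <- tryCatch(
      refit_network(responses$values[idx, , drop = FALSE],
                    responses$communities, gamma, n_lambdas,
                    lambda_min_ratio),
      error = function(e) NULL)
    if (is.null(net_b)) { failures <- failures + 1L; next }
    edges[b, ] <- net_b$W[ut]
    ei[b, ] <- expected_influence(net_b)
    bei[b, ] <- bridge_expected_influence(net_b)
  }
  if (failures > max_fail_prop * nboots) {
    stop(failures, "/", nboots, " bootstrap resamples failed", call. = FALSE)
  }
  ok <- !is.na(edges[, 1])
  structure(list(point = point,
                 edges = edges[ok, , drop = FALSE],
                 ei = ei[ok, , drop = FALSE],
                 bei = bei[ok, , drop = FALSE],
                 pairs = pairs, nboots = nboots, n_failed = failures,
                 seed = seed),
            class = "network_boot")
}

#' @export
print.network_boot <- function(x, ...) {
  cat("<network_boot> ", nrow(x$edges), "/", x$nboots,
      " successful resamples over ", length(x$pairs), " edge pairs\n",
      sep = "")
  invisible(x)
}

#' Percentile bootstrap confidence intervals for edge weights
#'
#' Quantile (percentile) intervals across the replicate store; the point
#' estimate comes from the full sample, the bounds from the 2.5/97.5 (for
#' `level = 0.95`) quantiles of the bootstrap distribution of each edge.
#'
#' @param boot A `network_boot` from [bootstrap_network()].
#' @param level Confidence level (default 0.95).
#' @return Data frame: from, to, estimate, boot_mean, lower, upper, with
#'   attributes `nboots` and `method = "percentile"`.
#' @export
edge_ci <- function(boot, level = 0.95) {
  stopifnot(inherits(boot, "network_boot"))
  a <- (1 - level) / 2
  est <- boot$point$W[upper.tri(boot$point$W)]
  qs <- apply(boot$edges, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  parts <- strsplit(boot$pairs, "--", fixed = TRUE)
  out <- data.frame(
    from = vapply(parts, `[`, "", 1L), to = vapply(parts, `[`, "", 2L),
    estimate = est, boot_mean = colMeans(boot$edges),
    lower = qs[1, ], upper = qs[2, ], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "nboots") <- boot$nboots
  attr(out, "method") <- "percentile"
  attr(out, "level") <- level
  out
}

#' Case-dropping correlation stability (CS) coefficient
#'
#' For each drop proportion, repeatedly removes `floor(prop * n)` subjects
#' without replacement, re-estimates the network and the chosen centrality,
#' and correlates it (Pearson, across nodes) with the full-sample
#' centrality. The CS coefficient is the largest proportion at which the
#' correlation reaches `threshold` in at least `confidence` of the
#' resamples; 0 if none. CS of at least 0.25 is the usual minimum for
#' interpretable centrality orderings, 0.5 indicates good stability.
#'
#' @param responses An `item_matrix`.
#' @param metric `"expected_influence"` or `"bridge_expected_influence"`.
#' @param drop_proportions Proportions examined (default 0.05 to 0.75 by
#'   0.05).
#' @param nboots Resamples per proportion (default 2000; reducible).
#' @param seed Master seed.
#' @param threshold Correlation threshold (default 0.7).
#' @param confidence Required fraction of resamples meeting the threshold
#'   (default 0.95).
#' @param gamma,n_lambdas,lambda_min_ratio Estimation settings.
#' @return A `cs_report`: `cs`, `metric`, a `curve` data frame with the
#'   per-proportion mean correlation and the fraction of resamples at or
#'   above the threshold, and the raw correlation matrix `correlations`
#'   (resamples x proportions).
#' @export
cs_coefficient <- function(responses,
                           metric = c("expected_influence",
                                      "bridge_expected_influence"),
                           drop_proportions = seq(0.05, 0.75, by = 0.05),
                           nboots = 2000L, seed = 1L, threshold = 0.7,
                           confidence = 0.95, gamma = 0.5,
                           n_lambdas = 100L, lambda_min_ratio = 0.01) {
  stopifnot(inherits(responses, "item_matrix"))
  metric <- match.arg(metric)
  metric_fun <- switch(metric,
                       expected_influence = expected_influence,
                       bridge_expected_influence = bridge_expected_influence)
  full <- metric_fun(refit_network(responses$values, responses$communities,
                                   gamma, n_lambdas, lambda_min_ratio))
  if (sd(full) == 0) {
    stop("full-sample ", metric, " is constant; stability correlation ",
         "undefined", call. = FALSE)
  }
  n <- nrow(responses$values)
  seeds <- derive_seeds(seed, nboots * length(drop_proportions))
  cors <- matrix(NA_real_, nboots, length(drop_proportions),
                 dimnames = list(NULL, paste0("drop_", drop_proportions)))
  for (j in seq_along(drop_proportions)) {
    keep_n <- n - floor(drop_proportions[j] * n)
    if (keep_n < length(full) + 1L) next
    for (b in seq_len(nboots)) {
      set.seed(seeds[(j - 1L) * nboots + b])
      idx <- sample.int(n, keep_n, replace = FALSE)
      m <- tryCatch(
        metric_fun(refit_network(responses$values[idx, , drop = FALSE],
                                 responses$communities, gamma, n_lambdas,
                                 lambda_min_ratio)),
        error = function(e) NULL)
      if (is.null(m) || sd(m) == 0) next
      cors[b, j] <- cor(m, full)
    }
  }
  prop_ok <- colMeans(cors >= threshold, na.rm = TRUE)
  prop_ok[colSums(!is.na(cors)) == 0] <- NA_real_
  meets <- !is.na(prop_ok) & prop_ok >= confidence
  cs <- if (any(meets)) max(drop_proportions[meets]) else 0
  structure(list(
    cs = cs, metric = metric, threshold = threshold, confidence = confidence,
    curve = data.frame(proportion = drop_proportions,
                       mean_cor = colMeans(cors, na.rm = TRUE),
                       prop_at_threshold = unname(prop_ok)),
    correlations = cors, nboots = nboots, seed = seed),
    class = "cs_report")
}

#' @export
print.cs_report <- function(x, ...) {
  cat("<cs_report> CS(", x$metric, ") = ", x$cs, " (threshold ",
      x$threshold, ", confidence ", x$confidence, ", nboots ", x$nboots,
      ")\n", sep = "")
  invisible(x)
}

#' Recompute a CS coefficient at a different threshold
#'
#' Reuses an existing replicate store, so raising the threshold can be
#' explored without re-estimating anything.
#'
#' @param report A `cs_report`.
#' @param threshold New correlation threshold.
#' @param confidence New confidence level (defaults to the report's).
#' @return The CS value under the new rule.
#' @export
cs_at_threshold <- function(report, threshold,
                            confidence = report$confidence) {
  stopifnot(inherits(report, "cs_report"))
  cors <- report$correlations
  prop_ok <- colMeans(cors >= threshold, na.rm = TRUE)
  prop_ok[colSums(!is.na(cors)) == 0] <- NA_real_
  meets <- !is.na(prop_ok) & prop_ok >= confidence
  if (any(meets)) max(report$curve$proportion[meets]) else 0
}

#' Bootstrapped difference tests
#'
#' For every pair of edges (or nodes, for a centrality metric) the bootstrap
#' distribution of the difference is formed from the replicate store; the
#' pair differs significantly when the (alpha/2, 1 - alpha/2) percentile
#' interval of the difference excludes zero. No multiplicity correction is
#' applied, matching the usual bootstrap-difference procedure for these
#' networks; treat the flags descriptively.
#'
#' @param boot A `network_boot`.
#' @param target `"edges"`, `"expected_influence"`, or
#'   `"bridge_expected_influence"`.
#' @param alpha Significance level (default 0.05).
#' @return A `difference_tests` object: logical `significant` matrix
#'   (symmetric, FALSE diagonal) plus `lower`/`upper` difference CI
#'   matrices and the point estimates.
#' @export
difference_tests <- function(boot,
                             target = c("edges", "expected_influence",
                                        "bridge_expected_influence"),
                             alpha = 0.05) {
  stopifnot(inherits(boot, "network_boot"))
  target <- match.arg(target)
  reps <- switch(target, edges = boot$edges, expected_influence = boot$ei,
                 bridge_expected_influence = boot$bei)
  est <- switch(target,
                edges = setNames(boot$point$W[upper.tri(boot$point$W)],
                                 boot$pairs),
                expected_influence = expected_influence(boot$point),
                bridge_expected_influence =
                  bridge_expected_influence(boot$point))
  k <- ncol(reps)
  labs <- colnames(reps)
  lower <- upper <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  sig <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  probs <- c(alpha / 2, 1 - alpha / 2)
  for (i in seq_len(k - 1L)) {
    d <- reps[, (i + 1L):k, drop = FALSE] - reps[, i]
    q <- apply(d, 2, quantile, probs = probs, names = FALSE)
    j <- (i + 1L):k
    lower[i, j] <- lower[j, i] <- q[1, ]
    upper[i, j] <- upper[j, i] <- q[2, ]
    sig[i, j] <- sig[j, i] <- q[1, ] > 0 | q[2, ] < 0
  }
  structure(list(target = target, alpha = alpha, estimates = est,
                 significant = sig, lower = lower, upper = upper,
                 nboots = nrow(reps)),
            class = "difference_tests")
}

#' @export
print.difference_tests <- function(x, ...) {
  k <- ncol(x$significant)
  n_pairs <- k * (k - 1) / 2
  n_sig <- sum(x$significant[upper.tri(x$significant)])
  cat("<difference_tests> ", x$target, ": ", n_sig, "/", n_pairs,
      " pairs significant at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Share of significant comparisons involving given targets
#'
#' Helper for summaries of the form "the strongest edges differed from x%
#' of the other edges": for each named target, the proportion of its
#' pairwise comparisons flagged significant.
#'
#' @param tests A `difference_tests` object.
#' @param targets Labels (edge pair names or node names) to summarize.
#' @return Named numeric vector of proportions.
#' @export
significant_share <- function(tests, targets) {
  stopifnot(inherits(tests, "difference_tests"))
  sig <- tests$significant
  missing_t <- setdiff(targets, rownames(sig))
  if (length(missing_t)) {
    stop("unknown targets: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  vapply(targets, function(t) mean(sig[t, colnames(sig) != t]), 0)
}
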