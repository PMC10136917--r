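# Latent-Gaussian threshold generator for two-community ordinal cohorts.
# The estimation stack (Spearman + GGM) assumes monotone-transformable
# Gaussian structure, so a latent GGM discretized by per-item thresholds is
# the generative model under which parameter recovery is a fair check.

#' Default item-level marginal calibration
#'
#' Item means and standard deviations typical of a tinnitus outpatient
#' cohort screened with the PHQ-9 and GAD-7 (0--3 items; note the strong
#' right skew of D9, a rare symptom). Used to calibrate the default
#' discretization thresholds of [generator_spec()].
#'
#' @return Data frame with columns `item`, `mean`, `sd`.
#' @export
default_item_marginals <- function() {
  data.frame(
    item = c(paste0("D", 1:9), paste0("A", 1:7)),
    mean = c(0.99, 0.84, 1.20, 1.15, 0.58, 0.55, 0.78, 0.56, 0.18,
             0.94, 0.77, 0.95, 0.89, 0.52, 0.97, 0.48),
    sd = c(1.01, 0.94, 1.05, 1.03, 0.83, 0.82, 0.92, 0.82, 0.47,
           0.91, 0.90, 0.95, 0.94, 0.80, 0.94, 0.76),
    stringsAsFactors = FALSE)
}

#' Analytic moments of a threshold-discretized standard normal
#'
#' With strictly increasing cut points `t = (t1, t2, t3)` the observed item
#' is `X = #\{k : Z > t_k\}` for latent `Z ~ N(0, 1)`; category
#' probabilities are normal orthant probabilities.
#'
#' @param thresholds Numeric vector of strictly increasing cut points.
#' @return List with `probs` (category probabilities), `mean`, `sd`.
#' @export
discretized_moments <- function(thresholds) {
  stopifnot(all(diff(thresholds) > 0))
  cum <- c(0, pnorm(thresholds), 1)
  probs <- diff(cum)
  k <- seq_along(probs) - 1
  m <- sum(k * probs)
  v <- sum(k^2 * probs) - m^2
  list(probs = probs, mean = m, sd = sqrt(v))
}

#' Calibrate discretization thresholds to target marginals
#'
#' Finds cut points whose discretized-normal mean matches the target
#' closely and whose SD matches approximately (three thresholds cannot hit
#' both exactly in general; the mean is weighted much more heavily).
#'
#' @param target_mean,target_sd Target item mean and SD on the 0--3 scale.
#' @param n_categories Number of ordinal categories (default 4).
#' @return Numeric vector of strictly increasing thresholds.
#' @export
calibrate_thresholds <- function(target_mean, target_sd,
                                 n_categories = 4L) {
  k <- n_categories - 1L
  obj <- function(theta) {
    t <- cumsum(c(theta[1], exp(theta[-1])))
    mm <- discretized_moments(t)
    50 * (mm$mean - target_mean)^2 + (mm$sd - target_sd)^2
  }
  init <- c(qnorm(pmin(pmax(1 - target_mean / k, 0.05), 0.95)),
            rep(log(0.8), k - 1L))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  cumsum(c(fit$par[1], exp(fit$par[-1])))
}

#' Specify a synthetic two-community cohort generator
#'
#' Defaults emulate a depression-anxiety comorbidity screening cohort:
#' 566 subjects, 9 + 7 items on a 0--3 scale, sparse ground-truth partial
#' correlations, three planted bridge symptoms with boosted cross-community
#' edges, and item marginals calibrated to [default_item_marginals()].
#'
#' @param n_subjects Cohort size (default 566).
#' @param communities Named integer vector: items per community.
#' @param within_density Probability of a within-community edge.
#' @param cross_density Probability of a background cross-community edge.
#' @param weight_range Range of absolute partial-correlation weights.
#' @param positive_ratio Probability that an edge weight is positive.
#' @param planted_bridges Item ids given boosted cross edges (their true
#'   bridge expected influence dominates); NULL for none.
#' @param n_bridge_edges Cross edges per planted bridge.
#' @param bridge_weight Weight of each planted cross edge.
#' @param thresholds Optional named list of per-item cut points; calibrated
#'   from `item_marginals` when NULL.
#' @param item_marginals Data frame (item, mean, sd) used for calibration.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A `generator_spec`.
#' @export
generator_spec <- function(n_subjects = 566L,
                           communities = c(depression = 9L, anxiety = 7L),
                           within_density = 0.35, cross_density = 0.04,
                           weight_range = c(0.10, 0.30),
                           positive_ratio = 0.9,
                           planted_bridges = c("A7", "D6", "D7"),
                           n_bridge_edges = 3L, bridge_weight = 0.18,
                           thresholds = NULL,
                           item_marginals = default_item_marginals(),
                           seed = 1L) {
  stopifnot(n_subjects >= 2, length(communities) >= 2,
            all(communities >= 2),
            within_density >= 0, within_density <= 1,
            cross_density >= 0, cross_density <= 1,
            length(weight_range) == 2, weight_range[1] <= weight_range[2],
            weight_range[1] >= 0)
  default_shape <- identical(unname(communities), c(9L, 7L)) &&
    identical(names(communities), c("depression", "anxiety"))
  items <- if (default_shape) {
    c(paste0("D", 1:9), paste0("A", 1:7))
  } else {
    unlist(lapply(names(communities),
                  function(nm) paste0(nm, seq_len(communities[[nm]]))))
  }
  comm <- rep(names(communities), communities)
  names(comm) <- items
  if (!is.null(planted_bridges)) {
    bad <- setdiff(planted_bridges, items)
    if (length(bad)) stop("planted bridges not among items: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- lapply(items, function(it) {
      row <- match(it, item_marginals$item)
      if (is.na(row)) calibrate_thresholds(0.8, 0.9)
      else calibrate_thresholds(item_marginals$mean[row],
                                item_marginals$sd[row])
    })
    names(thresholds) <- items
  }
  stopifnot(setequal(names(thresholds), items),
            all(vapply(thresholds, function(t) all(diff(t) > 0), TRUE)))
  structure(list(n_subjects = as.integer(n_subjects),
                 communities = comm, items = items,
                 within_density = within_density,
                 cross_density = cross_density,
                 weight_range = weight_range,
                 positive_ratio = positive_ratio,
                 planted_bridges = planted_bridges,
                 n_bridge_edges = as.integer(n_bridge_edges),
                 bridge_weight = bridge_weight,
                 thresholds = thresholds[items],
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("<generator_spec> ", x$n_subjects, " subjects x ", length(x$items),
      " items (", paste(names(table(x$communities)), table(x$communities),
                        sep = ": ", collapse = ", "),
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Build the ground-truth network of a generator spec
#'
#' Samples the sparsity pattern block-wise (within/cross densities plus the
#' planted bridge edges), assigns signed weights, and enforces positive
#' definiteness of the implied precision matrix by uniformly shrinking the
#' off-diagonal until the smallest eigenvalue clears 0.05 (partial
#' correlations shrink by the same factor, so the pattern is preserved).
#'
#' @param spec A [generator_spec()].
#' @return A `truth_network`: precision `K`, partial-correlation matrix `W`,
#'   standardized latent covariance `Sigma`, `communities`, true bridge
#'   nodes, true bridge expected influence, and per-node analytic
#'   predictability (`1 - 1/K_ii` of the standardized precision).
#' @export
make_truth_network <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  seeds <- derive_seeds(spec$seed, 2L)
  set.seed(seeds[1])
  items <- spec$items
  p <- length(items)
  comm <- spec$communities
  W0 <- matrix(0, p, p, dimnames = list(items, items))

  draw_weight <- function(n) {
    runif(n, spec$weight_range[1], spec$weight_range[2]) *
      ifelse(runif(n) < spec$positive_ratio, 1, -1)
  }
  ut <- which(upper.tri(W0), arr.ind = TRUE)
  same <- comm[ut[, 1]] == comm[ut[, 2]]
  keep_within <- same & runif(nrow(ut)) < spec$within_density
  keep_cross <- !same & runif(nrow(ut)) < spec$cross_density
  keep <- keep_within | keep_cross
  W0[ut[keep, , drop = FALSE]] <- draw_weight(sum(keep))

  # planted bridges: balanced partner assignment (least-used partners first)
  # so no single partner accumulates several planted edges
  used <- setNames(rep(0L, p), items)
  planted_edge <- matrix(FALSE, p, p, dimnames = list(items, items))
  for (b in spec$planted_bridges) {
    others <- items[comm != comm[b]]
    ord <- others[order(used[others], runif(length(others)))]
    partners <- ord[seq_len(min(spec$n_bridge_edges, length(others)))]
    used[partners] <- used[partners] + 1L
    W0[b, partners] <- spec$bridge_weight
    W0[partners, b] <- spec$bridge_weight
    planted_edge[b, partners] <- TRUE
    planted_edge[partners, b] <- TRUE
  }
  W0[lower.tri(W0)] <- t(W0)[lower.tri(W0)]

  # contract: planted bridges carry the maximal true bridge expected
  # influence, with enough separation that recovery failures reflect the
  # estimation method rather than truth-level near-ties. Background cross
  # edges of any competing node are shrunk until every non-planted node
  # sits below 60% of the weakest planted bridge (planted edges themselves
  # are never touched).
  if (length(spec$planted_bridges)) {
    cross <- outer(comm, comm, FUN = `!=`)
    is_planted <- items %in% spec$planted_bridges
    for (pass in 1:50) {
      bei0 <- rowSums(W0 * cross)
      lim <- 0.6 * min(bei0[spec$planted_bridges])
      offenders <- setdiff(items[bei0 > lim], spec$planted_bridges)
      drags <- cross & !planted_edge & W0 < -1e-4 &
        outer(is_planted, is_planted, `|`)
      if (!length(offenders) && !any(drags)) break
      if (pass == 50L) stop("planted bridges cannot dominate the true ",
                            "bridge influence; lower cross_density",
                            call. = FALSE)
      off <- items %in% offenders
      scale_mask <- (cross & !planted_edge & outer(off, off, `|`)) | drags
      w <- W0[scale_mask] * 0.7
      W0[scale_mask] <- ifelse(abs(w) < 1e-4, 0, w)
    }
  }

  K <- diag(p) - W0 # precision off-diagonals are minus the partials
  dimnames(K) <- list(items, items)
  for (i in 1:100) {
    if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) >= 0.05)
      break
    K[row(K) != col(K)] <- K[row(K) != col(K)] * 0.9
    if (i == 100) stop("could not reach positive definiteness", call. = FALSE)
  }
  Sigma <- solve(K)
  Sigma <- Sigma / tcrossprod(sqrt(diag(Sigma)))
  Sigma <- (Sigma + t(Sigma)) / 2
  Kstd <- solve(Sigma)
  W <- precision_to_partial(K)
  net <- symptom_network(W, communities = comm, n = NA_integer_)
  bei <- bridge_expected_influence(net)
  bridges <- if (!is.null(spec$planted_bridges)) spec$planted_bridges
             else if (any(bei != 0)) select_bridges(bei) else character(0)
  structure(list(K = K, W = W, Sigma = Sigma, communities = comm,
                 bridges = bridges, bei = bei,
                 predictability = setNames(1 - 1 / diag(Kstd), items)),
            class = "truth_network")
}

#' Sample an ordinal cohort from a generator spec
#'
#' Draws latent multivariate-normal vectors with the truth network's
#' standardized covariance and discretizes each item by its thresholds into
#' `0..3` (or however many categories the thresholds imply).
#'
#' @param spec A [generator_spec()].
#' @return A `synthetic_cohort`: `responses` (an `item_matrix`), `truth`
#'   (the [make_truth_network()] output), and the `spec`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  truth <- make_truth_network(spec)
  seeds <- derive_seeds(spec$seed, 2L)
  set.seed(seeds[2])
  Z <- MASS::mvrnorm(spec$n_subjects, mu = rep(0, length(spec$items)),
                     Sigma = truth$Sigma)
  X <- vapply(seq_along(spec$items),
              function(i) findInterval(Z[, i], spec$thresholds[[i]]),
              numeric(spec$n_subjects))
  colnames(X) <- spec$items
  rownames(X) <- sprintf("S%04d", seq_len(spec$n_subjects))
  structure(list(responses = item_matrix(X, communities = spec$communities),
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ")
  print(x$responses)
  invisible(x)
}

#' Compare an estimated network with the generating truth
#'
#' Edge-pattern sensitivity and specificity, weight RMSE, bridge
#' identification hit rate (percentile rule on the estimated bridge
#' expected influence vs the true bridge nodes), and the Spearman rank
#' correlation of estimated with true expected influence.
#'
#' @param cohort A `synthetic_cohort` (or `truth_network`).
#' @param estimated A `symptom_network` on the same labels.
#' @param min_weight Only true edges with `|weight| >= min_weight` count
#'   toward sensitivity (default 0: all true edges).
#' @param percentile Bridge-selection percentile (default 80).
#' @return List of recovery metrics.
#' @export
recovery_report <- function(cohort, estimated, min_weight = 0,
                            percentile = 80) {
  truth <- if (inherits(cohort, "synthetic_cohort")) cohort$truth else cohort
  stopifnot(inherits(truth, "truth_network"),
            inherits(estimated, "symptom_network"))
  if (!setequal(rownames(truth$W), estimated$labels)) {
    stop("truth and estimate have different node labels", call. = FALSE)
  }
  Wt <- truth$W[estimated$labels, estimated$labels]
  We <- estimated$W
  ut <- upper.tri(Wt)
  true_edge <- abs(Wt[ut]) > 1e-10
  est_edge <- We[ut] != 0
  strong <- abs(Wt[ut]) >= min_weight
  sens_den <- sum(true_edge & strong)
  spec_den <- sum(!true_edge)
  sel <- select_bridges(bridge_expected_influence(estimated), percentile)
  list(
    sensitivity = if (sens_den) sum(est_edge & true_edge & strong) / sens_den
                  else NA_real_,
    specificity = if (spec_den) sum(!est_edge & !true_edge) / spec_den
                  else NA_real_,
    rmse = sqrt(mean((We[ut] - Wt[ut])^2)),
    bridge_hit_rate = if (length(truth$bridges))
      mean(truth$bridges %in% sel) else NA_real_,
    ei_rank_cor = {
      ei_e <- expected_influence(estimated)
      ei_t <- rowSums(Wt)
      if (sd(ei_e) == 0 || sd(ei_t) == 0) NA_real_
      else cor(ei_e, ei_t, method = "spearman")
    },
    n_true_edges = sum(true_edge), n_estimated_edges = sum(est_edge))
}

#' Export a synthetic cohort as plain-text files
#'
#' Writes `cohort.csv` (one subject per row, item columns, ready for
#' [validate_responses()]) and `truth.json` (the generating partial
#' correlations as an edge list plus communities, bridge nodes and analytic
#' predictability) into a directory.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "cohort.csv")
  df <- data.frame(subject = rownames(cohort$responses$values),
                   cohort$responses$values, check.names = FALSE)
  write.csv(df, csv, row.names = FALSE)
  truth <- cohort$truth
  net <- symptom_network(truth$W, communities = truth$communities)
  js <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(edges = edge_list(net),
         communities = as.list(truth$communities),
         bridges = truth$bridges,
         bei = as.list(truth$bei),
         predictability = as.list(truth$predictability),
         seed = cohort$spec$seed),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}
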