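#' Graphical lasso fit at a single penalty
#'
#' Maximizes `log det K - trace(R K) - lambda * sum_{i != j} |K_ij|` (the
#' diagonal is unpenalized) by block coordinate descent. At `lambda = 0` on
#' a positive definite input this is the plain inverse.
#'
#' @param R A `cor_matrix` (PSD; run [nearest_psd()] first if unsure) or a
#'   plain symmetric matrix.
#' @param lambda Nonnegative penalty.
#' @param tol Convergence tolerance on the working covariance (default 1e-6).
#' @param maxit Maximum outer sweeps.
#' @return Symmetric positive definite precision matrix `K`.
#' @export
glasso_fit <- function(R, lambda, tol = 1e-6, maxit = 1000L) {
  S <- if (inherits(R, "cor_matrix")) R$R else as.matrix(R)
  stopifnot(lambda >= 0)
  fit <- .glasso_cpp(S, lambda, tol = tol, maxit = maxit)
  if (!fit$converged) {
    stop("graphical lasso did not converge at lambda = ",
         signif(lambda, 4), call. = FALSE)
  }
  K <- fit$K
  dimnames(K) <- dimnames(S)
  K
}

#' Convert a precision matrix to partial correlations
#'
#' `W_ij = -K_ij / sqrt(K_ii K_jj)` off the diagonal, zero on it. Signs flip
#' relative to the precision entries; entries of a positive definite `K` lie
#' strictly inside (-1, 1).
#'
#' @param K Symmetric precision matrix with positive diagonal.
#' @return Partial-correlation matrix `W` with zero diagonal.
#' @export
precision_to_partial <- function(K) {
  K <- as.matrix(K)
  if (any(diag(K) <= 0)) stop("precision matrix has nonpositive diagonal",
                              call. = FALSE)
  d <- sqrt(diag(K))
  W <- -K / tcrossprod(d)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

#' Extended BIC of a fitted precision matrix
#'
#' `EBIC = -2 l + E log n + 4 E gamma log p` where
#' `l = (n/2)(log det K - trace(R K))`, `E` counts nonzero upper-triangle
#' off-diagonals of `K` (|K_ij| > 1e-8, screening out solver-level zeros)
#' and `p` is the number of nodes.
#'
#' @param K Precision matrix (positive definite).
#' @param R A `cor_matrix` or plain matrix used for the likelihood.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter; 0.5 balances sensitivity/specificity.
#' @return List with `ebic`, `loglik`, `n_edges`.
#' @export
ebic_score <- function(K, R, n, gamma = 0.5) {
  S <- if (inherits(R, "cor_matrix")) R$R else as.matrix(R)
  p <- nrow(S)
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) stop("precision matrix is not positive definite",
                         call. = FALSE)
  loglik <- (n / 2) * (as.numeric(ld$modulus) - sum(S * K))
  E <- sum(abs(K[upper.tri(K)]) > 1e-8)
  list(ebic = -2 * loglik + E * log(n) + 4 * E * gamma * log(p),
       loglik = loglik, n_edges = E)
}

#' Log-spaced penalty path
#'
#' From `lambda_max` (the largest off-diagonal |R|, where the graph is
#' empty) down to `lambda_max * lambda_min_ratio`.
#'
#' @param R A `cor_matrix` or matrix.
#' @param n_lambdas Path length (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest penalty.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(R, n_lambdas = 100L, lambda_min_ratio = 0.01) {
  S <- if (inherits(R, "cor_matrix")) R$R else as.matrix(R)
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) lmax <- lambda_min_ratio # degenerate: identity input
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambdas))
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso along a log-spaced penalty path (warm starts)
#' and selects the penalty minimizing the EBIC at hyperparameter `gamma`.
#' The selected precision matrix is converted to the partial-correlation
#' edge-weight matrix `W`.
#'
#' @param R A `cor_matrix` with sample size `n` (PSD repair is applied
#'   automatically), or an `item_matrix`, in which case the Spearman matrix
#'   is computed first.
#' @param gamma EBIC hyperparameter, default 0.5.
#' @param n_lambdas,lambda_min_ratio Penalty-path settings.
#' @param communities Optional named community map (defaults to the one
#'   carried by the input).
#' @return A `symptom_network`: weight matrix `W` (zero diagonal), node
#'   `labels` and `communities`, `lambda_selected`, `gamma`, `n`, the
#'   selected precision matrix `K`, and a `path` data frame with per-lambda
#'   edge counts, log-likelihoods and EBICs.
#' @export
estimate_network <- function(R, gamma = 0.5, n_lambdas = 100L,
                             lambda_min_ratio = 0.01, communities = NULL) {
  if (inherits(R, "item_matrix")) R <- spearman_matrix(R)
  stopifnot(inherits(R, "cor_matrix"))
  if (is.null(communities)) communities <- R$communities
  if (is.na(R$n) || R$n < length(R$labels) + 1L) {
    stop("sample size n must exceed the number of nodes", call. = FALSE)
  }
  R <- nearest_psd(R)
  lambdas <- lambda_path(R, n_lambdas, lambda_min_ratio)
  fits <- .glasso_path_cpp(R$R, lambdas)
  if (!any(fits$converged)) {
    stop("graphical lasso failed to converge at every penalty", call. = FALSE)
  }
  scores <- vector("list", length(lambdas))
  for (l in seq_along(lambdas)) {
    if (!fits$converged[l]) next
    scores[[l]] <- ebic_score(fits$K[, , l], R, n = R$n, gamma = gamma)
  }
  ok <- !vapply(scores, is.null, TRUE)
  path <- data.frame(
    lambda = lambdas,
    n_edges = NA_integer_, loglik = NA_real_, ebic = NA_real_,
    converged = as.logical(fits$converged))
  path$n_edges[ok] <- vapply(scores[ok], `[[`, 0L, "n_edges")
  path$loglik[ok] <- vapply(scores[ok], `[[`, 0, "loglik")
  path$ebic[ok] <- vapply(scores[ok], `[[`, 0, "ebic")
  best <- which.min(path$ebic)
  K <- fits$K[, , best]
  dimnames(K) <- dimnames(R$R)
  W <- precision_to_partial(K)
  # solver-level numerical zeros are true zeros
  W[abs(W) < 1e-8] <- 0
  symptom_network(W, communities = communities,
                  lambda_selected = lambdas[best], gamma = gamma, n = R$n,
                  K = K, path = path)
}

#' Construct a symptom-network object
#'
#' @param W Symmetric partial-correlation weight matrix, zero diagonal,
#'   entries in (-1, 1), labels in `dimnames`.
#' @param communities Named community map over the labels (may be NULL for
#'   networks without a community structure).
#' @param lambda_selected,gamma,n,K,path Estimation metadata (optional for
#'   hand-built toy networks).
#' @return A `symptom_network`.
#' @export
symptom_network <- function(W, communities = NULL, lambda_selected = NA_real_,
                            gamma = NA_real_, n = NA_integer_, K = NULL,
                            path = NULL) {
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric", call. = FALSE)
  if (max(abs(diag(W))) > 1e-12) stop("W must have zero diagonal",
                                      call. = FALSE)
  if (any(abs(W) >= 1)) stop("edge weights must lie in (-1, 1)",
                             call. = FALSE)
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- paste0("V", seq_len(nrow(W)))
  }
  if (!is.null(communities)) {
    if (!setequal(names(communities), rownames(W))) {
      stop("communities must name exactly the nodes", call. = FALSE)
    }
    communities <- communities[rownames(W)]
  }
  structure(list(W = W, labels = rownames(W), communities = communities,
                 lambda_selected = lambda_selected, gamma = gamma,
                 n = as.integer(n), K = K, path = path),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  p <- length(x$labels)
  cat("<symptom_network> ", p, " nodes, ", n_edges(x), "/", n_possible_edges(x),
      " edges", sep = "")
  if (!is.na(x$lambda_selected)) {
    cat(" (lambda = ", signif(x$lambda_selected, 3), ", EBIC gamma = ",
        x$gamma, ", n = ", x$n, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Edge counts of a network
#'
#' `n_possible_edges()` is `p(p-1)/2`; `n_edges()` counts nonzero weights.
#'
#' @param net A `symptom_network`.
#' @return Integer count.
#' @export
n_possible_edges <- function(net) {
  p <- length(net$labels)
  as.integer(p * (p - 1) / 2)
}

#' @rdname n_possible_edges
#' @export
n_edges <- function(net) {
  as.integer(sum(net$W[upper.tri(net$W)] != 0))
}

#' Long-format edge list of a network
#'
#' @param net A `symptom_network`.
#' @param all Include zero-weight pairs (default FALSE).
#' @return Data frame with columns `from`, `to`, `weight`.
#' @export
edge_list <- function(net, all = FALSE) {
  ut <- which(upper.tri(net$W), arr.ind = TRUE)
  df <- data.frame(from = net$labels[ut[, 1]], to = net$labels[ut[, 2]],
                   weight = net$W[ut], stringsAsFactors = FALSE)
  if (!all) df <- df[df$weight != 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}
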