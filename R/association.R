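#' Spearman rank-correlation matrix of an item response matrix
#'
#' Pairwise Spearman's rho with average-rank tie handling (ties are heavy on
#' 0--3 items, so the convention matters and is fixed here). The sample size
#' and the item community labels are carried along for network estimation.
#'
#' @param responses An `item_matrix` (complete cases by construction).
#' @return An object of class `cor_matrix`: `R` (symmetric, unit diagonal),
#'   `n`, `labels`, `communities`, `method = "spearman"`.
#' @export
spearman_matrix <- function(responses) {
  stopifnot(inherits(responses, "item_matrix"))
  x <- responses$values
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("degenerate item(s) with zero variance: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  R <- cor(x, method = "spearman")
  R <- (R + t(R)) / 2
  diag(R) <- 1
  cor_matrix(R, n = nrow(x), communities = responses$communities,
             method = "spearman")
}

#' Construct a correlation-matrix object
#'
#' @param R Square symmetric matrix with unit diagonal and entries in
#'   \[-1, 1\]; labels taken from `dimnames`.
#' @param n Sample size the matrix was computed from.
#' @param communities Optional named community map over the labels.
#' @param method Correlation method label.
#' @return A `cor_matrix`.
#' @export
cor_matrix <- function(R, n, communities = NULL, method = "spearman") {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("R must be square", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-12) stop("R must be symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-12) stop("R must have unit diagonal",
                                          call. = FALSE)
  if (any(abs(R) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]",
                                    call. = FALSE)
  if (is.null(rownames(R))) {
    rownames(R) <- colnames(R) <- paste0("V", seq_len(nrow(R)))
  }
  if (!is.null(communities)) {
    if (!setequal(names(communities), rownames(R))) {
      stop("communities must name exactly the matrix labels", call. = FALSE)
    }
    communities <- communities[rownames(R)]
  }
  structure(list(R = R, n = as.integer(n), labels = rownames(R),
                 communities = communities, method = method),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat("<cor_matrix> ", length(x$labels), " x ", length(x$labels), " ",
      x$method, " matrix, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Repair a pseudo-correlation matrix to positive semidefiniteness
#'
#' Rank-correlation matrices need not be PSD. Eigenvalues below `floor` are
#' clipped to `floor`, the matrix is reassembled and the diagonal
#' renormalized to one (a minimal, deterministic perturbation). PSD inputs
#' are returned unchanged.
#'
#' @param x A `cor_matrix` (or plain symmetric matrix).
#' @param floor Eigenvalue floor, default 1e-6.
#' @return Repaired object of the same type.
#' @export
nearest_psd <- function(x, floor = 1e-6) {
  R <- if (inherits(x, "cor_matrix")) x$R else as.matrix(x)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= floor) {
    return(x)
  }
  R2 <- R
  # diagonal renormalization can push an eigenvalue back under the floor,
  # so clip-and-renormalize until the floor holds
  for (i in 1:100) {
    e <- eigen(R2, symmetric = TRUE)
    if (min(e$values) >= floor) break
    v <- pmax(e$values, floor * (1 + 1e-3))
    R2 <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    R2 <- (R2 + t(R2)) / 2
    diag(R2) <- 1
  }
  dimnames(R2) <- dimnames(R)
  if (inherits(x, "cor_matrix")) {
    cor_matrix(R2, n = x$n, communities = x$communities, method = x$method)
  } else R2
}

#' Write / read a labeled square correlation matrix as CSV
#'
#' The CSV dialect (header = labels, first column = labels) lets a published
#' correlation table be loaded directly as pipeline input, bypassing raw
#' item data.
#'
#' @param x A `cor_matrix`.
#' @param path Output CSV path.
#' @export
write_correlation_csv <- function(x, path) {
  stopifnot(inherits(x, "cor_matrix"))
  df <- data.frame(item = x$labels, x$R, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation_csv
#' @param n Sample size to attach on read (not stored in the CSV).
#' @param communities Optional community map to attach on read.
#' @export
read_correlation_csv <- function(path, n, communities = NULL) {
  df <- read.csv(path, check.names = FALSE)
  labels <- as.character(df[[1]])
  R <- as.matrix(df[, -1, drop = FALSE])
  rownames(R) <- labels
  R <- (R + t(R)) / 2
  diag(R) <- 1
  cor_matrix(R, n = n, communities = communities)
}
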