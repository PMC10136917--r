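#' Expected influence centrality
#'
#' One-step expected influence: the signed sum of all edge weights incident
#' to each node, `EI_i = sum_j W_ij`. With all-positive edges this equals
#' node strength; negative edges subtract.
#'
#' @param net A `symptom_network`.
#' @return Named numeric vector, one value per node.
#' @export
expected_influence <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  setNames(rowSums(net$W), net$labels)
}

#' Bridge expected influence centrality
#'
#' Signed sum of each node's edges to nodes in *other* communities,
#' `BEI_i = sum_{j : comm(j) != comm(i)} W_ij`. High values flag symptoms
#' likely to transmit activation across disorders.
#'
#' @param net A `symptom_network` whose communities cover all nodes, with at
#'   least two communities.
#' @return Named numeric vector.
#' @export
bridge_expected_influence <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  comm <- net$communities
  if (is.null(comm) || anyNA(comm)) {
    stop("every node needs a community label", call. = FALSE)
  }
  if (length(unique(comm)) < 2L) {
    stop("bridge expected influence needs >= 2 communities", call. = FALSE)
  }
  cross <- outer(comm, comm, FUN = `!=`)
  setNames(rowSums(net$W * cross), net$labels)
}

#' Select bridge symptoms by a percentile cut-off
#'
#' Nodes whose raw bridge expected influence reaches or exceeds the given
#' percentile of the scores. The percentile uses the type-6 linear
#' interpolation convention, whose threshold interpolates strictly between
#' order statistics for distinct scores (so 16 distinct scores at the 80th
#' percentile select exactly 3 nodes). Ties at the threshold are all
#' included, so with all-equal scores every node is selected.
#'
#' @param bei Named numeric vector of bridge scores.
#' @param percentile Percentile cut-off in (0, 100); default 80.
#' @return Character vector of selected node labels.
#' @export
select_bridges <- function(bei, percentile = 80) {
  stopifnot(length(bei) >= 2L)
  thr <- quantile(bei, probs = percentile / 100, type = 6, names = FALSE)
  names(bei)[bei >= thr]
}

#' Z-standardize a centrality vector
#'
#' `(x - mean) / sd` with the sample standard deviation; used for display
#' alongside raw scores.
#'
#' @param values Numeric vector with positive spread.
#' @return Standardized vector (mean 0, sd 1).
#' @export
z_standardize <- function(values) {
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-standardize a constant vector", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Full centrality profile of a network
#'
#' @param net A `symptom_network` with communities.
#' @param percentile Bridge-selection percentile (default 80).
#' @return Data frame: node, community, ei, ei_z, bei, bei_z, is_bridge.
#'   Bridge selection uses the raw (not z-scored) bridge scores. A constant
#'   metric (e.g. all-zero bridge influence in a network without
#'   cross-community edges) gets zero z-scores rather than an error.
#' @export
centrality_profile <- function(net, percentile = 80) {
  ei <- expected_influence(net)
  bei <- bridge_expected_influence(net)
  bridges <- select_bridges(bei, percentile)
  safe_z <- function(v) if (sd(v) == 0) rep(0, length(v)) else
    z_standardize(v)
  data.frame(node = net$labels,
             community = unname(net$communities),
             ei = unname(ei), ei_z = unname(safe_z(ei)),
             bei = unname(bei), bei_z = unname(safe_z(bei)),
             is_bridge = net$labels %in% bridges,
             stringsAsFactors = FALSE)
}

#' Flow decomposition around a focal node
#'
#' Splits the network, as seen from one focal symptom, into the directly
#' connected neighbors (nonzero edge to the focal node, ranked by absolute
#' weight) and indirect nodes layered by unweighted shortest-path hop count
#' through nonzero edges. Nodes with no path to the focal node are reported
#' separately.
#'
#' @param net A `symptom_network`.
#' @param focal Label of the focal node.
#' @return A `flow_decomposition`: `focal`, `direct` data frame
#'   (node, weight), `indirect` data frame (node, layer), `unreachable`.
#' @export
flow_network <- function(net, focal) {
  stopifnot(inherits(net, "symptom_network"))
  if (!focal %in% net$labels) {
    stop("focal node '", focal, "' not in network", call. = FALSE)
  }
  A <- (net$W != 0) * 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  d <- igraph::distances(g, v = focal)[1, ]
  w <- net$W[focal, ]

  direct_nodes <- net$labels[d == 1]
  direct <- data.frame(node = direct_nodes, weight = unname(w[direct_nodes]),
                       stringsAsFactors = FALSE)
  direct <- direct[order(-abs(direct$weight)), , drop = FALSE]
  rownames(direct) <- NULL

  ind <- net$labels[is.finite(d) & d >= 2]
  indirect <- data.frame(node = ind, layer = as.integer(d[ind]),
                         stringsAsFactors = FALSE)
  indirect <- indirect[order(indirect$layer, indirect$node), , drop = FALSE]
  rownames(indirect) <- NULL

  structure(list(focal = focal, direct = direct, indirect = indirect,
                 unreachable = net$labels[!is.finite(d)]),
            class = "flow_decomposition")
}

#' @export
print.flow_decomposition <- function(x, ...) {
  cat("<flow_decomposition> focal ", x$focal, ": ", nrow(x$direct),
      " direct, ", nrow(x$indirect), " indirect", sep = "")
  if (length(x$unreachable)) cat(", ", length(x$unreachable), " unreachable")
  cat("\n")
  invisible(x)
}
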