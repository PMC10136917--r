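# Export helpers. All writers are deterministic given their inputs
# (no timestamps), so identically configured runs produce identical bytes.

#' Write a network as a weighted edge-list CSV
#'
#' @param net A `symptom_network`.
#' @param path Output path.
#' @param all Include zero-weight pairs (default FALSE).
#' @export
write_edge_list <- function(net, path, all = FALSE) {
  write.csv(edge_list(net, all = all), path, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML with a community node attribute
#'
#' @param net A `symptom_network`.
#' @param path Output path.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(net$communities)) {
    igraph::V(g)$community <- unname(net$communities[igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a network and its penalty-path diagnostics as JSON
#'
#' @param net A `symptom_network`.
#' @param path Output path.
#' @export
write_network_json <- function(net, path) {
  payload <- list(
    labels = net$labels,
    communities = as.list(net$communities),
    edges = edge_list(net),
    lambda_selected = net$lambda_selected,
    ebic_gamma = net$gamma,
    n = net$n,
    n_edges = n_edges(net),
    n_possible_edges = n_possible_edges(net),
    path = net$path)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write the centrality (and optionally predictability) table as CSV
#'
#' @param net A `symptom_network`.
#' @param path Output path.
#' @param predictability Optional `predictability_profile` whose `r2` column
#'   is appended.
#' @param percentile Bridge-selection percentile.
#' @export
write_centrality_csv <- function(net, path, predictability = NULL,
                                 percentile = 80) {
  tab <- centrality_profile(net, percentile = percentile)
  if (!is.null(predictability)) {
    tab$predictability <-
      predictability$nodes$r2[match(tab$node, predictability$nodes$node)]
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a flow decomposition as JSON
#'
#' @param flow A `flow_decomposition`.
#' @param path Output path.
#' @export
write_flow_json <- function(flow, path) {
  jsonlite::write_json(
    list(focal = flow$focal, direct = flow$direct,
         indirect = flow$indirect, unreachable = flow$unreachable),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
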