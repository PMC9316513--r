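#' Shortest-path edge distances of a weighted network
#'
#' Converts edge weights to travel costs by the reciprocal-magnitude rule
#' `d_ij = 1 / |w_ij|` (absent edges are infinitely far; the diagonal is
#' zero). Stronger associations, of either sign, are shorter.
#'
#' @param net A `pcor_network`.
#' @return A p x p matrix of direct-edge distances.
#' @export
edge_distances <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  D <- 1 / abs(net$weights)      # |w| = 0 -> Inf
  diag(D) <- 0
  D
}

#' Node strength
#'
#' Sum of absolute edge weights incident to each node: the node's total
#' level of involvement in the network, regardless of edge sign.
#'
#' @param net A `pcor_network`.
#' @return Named numeric vector.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  rowSums(abs(net$weights))
}

shortest_path_matrix <- function(net) {
  g <- as_igraph(net)
  D <- igraph::distances(g, weights = igraph::E(g)$distance)
  D[net$labels, net$labels, drop = FALSE]
}

closeness_from_graph <- function(g, labels) {
  D <- igraph::distances(g, weights = igraph::E(g)$distance)
  D <- D[labels, labels, drop = FALSE]
  out <- vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  stats::setNames(out, labels)
}

betweenness_from_graph <- function(g, labels) {
  p <- length(labels)
  if (p < 3) return(stats::setNames(rep(0, p), labels))
  b <- igraph::betweenness(g, weights = igraph::E(g)$distance,
                           directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(b[labels]) / ((p - 1) * (p - 2) / 2), labels)
}

#' Closeness centrality
#'
#' Inverse of the summed shortest-path distances from a node to every
#' other node, with shortest paths computed by Dijkstra on the
#' reciprocal-magnitude edge distances. Unreachable nodes are excluded
#' from the sum; a node with no reachable neighbors scores 0.
#'
#' @param net A `pcor_network`.
#' @return Named numeric vector.
#' @export
node_closeness <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  closeness_from_graph(as_igraph(net), net$labels)
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths that pass through each node
#' (endpoints excluded), with tied shortest paths credited fractionally
#' (Brandes accumulation), normalized by the `(p-1)(p-2)/2` node pairs so
#' the value is a fraction in `[0, 1]`.
#'
#' @param net A `pcor_network`.
#' @return Named numeric vector.
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  betweenness_from_graph(as_igraph(net), net$labels)
}

#' Min-max scaling of a centrality vector
#'
#' Rescales to `[0, 1]` so that 1 marks the most and 0 the least central
#' node; a constant vector maps to all zeros by convention.
#'
#' @param values Numeric vector, length >= 2.
#' @return Scaled vector.
#' @export
scale_minmax <- function(values) {
  if (length(values) < 2) stop("scale_minmax needs at least 2 values")
  rng <- range(values)
  if (rng[1] == rng[2]) return(stats::setNames(rep(0, length(values)),
                                               names(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Centrality table of a network
#'
#' Computes strength, closeness and betweenness per node, raw and min-max
#' scaled (the scaled columns are the report/figure convention where 1 is
#' maximal importance).
#'
#' @param net A `pcor_network`.
#' @return Data frame of class `centrality_table` with columns `node`,
#'   `strength`, `closeness`, `betweenness` and their `_scaled` variants.
#' @export
centrality_table <- function(net) {
  g <- as_igraph(net)
  s <- node_strength(net)
  cl <- closeness_from_graph(g, net$labels)
  b <- betweenness_from_graph(g, net$labels)
  out <- data.frame(
    node = net$labels,
    strength = as.numeric(s),
    closeness = as.numeric(cl),
    betweenness = as.numeric(b),
    strength_scaled = as.numeric(scale_minmax(s)),
    closeness_scaled = as.numeric(scale_minmax(cl)),
    betweenness_scaled = as.numeric(scale_minmax(b)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Write a centrality table as CSV
#' @param tab A [centrality_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centrality_csv <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
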