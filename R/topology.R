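# Network topography statistics, hub/bottleneck backbone extraction, and a
# binomial edge-count enrichment test against a background density.

#' Network topography report
#'
#' Computes the statistics reported by STRING / Cytoscape NetworkAnalyzer
#' style summaries:
#' \itemize{
#'   \item `avg_degree` = 2m/n and `density` = 2m/(n(n-1));
#'   \item `avg_local_clustering`: mean over all nodes of the triangle density
#'     among neighbors, with degree < 2 nodes contributing 0;
#'   \item `diameter`, `radius`, `char_path_length`: hop-count eccentricities
#'     and mean shortest-path length over connected ordered pairs, computed on
#'     the largest connected component (singletons such as an isolated seed
#'     are thereby excluded, matching how finite values are reported for
#'     networks containing singletons);
#'   \item `heterogeneity`: coefficient of variation of the degree
#'     distribution, sd/mean with the population (divide-by-n) variance;
#'   \item `n_components`: connected components, isolated nodes included;
#'   \item per-node `degree` and normalized `betweenness` maps.
#' }
#'
#' @param net a [ppi_network()] with at least 2 nodes.
#' @return a list of class `topology_report`.
#' @export
topology_report <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- n_nodes(net)
  if (n < 2) stop("topology_report needs at least 2 nodes")
  m <- n_edges(net)
  g <- as_igraph(net)
  deg <- igraph::degree(g)

  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  lc[is.na(lc)] <- 0
  names(lc) <- igraph::V(g)$name

  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == giant))
  if (igraph::vcount(sub) > 1) {
    d <- igraph::distances(sub, weights = NA)
    ecc <- apply(d, 1, max)
    diameter <- max(ecc)
    radius <- min(ecc)
    cpl <- mean(d[row(d) != col(d)])
  } else {
    diameter <- 0; radius <- 0; cpl <- 0
  }

  mean_deg <- mean(deg)
  het <- if (mean_deg > 0) sqrt(mean((deg - mean_deg)^2)) / mean_deg else 0
  btw <- if (n >= 3) node_betweenness(net) else
    stats::setNames(rep(0, n), net$nodes)

  structure(list(
    n_nodes = n,
    n_edges = m,
    avg_degree = 2 * m / n,
    density = 2 * m / (n * (n - 1)),
    avg_local_clustering = mean(lc),
    diameter = as.integer(diameter),
    radius = as.integer(radius),
    char_path_length = cpl,
    heterogeneity = het,
    n_components = comp$no,
    degree = as.list(deg[net$nodes]),
    betweenness = as.list(btw[net$nodes])
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<topology_report> %d nodes, %d edges\n",
    "  avg degree %.3f | density %.3f | clustering %.3f\n",
    "  diameter %d | radius %d | CPL %.3f | heterogeneity %.3f | components %d\n"),
    x$n_nodes, x$n_edges, x$avg_degree, x$density, x$avg_local_clustering,
    x$diameter, x$radius, x$char_path_length, x$heterogeneity, x$n_components))
  invisible(x)
}

#' Normalized node betweenness centrality
#'
#' Shortest-path betweenness with even splitting over equal-length paths,
#' normalized by (n-1)(n-2)/2 so the center of a star scores 1. Edge
#' confidences are ignored (paths are hop counts).
#'
#' @param net a [ppi_network()] with at least 3 nodes.
#' @return named numeric vector in \[0,1\].
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (n_nodes(net) < 3) stop("betweenness needs at least 3 nodes")
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA,
                           normalized = TRUE)
  b[net$nodes]
}

#' Extract the hub / non-hub-bottleneck backbone
#'
#' Hubs are the top `n_hubs` nodes by degree (ties broken by betweenness
#' descending, then identifier ascending); non-hub bottlenecks are the top
#' `n_bottlenecks` nodes by betweenness among the remaining nodes (ties by
#' degree descending, then identifier).
#'
#' @param net a [ppi_network()].
#' @param n_hubs number of hubs (default 6).
#' @param n_bottlenecks number of non-hub bottlenecks (default 2).
#' @return a list of class `backbone` with data.frames `hubs` (node, degree)
#'   and `non_hub_bottlenecks` (node, betweenness).
#' @export
extract_backbone <- function(net, n_hubs = 6L, n_bottlenecks = 2L) {
  stopifnot(inherits(net, "ppi_network"),
            n_hubs >= 0, n_bottlenecks >= 0)
  n <- n_nodes(net)
  if (n_hubs + n_bottlenecks > n) {
    stop("n_hubs + n_bottlenecks exceeds the number of nodes")
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g)[net$nodes]
  btw <- if (n >= 3) node_betweenness(net) else
    stats::setNames(rep(0, n), net$nodes)
  ids <- net$nodes
  hub_ord <- order(-deg, -btw, ids)
  hubs <- ids[hub_ord][seq_len(n_hubs)]
  rest <- setdiff(ids, hubs)
  bot_ord <- order(-btw[rest], -deg[rest], rest)
  bots <- rest[bot_ord][seq_len(n_bottlenecks)]
  structure(list(
    hubs = data.frame(node = hubs, degree = unname(deg[hubs]),
                      stringsAsFactors = FALSE),
    non_hub_bottlenecks = data.frame(node = bots,
                                     betweenness = unname(btw[bots]),
                                     stringsAsFactors = FALSE)
  ), class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat("<backbone>\n  hubs:",
      paste(sprintf("%s(%d)", x$hubs$node, x$hubs$degree), collapse = ", "),
      "\n  non-hub bottlenecks:",
      paste(sprintf("%s(%.4f)", x$non_hub_bottlenecks$node,
                    x$non_hub_bottlenecks$betweenness), collapse = ", "),
      "\n")
  invisible(x)
}

#' Edge-count enrichment against a background density
#'
#' Tests whether the network has more edges than expected if each of the
#' C(n,2) node pairs were an edge independently with probability
#' `background_density`. This binomial null approximates (and is documented
#' as an approximation of) database nulls that condition on global degrees.
#' The upper-tail p-value is floored at 1e-16, mirroring the common reporting
#' convention for vanishingly small enrichment p-values.
#'
#' @param net a [ppi_network()].
#' @param background_density probability in (0,1).
#' @return a list of class `edge_enrichment` with `observed`, `expected`, and
#'   `p_value`.
#' @export
edge_enrichment <- function(net, background_density) {
  stopifnot(inherits(net, "ppi_network"), length(background_density) == 1L)
  if (!is.finite(background_density) ||
      background_density <= 0 || background_density >= 1) {
    stop("background_density must lie strictly inside (0, 1)")
  }
  n <- n_nodes(net)
  M <- choose(n, 2)
  observed <- n_edges(net)
  expected <- M * background_density
  p <- pbinom(observed - 1, size = M, prob = background_density,
              lower.tail = FALSE)
  p <- min(max(p, 1e-16), 1)
  structure(list(observed = observed, expected = expected, p_value = p),
            class = "edge_enrichment")
}
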