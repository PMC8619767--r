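# Markov clustering of the weighted network and detection of inter-cluster
# "switch" nodes (nodes with many high-confidence links to seed proteins in
# both of two clusters).

#' MCL parameters
#'
#' @param inflation entrywise power applied after each expansion; > 1.
#'   Granularity control: larger values give more, smaller clusters.
#' @param expansion matrix power per iteration (integer >= 2).
#' @param prune_threshold entries below this are zeroed after each iteration.
#' @param tolerance convergence threshold on the max absolute entry change.
#' @param max_iterations iteration cap.
#' @param self_loop `"max_weight"` (each node gets a self-loop equal to its
#'   maximum incident confidence; isolated nodes get 1) or `"unit"`.
#' @return a list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 3, expansion = 2L, prune_threshold = 1e-5,
                       tolerance = 1e-8, max_iterations = 200L,
                       self_loop = c("max_weight", "unit")) {
  self_loop <- match.arg(self_loop)
  stopifnot(inflation > 1, expansion >= 2, prune_threshold >= 0,
            tolerance > 0, max_iterations >= 1)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 self_loop = self_loop),
            class = "mcl_params")
}

#' Markov clustering (MCL)
#'
#' Builds the confidence-weighted adjacency matrix with self-loops, column
#' normalizes it to a stochastic matrix, and iterates expansion (matrix
#' power), inflation (entrywise power followed by column renormalization),
#' and pruning of entries below `prune_threshold` (followed by
#' renormalization) until the maximum absolute entry change drops below
#' `tolerance` or `max_iterations` is hit. Clusters are the connected
#' components of the graph on the nonzero entries of the limit matrix,
#' numbered 1..n_clusters by decreasing size, ties by smallest member
#' identifier.
#'
#' @param net a [ppi_network()] with at least one node.
#' @param params an [mcl_params()].
#' @return a list of class `ppi_clustering` with `assignment` (named integer
#'   vector node -> cluster id), `n_clusters`, `converged`, `iterations`.
#' @export
mcl <- function(net, params = mcl_params()) {
  stopifnot(inherits(net, "ppi_network"), inherits(params, "mcl_params"))
  nodes <- net$nodes
  n <- length(nodes)
  if (n < 1) stop("mcl needs at least one node")

  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (n_edges(net)) {
    ia <- match(net$edges$node_a, nodes)
    ib <- match(net$edges$node_b, nodes)
    A[cbind(ia, ib)] <- net$edges$confidence
    A[cbind(ib, ia)] <- net$edges$confidence
  }
  loop <- switch(params$self_loop,
                 max_weight = apply(A, 2, max),
                 unit = rep(1, n))
  loop[loop == 0] <- 1  # isolated nodes need a positive self-loop
  diag(A) <- loop

  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    E <- M
    for (i in seq_len(params$expansion - 1L)) E <- E %*% M
    E <- normalize(E ^ params$inflation)
    E[E < params$prune_threshold] <- 0
    cs <- colSums(E)
    dead <- cs == 0  # fully pruned column: park the walker on its own node
    if (any(dead)) {
      E[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    E <- sweep(E, 2, cs, "/")
    delta <- max(abs(E - M))
    M <- E
    if (delta < params$tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("MCL did not converge within %d iterations",
                    params$max_iterations))
  }

  support <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  groups <- split(nodes, comp$membership)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, min, character(1)))
  assignment <- integer(n)
  names(assignment) <- nodes
  for (i in seq_along(ord)) assignment[groups[[ord[i]]]] <- i
  structure(list(assignment = assignment,
                 n_clusters = length(groups),
                 converged = converged,
                 iterations = iter),
            class = "ppi_clustering")
}

#' @export
print.ppi_clustering <- function(x, ...) {
  cat(sprintf("<ppi_clustering> %d clusters over %d nodes (%s after %d iterations)\n",
              x$n_clusters, length(x$assignment),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Members of a cluster
#' @param clustering a `ppi_clustering`.
#' @param cluster_id cluster number.
#' @return character vector of node identifiers.
#' @export
cluster_members <- function(clustering, cluster_id) {
  names(clustering$assignment)[clustering$assignment == cluster_id]
}

#' Detect inter-cluster switch nodes
#'
#' For every node v, counts the seed members of `cluster_a` and of
#' `cluster_b` (excluding v itself) connected to v with confidence strictly
#' greater than `tau`. The switch score is the minimum of the two counts — a
#' switch must talk to seeds in both clusters. The same counts recomputed at
#' the 0.7 and 0.9 confidence tiers are reported as supplementary columns.
#' Nodes are ranked by score descending, then total seed connections
#' descending, then identifier.
#'
#' @param net a [ppi_network()].
#' @param clustering a `ppi_clustering` of `net`.
#' @param seeds a [seed_set()]; only seed members count as connection partners.
#' @param cluster_a,cluster_b distinct cluster ids.
#' @param tau confidence threshold in \[0,1\]; connections must exceed it
#'   strictly.
#' @param top_k how many top switches to flag.
#' @return a list of class `switch_report` with `table` (one row per node),
#'   `top_switches`, and `threshold`.
#' @export
find_switches <- function(net, clustering, seeds, cluster_a, cluster_b,
                          tau = 0.4, top_k = 2L) {
  stopifnot(inherits(net, "ppi_network"), inherits(clustering, "ppi_clustering"),
            inherits(seeds, "seed_set"), tau >= 0, tau <= 1)
  if (cluster_a == cluster_b) stop("cluster_a and cluster_b must differ")
  if (!all(c(cluster_a, cluster_b) %in% clustering$assignment)) {
    stop("unknown cluster id(s)")
  }
  seeds_a <- intersect(cluster_members(clustering, cluster_a), seeds$members)
  seeds_b <- intersect(cluster_members(clustering, cluster_b), seeds$members)
  ed <- net$edges
  count_links <- function(v, targets, thr) {
    t2 <- setdiff(targets, v)
    sum((ed$node_a == v & ed$node_b %in% t2 |
         ed$node_b == v & ed$node_a %in% t2) & ed$confidence > thr)
  }
  rows <- lapply(net$nodes, function(v) {
    ca <- count_links(v, seeds_a, tau)
    cb <- count_links(v, seeds_b, tau)
    data.frame(node = v,
               connections_to_clusterA_seeds = ca,
               connections_to_clusterB_seeds = cb,
               switch_score = min(ca, cb),
               conn_a_0.7 = count_links(v, seeds_a, 0.7),
               conn_b_0.7 = count_links(v, seeds_b, 0.7),
               conn_a_0.9 = count_links(v, seeds_a, 0.9),
               conn_b_0.9 = count_links(v, seeds_b, 0.9),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  total <- tab$connections_to_clusterA_seeds + tab$connections_to_clusterB_seeds
  tab <- tab[order(-tab$switch_score, -total, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 top_switches = head(tab$node, top_k),
                 threshold = tau),
            class = "switch_report")
}

#' @export
print.switch_report <- function(x, ...) {
  cat(sprintf("<switch_report> top switches (tau > %.2f): %s\n",
              x$threshold, paste(x$top_switches, collapse = ", ")))
  invisible(x)
}
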