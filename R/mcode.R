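# MCODE molecular complex detection: vertex weighting by the core-clustering
# coefficient times the highest core number, greedy seeded complex expansion,
# and haircut/fluff post-processing. Purely topological: edge confidences are
# ignored, as in the published algorithm.

#' MCODE parameters
#'
#' Defaults follow the common Metascape configuration: vertex weight
#' percentage 0.2, haircut on, fluff off, minimum complex size 3.
#'
#' @param vwp vertex weight percentage in \[0,1): a neighbor is included if
#'   its weight is at least (1 - vwp) times the complex seed's weight.
#' @param haircut iteratively remove members with a single intra-complex
#'   connection.
#' @param fluff add neighbors whose closed-neighborhood density exceeds
#'   `fluff_density` (fluffed nodes may overlap between complexes).
#' @param fluff_density density cutoff used when `fluff` is on.
#' @param min_complex_size smallest complex reported.
#' @return a list of class `mcode_params`.
#' @export
mcode_params <- function(vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.1, min_complex_size = 3L) {
  stopifnot(vwp >= 0, vwp < 1, fluff_density >= 0, min_complex_size >= 1)
  structure(list(vwp = vwp, haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density,
                 min_complex_size = as.integer(min_complex_size)),
            class = "mcode_params")
}

# loopless density of an induced subgraph given as an igraph object
subgraph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' For each node v, take the subgraph induced on v and its neighbors (the
#' closed neighborhood), find its highest k-core, and set
#' weight(v) = k * density of that k-core. Isolated nodes weigh 0.
#'
#' @param net a [ppi_network()].
#' @return named numeric vector of vertex weights.
#' @export
mcode_weights <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- as_igraph(net)
  w <- stats::setNames(numeric(n_nodes(net)), net$nodes)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (i in seq_along(w)) {
    nb <- adj[[i]]
    if (!length(nb)) next
    h <- igraph::induced_subgraph(g, c(igraph::V(g)[i], nb))
    core <- igraph::coreness(h)
    k <- max(core)
    top <- igraph::induced_subgraph(h, which(core == k))
    w[i] <- k * subgraph_density(top)
  }
  w
}

#' MCODE complex prediction
#'
#' Repeatedly seeds at the highest-weight unvisited node (ties broken by
#' identifier) and grows the complex breadth-first, including neighbors whose
#' weight is at least (1 - vwp) times the seed weight; included nodes are
#' marked visited and never reused, so complexes are node-disjoint. Haircut
#' then iteratively strips members with fewer than two intra-complex
#' connections; optional fluff adds dense boundary neighbors. Complexes
#' smaller than `min_complex_size` are dropped and the rest ranked by
#' score = density x size, descending.
#'
#' @param net a [ppi_network()].
#' @param params an [mcode_params()].
#' @return list of `mcode_complex` objects (fields `members`, `score`,
#'   `seed_node`), ranked by score.
#' @export
mcode_complexes <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "ppi_network"), inherits(params, "mcode_params"))
  g <- as_igraph(net)
  w <- mcode_weights(net)
  nodes <- net$nodes
  nbrs <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                 function(v) igraph::V(g)$name[v])
  names(nbrs) <- igraph::V(g)$name
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  complexes <- list()

  repeat {
    cand <- nodes[!visited & w > 0]
    if (!length(cand)) break
    seed <- cand[order(-w[cand], cand)][1]
    cutoff <- (1 - params$vwp) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    queue <- seed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in nbrs[[v]]) {
        if (!visited[u] && w[u] >= cutoff) {
          visited[u] <- TRUE
          members <- c(members, u)
          queue <- c(queue, u)
        }
      }
    }
    if (params$haircut) members <- haircut_members(net, members)
    if (params$fluff && length(members)) {
      members <- fluff_members(net, members, w, nbrs, params$fluff_density)
    }
    if (length(members) >= params$min_complex_size) {
      sub <- igraph::induced_subgraph(g, members)
      complexes[[length(complexes) + 1L]] <- structure(
        list(members = sort(members),
             score = subgraph_density(sub) * length(members),
             seed_node = seed),
        class = "mcode_complex")
    }
  }
  if (length(complexes)) {
    score <- vapply(complexes, `[[`, numeric(1), "score")
    size <- vapply(complexes, function(x) length(x$members), integer(1))
    first <- vapply(complexes, function(x) x$members[1], character(1))
    complexes <- complexes[order(-score, -size, first)]
  }
  complexes
}

# iteratively remove members with fewer than 2 intra-complex connections
haircut_members <- function(net, members) {
  ed <- net$edges
  repeat {
    if (length(members) < 2) return(character(0))
    sub <- ed[ed$node_a %in% members & ed$node_b %in% members, , drop = FALSE]
    deg <- table(factor(c(sub$node_a, sub$node_b), levels = members))
    drop <- names(deg)[deg < 2]
    if (!length(drop)) return(members)
    members <- setdiff(members, drop)
  }
}

# add boundary neighbors whose closed-neighborhood density exceeds the cutoff
fluff_members <- function(net, members, w, nbrs, fluff_density) {
  g <- as_igraph(net)
  boundary <- setdiff(unique(unlist(nbrs[members], use.names = FALSE)), members)
  add <- character(0)
  for (u in boundary) {
    h <- igraph::induced_subgraph(g, c(u, nbrs[[u]]))
    if (subgraph_density(h) > fluff_density) add <- c(add, u)
  }
  c(members, add)
}

#' @export
print.mcode_complex <- function(x, ...) {
  cat(sprintf("<mcode_complex> %d members, score %.3f, seeded at %s\n",
              length(x$members), x$score, x$seed_node))
  invisible(x)
}
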