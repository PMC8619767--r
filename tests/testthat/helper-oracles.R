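# Toy-network builders and independent brute-force oracles used across the
# suite. The oracles deliberately avoid igraph and the package's own code
# paths: distances and path counts come from hand-rolled BFS, triangles from
# direct neighborhood counting.

pn <- function(pairs, conf = 1, nodes = NULL) {
  pairs <- matrix(pairs, ncol = 2)
  ppi_network(data.frame(node_a = pairs[, 1], node_b = pairs[, 2],
                         confidence = conf, stringsAsFactors = FALSE),
              nodes = nodes)
}

pn_complete <- function(ids, conf = 1) pn(t(combn(ids, 2)), conf)

pn_path <- function(ids, conf = 1) {
  pn(cbind(ids[-length(ids)], ids[-1]), conf)
}

pn_star <- function(center, leaves, conf = 1) pn(cbind(center, leaves), conf)

random_net <- function(n, p = 0.4, conf = NULL) {
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  on <- runif(nrow(pairs)) < p
  if (!any(on)) on[1] <- TRUE
  cf <- if (is.null(conf)) runif(sum(on)) else rep(conf, sum(on))
  pn(pairs[on, , drop = FALSE], cf, nodes = ids)
}

adj_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    ia <- match(net$edges$node_a, net$nodes)
    ib <- match(net$edges$node_b, net$nodes)
    A[cbind(ia, ib)] <- TRUE
    A[cbind(ib, ia)] <- TRUE
  }
  A
}

# BFS from s: hop distances and shortest-path counts
bfs_sigma <- function(A, s) {
  n <- nrow(A)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in which(A[v, ])) {
        if (is.infinite(dist[u])) { dist[u] <- dist[v] + 1; nxt <- c(nxt, u) }
        if (dist[u] == dist[v] + 1) sigma[u] <- sigma[u] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

bf_components <- function(A) {
  n <- nrow(A)
  lab <- rep(NA_integer_, n); c <- 0L
  for (i in seq_len(n)) {
    if (!is.na(lab[i])) next
    c <- c + 1L
    stack <- i; lab[i] <- c
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      for (u in which(A[v, ])) {
        if (is.na(lab[u])) { lab[u] <- c; stack <- c(stack, u) }
      }
    }
  }
  lab
}

# brute-force topology statistics (all-pairs BFS, direct triangle counting)
bf_topology <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A); m <- sum(A) / 2
  deg <- rowSums(A)
  lc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ])
    if (length(nb) < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
  lab <- bf_components(A)
  giant <- which(lab == which.max(tabulate(lab)))
  if (length(giant) > 1) {
    D <- t(vapply(giant, function(s) bfs_sigma(A, s)$dist[giant],
                  numeric(length(giant))))
    ecc <- apply(D, 1, max)
    diam <- max(ecc); rad <- min(ecc)
    cpl <- mean(D[row(D) != col(D)])
  } else {
    diam <- 0; rad <- 0; cpl <- 0
  }
  list(n_nodes = n, n_edges = m, avg_degree = 2 * m / n,
       density = 2 * m / (n * (n - 1)),
       avg_local_clustering = mean(lc),
       diameter = diam, radius = rad, char_path_length = cpl,
       heterogeneity = if (mean(deg) > 0)
         sqrt(mean((deg - mean(deg))^2)) / mean(deg) else 0,
       n_components = max(lab))
}

# brute-force betweenness by path counting over all source-target pairs
bf_betweenness <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  b <- setNames(numeric(n), rownames(A))
  info <- lapply(seq_len(n), function(s) bfs_sigma(A, s))
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      dst <- info[[s]]$dist[t]
      if (is.infinite(dst)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(info[[s]]$dist[v]) &&
            info[[s]]$dist[v] + info[[t]]$dist[v] == dst) {
          b[v] <- b[v] + info[[s]]$sigma[v] * info[[t]]$sigma[v] /
            info[[s]]$sigma[t]
        }
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# independent MCL oracle: direct fixed-point iteration of the recurrence at
# high precision, no pruning; clusters read off the limit support with the
# local BFS component finder
mcl_oracle <- function(net, inflation, expansion = 2, max_iter = 500) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(net$edges)) {
    ia <- match(net$edges$node_a, nodes)
    ib <- match(net$edges$node_b, nodes)
    A[cbind(ia, ib)] <- net$edges$confidence
    A[cbind(ib, ia)] <- net$edges$confidence
  }
  loop <- apply(A, 2, max); loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(max_iter)) {
    E <- M
    for (j in seq_len(expansion - 1)) E <- E %*% M
    E <- E ^ inflation
    E <- sweep(E, 2, colSums(E), "/")
    if (max(abs(E - M)) < 1e-12) { M <- E; break }
    M <- E
  }
  support <- (M > 1e-9) | (t(M) > 1e-9)
  diag(support) <- FALSE
  lab <- bf_components(support)
  split(nodes, lab)
}

# partition comparison irrespective of cluster numbering
same_partition <- function(assignment, groups) {
  got <- unname(lapply(split(names(assignment), assignment), sort))
  want <- unname(lapply(groups, sort))
  setequal(lapply(got, paste, collapse = ","),
           lapply(want, paste, collapse = ","))
}

make_clustering <- function(assignment) {
  structure(list(assignment = assignment,
                 n_clusters = length(unique(assignment)),
                 converged = TRUE, iterations = 0L),
            class = "ppi_clustering")
}
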