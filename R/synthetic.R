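# Synthetic data: two-community weighted networks with designated seeds and
# planted bridge ("switch") nodes, plus gene-set collections with planted
# enriched terms, so the whole workflow is testable offline with known truth.

#' Specification for a synthetic two-community network
#'
#' Emulates the structure the analysis assumes: two communities (think immune
#' vs. hemostasis) of densely connected nodes, sparse inter-community edges,
#' designated seed nodes per community, and a few extra bridge nodes wired to
#' seeds in both communities with high confidence — the planted switches.
#'
#' Defaults: two blocks of 20 with p_in = 0.30 and p_out = 0.02, 10 seeds per
#' block, 2 bridges with 3 links per block at confidence >= 0.7; intra-block
#' confidences U(0.6, 0.99), inter-block U(0.40, 0.70).
#'
#' @param block_sizes sizes of the two communities.
#' @param p_in,p_out intra-/inter-block Bernoulli edge probabilities
#'   (0 <= p_out < p_in <= 1).
#' @param conf_in,conf_out uniform confidence ranges within \[0,1\].
#' @param n_seeds_per_block designated seeds per block.
#' @param n_bridges number of planted bridge nodes.
#' @param bridge_links_per_block distinct seeds per block each bridge links to
#'   (<= n_seeds_per_block).
#' @param bridge_conf_min minimum confidence on bridge links.
#' @param rng_seed integer RNG seed; mandatory for reproducibility.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(block_sizes = c(20L, 20L), p_in = 0.30,
                           p_out = 0.02, conf_in = c(0.6, 0.99),
                           conf_out = c(0.40, 0.70),
                           n_seeds_per_block = 10L, n_bridges = 2L,
                           bridge_links_per_block = 3L,
                           bridge_conf_min = 0.7, rng_seed = 1L) {
  stopifnot(length(block_sizes) == 2, all(block_sizes >= 1),
            p_out >= 0, p_out < p_in, p_in <= 1,
            all(conf_in >= 0 & conf_in <= 1), all(conf_out >= 0 & conf_out <= 1),
            n_seeds_per_block >= 1, n_seeds_per_block <= min(block_sizes),
            n_bridges >= 0, bridge_links_per_block <= n_seeds_per_block,
            bridge_conf_min >= 0, bridge_conf_min <= 1,
            length(rng_seed) == 1, is.finite(rng_seed))
  structure(list(block_sizes = as.integer(block_sizes), p_in = p_in,
                 p_out = p_out, conf_in = conf_in, conf_out = conf_out,
                 n_seeds_per_block = as.integer(n_seeds_per_block),
                 n_bridges = as.integer(n_bridges),
                 bridge_links_per_block = as.integer(bridge_links_per_block),
                 bridge_conf_min = bridge_conf_min,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-community network with planted bridges
#'
#' Intra-block node pairs become edges independently with probability `p_in`
#' (confidence drawn uniformly from `conf_in`), inter-block pairs with
#' probability `p_out` (confidence from `conf_out`). The first
#' `n_seeds_per_block` nodes of each block are flagged as seeds. Each bridge
#' node is wired to `bridge_links_per_block` distinct seeds in each block
#' with confidence >= `bridge_conf_min`. Fully reproducible from
#' `spec$rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (a [ppi_network()]) and `truth` (class
#'   `synthetic_truth`: `block_of` map, two `seed_sets`, `bridges`,
#'   `planted_terms`).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  b1 <- sprintf("B1N%03d", seq_len(spec$block_sizes[1]))
  b2 <- sprintf("B2N%03d", seq_len(spec$block_sizes[2]))
  bridges <- if (spec$n_bridges > 0) {
    sprintf("BRG%03d", seq_len(spec$n_bridges))
  } else character(0)

  draw_block <- function(nodes, p, range) {
    if (length(nodes) < 2) {
      return(data.frame(node_a = character(), node_b = character(),
                        confidence = numeric(), stringsAsFactors = FALSE))
    }
    pairs <- utils::combn(nodes, 2)
    on <- runif(ncol(pairs)) < p
    data.frame(node_a = pairs[1, on], node_b = pairs[2, on],
               confidence = runif(sum(on), range[1], range[2]),
               stringsAsFactors = FALSE)
  }
  draw_cross <- function(na, nb, p, range) {
    grid <- expand.grid(node_a = na, node_b = nb, stringsAsFactors = FALSE)
    on <- runif(nrow(grid)) < p
    data.frame(node_a = grid$node_a[on], node_b = grid$node_b[on],
               confidence = runif(sum(on), range[1], range[2]),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(draw_block(b1, spec$p_in, spec$conf_in),
                 draw_block(b2, spec$p_in, spec$conf_in),
                 draw_cross(b1, b2, spec$p_out, spec$conf_out))

  seeds1 <- b1[seq_len(spec$n_seeds_per_block)]
  seeds2 <- b2[seq_len(spec$n_seeds_per_block)]
  for (br in bridges) {
    t1 <- sample(seeds1, spec$bridge_links_per_block)
    t2 <- sample(seeds2, spec$bridge_links_per_block)
    targets <- c(t1, t2)
    edges <- rbind(edges, data.frame(
      node_a = br, node_b = targets,
      confidence = runif(length(targets), spec$bridge_conf_min, 0.99),
      stringsAsFactors = FALSE))
  }

  net <- ppi_network(edges, nodes = c(b1, b2, bridges), normalize = FALSE)
  truth <- structure(list(
    block_of = c(stats::setNames(rep(1L, length(b1)), b1),
                 stats::setNames(rep(2L, length(b2)), b2)),
    seed_sets = list(seed_set(seeds1, name = "block1_seeds", community = "block1"),
                     seed_set(seeds2, name = "block2_seeds", community = "block2")),
    bridges = bridges,
    planted_terms = character(0)
  ), class = "synthetic_truth")
  list(network = net, truth = truth)
}

#' Clustering from the generator's ground truth
#'
#' Turns a `synthetic_truth` into a `ppi_clustering` (block 1 -> cluster 1,
#' block 2 -> cluster 2, bridges -> cluster 3), so downstream stages such as
#' [find_switches()] can be evaluated against the planted partition directly.
#'
#' @param truth a `synthetic_truth` from [generate_network()].
#' @return a `ppi_clustering`.
#' @export
truth_clustering <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  assignment <- c(truth$block_of,
                  stats::setNames(rep(3L, length(truth$bridges)),
                                  truth$bridges))
  structure(list(assignment = assignment,
                 n_clusters = length(unique(assignment)),
                 converged = TRUE, iterations = 0L),
            class = "ppi_clustering")
}

#' Generate a gene-set collection with planted enriched terms
#'
#' Planted terms draw `ceiling(purity * term_size)` members from the block-1
#' nodes of a generated network (so a block-1 query is strongly enriched in
#' them) and the remainder from filler identifiers; decoy terms draw uniformly
#' from the whole universe. The universe is the network's nodes padded with
#' filler identifiers up to `universe_size`, and is attached to the collection
#' so over-representation queries are intersected with it.
#'
#' @param truth a `synthetic_truth` from [generate_network()].
#' @param n_planted number of planted (truly enriched) terms.
#' @param n_decoy number of decoy terms.
#' @param term_size genes per term.
#' @param purity fraction of each planted term drawn from block 1, in
#'   (0.5, 1\].
#' @param universe_size declared universe size (>= network size).
#' @param rng_seed integer RNG seed.
#' @return a [gene_set_collection()] with attribute `planted_terms` naming the
#'   planted term ids.
#' @export
generate_genesets <- function(truth, n_planted = 3L, n_decoy = 50L,
                              term_size = 25L, purity = 0.8,
                              universe_size = 5000L, rng_seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            purity > 0.5, purity <= 1, n_planted >= 0, n_decoy >= 0)
  set.seed(rng_seed)
  network_nodes <- c(names(truth$block_of), truth$bridges)
  if (universe_size < length(network_nodes)) {
    stop("universe_size must be at least the network size")
  }
  block1 <- names(truth$block_of)[truth$block_of == 1L]
  n_from_block <- ceiling(purity * term_size)
  if (n_from_block > length(block1)) {
    stop(sprintf("planted terms need %d block-1 genes but block 1 has %d",
                 n_from_block, length(block1)))
  }
  filler <- sprintf("GENE%05d", seq_len(universe_size - length(network_nodes)))
  universe <- c(network_nodes, filler)

  terms <- list()
  for (i in seq_len(n_planted)) {
    genes <- c(sample(block1, n_from_block),
               sample(filler, term_size - n_from_block))
    terms[[length(terms) + 1L]] <- list(
      term_id = sprintf("PLANTED%03d", i),
      description = "planted enriched term", genes = genes)
  }
  for (i in seq_len(n_decoy)) {
    terms[[length(terms) + 1L]] <- list(
      term_id = sprintf("DECOY%03d", i),
      description = "decoy term", genes = sample(universe, term_size))
  }
  coll <- gene_set_collection(terms, universe_size,
                              source_name = "synthetic",
                              universe_genes = universe)
  attr(coll, "planted_terms") <- sprintf("PLANTED%03d", seq_len(n_planted))
  coll
}
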