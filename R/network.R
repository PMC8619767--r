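# Network construction: confidence filtering, zero-order (seeds-only)
# induction, and first-order expansion with a fixed interactor budget.

#' Network build parameters
#'
#' Defaults mirror the standard STRING-style configuration: a minimum required
#' interaction score of 0.400 and 50 interactors in the first shell, none in
#' the second.
#'
#' @param tau confidence threshold in \[0,1\] (inclusive: edges with
#'   confidence >= tau are kept).
#' @param k_first_shell number of non-seed interactors added in the first
#'   shell (per network, not per seed).
#' @param k_second_shell must be 0; second-shell expansion is not supported.
#' @return a list of class `build_params`.
#' @export
build_params <- function(tau = 0.400, k_first_shell = 50L,
                         k_second_shell = 0L) {
  stopifnot(length(tau) == 1L, tau >= 0, tau <= 1,
            k_first_shell >= 0, is.finite(k_first_shell))
  if (k_second_shell != 0) {
    stop("second-shell expansion is not implemented (k_second_shell must be 0)")
  }
  structure(list(tau = tau, k_first_shell = as.integer(k_first_shell),
                 k_second_shell = 0L),
            class = "build_params")
}

#' Filter edges by confidence
#'
#' Keeps edges with confidence >= `tau`; the node set is unchanged, so nodes
#' losing all incident edges remain as isolated nodes.
#'
#' @param net a [ppi_network()].
#' @param tau threshold in \[0,1\].
#' @return a filtered `ppi_network`.
#' @export
filter_by_confidence <- function(net, tau) {
  stopifnot(inherits(net, "ppi_network"), length(tau) == 1L)
  if (is.na(tau) || tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  ed <- net$edges[net$edges$confidence >= tau, , drop = FALSE]
  ppi_network(ed, nodes = net$nodes, normalize = FALSE)
}

#' Zero-order (seeds-only) network
#'
#' Induced subgraph on the seed members. Seeds absent from the background are
#' retained as isolated nodes (with a message) so seed bookkeeping never
#' silently shrinks.
#'
#' @param background a [ppi_network()].
#' @param seeds a [seed_set()].
#' @return a `ppi_network` whose node set equals the seed members.
#' @export
zero_order <- function(background, seeds) {
  stopifnot(inherits(background, "ppi_network"), inherits(seeds, "seed_set"))
  members <- seeds$members
  missing <- setdiff(members, background$nodes)
  if (length(missing)) {
    message(sprintf("%d seed(s) absent from background kept as isolated nodes: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  ed <- background$edges
  ed <- ed[ed$node_a %in% members & ed$node_b %in% members, , drop = FALSE]
  ppi_network(ed, nodes = members, normalize = FALSE)
}

#' First-order network expansion
#'
#' Adds the top `k_first_shell` non-seed interactors to the seed set and
#' returns the induced subgraph. Candidates (non-seed nodes adjacent to at
#' least one seed) are ranked by (1) number of distinct seed neighbors,
#' descending; (2) summed confidence over seed-incident edges, descending;
#' (3) identifier, ascending. The background is expected to be already
#' confidence-filtered at `params$tau`.
#'
#' @param background a [ppi_network()], confidence-filtered.
#' @param seeds a [seed_set()].
#' @param params a [build_params()].
#' @return a `ppi_network` on seeds plus the selected interactors
#'   (`|seeds| + min(k, eligible)` nodes).
#' @export
first_order_expand <- function(background, seeds, params = build_params()) {
  stopifnot(inherits(background, "ppi_network"), inherits(seeds, "seed_set"),
            inherits(params, "build_params"))
  members <- seeds$members
  k <- params$k_first_shell
  ed <- background$edges
  inc_a <- ed$node_a %in% members
  inc_b <- ed$node_b %in% members
  # seed-incident edges whose other endpoint is a non-seed candidate
  cand_edges <- rbind(
    data.frame(cand = ed$node_b[inc_a & !inc_b],
               conf = ed$confidence[inc_a & !inc_b],
               seed = ed$node_a[inc_a & !inc_b], stringsAsFactors = FALSE),
    data.frame(cand = ed$node_a[inc_b & !inc_a],
               conf = ed$confidence[inc_b & !inc_a],
               seed = ed$node_b[inc_b & !inc_a], stringsAsFactors = FALSE))
  selected <- character(0)
  if (k > 0 && nrow(cand_edges)) {
    n_seed_nb <- tapply(cand_edges$seed, cand_edges$cand,
                        function(s) length(unique(s)))
    sum_conf <- tapply(cand_edges$conf, cand_edges$cand, sum)
    cand <- names(n_seed_nb)
    ord <- order(-as.numeric(n_seed_nb), -as.numeric(sum_conf), cand)
    selected <- cand[ord][seq_len(min(k, length(cand)))]
  }
  keep <- c(members, selected)
  ed <- background$edges
  ed <- ed[ed$node_a %in% keep & ed$node_b %in% keep, , drop = FALSE]
  missing <- setdiff(members, background$nodes)
  if (length(missing)) {
    message(sprintf("%d seed(s) absent from background kept as isolated nodes: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  ppi_network(ed, nodes = keep, normalize = FALSE)
}
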