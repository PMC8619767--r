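# Over-representation analysis: accumulative hypergeometric tail p-values,
# Benjamini-Hochberg FDR, fold enrichment and strength, and kappa-score
# clustering of enriched terms.

#' Accumulative hypergeometric tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n genes from a universe
#' of N containing K annotated genes. Computed in log space from exact
#' log-binomial coefficients so extreme tails remain accurate.
#'
#' @param k observed overlap (0 <= k <= min(n, K)).
#' @param n query size (n <= N).
#' @param K term (annotation) size (K <= N).
#' @param N universe size.
#' @return probability in (0, 1\].
#' @export
hypergeom_tail <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (k < 0 || n < 0 || K < 0 || N < 1 || n > N || K > N || k > min(n, K)) {
    stop("require 0 <= k <= min(n, K), n <= N, K <= N")
  }
  if (k == 0) return(1)
  i <- k:min(n, K)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(lt)
  min(exp(mx + log(sum(exp(lt - mx)))), 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, clipped at 1,
#' returned in input order.
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Over-representation analysis (ORA)
#'
#' Tests each term of a collection for over-representation in a query list
#' using the accumulative hypergeometric test. The effective query is the
#' normalized, de-duplicated query intersected with the collection's universe
#' when universe membership is known (members outside it are dropped with a
#' warning); otherwise the whole query is assumed annotated. For each term
#' with overlap k >= `min_overlap` the row reports the overlap, `ratio` =
#' K/N, `fold` = (k/n)/(K/N), `strength` = log10(fold), the hypergeometric p,
#' and the BH-FDR computed over exactly the emitted rows. Rows are sorted by
#' p ascending, ties by fold descending, then term id.
#'
#' @param query character vector of gene identifiers.
#' @param collection a [gene_set_collection()].
#' @param min_overlap smallest overlap reported (default 3).
#' @return a data.frame of class `enrichment_result`.
#' @export
ora <- function(query, collection, min_overlap = 3L) {
  stopifnot(inherits(collection, "gene_set_collection"), min_overlap >= 1)
  q <- unique(normalize_id(as.character(query)))
  q <- q[nzchar(q)]
  if (!is.null(collection$universe_genes)) {
    outside <- setdiff(q, collection$universe_genes)
    if (length(outside)) {
      warning(sprintf("%d query gene(s) outside the declared universe dropped",
                      length(outside)))
      q <- setdiff(q, outside)
    }
  }
  if (!length(q)) stop("effective query is empty")
  n <- length(q)
  N <- collection$universe_size
  rows <- lapply(collection$terms, function(t) {
    ov <- intersect(q, t$genes)
    k <- length(ov)
    if (k < min_overlap) return(NULL)
    K <- length(t$genes)
    fold <- (k / n) / (K / N)
    data.frame(term_id = t$term_id,
               description = t$description,
               k_overlap = k, n_query = n, K_term = K, N_universe = N,
               ratio = K / N,
               p = hypergeom_tail(k, n, K, N),
               fold = fold,
               strength = log10(fold),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term_id = character(), description = character(),
                      k_overlap = integer(), n_query = integer(),
                      K_term = integer(), N_universe = integer(),
                      ratio = numeric(), p = numeric(), fdr = numeric(),
                      fold = numeric(), strength = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p, -out$fold, out$term_id),
             c("term_id", "description", "k_overlap", "n_query", "K_term",
               "N_universe", "ratio", "p", "fdr", "fold", "strength",
               "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Cohen's kappa between two binary membership vectors
#'
#' Agreement between two logical vectors corrected for chance. Identical
#' vectors score 1 even when the expected agreement is also 1.
#'
#' @param x,y logical vectors of equal length.
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  x <- as.logical(x); y <- as.logical(y)
  if (identical(x, y)) return(1)
  t <- length(x)
  a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
  po <- (a + d) / t
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / t^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Kappa-score clustering of enriched terms
#'
#' Groups enriched terms whose query-membership patterns agree: for each pair
#' of emitted terms, Cohen's kappa is computed between their binary membership
#' vectors over the effective query, terms are linked when kappa >= the
#' threshold, and the clusters are the single-linkage connected components.
#' Each cluster's representative is its lowest-p member (ties broken by the
#' smaller term id).
#'
#' @param rows an `enrichment_result` (output of [ora()]).
#' @param query the query gene list the rows were computed from.
#' @param threshold kappa threshold in (-1, 1\] (default 0.3).
#' @return list of `term_cluster` objects (fields `member_terms`,
#'   `representative`, `kappa_threshold`).
#' @export
kappa_term_clusters <- function(rows, query, threshold = 0.3) {
  stopifnot(inherits(rows, "enrichment_result"),
            threshold > -1, threshold <= 1)
  if (nrow(rows) < 1) stop("need at least one enrichment row")
  q <- unique(normalize_id(as.character(query)))
  membership <- lapply(strsplit(rows$overlap_genes, ",", fixed = TRUE),
                       function(g) q %in% g)
  k <- nrow(rows)
  adj <- matrix(FALSE, k, k)
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        adj[i, j] <- adj[j, i] <-
          cohen_kappa(membership[[i]], membership[[j]]) >= threshold
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  lapply(split(seq_len(k), comp), function(idx) {
    sub <- rows[idx, , drop = FALSE]
    rep_id <- sub$term_id[order(sub$p, sub$term_id)][1]
    structure(list(member_terms = sort(sub$term_id),
                   representative = rep_id,
                   kappa_threshold = threshold),
              class = "term_cluster")
  })
}
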