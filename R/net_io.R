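# I/O and containers: scored edge tables, GMT gene-set collections, seed
# lists, and report serialization. Parsing and validation only; no analysis.

#' Normalize a gene/protein identifier
#'
#' Uppercases and strips surrounding whitespace. All readers apply this
#' normalization so that identifiers compare consistently across inputs.
#'
#' @param x character vector of identifiers.
#' @return normalized character vector.
#' @export
normalize_id <- function(x) toupper(trimws(x))

#' Construct a PPI network
#'
#' An undirected simple graph with a per-edge confidence in \[0,1\]. Edges are
#' stored with canonically ordered endpoints (`node_a < node_b`); self-loops
#' are rejected and duplicate unordered pairs are collapsed keeping the
#' maximum confidence.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `confidence`.
#' @param nodes optional character vector of node identifiers; defaults to all
#'   edge endpoints. Extra entries become isolated nodes.
#' @param normalize apply [normalize_id()] to identifiers (default TRUE).
#' @return an object of class `ppi_network` with elements `nodes` (character)
#'   and `edges` (data.frame).
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, normalize = TRUE) {
  if (is.null(edges)) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        confidence = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "confidence") %in% names(edges)))
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  if (normalize) {
    a <- normalize_id(a)
    b <- normalize_id(b)
    if (!is.null(nodes)) nodes <- normalize_id(nodes)
  }
  conf <- as.numeric(edges$confidence)
  if (any(is.na(conf)) || any(conf < 0 | conf > 1)) {
    stop("edge confidences must be numeric values in [0, 1]")
  }
  loop <- a == b
  if (any(loop)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loop)))
    a <- a[!loop]; b <- b[!loop]; conf <- conf[!loop]
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    conf <- vapply(split(conf, key), max, numeric(1))
    uk <- names(conf)
    parts <- strsplit(uk, "\r", fixed = TRUE)
    a <- vapply(parts, `[`, character(1), 1L)
    b <- vapply(parts, `[`, character(1), 2L)
  }
  ed <- data.frame(node_a = a, node_b = b, confidence = unname(conf),
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$node_a, ed$node_b), , drop = FALSE]
  rownames(ed) <- NULL
  nd <- sort(unique(c(nodes, ed$node_a, ed$node_b)))
  structure(list(nodes = nd, edges = ed), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net a `ppi_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

# internal: convert to igraph, confidence kept as a non-"weight" attribute so
# igraph's shortest-path routines stay purely topological unless asked.
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b", "confidence")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  readLines(path, warn = FALSE)
}

#' Read a scored interaction table
#'
#' Parses a whitespace/tab-separated table with columns node_a, node_b, score.
#' Two score dialects are supported: `"string1000"` (STRING combined scores,
#' integers 0-1000, divided by 1000) and `"unit"` (reals in \[0,1\]). Blank
#' lines and `#` comments are skipped; a header row is auto-detected by a
#' non-numeric third field. Duplicate unordered pairs are collapsed keeping
#' the maximum confidence and self-loops are dropped with a warning.
#'
#' @param path file path.
#' @param dialect `"string1000"` or `"unit"`.
#' @return a [ppi_network()].
#' @export
read_edge_table <- function(path, dialect = c("string1000", "unit")) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  a <- b <- character(0); s <- numeric(0)
  first <- TRUE
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3) {
      stop(sprintf("line %d: expected at least 3 columns, got %d", i, length(f)))
    }
    val <- suppressWarnings(as.numeric(f[3]))
    if (is.na(val)) {
      if (first) { first <- FALSE; next }  # header row
      stop(sprintf("line %d: non-numeric score '%s'", i, f[3]))
    }
    first <- FALSE
    a <- c(a, f[1]); b <- c(b, f[2]); s <- c(s, val)
  }
  if (dialect == "string1000") {
    if (any(s < 0 | s > 1000)) {
      stop("string1000 scores must lie in [0, 1000]")
    }
    s <- s / 1000
  } else if (any(s < 0 | s > 1)) {
    stop("unit-dialect scores must lie in [0, 1]")
  }
  ppi_network(data.frame(node_a = a, node_b = b, confidence = s,
                         stringsAsFactors = FALSE))
}

#' Construct a seed set
#'
#' @param members character vector of identifiers (normalized, de-duplicated,
#'   order preserved).
#' @param name label for the set.
#' @param community optional community label (e.g. "immune", "hemostasis").
#' @return an object of class `seed_set`.
#' @export
seed_set <- function(members, name = "seeds", community = NULL) {
  members <- normalize_id(as.character(members))
  members <- members[nzchar(members)]
  dup <- duplicated(members)
  if (any(dup)) {
    warning(sprintf("removing %d duplicate seed(s): %s",
                    sum(dup), paste(unique(members[dup]), collapse = ", ")))
    members <- members[!dup]
  }
  if (!length(members)) stop("seed set is empty")
  structure(list(name = name, members = members, community = community),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set '%s'%s> %d members\n", x$name,
              if (is.null(x$community)) "" else paste0(" (", x$community, ")"),
              length(x$members)))
  invisible(x)
}

#' Read a seed list
#'
#' One identifier per line; `#` starts a comment; blank lines are skipped.
#' Identifiers are normalized, optional aliases applied, and duplicates after
#' normalization removed with a warning.
#'
#' @param path file path.
#' @param name label for the seed set (defaults to the file name).
#' @param community optional community label.
#' @param aliases optional identifier aliases: either a named character vector
#'   (`c(FBG = "FGB")` maps FBG to FGB) or the path to a two-column TSV
#'   (alias, canonical).
#' @return a [seed_set()].
#' @export
read_seed_list <- function(path, name = basename(path), community = NULL,
                           aliases = NULL) {
  lines <- read_text_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("no identifiers in %s", path))
  ids <- normalize_id(lines)
  if (!is.null(aliases)) {
    if (is.character(aliases) && is.null(names(aliases)) &&
        length(aliases) == 1L) {
      tab <- read.table(aliases, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE, comment.char = "#")
      aliases <- stats::setNames(normalize_id(tab[[2]]), normalize_id(tab[[1]]))
    }
    hit <- ids %in% names(aliases)
    ids[hit] <- unname(aliases[ids[hit]])
  }
  seed_set(ids, name = name, community = community)
}

#' Construct a gene-set collection
#'
#' @param terms list of term entries, each a list with `term_id`,
#'   `description`, and `genes` (character vector).
#' @param universe_size declared annotation universe size; must be at least
#'   the size of the union of all term gene sets.
#' @param source_name label for the collection.
#' @param universe_genes optional character vector enumerating the universe;
#'   when present, over-representation queries are intersected with it.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, universe_size,
                                source_name = "collection",
                                universe_genes = NULL) {
  stopifnot(is.list(terms), length(universe_size) == 1L, universe_size >= 1)
  ids <- vapply(terms, function(t) t$term_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate term_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (t in terms) {
    if (!length(t$genes)) stop(sprintf("term %s has an empty gene set", t$term_id))
  }
  union_size <- length(unique(normalize_id(unlist(
    lapply(terms, function(t) t$genes), use.names = FALSE))))
  if (universe_size < union_size) {
    stop(sprintf("universe_size (%d) smaller than union of term genes (%d)",
                 universe_size, union_size))
  }
  if (!is.null(universe_genes)) {
    universe_genes <- unique(normalize_id(universe_genes))
    if (length(universe_genes) != universe_size) {
      stop("length(universe_genes) must equal universe_size")
    }
  }
  terms <- lapply(terms, function(t) {
    t$genes <- unique(normalize_id(t$genes)); t
  })
  names(terms) <- ids
  structure(list(source_name = source_name, terms = terms,
                 universe_size = as.integer(universe_size),
                 universe_genes = universe_genes),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection '%s'> %d terms, universe %d\n",
              x$source_name, length(x$terms), x$universe_size))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT lines: term id, description, then one or more genes, tab
#' separated. Terms are kept in file order and genes case-normalized.
#'
#' @param path file path.
#' @param universe_size declared annotation universe size.
#' @param source_name label (defaults to the file name).
#' @param universe_genes optional universe membership (see
#'   [gene_set_collection()]).
#' @return a [gene_set_collection()]; an empty file yields an empty collection
#'   with a warning.
#' @export
read_gmt <- function(path, universe_size, source_name = basename(path),
                     universe_genes = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning(sprintf("empty GMT file: %s", path))
    return(gene_set_collection(list(), universe_size, source_name,
                               universe_genes))
  }
  terms <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("line %d: GMT lines need term, description and >=1 gene", i))
    }
    terms[[i]] <- list(term_id = f[1], description = f[2],
                       genes = f[-(1:2)])
  }
  gene_set_collection(terms, universe_size, source_name, universe_genes)
}

#' Write a GMT gene-set file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$terms, function(t) {
    paste(c(t$term_id, t$description, t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a pipeline result
#'
#' JSON serialization preserves full numeric precision; TSV writes a flat
#' table (a `ppi_clustering` becomes (node, cluster_id) rows; an enrichment
#' table is written sorted by p ascending).
#'
#' @param report a pipeline result (network, report, clustering, data.frame, ...).
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_payload(report), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    df <- report_table(report)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# internal: strip classes into plain lists for lossless JSON round-trips
report_payload <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), report_payload))
  x
}

# internal: flatten a result into a data.frame for TSV output
report_table <- function(x) {
  if (is.data.frame(x)) {
    if (inherits(x, "enrichment_result")) {
      x <- x[order(x$p, -x$fold, x$term_id), , drop = FALSE]
    }
    return(x)
  }
  if (inherits(x, "ppi_clustering")) {
    return(data.frame(node = names(x$assignment),
                      cluster_id = unname(x$assignment),
                      stringsAsFactors = FALSE))
  }
  if (inherits(x, "backbone")) {
    return(rbind(
      data.frame(role = "hub", node = x$hubs$node,
                 value = x$hubs$degree, stringsAsFactors = FALSE),
      data.frame(role = "non_hub_bottleneck",
                 node = x$non_hub_bottlenecks$node,
                 value = x$non_hub_bottlenecks$betweenness,
                 stringsAsFactors = FALSE)))
  }
  stop("no tabular representation for class ",
       paste(class(x), collapse = "/"))
}
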