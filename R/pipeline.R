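# End-to-end orchestration: edge table + seed list + GMT collections in,
# directory of reports out. Defaults reproduce the standard configuration
# (tau 0.400, first shell 50, inflation 3.0, kappa 0.3, 6 hubs, 2 bottlenecks).

#' Pipeline configuration
#'
#' @param edges path to the scored edge table.
#' @param seeds path to the seed list.
#' @param out_dir output directory (created if absent).
#' @param dialect edge-table score dialect, see [read_edge_table()].
#' @param seed_name,seed_community,aliases passed to [read_seed_list()].
#' @param gmt named list of gene-set collections, each a list with `path` and
#'   `universe_size`; may be empty.
#' @param tau,k_first_shell network build parameters.
#' @param inflation MCL inflation.
#' @param switch_tau,switch_top_k switch-detection threshold (strict >) and
#'   list length.
#' @param vwp,haircut,min_complex_size MCODE parameters.
#' @param min_overlap,kappa_threshold enrichment parameters.
#' @param n_hubs,n_bottlenecks backbone sizes.
#' @param background_density optional density in (0,1) for the edge-count
#'   enrichment test; skipped when NULL.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(edges, seeds, out_dir,
                            dialect = "unit", seed_name = "seeds",
                            seed_community = NULL, aliases = NULL,
                            gmt = list(),
                            tau = 0.400, k_first_shell = 50L,
                            inflation = 3.0,
                            switch_tau = 0.4, switch_top_k = 2L,
                            vwp = 0.2, haircut = TRUE, min_complex_size = 3L,
                            min_overlap = 3L, kappa_threshold = 0.3,
                            n_hubs = 6L, n_bottlenecks = 2L,
                            background_density = NULL) {
  structure(list(edges = edges, seeds = seeds, out_dir = out_dir,
                 dialect = dialect, seed_name = seed_name,
                 seed_community = seed_community, aliases = aliases,
                 gmt = gmt, tau = tau, k_first_shell = k_first_shell,
                 inflation = inflation, switch_tau = switch_tau,
                 switch_top_k = switch_top_k, vwp = vwp, haircut = haircut,
                 min_complex_size = min_complex_size,
                 min_overlap = min_overlap,
                 kappa_threshold = kappa_threshold,
                 n_hubs = n_hubs, n_bottlenecks = n_bottlenecks,
                 background_density = background_density),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Reads the inputs, builds the confidence-filtered first-order network,
#' computes the topology report and backbone, clusters with MCL, scores
#' switch nodes between the two largest clusters, detects MCODE complexes,
#' and runs over-representation analysis of the network's nodes against each
#' configured gene-set collection. Every stage logs node/edge counts to
#' stderr. Outputs are written to `config$out_dir`: `net.json`, `topo.json`,
#' `backbone.tsv`, `clusters.tsv`, `switches.tsv`, `complexes.tsv`,
#' `enrichment-<collection>.tsv`, and `manifest.json` (parameters, input
#' checksums, package version; the only file carrying a timestamp). A stage
#' failure aborts with the stage name and leaves a `.partial` marker.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out, ".partial")
  file.create(marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  background <- stage("read_inputs", {
    b <- read_edge_table(config$edges, dialect = config$dialect)
    message(sprintf("[read_inputs] background: %d nodes, %d edges",
                    n_nodes(b), n_edges(b)))
    b
  })
  seeds <- stage("read_inputs", read_seed_list(
    config$seeds, name = config$seed_name,
    community = config$seed_community, aliases = config$aliases))

  net <- stage("build", {
    filtered <- filter_by_confidence(background, config$tau)
    params <- build_params(tau = config$tau,
                           k_first_shell = config$k_first_shell)
    n <- first_order_expand(filtered, seeds, params)
    message(sprintf("[build] first-order network: %d nodes, %d edges",
                    n_nodes(n), n_edges(n)))
    n
  })
  write_report(list(nodes = net$nodes, edges = net$edges),
               file.path(out, "net.json"), "json")

  topo <- stage("topology", topology_report(net))
  message(sprintf("[topology] avg degree %.3f, density %.3f, %d component(s)",
                  topo$avg_degree, topo$density, topo$n_components))
  write_report(topo, file.path(out, "topo.json"), "json")

  backbone <- stage("backbone", extract_backbone(
    net, n_hubs = min(config$n_hubs, n_nodes(net)),
    n_bottlenecks = min(config$n_bottlenecks,
                        n_nodes(net) - min(config$n_hubs, n_nodes(net)))))
  write_report(backbone, file.path(out, "backbone.tsv"), "tsv")

  enr <- NULL
  if (!is.null(config$background_density)) {
    enr <- stage("edge_enrichment",
                 edge_enrichment(net, config$background_density))
    write_report(enr, file.path(out, "edge_enrichment.json"), "json")
  }

  clustering <- stage("cluster", mcl(net, mcl_params(
    inflation = config$inflation)))
  message(sprintf("[cluster] %d cluster(s), converged: %s",
                  clustering$n_clusters, clustering$converged))
  write_report(clustering, file.path(out, "clusters.tsv"), "tsv")

  switches <- NULL
  if (clustering$n_clusters >= 2) {
    switches <- stage("switches", find_switches(
      net, clustering, seeds, cluster_a = 1L, cluster_b = 2L,
      tau = config$switch_tau, top_k = config$switch_top_k))
    message(sprintf("[switches] top: %s",
                    paste(switches$top_switches, collapse = ", ")))
    write_report(switches$table, file.path(out, "switches.tsv"), "tsv")
  } else {
    message("[switches] fewer than two clusters; skipped")
    write_report(data.frame(node = character(), switch_score = integer()),
                 file.path(out, "switches.tsv"), "tsv")
  }

  complexes <- stage("mcode", mcode_complexes(net, mcode_params(
    vwp = config$vwp, haircut = config$haircut,
    min_complex_size = config$min_complex_size)))
  message(sprintf("[mcode] %d complex(es)", length(complexes)))
  ctab <- if (length(complexes)) {
    do.call(rbind, lapply(seq_along(complexes), function(i) {
      cx <- complexes[[i]]
      data.frame(complex_id = i, score = cx$score, size = length(cx$members),
                 seed_node = cx$seed_node,
                 members = paste(cx$members, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(complex_id = integer(), score = numeric(), size = integer(),
               seed_node = character(), members = character(),
               stringsAsFactors = FALSE)
  }
  write_report(ctab, file.path(out, "complexes.tsv"), "tsv")

  enrichments <- list()
  for (nm in names(config$gmt)) {
    spec <- config$gmt[[nm]]
    res <- stage(paste0("enrich_", nm), {
      coll <- read_gmt(spec$path, universe_size = spec$universe_size,
                       source_name = nm)
      ora(net$nodes, coll, min_overlap = config$min_overlap)
    })
    message(sprintf("[enrich] %s: %d term(s) emitted", nm, nrow(res)))
    enrichments[[nm]] <- res
    write_report(res, file.path(out, sprintf("enrichment-%s.tsv", nm)), "tsv")
  }

  manifest <- list(
    parameters = unclass(config),
    inputs = as.list(tools::md5sum(c(
      config$edges, config$seeds,
      unlist(lapply(config$gmt, `[[`, "path"), use.names = FALSE)))),
    package_version = as.character(utils::packageVersion("seednet")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.remove(marker)

  invisible(list(network = net, topology = topo, backbone = backbone,
                 edge_enrichment = enr, clustering = clustering,
                 switches = switches, complexes = complexes,
                 enrichments = enrichments, out_dir = out))
}
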