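# Pipeline orchestration: a single config drives read -> superpose ->
# correlate -> network -> communities -> paths -> perturbation -> report,
# with one seed feeding every source of randomness so reruns are
# byte-identical.

#' Build a run configuration
#'
#' Either `topology` + `trajectories` (file inputs) or `synthetic` (argument
#' list for [planted_spec()]) must be given. All thresholds carry their
#' conventional defaults: contact 4.5 A at 75% occupancy, hydrophobic 6.5 A,
#' electrostatic 11 A, hydrogen bond 3.5 A / 120 degrees, population report
#' threshold 40%, hub-degree cutoff 10.
#'
#' @param label system label used in reports
#' @param topology path to a PDB topology
#' @param trajectories character vector of trajectory files (one replicate
#'   each)
#' @param synthetic list of [planted_spec()] arguments (the run seed
#'   overrides the spec seed), or `NULL`
#' @param source source node selector: `NULL` (all ligand nodes), 0-based
#'   node ids, or node labels
#' @param sink sink selector: `NULL` (all effector-region nodes), node ids,
#'   node labels, or `list(chain =, resid =)` residue range marked as the
#'   effector region
#' @param stride,window frame selection passed to [read_trajectory()]
#' @param superpose fit frames onto the window mean before analysis;
#'   `NULL` = TRUE for file input, FALSE for synthetic systems (whose
#'   sampler plants no global rigid-body motion)
#' @param occupancy_threshold,contact_cutoff edge definition parameters
#' @param hydrophobic_cutoff,electrostatic_cutoff,hbond_distance,hbond_angle
#'   interaction criteria
#' @param population_threshold strong-interaction report threshold
#' @param degree_cutoff hub-degree report cutoff
#' @param replicate_mode `"consensus"` (per-replicate networks, majority
#'   consensus) or `"pooled"` (frames concatenated into one network)
#' @param weaken `NULL`, `TRUE` (weaken all ligand nodes) or a node selector
#' @param interactions also compute interaction fingerprints (default FALSE)
#' @param seed integer seed for all randomness
#' @return a `dynet_config` list
#' @export
run_config <- function(label = "system",
                       topology = NULL, trajectories = NULL, synthetic = NULL,
                       source = NULL, sink = NULL,
                       stride = 1L, window = NULL, superpose = NULL,
                       occupancy_threshold = 0.75, contact_cutoff = 4.5,
                       hydrophobic_cutoff = 6.5, electrostatic_cutoff = 11,
                       hbond_distance = 3.5, hbond_angle = 120,
                       population_threshold = 0.4, degree_cutoff = 10,
                       replicate_mode = c("consensus", "pooled"),
                       weaken = NULL, interactions = FALSE, seed = 1L) {
  replicate_mode <- match.arg(replicate_mode)
  thr <- c(occupancy_threshold, contact_cutoff, hydrophobic_cutoff,
           electrostatic_cutoff, hbond_distance, hbond_angle,
           population_threshold, degree_cutoff)
  if (any(thr <= 0)) stop("config error: all thresholds must be positive")
  if (occupancy_threshold > 1) stop("config error: occupancy must be in (0,1]")
  if (is.null(synthetic) && (is.null(topology) || is.null(trajectories))) {
    stop("config error: give topology + trajectories, or synthetic")
  }
  structure(list(
    label = label, topology = topology, trajectories = trajectories,
    synthetic = synthetic, source = source, sink = sink,
    stride = as.integer(stride), window = window, superpose = superpose,
    occupancy_threshold = as.numeric(occupancy_threshold),
    contact_cutoff = as.numeric(contact_cutoff),
    hydrophobic_cutoff = as.numeric(hydrophobic_cutoff),
    electrostatic_cutoff = as.numeric(electrostatic_cutoff),
    hbond_distance = as.numeric(hbond_distance),
    hbond_angle = as.numeric(hbond_angle),
    population_threshold = as.numeric(population_threshold),
    degree_cutoff = as.numeric(degree_cutoff),
    replicate_mode = replicate_mode, weaken = weaken,
    interactions = isTRUE(interactions), seed = as.integer(seed)
  ), class = "dynet_config")
}

#' Read a YAML run configuration
#' @param path YAML file with [run_config()] fields
#' @return a `dynet_config`
#' @export
read_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

#' Write a run configuration as YAML
#' @param config a `dynet_config`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(.drop_null(unclass(config)), path)
  invisible(path)
}

.drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

# stable md5 of the canonical JSON serialization of the config
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(.drop_null(unclass(config)), tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

# resolve a node selector to 0-based node ids
.resolve_nodes <- function(sel, nodemap, default_role) {
  if (is.null(sel) || isTRUE(sel)) {
    out <- nodes_by_role(nodemap, default_role)
  } else if (is.list(sel)) {
    m <- nodemap$nodes$resid %in% sel$resid
    if (!is.null(sel$chain)) m <- m & nodemap$nodes$chain == sel$chain
    out <- nodemap$nodes$node_id[m]
  } else if (is.numeric(sel)) {
    out <- as.integer(sel)
  } else {
    out <- nodemap$nodes$node_id[match(sel, nodemap$nodes$name)]
  }
  if (length(out) == 0L || anyNA(out)) {
    stop("config error: node selector matched no nodes")
  }
  sort(out)
}

#' Run the full network pipeline
#'
#' Reads or generates the replicate trajectories, superposes them if
#' requested, builds per-replicate correlation networks (or one pooled
#' network), detects Girvan-Newman communities, traces the shortest
#' regulation path from every source to the sink set with replicate SPL
#' statistics, optionally weakens ligand edges and recomputes, and
#' optionally adds interaction fingerprints. Every artifact is stamped with
#' the config hash and seed.
#'
#' @param config a `dynet_config`
#' @param out_dir if non-NULL, report files (JSON, Markdown, edge/community
#'   TSV, GraphML) are written there
#' @return a `dynet_report` list
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "dynet_config"))
  synth <- !is.null(config$synthetic)
  ground_truth <- NULL
  if (synth) {
    args <- config$synthetic
    args$seed <- config$seed
    spec <- do.call(planted_spec, args)
    geom <- build_geometry(spec, contact_cutoff = config$contact_cutoff)
    trajs <- sample_trajectory(spec, geom)
    nodemap <- geom$nodemap
    ground_truth <- geom$ground_truth
  } else {
    nodemap <- read_topology(config$topology)
    if (is.list(config$sink)) {
      nodemap <- mark_effector(nodemap, config$sink$resid, config$sink$chain)
    }
    trajs <- read_trajectory(config$trajectories, nodemap,
                             stride = config$stride, window = config$window)
  }
  do_fit <- if (is.null(config$superpose)) !synth else isTRUE(config$superpose)
  if (do_fit) trajs <- lapply(trajs, superpose)

  if (config$replicate_mode == "pooled") {
    trajs_net <- list(pool_trajectories(trajs))
  } else {
    trajs_net <- trajs
  }
  nets <- lapply(trajs_net, function(tr) {
    build_network(correlation_matrix(tr),
                  contact_occupancy(tr, cutoff = config$contact_cutoff),
                  nodemap, occ_threshold = config$occupancy_threshold)
  })
  consensus <- consensus_network(nets)

  summary <- network_summary(consensus, degree_cutoff = config$degree_cutoff)
  communities <- girvan_newman(consensus)

  sources <- .resolve_nodes(config$source, nodemap, "ligand")
  sink_set <- if (is.list(config$sink)) {
    .resolve_nodes(NULL, nodemap, "effector-region")
  } else {
    .resolve_nodes(config$sink, nodemap, "effector-region")
  }
  paths <- lapply(sources, function(s) {
    average_spl(nets, s, sink_set, consensus = consensus)
  })
  names(paths) <- nodemap$nodes$name[match(sources, nodemap$nodes$node_id)]
  spl_means <- vapply(paths, function(p) p$mean, numeric(1))

  weakened <- NULL
  if (!is.null(config$weaken) && !isFALSE(config$weaken)) {
    wn <- .resolve_nodes(config$weaken, nodemap, "ligand")
    wcons <- weaken_ligand(consensus, wn)
    wnets <- lapply(nets, weaken_ligand, ligand_nodes = wn)
    wcomm <- tryCatch(girvan_newman(wcons), error = function(e) NULL)
    wpaths <- lapply(sources, function(s) {
      average_spl(wnets, s, sink_set, consensus = wcons)
    })
    names(wpaths) <- names(paths)
    weakened <- list(
      nodes = wn,
      n_communities = if (is.null(wcomm)) NA_integer_ else wcomm$n_communities,
      n_isolated = if (is.null(wcomm)) NA_integer_ else wcomm$n_isolated,
      spl = vapply(wpaths, function(p) p$mean, numeric(1)),
      paths = wpaths
    )
  }

  inter <- NULL
  if (config$interactions) {
    pooled <- if (length(trajs) > 1L) pool_trajectories(trajs) else trajs[[1]]
    rec <- rbind(
      hydrophobic_contacts(pooled, cutoff = config$hydrophobic_cutoff),
      electrostatic_contacts(pooled, cutoff = config$electrostatic_cutoff),
      hydrogen_bonds(pooled, d_cut = config$hbond_distance,
                     angle_cut = config$hbond_angle)
    )
    inter <- list(records = rec,
                  strong = filter_interactions(rec, config$population_threshold))
  }

  report <- structure(list(
    label = config$label,
    seed = config$seed,
    config_hash = .config_hash(config),
    summary = unclass(summary),
    communities = list(n_communities = communities$n_communities,
                       n_isolated = communities$n_isolated,
                       modularity = communities$modularity),
    sources = sources,
    sink_set = sink_set,
    sink_labels = nodemap$nodes$name[match(sink_set, nodemap$nodes$node_id)],
    paths = paths,
    spl = spl_means,
    spl_sum = sum(spl_means),
    weakened = weakened,
    interactions = inter,
    ground_truth = ground_truth,
    network = consensus,
    replicate_networks = nets,
    partition = communities
  ), class = "dynet_report")

  if (!is.null(out_dir)) .write_report(report, config, out_dir)
  report
}

#' @export
print.dynet_report <- function(x, ...) {
  cat("== dynet report:", x$label, "==\n")
  print(structure(x$summary, class = "dynet_summary"))
  cat(sprintf("Communities: %d (%d isolated), modularity %.3f\n",
              x$communities$n_communities, x$communities$n_isolated,
              x$communities$modularity))
  for (nm in names(x$paths)) {
    cat(sprintf("Path from %s: ", nm))
    print(x$paths[[nm]])
  }
  cat(sprintf("Sum of pathway SPLs: %.3f\n", x$spl_sum))
  invisible(x)
}

.report_json <- function(report) {
  paths <- lapply(report$paths, function(p) list(
    replicate_spl = p$replicate_spl, mean = p$mean, sd = p$sd,
    consensus_path = p$consensus_path$labels,
    consensus_length = p$consensus_path$length
  ))
  out <- list(
    label = report$label, seed = report$seed,
    config_hash = report$config_hash,
    summary = report$summary[c("n_nodes", "n_edges", "max_degree",
                               "avg_degree", "n_degree_gt",
                               "max_edge_betweenness",
                               "max_node_betweenness")],
    communities = report$communities,
    sink = report$sink_labels,
    paths = paths,
    spl_sum = report$spl_sum
  )
  if (!is.null(report$weakened)) {
    out$weakened <- report$weakened[c("n_communities", "n_isolated", "spl")]
  }
  if (!is.null(report$interactions)) {
    st <- report$interactions$strong
    out$interactions <- list(
      n_records = nrow(report$interactions$records),
      n_strong = nrow(st),
      strong = st[, c("label_i", "label_j", "type", "population")]
    )
  }
  out
}

.write_report <- function(report, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.report_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_edge_table(report$network, file.path(out_dir, "edges.tsv"))
  utils::write.table(community_table(report$partition, report$network),
                     file.path(out_dir, "communities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_graphml(report$network, file.path(out_dir, "network.graphml"))
  write_config(config, file.path(out_dir, "config.yaml"))
  .write_report_md(report, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

.write_report_md <- function(report, path) {
  s <- report$summary
  lines <- c(
    paste("#", report$label),
    "", paste0("seed ", report$seed, ", config ", report$config_hash), "",
    "## Network parameters", "",
    "| parameter | value |", "|---|---|",
    sprintf("| Number of nodes | %d |", s$n_nodes),
    sprintf("| Edge number | %d |", s$n_edges),
    sprintf("| Max degree | %d |", s$max_degree),
    sprintf("| Avg. degree | %.2f |", s$avg_degree),
    sprintf("| Nodes of degree > %g | %d |", s$degree_cutoff, s$n_degree_gt),
    sprintf("| Max edge betweenness | %.3f |", s$max_edge_betweenness),
    sprintf("| Max node betweenness | %.3f |", s$max_node_betweenness),
    "",
    sprintf("Communities: %d including %d isolated cluster(s); modularity %.3f",
            report$communities$n_communities, report$communities$n_isolated,
            report$communities$modularity),
    "", "## Shortest regulation pathways", "",
    "| source | pathway | nodes | SPL |", "|---|---|---|---|"
  )
  for (nm in names(report$paths)) {
    p <- report$paths[[nm]]
    lines <- c(lines, sprintf(
      "| %s | %s | %d | %.2f ± %.2f |", nm,
      paste(p$consensus_path$labels, collapse = "-"),
      p$consensus_path$n_intermediate, p$mean, p$sd
    ))
  }
  if (!is.null(report$weakened)) {
    lines <- c(lines, "",
               sprintf("After weakening: %d communities (%d isolated); SPL %s",
                       report$weakened$n_communities,
                       report$weakened$n_isolated,
                       paste(sprintf("%.2f", report$weakened$spl),
                             collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Compare systems and compute transfer efficiencies
#'
#' Side-by-side network parameters for a set of pipeline reports sharing a
#' sink definition, with the information-transfer efficiency of every system
#' against a declared reference (reference = 100%).
#'
#' @param reports list of `dynet_report`
#' @param reference label of the reference system (default: first report)
#' @return data frame, one row per system
#' @export
compare_systems <- function(reports, reference = reports[[1]]$label) {
  stopifnot(length(reports) >= 2L)
  sinks <- lapply(reports, function(r) r$sink_labels)
  if (length(unique(vapply(sinks, paste, character(1), collapse = ","))) > 1L) {
    stop("incompatible sink definitions across reports")
  }
  labels <- vapply(reports, function(r) r$label, character(1))
  ref <- match(reference, labels)
  if (is.na(ref)) stop("reference system not among the reports")
  ref_sum <- reports[[ref]]$spl_sum
  do.call(rbind, lapply(reports, function(r) {
    s <- r$summary
    data.frame(
      label = r$label, n_nodes = s$n_nodes, n_edges = s$n_edges,
      max_degree = s$max_degree, avg_degree = s$avg_degree,
      n_degree_gt = s$n_degree_gt,
      max_edge_betweenness = s$max_edge_betweenness,
      max_node_betweenness = s$max_node_betweenness,
      n_communities = r$communities$n_communities,
      n_isolated = r$communities$n_isolated,
      spl_sum = r$spl_sum,
      efficiency = transfer_efficiency(ref_sum, r$spl_sum)
    )
  }))
}
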