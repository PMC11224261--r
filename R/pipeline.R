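## Pipeline orchestration: seeded end-to-end runs writing machine-readable
## reports plus a manifest, wrapped by a thin command-line script
## (inst/cli/coreactnet.R).

file_hash <- function(path) unname(tools::md5sum(path))

write_manifest <- function(out_dir, command, inputs, seed, extra = list()) {
  manifest <- c(list(
    command = command,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = if (file.exists(p)) file_hash(p) else NA)),
    seed = seed,
    tool = "coreactnet",
    version = as.character(utils::packageVersion("coreactnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' YAML mirror of [simulation_config()]: top-level keys `groups` (list of
#' `{name, n_animals}`), optional `regions` (list of
#' `{region, anatomical_group}`), `dapi_mean`, `p_td`, `p_cfos`, `ratio`,
#' `sigma_animal`, and optional `corr` (per-group list of row-lists).
#'
#' @param path Path to the YAML file.
#' @return A `coreact_sim_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) schema_stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) schema_stop("config is missing 'groups'")
  groups <- do.call(rbind, lapply(y$groups, function(g)
    data.frame(name = g$name, n_animals = g$n_animals)))
  regions <- if (!is.null(y$regions))
    do.call(rbind, lapply(y$regions, function(r)
      data.frame(region = r$region, anatomical_group = r$anatomical_group)))
  else default_region_metadata()
  as_mat <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) do.call(cbind, lapply(x, unlist)) else unlist(x)
  }
  corr <- if (!is.null(y$corr))
    lapply(y$corr, function(cm) do.call(rbind, lapply(cm, unlist)))
  else NULL
  simulation_config(
    groups = groups, regions = regions,
    dapi_mean = y$dapi_mean %||% 5000,
    p_td = as_mat(y$p_td) %||% 0.06,
    p_cfos = as_mat(y$p_cfos) %||% 0.03,
    ratio = as_mat(y$ratio) %||% 1,
    sigma_animal = y$sigma_animal %||% 0.3,
    corr = corr)
}

#' Simulate a dataset to disk
#'
#' Generates a synthetic count dataset from a config (YAML path or
#' `coreact_sim_config`) and writes `counts.csv`, `regions.csv`,
#' `ground_truth.json`, and `manifest.json` into `out_dir`.
#'
#' @param config YAML path or `coreact_sim_config` object.
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed.
#' @return Paths of the written files, invisibly.
#' @export
cli_simulate <- function(config, out_dir, seed = 1) {
  cfg <- if (is.character(config)) read_simulation_config(config) else config
  stopifnot(inherits(cfg, "coreact_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- generate_dataset(cfg, seed = substream_seed(seed, "simulate"))
  counts_path <- file.path(out_dir, "counts.csv")
  regions_path <- file.path(out_dir, "regions.csv")
  gt_path <- file.path(out_dir, "ground_truth.json")
  write_counts(counts, counts_path)
  write.csv(cfg$regions, regions_path, row.names = FALSE, quote = FALSE)
  write_ground_truth(counts, gt_path)
  write_manifest(out_dir, "simulate",
                 inputs = if (is.character(config)) list(config = config)
                 else list(),
                 seed = seed)
  invisible(c(counts = counts_path, regions = regions_path,
              ground_truth = gt_path))
}

#' Run the full co-reactivation analysis
#'
#' End-to-end orchestration: reactivation table with chance levels and
#' ratios; per-group correlation matrices; networks under the chosen sign
#' mode with centralities, hubs, communities and topology metrics; pairwise
#' group-label permutation families (edges and centralities) with global BH
#' adjustment; all written as machine-readable files plus a manifest.
#'
#' Written files: `reactivation.csv`, `reactivation_summary.csv` (+ `.json`),
#' `corr_<group>.csv`, `network_<group>.graphml`, `edges_<group>.tsv`,
#' `centralities_<group>.csv`, `hubs_<group>.json`,
#' `communities_<group>.json`, `topology.csv`, `permutation_results.json`,
#' `manifest.json`.
#'
#' @param counts_path Path to the counts CSV.
#' @param regions_path Path to the region metadata CSV (`NULL` for the
#'   built-in panel).
#' @param out_dir Output directory.
#' @param sign_mode Network sign mode (default `"positive"`).
#' @param B Permutation resamples (default 1000).
#' @param seed RNG seed.
#' @param compare Character vector of the two groups compared by the
#'   permutation stage; default the first two non-homecage groups (groups
#'   named `"HC"` are treated as baseline and excluded from comparison).
#' @return Invisibly, a list with the in-memory results.
#' @export
cli_analyze <- function(counts_path, regions_path = NULL, out_dir,
                        sign_mode = "positive", B = 1000, seed = 1,
                        compare = NULL) {
  metadata <- if (is.null(regions_path)) default_region_metadata()
  else read_region_metadata(regions_path)
  counts <- read_counts(counts_path, metadata)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "reactivation"
  res <- tryCatch({
    rows <- reactivation_table(counts)
    write.csv(rows, file.path(out_dir, "reactivation.csv"),
              row.names = FALSE, quote = FALSE)
    summ <- reactivation_summary(rows)
    write.csv(summ, file.path(out_dir, "reactivation_summary.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summ, file.path(out_dir,
                                         "reactivation_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")

    stage <- "networks"
    groups <- unique(rows$group)
    per_group <- list()
    topo <- list()
    for (g in groups) {
      m <- correlation_matrix(rows, g)
      write_corr_csv(m, file.path(out_dir, paste0("corr_", g, ".csv")))
      net <- build_network(m, sign_mode = sign_mode)
      prof <- identify_hubs(compute_centralities(net))
      comm <- detect_communities(net, seed = substream_seed(seed, "community"))
      write_network(net,
                    path_graphml = file.path(out_dir,
                                             paste0("network_", g, ".graphml")),
                    path_tsv = file.path(out_dir, paste0("edges_", g, ".tsv")),
                    profile = prof, communities = comm)
      write.csv(prof, file.path(out_dir, paste0("centralities_", g, ".csv")),
                row.names = FALSE, quote = FALSE)
      jsonlite::write_json(list(group = g, hubs = prof$region[prof$hub]),
                           file.path(out_dir, paste0("hubs_", g, ".json")),
                           auto_unbox = TRUE)
      jsonlite::write_json(list(group = g, Q = comm$Q,
                                membership = as.list(comm$membership)),
                           file.path(out_dir,
                                     paste0("communities_", g, ".json")),
                           auto_unbox = TRUE, digits = NA)
      per_group[[g]] <- list(corr = m, network = net, profile = prof,
                             communities = comm,
                             topology = topology_metrics(net))
      topo[[g]] <- data.frame(group = g,
                              as.data.frame(per_group[[g]]$topology))
    }
    write.csv(do.call(rbind, topo), file.path(out_dir, "topology.csv"),
              row.names = FALSE, quote = FALSE)

    stage <- "permutation"
    compare <- compare %||% setdiff(groups, "HC")[1:2]
    perm <- NULL
    if (length(compare) == 2L && !any(is.na(compare))) {
      pseed <- substream_seed(seed, "permute")
      edges <- permute_edge_family(rows, compare, B = B, seed = pseed,
                                   metadata = metadata)
      cents <- permute_centrality_family(rows, compare,
                                         sign_mode = sign_mode, B = B,
                                         seed = pseed, metadata = metadata)
      perm <- list(edges = edges, centralities = cents)
      jsonlite::write_json(
        list(compare = compare, B = B, seed = seed,
             edges = edges, centralities = cents),
        file.path(out_dir, "permutation_results.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    list(rows = rows, per_group = per_group, permutation = perm)
  }, coreact_error = function(e) {
    coreact_stop("analysis stage '", stage, "' failed: ",
                 conditionMessage(e))
  })
  write_manifest(out_dir, "analyze",
                 inputs = list(counts = counts_path,
                               regions = regions_path %||% "<builtin>"),
                 seed = seed,
                 extra = list(sign_mode = sign_mode, B = B,
                              defaults = list(
                                threshold = "none (sign-only edge filter)",
                                path_length = "1/weight",
                                closeness = "inverse mean shortest path",
                                hub_rule = "top ceil(0.25*N) in >=3 of 4",
                                p_formula = "(# null > empirical)/B")))
  invisible(res)
}
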