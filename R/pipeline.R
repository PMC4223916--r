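#' Default pipeline configuration
#'
#' @param edges path to an edge-list file (or `NULL` when a network is
#'   passed to [run_pipeline()] directly).
#' @param out_dir output directory for all artifacts.
#' @param ... overrides for any default field.
#' @return named list of configuration values.
#' @export
default_config <- function(edges = NULL, out_dir = "flowscope_out", ...) {
  cfg <- list(
    edges = edges,
    out_dir = out_dir,
    delimiter = "\t",
    weighted = TRUE,
    tau = 0.85,
    t_min = 1e-2,
    t_max = 1e1,
    n_times = 40,
    n_runs = 10,
    vi_tol = NULL,
    min_plateau = 5,
    beta = 0.87,
    k_max = "auto",
    gamma = 0.5,
    organigram_k = "auto",
    kmeans_restarts = 50,
    seed = 1L
  )
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Load a pipeline configuration from JSON or YAML
#' @param path config file; fields override [default_config()].
#' @return named configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stopf("yaml package not available")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_config, vals)
}

#' Run the full flow analysis pipeline
#'
#' Largest weakly connected component -> stability sweep -> robust
#' partition selection -> RBS features -> RMST role similarity graph ->
#' role detection -> role mixes of the selected partition -> organigram
#' clustering. All tabular artifacts are written as CSV (partitions per
#' time, sweep summary, roles, mixes), the role similarity graph as
#' GraphML, and a machine-readable `summary.json` holding the resolved
#' configuration, package version, community counts per time, plateaus,
#' role count and organigram labels. Given a fixed master seed the run is
#' deterministic and the summary file is byte-identical across runs.
#'
#' @param cfg configuration list from [default_config()] or
#'   [read_config()].
#' @param net optionally a [directed_network()]; otherwise `cfg$edges` is
#'   read.
#' @param verbose log stage progress.
#' @return (invisibly) list with all intermediate objects and
#'   `summary_path`.
#' @export
run_pipeline <- function(cfg = default_config(), net = NULL, verbose = TRUE) {
  stage <- "config"
  result <- list()
  tryCatch({
    stage <- "read"
    if (is.null(net)) {
      if (is.null(cfg$edges)) stopf("no input network: set cfg$edges")
      net <- read_edge_list(cfg$edges, delimiter = cfg$delimiter,
                            weighted = cfg$weighted, verbose = verbose)
    }
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "lcc"
    lcc <- largest_weakly_connected_component(net)
    if (verbose) fs_log(stage, sprintf("kept %d of %d nodes", lcc$N, net$N))

    stage <- "sweep"
    times <- 10^seq(log10(cfg$t_min), log10(cfg$t_max),
                    length.out = cfg$n_times)
    sw <- stability_sweep(lcc, times = times, n_runs = cfg$n_runs,
                          tau = cfg$tau, seed = cfg$seed, verbose = FALSE)
    utils::write.csv(summary.partition_sequence(sw),
                     file.path(cfg$out_dir, "sweep_summary.csv"),
                     row.names = FALSE)
    write_partition_table(sw, file.path(cfg$out_dir, "partitions.csv"))

    stage <- "plateaus"
    wins <- select_robust_partitions(sw, vi_tol = cfg$vi_tol,
                                     min_plateau = cfg$min_plateau)
    if (verbose) fs_log(stage, sprintf("%d plateau(s)", length(wins)))

    stage <- "rbs"
    Xf <- build_feature_matrix(lcc, beta = cfg$beta, k_max = cfg$k_max)
    Y <- cosine_similarity(Xf)

    stage <- "rmst"
    rsg <- rmst(similarity_to_distance(Y), gamma = cfg$gamma, Y = Y)
    write_graphml(rsg_as_network(rsg),
                  file.path(cfg$out_dir, "role_similarity.graphml"))

    stage <- "roles"
    roles <- detect_roles(rsg, lcc, n_runs = cfg$n_runs,
                          seed = derive_seed(cfg$seed, 999983L))
    write_partition_csv(roles$roles, file.path(cfg$out_dir, "roles.csv"))
    if (verbose) fs_log(stage, sprintf("%d role(s)", roles$n_roles))

    stage <- "mixes"
    ref_part <- if (length(wins) > 0) {
      wins[[length(wins)]]$partition  # coarsest robust partition
    } else {
      sw$partitions[[ceiling(length(times) / 2)]]
    }
    mix <- role_mix(ref_part, roles)
    utils::write.csv(data.frame(community = rownames(mix), mix,
                                check.names = FALSE),
                     file.path(cfg$out_dir, "role_mixes.csv"),
                     row.names = FALSE)

    stage <- "organigrams"
    org <- if (nrow(mix) >= 2) {
      cluster_role_mixes(mix, k = cfg$organigram_k,
                         n_restarts = cfg$kmeans_restarts,
                         seed = derive_seed(cfg$seed, 999979L))
    } else NULL

    stage <- "summary"
    summary_path <- file.path(cfg$out_dir, "summary.json")
    summ <- list(
      package_version = as.character(utils::packageVersion("flowscope")),
      config = cfg[order(names(cfg))],
      n_nodes = lcc$N,
      n_edges = n_edges(lcc),
      times = sw$times,
      k_per_time = sw$k,
      stability_per_time = sw$stability,
      vi_runs_per_time = sw$vi_runs,
      plateaus = lapply(wins, function(w)
        list(t_start = w$t_start, t_end = w$t_end, k = w$k)),
      n_roles = roles$n_roles,
      organigram = if (!is.null(org))
        list(k = org$k, labels = as.list(org$cluster)) else NULL
    )
    jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = 17,
                         pretty = TRUE, null = "null")
    result <- list(net = lcc, sweep = sw, plateaus = wins, features = Xf,
                   similarity = Y, rsg = rsg, roles = roles, mix = mix,
                   organigrams = org, summary_path = summary_path)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}

# All-times partition table: one row per node, one column per Markov time
# (header = time at 17 significant digits).
write_partition_table <- function(sw, path) {
  tab <- do.call(cbind, lapply(sw$partitions, unname))
  colnames(tab) <- format(sw$times, digits = 17, trim = TRUE)
  df <- data.frame(node = sw$labels, tab, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
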