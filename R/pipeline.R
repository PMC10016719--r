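#' Default end-to-end demo configuration
#'
#' A small synthetic study: three electrophysiological archetypes of
#' synthetic neurons, one channel family with three kinetic archetypes, and
#' per-cell conductance files referencing the channel models.
#'
#' @param out_dir Output directory for stage tables and the run manifest.
#' @param seed Master seed; each stage derives its own sub-seed from it.
#' @return A named config list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("neurochar_run_"),
                                    seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("synth", "features", "complexity", "cluster_cells",
               "cluster_channels", "ncd"),
    n_per_archetype = 4,
    min_cluster_size = 4,
    channel_family = "Kv",
    n_channel_archetypes = 3,
    channel_n_per_range = c(4, 10),
    channel_grid_points = 128,
    runtime_step = 1e-5,
    n_boot = 1000
  )
}

validate_config <- function(config) {
  stop_if_not(is.list(config), "config must be a list or a YAML/JSON path")
  required <- c("seed", "out_dir", "stages")
  missing <- setdiff(required, names(config))
  stop_if_not(length(missing) == 0,
              paste0("config schema violation: missing field(s) ",
                     paste(missing, collapse = ", ")))
  known <- c("synth", "features", "complexity", "cluster_cells",
             "cluster_channels", "ncd")
  bad <- setdiff(config$stages, known)
  stop_if_not(length(bad) == 0,
              paste0("config schema violation: unknown stage(s) ",
                     paste(bad, collapse = ", ")))
  defaults <- default_pipeline_config(config$out_dir, config$seed)
  utils::modifyList(defaults, config)
}

# three stylized electrophysiology archetypes: regular, delayed, fast
demo_neuron_population <- function(n_per_archetype, seed) {
  arch <- list(
    regular = list(rheobase_na = 0.2, delay_ms = 40, isi_base_ms = 50,
                   accommodation_rate = 1.02),
    delayed = list(rheobase_na = 0.3, delay_ms = 300, isi_base_ms = 60,
                   accommodation_rate = 1.0),
    fast    = list(rheobase_na = 0.15, delay_ms = 15, isi_base_ms = 12,
                   accommodation_rate = 1.0, freq_band = c(40, 120))
  )
  specs <- list()
  jit <- with_seed(seed, rnorm(3 * n_per_archetype * 4, sd = 0.05))
  j <- 0
  for (a in names(arch)) {
    for (i in seq_len(n_per_archetype)) {
      p <- arch[[a]]
      specs[[sprintf("%s_%02d", a, i)]] <- synthetic_neuron(
        rheobase_na = p$rheobase_na * (1 + jit[j + 1]),
        delay_ms = p$delay_ms * (1 + jit[j + 2]),
        isi_base_ms = p$isi_base_ms * (1 + jit[j + 3]),
        accommodation_rate = p$accommodation_rate,
        freq_band = p$freq_band,
        noise_sd = 0.1,
        seed = seed + j)
      j <- j + 4
    }
  }
  specs
}

#' Run the characterization pipeline end to end
#'
#' Executes the requested stages in dependency order — synthesize inputs,
#' extract features, fit complexity, cluster cell models, cluster channel
#' models, integrate NCDs — writing each stage's tables as delimited text
#' under `out_dir` and a JSON run manifest (config snapshot, seeds, file
#' hashes, timestamps). Deterministic stages are byte-identical across
#' reruns with the same config.
#'
#' @param config A config list (see [default_pipeline_config()]) or a path
#'   to a YAML/JSON file holding one.
#' @return Invisibly, a list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  res <- list()
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    utils::write.table(as.data.frame(df), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  if ("synth" %in% stages) {
    res$neurons <- demo_neuron_population(config$n_per_archetype, config$seed)
    chan <- generate_channel_archetype_set(
      config$channel_family, config$n_channel_archetypes,
      n_per_range = config$channel_n_per_range, seed = config$seed + 1)
    res$channel_specs <- chan$specs
    res$channel_truth <- chan$truth
    cond <- generate_cell_conductance_files(
      n_cells = length(res$neurons),
      channel_ids = names(chan$specs),
      dir = file.path(config$out_dir, "nml"),
      seed = config$seed + 2)
    res$conductance_paths <- cond$paths
    res$conductance_truth <- cond$truth
  }

  if ("features" %in% stages) {
    stop_if_not(!is.null(res$neurons), "missing upstream artifact: synth")
    raw <- compute_feature_matrix(res$neurons)
    res$features_raw <- raw
    res$features <- prepare_feature_matrix(raw)
    emit(raw, "features_raw")
    emit(res$features, "features_prepared")
  }

  if ("complexity" %in% stages) {
    stop_if_not(!is.null(res$neurons), "missing upstream artifact: synth")
    ids <- names(res$neurons)
    base_true <- with_seed(config$seed + 3,
                           stats::runif(length(ids), 800, 4000))
    ap_true <- with_seed(config$seed + 4,
                         stats::runif(length(ids), 50, 400))
    fits <- purrr::map(seq_along(ids), function(i) {
      series <- complexity_current_series(res$neurons[[i]]$rheobase_na,
                                          0.9 * res$neurons[[i]]$rheobase_na)
      tbl <- generate_step_count_table(base_true[i], ap_true[i], series,
                                       ap_counts = c(0L, 0L, 2L * (1:11)),
                                       counting_noise = "poisson",
                                       seed = config$seed + 10 + i)
      fit_step_model(tbl)
    })
    names(fits) <- ids
    rts <- setNames(rep(config$runtime_step, length(ids)), ids)
    res$complexity <- complexity_report(fits, rts, reference = ids[1])
    emit(res$complexity, "complexity_report")
  }

  if ("cluster_cells" %in% stages) {
    stop_if_not(!is.null(res$features), "missing upstream artifact: features")
    res$cell_tree <- run_nested_clustering(
      res$features, min_cluster_size = config$min_cluster_size,
      seed = config$seed)
    emit(res$cell_tree$assignments, "cell_cluster_assignments")
  }

  if ("cluster_channels" %in% stages) {
    stop_if_not(!is.null(res$channel_specs),
                "missing upstream artifact: synth")
    responses <- generate_channel_response_set(res$channel_specs)
    res$channels <- characterize_channels(
      responses, grid_points = config$channel_grid_points)
    emit(res$channels$scores, "channel_family_scores")
    emit(res$channels$clusters$labels, "channel_cluster_labels")
  }

  if ("ncd" %in% stages) {
    stop_if_not(!is.null(res$channels),
                "missing upstream artifact: cluster_channels")
    stop_if_not(!is.null(res$cell_tree),
                "missing upstream artifact: cluster_cells")
    table <- read_conductance_table(res$conductance_paths,
                                    names(res$channel_specs))
    ncd <- integrate_cluster_density(normalize_densities(table),
                                     res$channels$clusters$labels)
    # map cell documents onto the clustered neuron models by position
    cell_clusters <- tibble(
      cell_id = ncd$cell_id,
      cluster = res$cell_tree$assignments$final_label)
    res$ncd <- ncd
    res$ncd_summary <- summarize_ncd(ncd, cell_clusters,
                                     n_boot = config$n_boot,
                                     seed = config$seed + 5)
    emit(ncd, "ncd_matrix")
    emit(res$ncd_summary, "ncd_summary")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("neurochar")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config[setdiff(names(config), "out_dir")],
    outputs = lapply(setNames(outputs, basename(outputs)), file_hash)
  )
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
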