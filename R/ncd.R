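#' Parse somatic conductance densities from a NeuroML-subset XML file
#'
#' Reads the `channelDensity` elements of a NeuroML cell file and returns
#' the somatic conductance density of each requested channel in mS/cm2.
#' "Somatic" means the element's `segmentGroup` attribute matches
#' `soma_pattern` (default: any group name containing "soma"); densities on
#' other segment groups are ignored. A channel listed in `channel_ids` but
#' absent from the file gets exactly 0. When several somatic elements
#' reference the same channel, their (area-unweighted) mean is used.
#'
#' Recognized density units: `S_per_cm2`, `mS_per_cm2`, `S_per_m2`.
#'
#' @param path Path to the XML document.
#' @param channel_ids Character vector of channel model ids (columns of the
#'   conductance table).
#' @param soma_pattern Regular expression identifying somatic segment
#'   groups.
#' @param cell_id Identifier for the row (defaults to the file name).
#' @return One-row tibble: `cell_id` plus one mS/cm2 column per channel.
#' @export
parse_somatic_densities <- function(path, channel_ids,
                                    soma_pattern = "soma",
                                    cell_id = NULL) {
  doc <- xml2::read_xml(path)  # errors on malformed XML
  cell_id <- cell_id %||% sub("\\.[^.]*$", "", basename(path))
  nodes <- xml2::xml_find_all(doc, "//*[local-name()='channelDensity']")
  vals <- setNames(rep(0, length(channel_ids)), channel_ids)
  acc <- lapply(vals, function(...) numeric(0))
  for (nd in nodes) {
    grp <- xml2::xml_attr(nd, "segmentGroup")
    if (is.na(grp) || !grepl(soma_pattern, grp, ignore.case = TRUE)) next
    ch <- xml2::xml_attr(nd, "ionChannel")
    if (!(ch %in% channel_ids)) next
    acc[[ch]] <- c(acc[[ch]],
                   parse_density_value(xml2::xml_attr(nd, "condDensity")))
  }
  for (ch in channel_ids) if (length(acc[[ch]]) > 0) vals[ch] <- mean(acc[[ch]])
  dplyr::bind_cols(tibble(cell_id = cell_id), as_tibble(as.list(vals)))
}

# "0.12 S_per_cm2" -> 120 (mS/cm2)
parse_density_value <- function(s) {
  stop_if_not(!is.na(s), "channelDensity element lacks condDensity")
  parts <- strsplit(trimws(s), "\\s+")[[1]]
  stop_if_not(length(parts) == 2, paste0("unparseable density: '", s, "'"))
  num <- suppressWarnings(as.numeric(parts[1]))
  stop_if_not(is.finite(num), paste0("unparseable density value: '", s, "'"))
  factor <- switch(parts[2],
                   S_per_cm2 = 1000,
                   mS_per_cm2 = 1,
                   S_per_m2 = 0.1,
                   abort(paste0("unparseable density unit: '", parts[2], "'")))
  num * factor
}

#' Read a conductance table from many NeuroML files
#'
#' @param paths Character vector of file paths.
#' @param channel_ids Channel model ids.
#' @inheritParams parse_somatic_densities
#' @return Tibble: one row per cell, one mS/cm2 column per channel.
#' @export
read_conductance_table <- function(paths, channel_ids, soma_pattern = "soma") {
  purrr::map_dfr(paths, parse_somatic_densities, channel_ids = channel_ids,
                 soma_pattern = soma_pattern)
}

#' Scale each channel column by its maximum across cells
#'
#' Column-wise max scaling: each channel's densities are divided by the
#' largest value observed across the cell models, preserving each column's
#' statistical structure while mapping it onto `[0, 1]`. All-zero columns
#' are left as zeros.
#'
#' @param table Conductance tibble (`cell_id` + numeric channel columns,
#'   values `>= 0`).
#' @return The scaled tibble.
#' @export
normalize_densities <- function(table) {
  out <- as_tibble(table)
  for (col in names(out)[vapply(out, is.numeric, logical(1))]) {
    x <- out[[col]]
    stop_if_not(all(x >= 0), paste0("negative density in column '", col, "'"))
    mx <- max(x)
    if (mx > 0) out[[col]] <- x / mx
  }
  out
}

#' Integrate scaled densities over channel clusters (NCD)
#'
#' For each cell and each discovered channel cluster, the cell's max-scaled
#' densities over the cluster's member channels are summed, yielding the
#' normalized channel density (NCD): a non-negative, unitless measure of the
#' summed presence of that channel cluster in the cell model.
#'
#' @param scaled Scaled conductance tibble from [normalize_densities()].
#' @param channel_clusters Tibble `model_id` (channel id), `cluster` — e.g.
#'   the `$labels` of [cluster_channels()]. Every channel column must be
#'   labeled.
#' @return Tibble: `cell_id` plus one `ncd_<cluster>` column per channel
#'   cluster.
#' @export
integrate_cluster_density <- function(scaled, channel_clusters) {
  chans <- names(scaled)[vapply(scaled, is.numeric, logical(1))]
  unlabeled <- setdiff(chans, channel_clusters$model_id)
  stop_if_not(length(unlabeled) == 0,
              paste0("unlabeled channel(s): ", paste(unlabeled, collapse = ", ")))
  cl <- channel_clusters$cluster[match(chans, channel_clusters$model_id)]
  out <- tibble(cell_id = scaled$cell_id)
  for (k in sort(unique(cl))) {
    member_cols <- chans[cl == k]
    out[[paste0("ncd_", k)]] <-
      rowSums(as.matrix(scaled[, member_cols, drop = FALSE]))
  }
  out
}

#' Bootstrap summaries of NCDs per cell cluster
#'
#' For every (cell cluster, channel cluster) pair, the mean NCD over the
#' cluster's cell models plus a seeded percentile-bootstrap confidence
#' interval obtained by resampling cells with replacement. All models are
#' used — no outlier exclusion enters the summaries.
#'
#' @param ncd NCD tibble from [integrate_cluster_density()].
#' @param cell_clusters Tibble `cell_id`, `cluster`; every cell must be
#'   labeled and every cluster non-empty.
#' @param n_boot Number of bootstrap resamples (`>= 100`).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `cell_cluster`, `channel_cluster`, `n_cells`, `mean_ncd`,
#'   `ci_lo`, `ci_hi`.
#' @export
summarize_ncd <- function(ncd, cell_clusters, n_boot = 10000, seed = 1L,
                          conf = 0.95) {
  stop_if_not(n_boot >= 100, "n_boot must be >= 100")
  unlabeled <- setdiff(ncd$cell_id, cell_clusters$cell_id)
  stop_if_not(length(unlabeled) == 0,
              paste0("unlabeled cell(s): ", paste(unlabeled, collapse = ", ")))
  ncd_cols <- names(ncd)[vapply(ncd, is.numeric, logical(1))]
  lab <- cell_clusters$cluster[match(ncd$cell_id, cell_clusters$cell_id)]
  alpha <- (1 - conf) / 2
  purrr::map_dfr(sort(unique(cell_clusters$cluster)), function(cc) {
    rows <- which(lab == cc)
    stop_if_not(length(rows) > 0, paste0("empty cell cluster: ", cc))
    n <- length(rows)
    idx <- with_seed(seed + as.integer(factor(cc,
             levels = sort(unique(cell_clusters$cluster)))),
           matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot))
    purrr::map_dfr(ncd_cols, function(col) {
      v <- ncd[[col]][rows]
      boot_means <- rowMeans(matrix(v[idx], nrow = n_boot))
      ci <- quantile(boot_means, c(alpha, 1 - alpha), names = FALSE,
                     type = 7)
      tibble(cell_cluster = cc, channel_cluster = col, n_cells = n,
             mean_ncd = mean(v), ci_lo = ci[1], ci_hi = ci[2])
    })
  })
}

#' Flag outliers in a low-dimensional property space
#'
#' The visualization stages can restrict plotted models to those with
#' `|z| < z_max` on every supplied axis; this filter affects plots only and
#' never the NCD summary statistics.
#'
#' @param data Data frame of plotted properties.
#' @param cols Columns to screen.
#' @param z_max Z-score magnitude threshold (default 3).
#' @return Logical vector, `TRUE` = keep for plotting.
#' @export
plot_inlier_filter <- function(data, cols, z_max = 3) {
  z <- vapply(cols, function(col) {
    x <- data[[col]]
    abs((x - mean(x)) / sd_pop(x)) < z_max
  }, logical(nrow(data)))
  apply(z, 1, all)
}
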