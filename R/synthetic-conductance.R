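#' Generate synthetic NeuroML-subset cell conductance files
#'
#' Writes one XML document per cell containing `channelDensity` elements
#' with somatic (and optionally dendritic) segment-group attribution and
#' explicit units. Channels absent from a cell are genuinely absent from its
#' file, not written as zero. Somatic densities are drawn from a log-normal
#' law; the true somatic values in mS/cm2 are returned so the parser can be
#' validated against them.
#'
#' @param n_cells Number of cell documents.
#' @param channel_ids Channel model identifiers.
#' @param density_law List `meanlog`, `sdlog` of the log-normal somatic
#'   density law in S/cm2 (both finite; resulting densities are positive).
#' @param p_present Probability a given channel is present in a given cell.
#' @param p_dendritic Probability a present channel also gets a dendritic
#'   density element (ignored by the somatic parser).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; fixed seed gives byte-identical documents.
#' @return List: `paths` (files written), `truth` (tibble `cell_id` + one
#'   true somatic mS/cm2 column per channel; absent channels are 0).
#' @export
generate_cell_conductance_files <- function(n_cells, channel_ids,
                                            density_law = list(meanlog = log(0.05),
                                                               sdlog = 0.5),
                                            p_present = 0.8,
                                            p_dendritic = 0.3,
                                            dir = tempfile("nml_cells_"),
                                            seed = 1L) {
  stop_if_not(is_number(density_law$meanlog) && is_number(density_law$sdlog) &&
                density_law$sdlog >= 0,
              "negative density parameter: density_law needs finite meanlog and non-negative sdlog")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  draws <- with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      present <- runif(length(channel_ids)) < p_present
      soma <- exp(rnorm(length(channel_ids), density_law$meanlog,
                        density_law$sdlog))
      dend <- exp(rnorm(length(channel_ids), density_law$meanlog,
                        density_law$sdlog))
      has_dend <- runif(length(channel_ids)) < p_dendritic
      list(present = present, soma = soma, dend = dend, has_dend = has_dend)
    })
  })
  paths <- character(n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell_id <- sprintf("cell_%03d", i)
    dr <- draws[[i]]
    doc <- xml2::xml_new_root("neuroml",
                              xmlns = "http://www.neuroml.org/schema/neuroml2",
                              id = paste0("doc_", cell_id))
    cell <- xml2::xml_add_child(doc, "cell", id = cell_id)
    bio <- xml2::xml_add_child(cell, "biophysicalProperties",
                               id = paste0(cell_id, "_biophys"))
    mem <- xml2::xml_add_child(bio, "membraneProperties")
    for (j in seq_along(channel_ids)) {
      if (!dr$present[j]) next
      xml2::xml_add_child(
        mem, "channelDensity",
        id = paste0(channel_ids[j], "_soma"),
        ionChannel = channel_ids[j],
        condDensity = sprintf("%.6g S_per_cm2", dr$soma[j]),
        segmentGroup = "soma_group")
      if (dr$has_dend[j]) {
        xml2::xml_add_child(
          mem, "channelDensity",
          id = paste0(channel_ids[j], "_dend"),
          ionChannel = channel_ids[j],
          condDensity = sprintf("%.6g S_per_cm2", dr$dend[j]),
          segmentGroup = "dendrite_group")
      }
    }
    paths[i] <- file.path(dir, paste0(cell_id, ".nml"))
    xml2::write_xml(doc, paths[i])
    vals <- ifelse(dr$present, dr$soma * 1000, 0)  # S/cm2 -> mS/cm2
    truth[[i]] <- dplyr::bind_cols(tibble(cell_id = cell_id),
                                   as_tibble(as.list(setNames(vals,
                                                              channel_ids))))
  }
  list(paths = paths, truth = dplyr::bind_rows(truth))
}
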