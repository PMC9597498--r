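#' Write a band power table as tidy CSV
#'
#' One row per entity and band with absolute and relative power, plus a
#' companion `<path>_ratios.csv` with TAR/DAR/TBR/TB2R when ratios are
#' filled.
#'
#' @param table A `band_power_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_band_power_csv <- function(table, path) {
  stopifnot(inherits(table, "band_power_table"))
  long <- do.call(rbind, lapply(seq_along(table$labels), function(i)
    data.frame(entity = table$labels[i],
               band = colnames(table$absolute),
               absolute = table$absolute[i, ],
               relative = if (is.null(table$relative)) NA_real_ else
                 table$relative[i, ],
               row.names = NULL)))
  utils::write.csv(long, path, row.names = FALSE)
  if (!is.null(table$ratios)) {
    rp <- sub("\\.csv$", "_ratios.csv", path)
    utils::write.csv(data.frame(entity = table$labels, table$ratios,
                                row.names = NULL), rp, row.names = FALSE)
  }
  invisible(path)
}

#' Write a connectivity matrix (or binary graph) as labeled CSV
#'
#' @param m Square labeled matrix (`connectivity_matrix` or
#'   `binary_graph`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(m, path) {
  utils::write.csv(data.frame(roi = rownames(m), unclass(m),
                              check.names = FALSE, row.names = NULL),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write graph metrics as tidy CSV
#'
#' Nodal rows (`metric` in degree/clustering/path_length) followed by
#' global rows with `node = "(global)"`.
#'
#' @param metrics A `graph_metrics` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  stopifnot(inherits(metrics, "graph_metrics"))
  nodal <- metrics$nodal
  long <- rbind(
    data.frame(node = nodal$node, metric = "degree", value = nodal$degree),
    data.frame(node = nodal$node, metric = "clustering",
               value = nodal$clustering),
    data.frame(node = nodal$node, metric = "path_length",
               value = nodal$path_length),
    data.frame(node = "(global)",
               metric = c("path_length", "clustering", "small_worldness",
                          "unreachable_frac"),
               value = c(metrics$global$L, metrics$global$C,
                         metrics$global$sigma,
                         metrics$global$unreachable_frac)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
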