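#' Read and write spike rasters
#'
#' Rasters are exchanged as headered TSV with columns `unit_id` (integer,
#' 1-based), `time_ms` (double) and `kind` (`net`/`stim`), sorted by time.
#'
#' @param raster an `nc_raster`.
#' @param path file path.
#' @param duration stored in a `# duration_ms:` comment line and restored on
#'   read.
#' @return `read_raster()` returns an `nc_raster`; writers return `path`
#'   invisibly.
#' @export
write_raster <- function(raster, path, duration = raster_duration(raster)) {
  con <- file(path, "w")
  writeLines(paste0("# duration_ms: ", format(duration, digits = 15)), con)
  close(con)
  readr::write_tsv(tibble(unit_id = raster$unit, time_ms = raster$time_ms,
                          kind = raster$kind),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  first <- readLines(path, n = 1)
  dur <- if (grepl("^# duration_ms:", first)) {
    as.numeric(sub("^# duration_ms:\\s*", "", first))
  } else {
    NA_real_
  }
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (is.na(dur)) dur <- max(d$time_ms)
  new_raster(d$unit_id, d$time_ms, d$kind, dur)
}

#' Read and write weight matrices
#'
#' The dense `N x N` weight matrix goes to a plain numeric TSV (rows =
#' source, columns = target); a JSON sidecar (`<path>.json`) carries the
#' external and inhibitory masks, `K_ext` and the seeds.
#'
#' @param w weight matrix.
#' @param topology the matching `nc_topology`.
#' @param path TSV path.
#' @param seeds named list of seeds to record.
#' @export
write_weights <- function(w, topology, path, seeds = list()) {
  readr::write_tsv(as.data.frame(w), path, col_names = FALSE)
  meta <- list(N = topology$N, K_ext = topology$K_ext,
               N_inh = topology$N_inh, mode = topology$mode,
               topology_seed = topology$seed, seeds = seeds,
               ext = as.integer(topology$ext), inh = as.integer(topology$inh))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  w <- as.matrix(readr::read_tsv(path, col_names = FALSE,
                                 show_col_types = FALSE))
  dimnames(w) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  topo <- structure(list(N = meta$N, K_ext = meta$K_ext, N_inh = meta$N_inh,
                         mode = meta$mode, seed = meta$topology_seed,
                         ext = matrix(meta$ext, meta$N, meta$N),
                         inh = matrix(meta$inh, meta$N, meta$N)),
                    class = "nc_topology")
  list(w = w, topology = topo, seeds = meta$seeds)
}
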